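variable	category	code
GenSize	<5Mb	1
GenSize	5-7Mb	2
GenSize	7-9Mb	3
GenSize	>9Mb	4
GCpct	<60	1
GCpct	60-65	2
GCpct	65-70	3
GCpct	>70	4
Temp	psychrophile	1
Temp	mesophile	2
Temp	thermophile	3
Mot	non-motile	1
Mot	motile	2
OxyReq	anaerobe	1
OxyReq	facultative	2
OxyReq	microaerophile	3
OxyReq	aerobe	4
Spor	non-sporulating	1
Spor	sporulating	2
CellArr	single	1
CellArr	pairs-chains	2
CellArr	filaments	3
CellArr	mycelium	4
HostDep	free-living	1
HostDep	facultative-host	2
HostDep	obligate-host	3
HostKind	none	1
HostKind	plant	2
HostKind	animal	3
TPKNRP	<metric>	metric
otherSM	<metric>	metric
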
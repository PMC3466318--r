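species_id	architecture	count
Acidothermus cellulolyticus 11B	REC+LuxR	6
Arthrobacter aurescens TC1	REC+LuxR	5
Arthrobacter aurescens TC1	LuxR	11
Arthrobacter chlorophenolicus A6	REC+LuxR	5
Arthrobacter chlorophenolicus A6	LuxR	11
Arthrobacter chlorophenolicus A6	AAA+LuxR	1
Arthrobacter sp. FB24	REC+LuxR	5
Arthrobacter sp. FB24	LuxR	9
Bifidobacterium adolescentis ATCC15703	REC+LuxR	7
Bifidobacterium animalis subsp. lactis AD011	REC+LuxR	5
Bifidobacterium longum DJO10A	REC+LuxR	4
Bifidobacterium longum subsp. infantis ATCC15697	REC+LuxR	14
Clavibacter michiganensis subsp. michiganensis NCPPB 382	REC+LuxR	13
Clavibacter michiganensis subsp. michiganensis NCPPB 382	LuxR	4
Clavibacter michiganensis subsp. sepedonicus	REC+LuxR	10
Clavibacter michiganensis subsp. sepedonicus	LuxR	5
Corynebacterium aurimucosum ATCC 700975	REC+LuxR	7
Corynebacterium aurimucosum ATCC 700975	LuxR	1
Corynebacterium diphtheriae NCTC 13129	REC+LuxR	5
Corynebacterium diphtheriae NCTC 13129	LuxR	1
Corynebacterium efficiens YS-314	REC+LuxR	6
Corynebacterium efficiens YS-314	LuxR	4
Corynebacterium glutamicum R	REC+LuxR	5
Corynebacterium glutamicum R	LuxR	3
Corynebacterium jeikeium K411	REC+LuxR	3
Corynebacterium jeikeium K411	LuxR	1
Corynebacterium urealyticum DSM 7109	REC+LuxR	3
Corynebacterium urealyticum DSM 7109	LuxR	1
Frankia alni ACN14a	REC+LuxR	13
Frankia alni ACN14a	LuxR	12
Frankia sp. CcI3	REC+LuxR	6
Frankia sp. CcI3	LuxR	12
Frankia sp. EAN1pec	REC+LuxR	31
Frankia sp. EAN1pec	LuxR	16
Frankia sp. EAN1pec	AAA+LuxR	1
Kineococcus radiotolerans SRS30216	REC+LuxR	18
Kineococcus radiotolerans SRS30216	LuxR	10
Kocuria rhizophila DC2201	REC+LuxR	7
Kocuria rhizophila DC2201	LuxR	1
Leifsonia xyli subsp. xyli str. CTCB07	REC+LuxR	7
Leifsonia xyli subsp. xyli str. CTCB07	LuxR	7
Mycobacterium abscessus ATCC 19977	REC+LuxR	6
Mycobacterium abscessus ATCC 19977	LuxR	3
Mycobacterium avium 104	REC+LuxR	4
Mycobacterium avium 104	LuxR	2
Mycobacterium avium 104	HDc+LuxR	1
Mycobacterium avium 104	AAA+LuxR	1
Mycobacterium bovis BCG str. Pasteur 1173P2	REC+LuxR	2
Mycobacterium bovis BCG str. Pasteur 1173P2	LuxR	2
Mycobacterium bovis BCG str. Pasteur 1173P2	CHD+LuxR	3
Mycobacterium bovis BCG str. Tokyo 172	REC+LuxR	2
Mycobacterium bovis BCG str. Tokyo 172	LuxR	2
Mycobacterium bovis BCG str. Tokyo 172	CHD+LuxR	3
Mycobacterium gilvum PYR-GCK	REC+LuxR	6
Mycobacterium gilvum PYR-GCK	LuxR	8
Mycobacterium gilvum PYR-GCK	HDc+LuxR	1
Mycobacterium leprae Br4923	LuxR	1
Mycobacterium leprae TN	LuxR	1
Mycobacterium marinum M	REC+LuxR	5
Mycobacterium marinum M	LuxR	4
Mycobacterium marinum M	CHD+LuxR	2
Mycobacterium smegmatis str. MC2 155	REC+LuxR	13
Mycobacterium smegmatis str. MC2 155	LuxR	18
Mycobacterium smegmatis str. MC2 155	AAA+LuxR	1
Mycobacterium sp. JLS	REC+LuxR	7
Mycobacterium sp. JLS	LuxR	12
Mycobacterium sp. JLS	HDc+LuxR	1
Mycobacterium sp. JLS	AAA+LuxR	1
Mycobacterium sp. KMS	REC+LuxR	7
Mycobacterium sp. KMS	LuxR	10
Mycobacterium sp. KMS	HDc+LuxR	1
Mycobacterium sp. MCS	REC+LuxR	7
Mycobacterium sp. MCS	LuxR	10
Mycobacterium sp. MCS	HDc+LuxR	1
Mycobacterium tuberculosis H37Ra	REC+LuxR	2
Mycobacterium tuberculosis H37Ra	LuxR	2
Mycobacterium tuberculosis H37Ra	CHD+LuxR	3
Mycobacterium tuberculosis H37Rv	REC+LuxR	2
Mycobacterium tuberculosis H37Rv	LuxR	2
Mycobacterium tuberculosis H37Rv	CHD+LuxR	3
Mycobacterium ulcerans Agy99	REC+LuxR	3
Mycobacterium ulcerans Agy99	LuxR	2
Mycobacterium vanbaalenii PYR-1	REC+LuxR	11
Mycobacterium vanbaalenii PYR-1	LuxR	16
Mycobacterium vanbaalenii PYR-1	HDc+LuxR	1
Mycobacterium vanbaalenii PYR-1	AAA+LuxR	1
Mycobacterium vanbaalenii PYR-1	CHD+LuxR	1
Nocardia farcinica	REC+LuxR	14
Nocardia farcinica	LuxR	13
Nocardia farcinica	FHA+LuxR	1
Nocardioides sp. JS614	REC+LuxR	14
Nocardioides sp. JS614	LuxR	11
Nocardioides sp. JS614	HDc+LuxR	2
Propionibacterium acnes KPA171202	REC+LuxR	6
Renibacterium salmoninarum ATCC 33209	REC+LuxR	4
Renibacterium salmoninarum ATCC 33209	LuxR	5
Rhodococcus erythropolis PR4	REC+LuxR	20
Rhodococcus erythropolis PR4	LuxR	12
Rhodococcus erythropolis PR4	PKc+TPR+LuxR	1
Rhodococcus opacus B4	REC+LuxR	17
Rhodococcus opacus B4	LuxR	23
Rhodococcus opacus B4	PKc+LuxR	6
Rhodococcus opacus B4	HDc+LuxR	1
Rhodococcus opacus B4	FHA+LuxR	1
Rhodococcus opacus B4	TPR+LuxR	1
Rhodococcus opacus B4	LuxR+CSP_CDS	1
Rhodococcus sp. RHA1	REC+LuxR	17
Rhodococcus sp. RHA1	LuxR	24
Rhodococcus sp. RHA1	PKc+LuxR	9
Rhodococcus sp. RHA1	HDc+LuxR	1
Rhodococcus sp. RHA1	FHA+LuxR	2
Rhodococcus sp. RHA1	TPR+LuxR	2
Rhodococcus sp. RHA1	PKc+TPR+LuxR	2
Rubrobacter xylanophilus DSM 9941	REC+LuxR	8
Rubrobacter xylanophilus DSM 9941	LuxR	4
Rubrobacter xylanophilus DSM 9941	PAS+LuxR	1
Saccharopolyspora erythraea NRRL 2338	REC+LuxR	23
Saccharopolyspora erythraea NRRL 2338	LuxR	28
Saccharopolyspora erythraea NRRL 2338	TPR+LuxR	1
Salinispora arenicola CNS-205	REC+LuxR	7
Salinispora arenicola CNS-205	LuxR	13
Salinispora tropica CNB-440	REC+LuxR	9
Salinispora tropica CNB-440	LuxR	9
Streptomyces avermitilis MA-4680	REC+LuxR	32
Streptomyces avermitilis MA-4680	LuxR	18
Streptomyces coelicolor A3(2)	REC+LuxR	45
Streptomyces coelicolor A3(2)	LuxR	24
Streptomyces coelicolor A3(2)	AAA+LuxR	2
Streptomyces griseus subsp. griseus NBRC 13350	REC+LuxR	36
Streptomyces griseus subsp. griseus NBRC 13350	LuxR	11
Streptomyces griseus subsp. griseus NBRC 13350	TPR+LuxR	1
Thermobifida fusca YX	REC+LuxR	11
Thermobifida fusca YX	LuxR	4
Thermobifida fusca YX	TPR+LuxR	1
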
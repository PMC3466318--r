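---
title: "Models and methods behind archevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind archevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archevo)
```

`archevo` analyses the evolution of multi-domain transcription-factor
families — the LuxR-type regulators being the motivating case — through four
stages: a domain-architecture census, parsimony inference of architecture
histories, an ecological correlation battery, and term enrichment. This
vignette records the models, the tunable parameters, and the design choices
made where the methodology was genuinely open.

## The census and its retention rule

The census consumes tabular domain hits (protein, species, domain accession,
hit class, coordinates, e-value) as produced by conserved-domain searches;
running the searches themselves is out of scope and the table is taken as
given. Two decisions define the family:

1. **Anchor retention.** A protein is retained only if it has at least one
   hit to the anchor accession (`cd06170` by default) with hit class
   `specific`. Superfamily- and multidomain-class anchor matches are
   rejected; they indicate a related but unconfirmed domain assignment.
2. **Additional domains.** Among retained proteins, only specific-class
   hits contribute to the architecture; they are ordered by start
   coordinate (ties by end, then accession) and joined N→C with `+`.

Hit coordinates are 1-based inclusive; only their ordering matters
downstream. Three situations are not determined by the retention rule and
are fixed here by explicit convention: overlapping specific hits are both
kept; a protein with several anchor hits keeps every occurrence in its
architecture string; and a specific hit whose accession is missing from the
domain catalog keeps the accession itself as its label (with a warning)
rather than being dropped silently — an unknown domain should surface in the
census, not vanish. Printed percentages use half-up rounding to the nearest
integer, which is the rounding that reproduces the packaged census's
published summary figures (59% multidomain from 588/991, 53% REC fusion
from 525/991).

## Parsimony on the species tree

For one architecture, presence/absence over the species-tree leaves is
analysed under a single-gain (Dollo) model: the architecture arises once, on
the branch above an origin node, and can only be lost afterwards. The
minimal number of independent losses below the origin equals the number of
maximal all-absent subtrees, found in one postorder sweep. Under a
multifurcation, each all-absent child subtree counts as one loss; if the
whole multifurcating clade is absent the loss moves to its stem. This
convention is explicit and testable; the package's test suite checks the
sweep against exhaustive loss-subset enumeration on all small trees it
generates.

Origin hypotheses generalise this: every ancestor of at least one present
leaf is a candidate origin; present leaves outside the candidate's clade
are attributed to one horizontal transfer each, and the hypothesis cost is
`gain + loss × n_losses + hgt × n_recipients`. All three costs default to 1
and are exposed: the literature this formalises weighs such hypotheses
informally ("more parsimonious"), never with explicit weights, so unit
costs are the neutral choice and sensitivity is one `costs =` argument away.
Two consequences deserve note. With `hgt = Inf` the ranking degenerates to
pure Dollo: the best origin is the MRCA of the present leaves. And for data
simulated under a loss-only model, recovery of the true (root) origin must
be assessed with `hgt = Inf` as well — under finite equal costs, an origin
at a lower node plus a single transfer can legitimately undercut the true
history, which is a property of parsimony, not a defect of the
implementation.

A Fitch/Sankoff counter (`fitch_changes`, unit costs, exact on
multifurcations) provides the unconstrained minimal-change count; it serves
as an internal cross-check (`fitch ≤ dollo_losses + 1` always) and is
validated against exhaustive labeling enumeration and against an
independent phylogenetics library in the tests.

Trees are handled rooted internally. Unrooted species trees must be rooted
explicitly (outgroup, or a node-midpoint heuristic that places the root at
the node nearest the midpoint of the longest tip-to-tip path); gene trees
may alternatively be rooted at the principal architecture bipartition.

## Gene-tree censuses

The principal bipartition of an annotated gene tree is the internal edge
maximising the mean architecture purity of its two sides (purity of a side
= frequency of its commonest architecture). Ties prefer the more balanced
split, then the lexicographically smallest tip set — arbitrary but
deterministic. Note that with one tip "swapped" across an otherwise perfect
split, the maximising edge need not be the original split: a smaller fully
pure clade can win on mean purity. The operation is therefore specified —
and tested — as an argmax over an explicit enumeration, not as "the
intuitive edge".

`cluster_census` counts, inside a background clade, maximal subtrees whose
tips all carry a focal architecture: subtrees of size ≥ 2 are monophyletic
clusters, singletons are isolated sequences, and sizes always sum to the
number of focal tips. This is the machinery behind statements of the form
"N occurrences, in k monophyletic groups and m isolated sequences".

## The correlation battery

Each sub-family frequency (`rec_luxr`, `luxr`, `other`, `total`) is crossed
with each coded ecological variable:

* **Spearman `r_s`** is the Pearson correlation of midranks (ties allowed).
  The two-sided p-value is the exact permutation tail mass — full
  enumeration of all n! orderings, done in compiled code — for n ≤ 10, and
  the `t = r√((n−2)/(1−r²))` approximation above. The crossover at n = 10
  is configurable (`exact_max`); 10! ≈ 3.6 million permutations enumerate
  in well under a second, while the t approximation is accurate by n ≈ 11.
* **Fisher-z power** `β` is the standard power of the two-sided test of
  ρ = 0 via the variance-stabilising transform, `power =
  Φ(z√(n−3) − z₁₋α/₂) + Φ(−z√(n−3) − z₁₋α/₂)`. The battery's historical
  label for this column ("refined" Fisher z, a statistics-suite label) is
  interpreted as exactly this computation; at r = 0 it equals α, and |r| = 1
  returns power 1 by continuity.
* **Eta** is the correlation ratio `√(SS_between/SS_total)` with the
  ecological variable as the grouping factor and the frequency as the
  dependent variable — direction matters and is fixed this way throughout.
* **Least squares** goes through the standard linear-model fitter;
  rank-deficient designs are rejected with the collinear columns named.

Missing data are handled pairwise: each cell drops incomplete pairs and
reports its own n, matching the way such tables report per-cell sample
sizes (45–53 in the motivating study). Cells with fewer than 3 complete
pairs are flagged missing; zero-variance responses yield a flagged
degenerate result rather than an error, since an all-zero sub-family is a
legitimate data configuration.

**Ordinal coding.** The published coding scheme for the motivating study's
ecological variables is not available, so the coding scheme is a
user-supplied table (`variable`, `category`, `code`; `<metric>` marks
passthrough variables). A documented example scheme for eleven
genetic/ecological variables ships with the package; it is illustrative,
and exact reproduction of the original correlation coefficients is
explicitly not claimed anywhere in the package.

## Enrichment

Per term, a 2×2 table (focal with/without term × reference with/without) is
tested with the Fisher exact test, implemented as the sum of hypergeometric
point probabilities not exceeding the observed table's (with the customary
1e-7 relative tolerance); the test suite checks it against the reference
implementation over every table with margins up to 12. Adjustment is
step-up Benjamini–Hochberg. The reference group defaults to the complement
of the focal group. Two open points are settled as options: sequence
annotations are *not* propagated to ancestor terms unless
`propagate = TRUE` (the behaviour of annotation suites varies and the
motivating study's setting is unknowable), and the final filter keeps only
significant terms that are not ancestors of other significant terms — the
reported set is an antichain of the DAG, the "most specific" terms.

## The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. It emulates a multi-species regulator-family census: a Yule
(pure-birth) species tree of 53 species (birth rate 1); a single ancestral
single-domain gene entering the root; and per-lineage Poisson events per
unit branch length — fusion (rate 0.015, drawing from the nine non-anchor
catalog domains, N-terminal with probability 0.8, mirroring the
predominance of N-terminal sensor modules), fission (0.005, removing a
non-anchor domain), loss (0.05), duplication (0.65) and horizontal transfer
(0.02, recipient branch uniform among those alive at the event time — no
distance bias, a documented simplification). At speciation every lineage is
inherited by both daughters. These rates were chosen once so that simulated
censuses resemble the motivating family's shape — per-species family sizes
mostly in the single digits with maxima of several tens, and a handful
(typically 2–11) of distinct architectures — and are not tuned per
analysis.

Every event is logged (type, branch, time, lineage, architecture after),
and the log is replayable: an independent deterministic replay of the log
over the tree reproduces the tip repertoires exactly, for any seed. This is
the bookkeeping oracle used by the round-trip tests. The emitted hit tables
add per-species decoys (superfamily-class anchor hits, anchor-free
proteins) that the census filter must reject.

The ecological covariates plant one monotone link — a latent
`0.2 × family_size + N(0, 0.5)` discretised into 5 quantile levels,
mirroring the ordinal coding of genome-size-like variables — one
independent null variable, and one two-level categorical split on a second
latent, for Eta recovery. The planted slope and noise were fixed so that
the latent correlation is strong (≈0.8) at the default world size, the
regime the end-to-end recovery checks assume. The annotation simulator
plants one term at 0.9 vs 0.1 frequency over 50 sequences per group under a
three-level toy DAG.

**What the generator does not emulate.** Real domain-hit tables carry
e-value noise, fragmented and overlapping hits, and annotation errors; real
species trees are not ultrametric pure-birth trees; real HGT is
phylogenetically biased; ecological codings are far noisier than one
planted monotone link. Passing the synthetic round-trip and recovery suites
therefore demonstrates the correctness of the bookkeeping and the
statistical machinery under the stated models — not robustness to the full
messiness of real comparative data.

## Numerical and scale choices

Exact Spearman enumeration caps at n = 10 (3.6M permutations, compiled);
two-sided permutation and Fisher p-values include ties at the observed
statistic within a small relative tolerance; percentages round half-up;
Benjamini–Hochberg goes through the standard adjustment routine; the
least-squares stage uses the standard QR-based fitter. The test suite's
exhaustive oracles run on trees of 4–10 leaves with a few dozen profiles
per topology, Fisher enumeration covers all tables with margins ≤ 12, the
null error-rate simulations use 2,000 replicates, and the end-to-end
recovery suite uses 200 simulated worlds at the default 53-species
configuration — sizes at which the exhaustive checks are still exact while
the whole suite completes in a few minutes.

## Known limitations

* Origin-hypothesis scoring treats each outside-present leaf as one
  transfer and does not model transfer into internal branches followed by
  speciation; recipients are leaves by construction.
* The loss-counting unit is the species-tree leaf; if leaves are strains,
  losses are counted per strain, which may differ from a per-species count
  on trees with multiple strains per species.
* The Dollo machinery is presence/absence only; copy-number changes
  (duplication within a presence run) are invisible to it and are handled
  only by the gene-tree cluster census.
* The node-midpoint rooting heuristic places the root at a node rather than
  inside an edge; for precise midpoint rooting supply an outgroup instead.
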
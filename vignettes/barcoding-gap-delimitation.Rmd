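---
title: "Barcoding-gap species delimitation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcoding-gap species delimitation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The procedure and its assumptions

DNA-barcoding delimitation assumes that a single marker (here mitochondrial
*COI*) accumulates substitutions fast enough that conspecific pairs are
clearly less divergent than heterospecific pairs, so that the distribution
of all pairwise distances is bimodal with an empty interval — the
*barcoding gap* — between the modes. The package does not assume where that
gap lies; it reports candidate gaps and the species partition each one
implies, because a small sample can legitimately show more than one empty
interval with different taxonomic readings.

Three model-level assumptions matter:

* **Distance model.** The K2P correction assumes equal base frequencies and
  a single transition and transversion rate; it is the de facto barcoding
  standard and what published tables usually print. The uncorrected
  p-distance is kept as a companion because at barcode-scale divergences
  the two mostly agree to first order; both are always computed in
  fractions internally, with percent only at the reporting layer (one
  decimal, mirroring the usual printed format).
* **Missing data.** Sites with gaps, `N` or IUPAC ambiguity codes are never
  counted. Under *pairwise deletion* each pair keeps its own valid sites;
  under *partial deletion* (the default, matching common distance-software
  behavior) a site must be called in at least a fraction `coverage = 0.95`
  of all sequences to enter the analysis at all, and pairs then still skip
  their own residual missing positions. The published table this package
  verifies against was produced with partial deletion; the cutoff is not
  stated in such tables, so the common 95% default is used.
* **Gap detection on exact values.** Candidate gaps are the intervals
  between consecutive *distinct observed distances* of the upper triangle,
  ranked by width (ties broken toward the smaller lower endpoint). A
  histogram (default bin width: one percentage point) is produced for
  plotting only; binning would blur interval endpoints, so it never feeds
  detection.

## Delimitation

Putative species are connected components of the graph joining pairs with
`d ≤ t` (single linkage) — the natural reading of "within a species, all
distances fall below the gap", and robust to chains of intermediate
populations. Complete linkage is available behind a flag for comparison but
plays no role in the validated pipeline. The threshold for a candidate gap
is its **lower endpoint, inclusive**: a pair observed exactly at the last
within-species distance must be conspecific. With single linkage the
inclusive and exclusive rules give identical components whenever no pair
sits exactly on the endpoint; on the packaged table one pair does sit at
the higher gap's endpoint (10.4%), and the inclusive rule keeps it
intraspecific, which is the published reading.

Undefined distances (saturated K2P pairs, or pairs with no shared valid
sites) are flagged `NA`, excluded from gap detection, and treated as
"above threshold" during clustering, each with a warning — never silently
zero.

Region-stratified counts answer "how many of these species occur in area
X": a cluster counts if at least one member was sampled in the region set.
The Italian-region set ships as a plain text file (all sampled regions
except Cyprus and the Alborz Mountains) rather than being hard-coded, so
the same machinery serves any other stratification.

## Bootstrap standard errors

SEs are the standard deviation of each pairwise distance across `B = 500`
site-bootstrap pseudoreplicates (columns of the full alignment resampled
with replacement; the partial-deletion mask travels with the resampled
columns, and each pair then applies its own deletion). Replicates where a
pair is undefined are dropped and counted. The SE of a distance estimated
from L sites scales as 1/√L; the acceptance suite checks the ratio between
L = 500 and L = 2000 is ≈ 2 within 25%.

## Composition screen

Compositional bias can attract unrelated sequences in tree reconstruction,
so outgroups are screened before use: GC-content `(G+C)/(A+C+G+T)` and
GC-skew `(G−C)/(G+C)`, both over unambiguous called bases only, are
compared against the ingroup min–max range per statistic. The skew is
oriented `(G−C)/(G+C)`, which reproduces the negative skews reported for
*COI* on the deposited strands. Published composition tables may have been
computed on full deposited sequences or on the positions shared by all
sequences; the screen accepts either input, since it only compares values
computed consistently within one table.

## Surrogate phylogeny and strict-clock dating

The package deliberately replaces likelihood and Bayesian tree inference
with neighbor joining on the same distance matrix: its claim is the
delimitation analysis, and the tree is an exploratory summary, not a
reproduction of published ML/Bayesian topologies or node supports. Negative
NJ branch estimates are clamped to zero (standard practice) with the count
reported. Rooting is by outgroup stem when outgroups are present (falling
back, with a warning, to the edge with the purest outgroup side when the
outgroup is not monophyletic on the NJ tree), else by midpoint.

Dating is a simplified strict clock, not the relaxed-clock Bayesian
machinery sometimes used with these rates:

* the rooted tree is made ultrametric by setting each node's height to the
  mean of its node-to-descendant-tip path lengths (tips at height 0),
  projecting a parent just above its tallest child if averaging inverts
  them (with a warning);
* ages are `height / rate`, with defaults rate = 0.0016
  substitutions/site/Ma and SD = 0.0010 (an arthropod nuclear-rRNA
  estimate used in the absence of a centipede-specific rate), and age
  intervals are 2.5–97.5 percentiles over 1000 truncated-normal rate draws;
* a root-age reference of 200 ± 50 Ma is used only as a sanity check — a
  warning if the estimated root age leaves mean ± 3 SD — never as a prior
  that moves estimates.

Because a strict clock cannot emulate a relaxed (random local) clock, node
ages from this stage are qualitative context; the package asserts only the
self-consistency checks below, never agreement with published Bayesian age
estimates.

## What the simulator emulates — and what it does not

`simulate_yule_tree()` grows a pure-birth tree: with k extant lineages the
wait to the next split is Exp(k·λ), and the process stops at the first
would-be split after reaching `n_tips`, so pendant branches are positive
and the root age is Σ_{k=2..n} Exp(kλ) with mean (H_n − 1)/λ. (A stopping
rule that halts exactly at the n-th birth would give the last split a
zero-length pendant edge, so the memoryless overshoot is used instead;
the Monte-Carlo tests check the mean root age against this expectation.)
`evolve_k2p()` then evolves sequences site-independently using exact K2P
per-branch transition probabilities (matrix-exponential form, not
event-by-event simulation) — exact, fast, and the same model family the
estimator assumes. Defaults mirror the motivating study's conditions:
12 tips, 650 sites, rate 0.0016 subs/site/Ma, κ = 4, and birth rate
0.03/Ma, giving an expected root age near 65 Ma, the depth of the dated
ingroup.

`make_planted_matrix()` skips sequences entirely and draws within-species
distances uniform in (0, a) and between-species in (b, c), a < b. Such
matrices need not satisfy the triangle inequality — delimitation is purely
graph-based and does not require metricity — so NJ validation uses
tree-derived (additive) matrices only.

What passing these tests shows: the estimators are consistent under their
own model, the pipeline recovers planted truth, and the published-table
numbers are reproduced exactly. What they do not show: robustness to
among-site rate variation, indels, alignment error, compositional
heterogeneity or rate variation across lineages — real-data features the
generator deliberately omits (they belong to the likelihood-based stages
this package does not reimplement).

## Numerical choices and degenerate inputs

* K2P log arguments ≤ 0 (saturation) → flagged `NA`, never an exception
  that aborts a matrix.
* Pairs with zero valid sites → flagged undefined; composition of a
  sequence with no unambiguous base → `NA` with `defined = FALSE`.
* Ultrametricize on an already-clock-like tree is a fixed point to 1e-12;
  the constraint projection offset is 1e-9.
* Cluster ids are deterministic (ordered by first member's matrix
  position); NJ ties resolve by label order via the underlying
  implementation; reruns of the pipeline with the same seed are
  byte-identical, and output provenance headers carry version, seed and a
  config hash but no timestamps.
* Problem sizes used by the validation suite — 50 two-tip replicates at
  L = 10000 for estimator consistency, 10 replicates × B = 500 for the
  bootstrap scaling law, 50 ten-tip Yule datasets at L = 5000 for
  end-to-end dating recovery, 100 planted matrices for partition recovery —
  were chosen to make the Monte-Carlo error a small fraction of each
  tolerance while keeping the whole suite fast on a single core.

## Known limitations

* The published table is printed to one decimal; gap endpoints inherit that
  rounding. Whether unrounded distances would shift an endpoint cannot be
  known without the raw sequences, so the packaged values pin the printed
  precision.
* One printed SE ("0.17" where its neighbors are ~1.7) is anomalous in the
  source; the fixture stores it as printed with a suspect flag rather than
  guessing a correction.
* Single-marker, single-specimen-per-population sampling cannot separate
  within-population variation from geographic structure; the two candidate
  gaps express exactly that uncertainty, and the package reports both
  rather than choosing.
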
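# barcodegap

Distance-based DNA-barcoding species delimitation in R: pairwise p- and
Kimura 2-parameter (K2P) distances with bootstrap standard errors,
barcoding-gap detection, single-linkage threshold clustering into putative
species, compositional (GC) screening of outgroups, a neighbor-joining
surrogate phylogeny, and simplified strict-clock divergence dating.

## The problem

DNA barcoding delimits species from a standard marker (typically a ~650 bp
fragment of mitochondrial *COI*) by exploiting the *barcoding gap*: an
interval of pairwise genetic distance expected to separate within-species
from between-species comparisons. For taxa with uniform morphology — the
motivating case is a genus of geophilid centipedes sampled across the
Italian region — the gap, wherever it falls, converts a matrix of pairwise
distances directly into a species count.

The package operationalizes this as:

1. **Distances.** For each pair of aligned sequences, count transitions
   (A↔G, C↔T) and transversions over the L sites valid in both sequences
   (gap/ambiguity handling by pairwise or site-coverage "partial" deletion),
   giving proportions *P* and *Q*. Then

   - p-distance: `d = P + Q`
   - K2P: `d = -½ ln(1 - 2P - Q) - ¼ ln(1 - 2Q)`

   with standard errors from site-bootstrap pseudoreplicates (default
   B = 500).
2. **Gap detection.** Every interval between consecutive distinct observed
   distances is a zero-frequency interval; candidates are ranked by width.
   The two widest typically express a "many shallow species" vs "few deep
   species" alternative.
3. **Delimitation.** Putative species are the connected components of the
   graph linking pairs with `d ≤ threshold` (single linkage), the threshold
   being a candidate gap's lower endpoint; counts can be stratified by a
   region set (e.g. the Italian region).
4. **Trees and dates.** A neighbor-joining tree (midpoint- or
   outgroup-rooted) is made ultrametric by least-squares node heights and
   converted to ages via a strict clock (`age = height / rate`, default rate
   0.0016 substitutions/site/Ma ± 0.0010, truncated at zero for interval
   draws).

A seeded simulator (Yule trees, exact K2P branch-transition probabilities,
planted-partition matrices) provides ground truth for every stage.

## Worked example

The package ships the published 12-specimen centipede *COI* distance table
(K2P upper triangle / p lower, percent units) together with specimen
metadata and an Italian-region set:

```r
library(barcodegap)

fix <- read_printed_matrix(bg_fixture("table3"), bg_fixture("table3_se"))
fit <- barcode_delimit(fix$K2P,
                       metadata = bg_fixture("metadata"),
                       region_set = read_region_set(bg_fixture("italian_regions")))
fit
#> Barcoding-gap species delimitation
#>   12 taxa, 66 pairwise K2P distances (percent), range 0.5 - 27.4
#>   candidate gap 1: (0.5, 6.5)
#>   candidate gap 2: (10.4, 16.1)
#> delimitation scenarios (threshold = gap lower endpoint, inclusive):
#>  gap_rank gap_lo gap_hi threshold n_species n_species_region
#>         1    0.5    6.5       0.5        11                9
#>         2   10.4   16.1      10.4         8                6
```

Reading: distances range from 0.5% (two Western-Alps specimens) to 27.4%
(Cyprus vs the Eastern Prealps). Two zero-frequency intervals stand out.
Treating the *lower* one as the barcoding gap splits the 12 specimens into
11 species (9 with members in the Italian region); treating the *higher*
one yields 8 species (6 Italian), with exactly three multi-specimen
clusters. `plot(fit)` draws the distance histogram with the candidate gaps
shaded.

The same analysis runs from sequences (`barcode_delimit(read_fasta("aln.fasta"), ...)`)
or end to end via `run_pipeline(pipeline_config(...))`, which adds the
composition screen, NJ tree and dated tree, writing every artifact with a
provenance header. A thin CLI wrapper lives at
`inst/scripts/barcodegap-cli.R`.

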
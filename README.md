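# replichore

Comparative genomics of bacterial chromosome topology. Given a pair of
closely related, fully annotated bacterial genomes, `replichore` measures
how often orthologous genes have moved between the two replichores (the
two arms of the circular chromosome, running from the replication origin
*oriC* to the terminus *ter*) and how positionally symmetric those moves
are — and from this calls the gross spatial organisation of the
chromosome: **transverse** (E. coli-like, arms apart, few interreplichore
translocations) or **longitudinal** (Caulobacter-like, arms juxtaposed,
frequent and symmetric interreplichore translocations). It is aimed at
microbial comparative genomicists who have genome sequences for organisms
that will never see a Hi-C experiment.

## The statistics

Each gene is mapped to the normalized distance from the origin,
*d* = min(arc, circumference − arc) / (genome length / 2) ∈ [0, 1], a
replichore label (L/R), and one of four equal chromosomal bins anchored
on *oriC*: **O** (origin quarter), **R**, **T** (terminus quarter), **L**.
For a one-to-one ortholog map between genomes A and B the package
computes:

- ρ_GOC — Spearman correlation of the ortholog *d* vectors (gene-order
  conservation), with LOESS residuals against 16S identity to remove the
  phylogenetic-distance trend;
- P_i and T_i−j — bin position-conservation and translocation rates from
  the 4×4 bin cross-table; the interreplichore rate pools T_L−R and
  T_R−L (the O and T quarters are excluded from the rate because local
  inversions cluster around *oriC* and *ter*);
- D_inter = |d_A − d_B| per interreplichore ortholog pair, with the
  fraction of symmetric translocations (D_inter < 0.1), leading-strand
  flip rates, and a seeded randomization null for both (null mean
  D_inter = 1/3 for uniform positions);
- the topology call: longitudinal iff the combined interreplichore rate
  exceeds 0.1;
- corroborating tests: Wilcoxon contact-map enrichment at translocated
  loci, expression symmetry of co-expressed cross-replichore gene pairs,
  per-bin COG-class enrichment and horizontally-acquired-gene depletion
  (one-sided Fisher, Bonferroni);
- growth physiology: the R-factor R_f = T_R / T_D (replication time over
  minimum doubling time; R_f > 1 marks fast growers), with doubling
  times estimated from 16S rRNA copy number when unmeasured.

A synthetic generator (`generate_genome()`, `evolve_pair()`,
`synth_contact_map()`) produces genome pairs under a known event model —
ortholog loss, mirrored interreplichore translocation with tunable
symmetry noise, origin/terminus-local inversions, leading-strand
preservation — and emits the ground truth every estimator is validated
against.

## Worked example

```r
library(replichore)

anc <- generate_genome(n_genes = 1000, genome_length = 1e6, seed = 42,
                       proteins = FALSE)
ev  <- evolve_pair(anc, evolution_params(crossing_fraction = 0.45,
                                         symmetry_sd = 0.02, seed = 43))
fit <- compare_genomes(anc$genome, ev$genome_b, ev$map, seed = 44)
summary(fit)
#> <topology_pair> SYN_A vs SYN_B: 720 orthologs
#>   rho_GOC (spearman) = 1
#>   T_L-R = 0.425, T_R-L = 0.433, combined = 0.429
#>   topology: longitudinal (threshold 0.1)
#>
#> bin conservation/translocation rates:
#>       O     R     T     L
#> O 1.000 0.000 0.000 0.000
#> R 0.017 0.534 0.017 0.433
#> T 0.000 0.000 1.000 0.000
#> L 0.000 0.425 0.006 0.569
#>
#> interreplichore pairs: 174
#>   median D_inter = 0.011 (null 0.178)
#>   frac symmetric = 1.000 (null 0.301)
#>   strand-flip rate = 0.121 (null 0.396)
```

Reading this: 72% of the ancestor's 1000 genes kept an ortholog (the
generator's default loss rate is 0.28); the estimated interreplichore
rate 0.429 recovers the generated crossing fraction 0.45 up to binomial
noise and a small bin-boundary effect, so the pair is called
longitudinal; translocations are essentially all symmetric (median
D_inter 0.011 against a null of 0.178), and ρ_GOC stays at 1 because
symmetric interreplichore moves do not change a gene's distance from
*oriC*. `plot(fit)` draws the d_A–d_B ortholog scatter with
interreplichore translocations highlighted, the package's signature
diagnostic.

Real annotations enter through `read_ptt()` / `read_gff3()` +
`read_doric()` + `genome()`, orthologs through `best_hits()` (pluggable
scorer; deterministic internal aligner included) or
`read_ortholog_map()`, contact maps through `read_contact_matrix()`.
`run_pair()` and `run_simulate()` orchestrate whole analyses and write
TSV outputs with seed-carrying headers.

## Vignette

`vignettes/chromosome-topology.Rmd` documents the model, the coordinate
system, every tunable parameter with its default and rationale, the
generator's event model and its limits, and the package's numerical
conventions.
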
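---
title: "Inferring gross chromosome topology from interreplichore translocations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gross chromosome topology from interreplichore translocations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replichore)
```

## The idea

Bacterial chromosomes are circular and replicate bidirectionally from a
single origin (oriC) to a terminus (ter), dividing the molecule into two
*replichores*. Chromosome conformation work on model organisms has
established two gross spatial arrangements: a *transverse* topology
(E. coli-like), in which the two replichores occupy opposite cell halves
and rarely touch, and a *longitudinal* topology (Caulobacter-like), in
which the two arms run side by side from pole to pole and loci equidistant
from oriC are spatially juxtaposed.

Spatial proximity promotes recombination. Over evolutionary time, a pair
of closely related genomes therefore accumulates *interreplichore
translocations* — orthologous genes that sit on opposite replichores in
the two genomes — at a rate that reflects how often the two arms touch.
The package estimates that rate (and the positional symmetry of the
translocations) from an ortholog map between two annotated genomes, and
calls the gross topology from it. Conformation-capture data, where they
exist, can corroborate the call; a synthetic genome-pair generator with
known ground truth validates every estimator.

## Coordinate system

Every gene is represented by the midpoint of its coordinate span (a
strand-neutral anchor; genes wrapping the sequence origin are handled on
the circle). The midpoint maps to:

* `d_norm` — the shorter circular arc distance from oriC divided by half
  the genome length, so 0 at oriC and 1 at the antipode. Note the
  normalization is by half the genome even when the two replichores are
  physically unequal, so genes on the long replichore can approach
  `d_norm = 1` before reaching ter; this is deliberate and keeps the two
  replichores metrically comparable.
* the replichore — `R` if the shorter arc runs in the
  increasing-coordinate direction, `L` otherwise. The probability-zero
  exactly antipodal point is assigned to `R`.
* a chromosomal bin — the circle is split into four equal quarters
  anchored on oriC *only*: `O` centered on oriC, then `R`, `T`
  (containing the antipode), and `L` in increasing-coordinate order. When
  ter is not antipodal it may sit off-center inside `T`; `summary()` of a
  pair flags this. Half-open interval conventions make the four bins an
  exact partition, which the tests assert on full coordinate grids
  together with rotation invariance of the whole construction.

## Statistics computed per genome pair

Given a one-to-one ortholog map (`best_hits()`, or the generator's true
map):

* **Gene-order conservation** `rho_GOC`: Spearman correlation of the two
  `d_norm` vectors. Spearman is the default because ranks are robust to
  the nonlinearity of the distance fold; Pearson is available via
  `goc_method`. Because `d_norm` folds the two replichores together, a
  perfectly symmetric interreplichore translocation does not reduce
  `rho_GOC` — that separation of "distance from oriC" from "which arm" is
  the analytical point of the coordinate system.
* **Bin matrix**: 4×4 cross-tabulation of bin-in-A against bin-in-B.
  Row-normalized rates give position conservation `P_i` on the diagonal
  and translocation rates `T_i-j` off it; denominators count only genes
  that have an ortholog at all, and empty rows report `NA` rather than 0.
* **Interreplichore rate** `T_L-R`, `T_R-L` and their pooled combination:
  crossings between the L and R bins only. The quarter-chromosome around
  oriC and around ter is deliberately excluded here because local
  inversions cluster at those loci and would masquerade as
  interreplichore traffic. Both directions are reported alongside the
  pooled rate since no averaging convention is canonical.
* **Translocation profile**: every ortholog pair whose replichore label
  differs between genomes (all bins, so origin/terminus-proximal
  interreplichore moves are visible here even though they are excluded
  from the rate). Per pair: `D_inter = |d_A − d_B|` (0 for a perfectly
  symmetric translocation) and a leading-strand flip flag, where a gene
  is *leading* when its coding strand is co-directional with the
  replication fork on its replichore (`+` on R, `−` on L).
* **Randomized null** (`randomized_null()`): partner positions and
  strands are permuted uniformly *within the interreplichore set*,
  breaking the gene–ortholog assignment while preserving both marginal
  position distributions; `D_inter` and the flip rate are recomputed per
  replicate. For uniform positions the null mean of `D_inter` is exactly
  1/3 (`E|U − U′|`), which the tests verify at 10^5 samples.
* **Topology call**: `longitudinal` iff the combined L/R rate strictly
  exceeds 0.1. The threshold sits in the empirical gap between the
  low-crossing regime (rates of a few percent, as between E. coli and
  Salmonella) and the high-crossing regime (rates near 0.45–0.7, as for
  Caulobacter or M. smegmatis against their relatives); exactly 0.1 is
  called transverse.

### Correcting for phylogenetic distance

Across many pairs, statistics such as `rho_GOC` trend with 16S identity.
`loess_residual()` fits the statistic against 16S identity by LOESS
(span 0.75, degree 2) and returns `observed − fitted`, so a positive
residual always means *more* conservation than expected at that
phylogenetic distance. The sign convention is the standard one; the
alternative (fitted − observed) merely flips every downstream comparison
and is not offered.

### Ancillary tests

* **Contact-map enrichment**: translocated interreplichore locus pairs
  are projected into the contact-map genome's coordinates (own position,
  plus the partner's `d_norm` mirrored onto the opposite replichore),
  assigned to matrix bins by midpoint, and their normalized contact
  frequencies compared against all remaining interreplichore bin pairs
  with a two-sided Wilcoxon rank-sum test (normal approximation with
  continuity correction; a cell touched by any translocation belongs to
  the test set only).
* **Expression symmetry**: for all cross-replichore gene pairs, Spearman
  correlation of expression across conditions; the `|d_i − d_j|`
  distribution of strongly co-expressed pairs (ρ > 0.5) is compared with
  that of uncorrelated pairs (ρ ≤ 0) by Wilcoxon. The gap between the
  two cutoffs is intentional — weakly positive pairs carry little signal
  either way.
* **Positional function tests**: per-bin one-sided Fisher's exact tests —
  enrichment for each of the 23 single-letter COG classes (Bonferroni
  family: 23 × 4 = 92 tests per genome) and depletion of horizontally
  acquired genes (family: 4 bins). One-sidedness follows the direction of
  biological interest in each case. Compositional HGT predictions are
  only meaningful at intermediate base composition, so genomes outside
  40–60% GC are skipped with an explicit status. `p = 0.05` corresponds
  to `-log10(p) = 1.3` on the reported scale.

### Growth physiology

`replication_time()` is half the genome length over a uniform fork speed
of 600 nt/s — a deliberate simplification, overridable per organism.
`r_factor()` is replication time over minimum doubling time; strict
`R_f > 1` marks fast growers with overlapping replication rounds. When a
doubling time is unknown, `doubling_time_from_rrna()` estimates it from
the 16S rRNA copy number as the per-class median of a reference table
with log-linear interpolation between observed classes (clamped at the
range ends); a class-wise median was chosen over a parametric regression
because the copy-number–doubling-time relation is monotone but not
reliably log-linear across its whole range.

## Pair selection

`select_pairs()` scores all unordered pairs of genome summaries and
accepts those with ≥ 97% 16S identity (Needleman–Wunsch global
alignment, match +5 / mismatch −4, gap open 10 / extend 0.5; identity is
matches over the full alignment length including end-gap columns),
identical 16S copy number (a growth-rate proxy), both genomes at least
1.3 Mb (reduced obligate-parasite genomes have atypically stable gene
order), and different species (identical genus+species name tokens are
treated as strains). One pair per unordered species pair is kept — the
lexicographically smallest accession pair, a deterministic stand-in for
picking one at random. Determinism over arbitrary choice is a package-wide
rule: best-hit score ties break by protein identifier, for the same
reason.

The internal `alignment_scorer()` used by `best_hits()` is a
deterministic global protein aligner (BLOSUM62, gap 11/1) whose score is
mapped to a pseudo E-value by a fixed monotone Karlin–Altschul-style
transform. The transform preserves score ranking exactly, so best-hit
results equal ranking on raw scores while the E-value cutoff contract of
an external phmmer-style search remains exercisable; an adapter around
such an external tool can be supplied as `scorer` without touching the
mapping logic.

## The synthetic generator

`generate_genome()` places non-overlapping genes uniformly on a circle
(oriC at the sequence origin, ter antipodal), draws strands with a
leading-strand bias of 0.75 — the typical bacterial excess of
co-directional genes — and concentrates COG class J (translation,
ribosome biogenesis) near oriC. `evolve_pair()` then applies, in order:
ortholog loss, symmetric interreplichore translocation of a fraction of
L/R-bin genes (mirrored `d_norm` plus Gaussian noise), local
origin/terminus inversions (replichore flip at preserved distance with a
strand flip, which preserves leading-strand status — the geometry of an
inversion spanning oriC), and stochastic leading-strand preservation for
translocated genes. Defaults: 2000 genes on 2 Mb (typical gene density),
ortholog loss 0.28 (matching the ~72% median ortholog conservation
between closely related pairs), crossing fraction 0.3, symmetry noise
0.02, strand preservation 0.9, inversion rate 0.05. Partner protein and
16S sequences diverge by per-site substitution at 2% and ≤ 1%
respectively — enough to be non-trivial, small enough that best-hit
orthology recovers the true map, so orthology error is not confounded
with topology statistics.

What the generator does *not* emulate: realistic molecular evolution
(codon structure, indels), operon structure, intrareplichore
rearrangement, genome-size change, or annotation error. Passing tests
therefore demonstrate estimator correctness under the stated event
model, not robustness to every artifact of real annotations.

`synth_contact_map()` builds a symmetric binned matrix with power-law
distance decay and multiplicative log-normal noise; the longitudinal mode
multiplies contacts between opposite-replichore bins at similar `d_norm`
by `1 + band_strength`, emulating the juxtaposed-arm geometry.

## Numerical choices and known limitations

* Internal circular arithmetic is 0-based; all user-facing coordinates
  are 1-based inclusive, converted at the boundaries.
* Bin boundaries are half-open in the increasing-coordinate direction;
  gene midpoints may be half-integers and are binned in real arithmetic.
* The combined L/R rate is measured against the generator's crossing
  fraction with a small downward bias (~0.015 at fraction 0.5, noise sd
  0.02): positional noise can carry a translocated gene just across the
  O/T bin boundary in the partner, where it leaves the L/R numerator.
  This is inherent to the bin definition, stays well inside the ±0.02
  recovery tolerance the tests enforce, and vanishes as the noise
  shrinks.
* Evolved partner genomes may contain occasional overlapping gene spans
  (mirrored positions are re-packed only against coordinate collisions,
  not span overlaps); real annotations overlap too, and no estimator
  depends on disjoint spans.
* Multi-chromosome organisms and plasmids are out of scope: one circular
  chromosome per genome.
* The topology call is a two-state summary of a continuous quantity;
  organisms that oscillate between conformations (B. subtilis-like) or
  sit near the threshold are reported with the underlying rate so the
  user is never reduced to the label alone.

## Validation problem sizes

The shipped test suite validates: coordinate properties on 10^4 random
coordinates and full grids; alignment identity against an exhaustive
affine-gap DP oracle (score equality plus membership in the set of
identities achievable by any optimal alignment) on 200 random pairs;
Fisher tests against hypergeometric enumeration over all 2×2 tables with
total ≤ 30; null D_inter and flip rates at 10^5 permutation samples;
parameter recovery at 2000 genes over 20 seeds per setting (crossing
fractions 0–0.5, tolerance ±0.02); topology discrimination over 100
replicates per regime (≥ 95% required); and contact-map calibration by
KS-uniformity of 200 null p-values. `scripts/acceptance.R` recomputes
the headline quantities from scratch at the same sizes.

## A worked example

```{r example}
anc <- generate_genome(n_genes = 1000, genome_length = 1e6, seed = 42,
                       proteins = FALSE)
ev <- evolve_pair(anc, evolution_params(crossing_fraction = 0.45,
                                        symmetry_sd = 0.02, seed = 43))
fit <- compare_genomes(anc$genome, ev$genome_b, ev$map, seed = 44)
summary(fit)
```

```{r plot, fig.width = 5, fig.height = 5}
plot(fit)
```
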
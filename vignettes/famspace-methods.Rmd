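---
title: "Methods: rank-encoded sequence-space PCA and companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-encoded sequence-space PCA and companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famspace)
```

famspace implements the computational core of a study of the Cdc48-like
AAA+ ATPase of actinobacteria (Cpa): discriminating protein families in
sequence space by PCA of rank-encoded alignments, mapping conserved and
variable positions onto a structural model, quantifying gene co-occurrence,
and the surrounding biochemical and proteomic arithmetic. This vignette is
the package's account of the methods, the tunable parameters, and the
design decisions taken where the methods literature leaves choices open.

## Rank encoding and sequence-space PCA

For each alignment column, symbols are sorted by their occurrence in that
column; ties are broken by ascending alphabetical order of the one-letter
code; the most frequent symbol receives rank 1. Every residue is replaced
by its symbol's rank, producing an integer matrix with one row per
sequence. The direction of ranking (most frequent = 1) is a convention:
reversing it only reflects the principal axes, so we fix it and document
it rather than expose it.

PCA is computed on the mean-centered rank matrix without variance scaling.
Ranks are already on a shared, bounded scale, so column standardisation
would only inflate near-constant columns. Components are the right
singular directions; loadings have unit norm; the per-component explained
variance fraction is reported against the total variance of the centered
matrix. Two determinism choices matter for testing and reproducibility:

* the sign of each component is fixed so that its largest-magnitude
  loading is positive;
* columns that are constant after encoding are retained (they receive
  zero loading), keeping loading indices aligned with alignment columns.

Gap handling is surfaced as a flag because the method's description is
silent about it. `gap_as_symbol` (default) lets `-` compete in the
occurrence ranking like any residue, which keeps the matrix complete and
deterministic; `gap_worst_rank` always pushes gaps to (max rank + 1),
which treats them as maximally unusual rather than as a character state.

Family separation in a score subspace is summarised by the mean silhouette
width (Euclidean distance over the selected components). This statistic is
an addition of this package — the original analysis argued separation
visually — and is exposed so that the qualitative claim "families form
tight, separate clusters" becomes a number with a threshold.

## Conservation classification and sequence logos

Positions are classified against the maximal absolute loading of a chosen
component (the second component is the family-discriminating one in the
motivating analysis): strictly above 30% of the maximum is *variable*,
strictly below 10% is *conserved*, anything else *intermediate*. Both
thresholds compare `|loading|`; magnitudes are the only choice that is
invariant to the component sign convention. Values exactly at a threshold
are intermediate, reading "exceeded" and "below" as strict. The
classification is scale-invariant, so it does not depend on loading
normalisation.

Logo columns use the standard information-content definition
`IC = log2(A) - H - e_n`, with `A = 20` by default, `H` the Shannon
entropy of the observed residue frequencies (gaps excluded, the standard
logo convention), and `e_n = (A - 1) / (2 ln(2) n)` the small-sample
correction. The correction is off by default so that closed-form anchor
values (a conserved column gives exactly `log2(20) ≈ 4.32` bits; an equal
two-residue split gives `log2(20) - 1`) hold exactly in tests; the flag
enables it for WebLogo-comparable output. IC is clamped at zero because
the correction can exceed `log2(A)` for very small `n`.

Motif windows (e.g. Walker A/B boxes) are specified in ungapped residue
coordinates of a reference sequence and mapped to alignment columns by
skipping reference gaps. The per-residue structure export joins position
categories onto (chain, residue) targets; duplicate targets resolve
last-writer-wins with a warning, and unmapped columns are dropped.

## Gene co-occurrence

The presence/absence analysis asks whether one gene (e.g. *cpa*) is
confined to genomes carrying another (e.g. the proteasome subunit genes
*prcA*/*prcB*). `nestedness_and_test` reports the nestedness flag (the
"A without B" cell is empty) and a one-sided exact hypergeometric p-value
for positive association. The test is directional by default because the
biological claim is directional; a two-sided variant is available. The
exact-test quantification is an artifact addition: the motivating study
reported the pattern, not a statistic.

## Hill fits, ATPase turnover, assembly fraction

Binding curves are fit with the four-parameter Hill form
`y = U + (B - U) S^h / (Kd^h + S^h)` by bounded Levenberg–Marquardt
(unweighted least squares; the source analysis fit the plain Hill form
with no weighting and no ligand-depletion correction). Auto-initialisation
takes `U` and `B` from the curve ends, `Kd` from the concentration nearest
half-signal, and `h = 1`. Bounds `Kd ∈ (0, 100·max S]`, `h ∈ (0, 10]`
stabilise the fit: an unbounded Hill coefficient is unidentifiable on
sparse titrations. Non-convergence is reported via a flag, never silently.
The default simulated titration is a 10-point 1.5-fold dilution series
from 3.5 µM down to 0.09 µM, the design of the thermophoresis experiments
the package mirrors; recovery tests use generating constants of 0.36 and
0.56 µM, the two measured core-particle affinities.

ATPase turnover converts a coupled-assay A340 slope via the NADH
extinction coefficient 6.22 mM⁻¹cm⁻¹ (1 ATP per NADH). The optical path
must be supplied: in a plate the path depends on fill volume, so no
default is safe.

The SEC assembly fraction is `(hexamer + dodecamer) / (monomer + hexamer
+ dodecamer)` over baseline-corrected peak areas. Integration is
trapezoidal with a straight-line baseline between window endpoints. The
chromatogram simulator derives windows at peak center ± 4σ: with the
endpoint-baseline rule a ± 3σ window would clip about 2.9% of a Gaussian
peak (truncation plus baseline lift), while ± 4σ keeps the error near
0.3%, inside the 1% closed-form recovery the tests assert. Overlapping
auto-windows are clipped at the midpoint between peak centers.

## LFQ differential analysis

Per-protein fold changes are differences of group means of log2
intensities (positive = higher in the knockout), with a two-sided
two-sample t-test. Welch's test is the default — unequal variances are
the norm in LFQ data — with Student's test available. Zero intensities
are treated as missing and dropped per protein (`impute_min` substitutes
half the smallest positive intensity); a protein with fewer than two
observed values in a group is reported with `p = NA` and counted
*unchanged*. Volcano classification uses an inclusive fold-change
threshold (≥ 1.5-fold) and a strict p threshold (< 0.05), the filter
used for the published counts; both are configurable. No multiple-testing
correction is applied by default because the published filter uses raw
p-values; a Benjamini–Hochberg option exists. The COG summary drops
proteins without a class and class S (function unknown), as in the
published class breakdown.

Two statistical facts about these defaults, established by the test
suite, deserve emphasis:

* *Calibration.* Under the null generator (equal-variance log-normal
  intensities), Student's test is exactly calibrated and the suite checks
  its empirical type-I error against the binomial 99% interval. Welch's
  test at n = 5 per group is slightly conservative (empirical rate near
  0.044) — expected Satterthwaite small-sample behaviour, not a defect.
* *Raw-p filtering does not control the FDR.* With 10% of proteins truly
  changed and noise calibrated so the t-test has ≈ 0.9 power, nearly
  every null protein passing p < 0.05 also passes the 1.5-fold gate, so
  the expected false-discovery proportion of the raw filter is about
  `0.05·π₀/(0.05·π₀ + 0.9·π₁) ≈ 0.33`, independent of the noise scale.
  The suite therefore asserts sensitivity (≥ 0.8) on the raw filter and
  FDP control (≤ 0.15) on the BH option — no single configuration can
  deliver both under this design, and a published-style raw-p volcano
  should be read with that in mind.

## The synthetic-data generators

All generators are pure functions of a config and a seed, and every
generator emits its ground truth, so each downstream module is tested by
parameter recovery rather than against stored fixtures.

*Family MSA.* One ancestral background consensus is drawn, with Walker
A/B-like motif blocks at fixed positions. Each family's consensus then
diverges from the background independently at each variable-region site
with probability `p_v` (default 0.4; two family consensuses then differ
at about 63% of variable-region sites in expectation), and every
sequence adds per-site replicate substitutions at rate `p_c` (default
0.05, uniform over the 19 non-consensus residues) and optional per-site
gaps. Defaults — 3 families × 20 sequences, 300 columns, variable region
1–90 — emulate a family panel whose N-terminal domains distinguish the
families while the ATPase modules are shared. Bernoulli per-site gaps
keep ground-truth bookkeeping exact but are not realistic indel blocks,
and the uniform exchange model ignores residue similarity, so passing
tests demonstrate the pipeline's statistical behaviour, not performance
on real phylogenetic correlation structures.

*Binding curves and chromatograms.* Hill signal plus i.i.d. Gaussian
noise; sums of Gaussian peaks plus flat baseline. Neither models
instrument drift or peak tailing; they exist to verify fitting and
integration arithmetic against closed forms.

*LFQ tables.* Log-normal intensities: per-protein true log2 abundance
`N(25, 2)`, replicate noise `N(0, σ)` with σ = 0.64 by default — the
value at which a two-sample t-test with n = 5 per group has ≈ 0.9 power
against a 1.5 log2-unit shift at α = 0.05 — and a configurable spiked
fraction (default 10% at ±1.5 log2 units) in a pentaplicate design. The
generator has equal variances across groups and no missingness structure;
real LFQ data have intensity-dependent missingness that the `drop` and
`impute_min` policies only coarsely represent.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data
at deliberately modest sizes: 60-sequence × 300-column alignments, 100
seeded Hill replicates per constant, 2000-protein tables over up to 50
seeds for calibration, and exhaustive 2×2 enumeration up to table total
30. These sizes were chosen to make every check exact or tightly bounded
while keeping a full run in the order of seconds. All randomness flows
from explicit integer seeds; re-running any pipeline with the same
inputs, config, and seed produces byte-identical primary outputs.

## Known limitations

* The rank encoding treats columns independently; covariation between
  positions is invisible to it.
* Silhouette-based separation assumes roughly convex clusters in score
  space; elongated clades can score low despite clean separation.
* The co-occurrence test ignores shared ancestry; phylogenetically
  corrected models are out of scope.
* The Hill fit pools replicates; a hierarchical per-replicate error model
  is not attempted.
* Published LFQ comparison tables are not redistributable with the
  package; the checks that reproduce the published volcano counts
  activate only when those tables are placed under
  `inst/extdata/published/`.
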
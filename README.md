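# famspace

Sequence-space analysis of AAA+ protein families, built around the
computational workflow used to characterise the Cdc48-like protein of
actinobacteria (Cpa): a tandem AAA+ ATPase that assembles into hexameric
rings and interacts with the bacterial 20S proteasome.

The package is for computational biologists who want to reproduce or
reuse that workflow on their own protein families:

* **Rank-encoded PCA of an alignment.** Each residue in a multiple
  sequence alignment is replaced by the occurrence rank of its symbol in
  its column (most frequent → rank 1, ties broken alphabetically); PCA of
  the centered rank matrix places sequences in a low-dimensional
  "sequence space" where families form clusters. Per-column loadings of a
  component identify the positions that discriminate families.
* **Conservation mapping.** Positions are classified against the maximal
  absolute loading of a chosen component — strictly above 30% *variable*,
  strictly below 10% *conserved* — and exported as per-residue structure
  annotations. Sequence-logo information content
  `IC = log2(20) − H − e_n` quantifies per-column conservation (e.g. of
  Walker A/B motifs).
* **Gene co-occurrence.** 2×2 presence/absence contingency with a
  nestedness flag and a one-sided exact hypergeometric test, for claims
  of the form "*cpa* occurs only in proteasome-positive genomes".
* **Biochemical calculations.** Hill-equation fits
  `y = U + (B − U)·S^h/(Kd^h + S^h)` of binding titrations (bounded
  Levenberg–Marquardt), coupled-assay ATPase turnover via the NADH
  extinction coefficient 6.22 mM⁻¹cm⁻¹, and size-exclusion assembly
  fractions `(hexamer + dodecamer)/(all peaks)`.
* **LFQ differential proteomics.** Per-protein log2 fold changes and
  t-test p-values across replicate intensities, volcano classification at
  fold-change ≥ 1.5 / p < 0.05, and COG class summaries (class S
  excluded).
* **Seeded synthetic-data generators** for every input type, so the whole
  pipeline runs and is tested offline with no downloads.

## Worked example

```r
library(famspace)

# a synthetic 3-family alignment: shared Walker-motif blocks,
# family-divergent N-terminal region
aln <- simulate_family_msa(family_sim_config(seed = 1))
aln
#> fs_alignment: 60 sequences x 300 columns
#> families: F1=20, F2=20, F3=20

res <- run_pca(rank_encode(aln, gap_policy = "gap_as_symbol"), k = 2)
res
#> fs_pca: 60 samples, 300 columns, k = 2
#> explained variance fraction: 0.154 0.109

family_separation(res, aln$labels, components = 1:2)
#> [1] 0.878
```

The mean silhouette width of 0.878 over the first two components says the
three families form tight, well-separated clusters in rank space — the
quantitative form of "families cluster apart in sequence-space PCA".
Classifying positions on the second component recovers where that
discrimination lives:

```r
cls <- classify_positions(res, component = 2, upper = 0.30, lower = 0.10)
table(cls$category)
#>     variable intermediate    conserved
#>           38           54          208
```

The 38 variable positions concentrate in the simulated N-terminal
variable region (columns 1–90), while the conserved Walker-motif blocks
carry near-zero loadings. On the biochemistry side:

```r
cur <- simulate_binding_curve(U = 0.2, B = 1.0, Kd = 0.36, h = 2,
                              noise_sd = 0.008, seed = 42)
fit_hill(cur)
#> Hill fit: Kd = 0.3647, h = 2.03, U = 0.2091, B = 1.005 (RSS 0.000372, converged)

assembly_fraction(c(monomer = 60, hexamer = 30, dodecamer = 10))
#> [1] 0.4
atpase_rate(slope = -0.00622, path_cm = 1, enzyme_conc = 0.25)
#> [1] 4
```

A 10-point 1.5-fold titration with 1%-range noise recovers the generating
dissociation constant (0.36 µM) to within a few percent; a SEC trace with
peak areas 60/30/10 is 40% assembled; an A340 slope of −0.00622 per
minute over a 1 cm path at 0.25 µM hexamer corresponds to 4 ATP min⁻¹
hexamer⁻¹.

## Documentation

The methods vignette (`vignettes/famspace-methods.Rmd`) describes the
models, parameter defaults, numerical choices, the synthetic generators'
scope, and known limitations.
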
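# cebu: cell-specific expression buffering inference

Genetic screens across large cell-line panels show that the essentiality of
many genes is *context-dependent*: knocking out a gene cripples some cell
lines and barely touches others.  One proposed mechanism is **cell-specific
expression buffering**: a constitutively expressed *buffering* gene (G2) can
stand in for the function of a *buffered* gene (G1), so cell lines that
express more G2 tolerate the loss of G1 better.  Classic examples are
paralog pairs (higher paralog expression, weaker dependency on its
duplicate), but the same logic extends to non-duplicated genes in the same
pathway or protein complex.

`cebu` is an R package for screening G1 x G2 gene pairs for this
relationship in CRISPR dependency (CERES-style dependency scores, more
negative = more essential) and expression (log2 TPM) panels that share a
cell-line axis, and for the downstream statistics such a screen needs.  It
is aimed at computational biologists working with DepMap/CCLE-style data or
any comparable paired panel.

## The C-score

For a candidate pair, let `rho` be the Pearson correlation between the G1
dependency profile and the G2 expression profile across cell lines, and
`slope` the least-squares slope of expression regressed on dependency.  The
screen's index is

```
C = rho * (1 + b * slope_min / slope)
```

where `slope_min` is the smallest slope among all pairs in the screened
universe with a significantly positive correlation (unadjusted two-sided
p < 0.05), and `b` (default 1) weights the slope term.  The ratio
up-weights pairs whose expression is nearly flat against a wide dependency
range — the geometry expected when modest expression differences decide
whether a knockout is tolerated.  With `b = 0` the index reduces to the
plain correlation.

Around the index, the package provides:

* **Null calibration** — expression profiles are permuted across cell lines
  (per gene), the universe is re-scored with the real-data `slope_min`, and
  a normal distribution fitted to the pooled shuffled C-scores yields
  upper-tail p-values and Benjamini–Hochberg q-values.
* **Pair enrichment** — hypergeometric enrichment of duplicated pairs above
  a cutoff, log2 ratio enrichment for pathway/PPI pair sets, enrichment
  curves over cutoff ladders, and a directed buffering network (g2 → g1)
  with SIF/GraphML export.
* **Tissue context** — the tissue-specificity index τ, paired τ contrasts,
  rank-normalized dependency-expression plots divided into nine 10° sectors
  (R1 nearest the expression axis … R9 nearest the dependency axis), and
  region × tissue enrichment tables.
* **Buffering capacity** — per cell line,
  `(expression − 25th percentile) / slope_mod` with
  `slope_mod = C × sd(expr)/sd(dep)`; tissue means; Bliss independence
  scores for double-suppression growth experiments; exponential growth-rate
  fits.
* **Validation** — orientation-maximum C-score assignment to
  genetic-interaction tables, rank-based ROC/AUC with Mann–Whitney tests,
  capacity–GI correlation, and per-cancer prognosis AUC against Cox-derived
  ground-truth tables.
* **Synthetic data** — `sim_cebu()` generates DepMap-like panels with
  tissue-blocked cell lines, heterogeneous per-gene expression variability
  and planted buffering pairs of known slope, plus companion duplicated/GI/
  prognosis ground-truth tables, so the whole pipeline is testable without
  any downloads.

## Worked example

```r
library(cebu)
sim <- sim_cebu(sim_config(seed = 1))   # 50 x 200 genes, 200 cell lines
fit <- cebu(sim$data, b = 1, alpha = 0.05, threshold = 0.25)
fit
#> C-score screen
#>   50 G1 x 200 G2 candidates, 200 cell lines, 10000 pairs scored
#>   slope_min = 3.6003e-06, b = 1, report threshold = 0.25
#>   2803 pair(s) at c_score >= 0.25

null <- cebu_null(fit, n_shuffles = 5, seed = 1)
null
#> Shuffled-expression C-score null: normal(mu = 0.001489, sigma = 0.07309)
#>   5 shuffle(s), 50000 scores pooled, seed 1

fit <- cebu_significance(fit, null)
head(fit$records, 3)
#>        g1      g2 rho slope c_score        p        q
#> 1 G1_0007 G2_0011   1  0.01       1 8.13e-43 1.63e-40
#> 2 G1_0020 G2_0024   1  0.01       1 8.13e-43 1.63e-40
#> 3 G1_0038 G2_0042   1  0.01       1 8.13e-43 1.63e-40

caps <- buffering_capacity(fit, pairs = head(fit$records, 100))
head(tissue_mean_capacity(caps, sim$data$annotation), 3)
#>   tissue_type mean_capacity    n
#> 1    tissue01        245.62 2500
#> 5    tissue05         89.53 2500
#> 7    tissue07         81.04 2500
```

The top records are the planted buffering pairs: near-perfect correlation
at the planted slope 0.01, q-values far below any sensible threshold, and
`tissue01` — the simulated high-expression tissue — ranks first in mean
buffering capacity.  `run_pipeline(cebu_config())` chains all stages
(fit, null, enrichment, network, τ, regions, capacity, GI and prognosis
validation) and writes one TSV per stage plus a `manifest.yaml` of
parameter values and output hashes.  A thin command-line wrapper lives in
`inst/scripts/cebu.R` (`synth` and `run` subcommands).

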
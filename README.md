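# eigenmetab

Statistical tools for staged developmental omics series — the kind of data
produced by profiling *Drosophila* embryogenesis in two-hour bins: a
genome-wide expression time course on one side, and replicated GC-MS
metabolite tables plus bulk nutrient-store assays on the other. The package
is aimed at researchers who want to find the coordinated temporal programs
in such a series, test them for enrichment of an annotated gene catalog,
and score which metabolites change significantly relative to the earliest
stage.

## What it computes

**Eigengene decomposition.** The expression table D (genes × ordered
stages, nonnegative) is factored by thin SVD, D = U S Vᵀ, transforming the
data from (gene) × (time) space to (eigengene) × (eigentime) space. Each
row of Vᵀ is an *eigengene* — a unit-norm temporal pattern shared across
genes — and all r = number-of-timepoints patterns are kept, so a 12-stage
series yields exactly 12 eigengenes. The spectrum is summarized by
eigenexpression fractions eᵢ = sᵢ / Σⱼ sⱼ and their normalized Shannon
entropy d = −(1/ln n) Σ eᵢ ln eᵢ ∈ [0, 1] (0 = one pattern dominates,
1 = all patterns equal). Genes are ranked per pattern by their oriented U
loading (top 500 by default).

**Catalog enrichment.** A ranked list is tested for over-representation of
an annotated catalog (e.g. metabolic genes) with the exact hypergeometric
upper tail

P(X ≥ k) = Σᵢ₌ₖ^min(K,m) C(K,i) C(M−K, m−i) / C(M,m),

evaluated in log space via log-gamma so p-values of order 10⁻²⁰ are exact
to full relative precision.

**Metabolite time courses.** Peak areas are divided by each sample's
spiked internal standard (D4-succinate), expressed relative to the median
of the 0–2 h baseline (mapped to 100), compared to baseline per timepoint
with two-sided Welch t-tests (α = 0.01), and summarized as box-plot
five-number rows. Within-sample metabolite ratios (e.g.
lactate / pyruvate) and nutrient-store assays (baseline-normalized means,
SEM, pooled-variance Student t-tests at α = 0.05) are covered by
`ratio_series()` and `analyze_stores()`.

**Synthetic data with ground truth.** `simulate_expression()`,
`simulate_annotations()`, `simulate_metabolome()` and `simulate_stores()`
generate the full data bundle with planted patterns, planted enrichment and
planted fold changes recorded in a truth object, so every pipeline stage is
testable end to end without downloads.

## Worked example

```r
library(eigenmetab)
library(dplyr)

sim <- simulate_expression(n_genes = 5000, n_timepoints = 12, seed = 42)
fit <- eigen_decompose(sim$expression)
fit
#> <eigengene_fit> 5000 genes x 12 timepoints (transform = none, center = FALSE)
#>   12 eigengene patterns; entropy d = 0.211; top-3 fraction = 98.5%

tidy(fit, "fractions") %>% head(4)
#> # A tibble: 4 x 4
#>   pattern singular_value fraction cumulative
#>     <int>          <dbl>    <dbl>      <dbl>
#> 1       1        295.     0.876        0.876
#> 2       2         24.8    0.0736       0.949
#> 3       3         11.9    0.0355       0.985
#> 4       4          0.590  0.00175      0.987
```

The low entropy (d = 0.21) says the series is highly ordered: three
patterns carry 98.5% of total expression — the constant program plus the
two planted temporal programs. Rank the genes on pattern 2 (the mid-series
induction) and test the planted metabolic catalog:

```r
ann <- simulate_annotations(sim$truth, K = 400, ratio = 3, pattern = 2,
                            top_m = 500, seed = 42)
enrich(rank_genes(fit, pattern = 2, top_n = 500), ann$catalog)
#> # A tibble: 1 x 7
#>       M     K     m     k  p_value log10_p label
#>   <int> <int> <int> <int>    <dbl>   <dbl> <chr>
#> 1  5000   400   500   102 5.45e-21   -20.3 planted catalog
```

102 of the top 500 genes carry the annotation where 40 would be expected
by chance — the planted three-fold enrichment, detected at p ≈ 5 × 10⁻²¹.
The metabolite side chains the same way:

```r
ms <- simulate_metabolome(seed = 42)
summ <- ms$timecourse %>%
  normalize_to_standard() %>%
  relative_to_baseline("0-2h") %>%
  summarize_timecourse("0-2h", alpha = 0.01)
summ %>% filter(metabolite == "g3p_like",
                timepoint %in% c("0-2h", "12-14h", "22-24h"))
#> # A tibble: 3 x 11
#>   metabolite timepoint     n   min     q1 median    q3   max ...
#> 1 g3p_like   0-2h          7  86.1   93.0   100   107.  137.
#> 2 g3p_like   12-14h        7 243.   286.    332.  387.  499.
#> 3 g3p_like   22-24h        7 909.  1025.   1122. 1242. 1532.
```

The planted ten-fold glycerol-3-phosphate-like rise is recovered: the
final-bin median is ~1122 on the scale where the baseline median is fixed
at 100, and the later bins are flagged significant. `plot_metabolite_boxes()`
draws these rows as the conventional quartile boxes with min–max whiskers;
`autoplot(fit)` draws the eigengene patterns; `run_eigengene_pipeline()`
and `run_metabolome_pipeline()` run either side end to end from a config
list (or YAML file) into a directory of TSV/JSON artifacts with a run log.

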
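# mxprox

Spatial proximity and survival analysis for multiplex immunohistochemistry
(MxIHC) cell-centroid data.

## The problem

Iterative chromogenic MxIHC yields, per whole-slide tumor section, a table of
single-cell centroids with binary marker calls (here: SOX10 for melanoma
cells; CD8 for cytotoxic T cells; optionally CD11c, CD40, CD80). Two
questions drive the analysis:

1. **Slide level.** How does the tumor-cell compartment change between a
   pre-treatment section and a matched section taken at disease progression,
   and does that change track progression-free survival (PFS)? The readouts
   are the marker density (cells/mm²), the marker frequency (% of nucleated
   cells), and a *proximity pair statistic*: the number of distinct SOX10⁺
   cells having at least one CD8⁺ cell within a Euclidean centroid distance
   r (default 45 µm, the scale of paracrine cell–cell communication),
   normalized to the CD8⁺ count,

   ```
   pair_statistic(r) = #{ SOX10+ cells with ≥1 CD8+ cell within r } / #CD8+
   ```

   Per patient, each metric m is summarized as the log2 fold-change
   `FC = log2(m_post / m_pre)`, compared pre vs post with the exact Wilcoxon
   matched-pairs signed-rank test, and correlated with PFS by Spearman rank
   correlation.

2. **Cohort level.** In an expression cohort with overall survival (OS),
   does tumor cellularity (SOX10/MLANA z-score) add prognostic value to an
   immune-admixture score? Tools: exclusion filters, Kaplan–Meier and
   log-rank, univariable Cox with hazard ratios reported per interquartile
   range (`HR = exp(β·IQR)`), stage-stratified Cox models with a
   score×marker interaction tested by likelihood ratio, Harrell's c-index
   with bootstrap optimism correction, median-split subgroup Wilcoxon
   rank-sum tests (Bonferroni×6), and a linear marker×log2(CD8) interaction
   model on log2 gene expression.

A synthetic-data module generates both layers with known ground truth —
marked Poisson point patterns with an optional attraction construct coupling
SOX10-like cells to CD8-like cells, paired cohorts with a programmed
expansion–PFS link, and exponential proportional-hazards survival cohorts —
so every stage runs and is testable with no data download.

## Worked example

Simulate an 11-patient paired cohort in which faster progression is
programmed to coincide with greater SOX10⁺ expansion, then run the full
slide-level pipeline:

```r
library(mxprox)

cfg <- cohort_sim_config(
  n_patients = 11, slope = 1.5, noise_sd = 0.3, seed = 42,
  baseline = slide_sim_config(lambda_ref = 2e-4, lambda_target = 3e-4,
                              lambda_other = 5e-4))
sim <- simulate_paired_cohort(cfg)
report <- run_mxihc_pipeline(sim$slides, sim$clinical, radii = c(45, Inf))
print(report)
```

```
<mx_report> 22 slides, 11 patients
Spearman (log2 FC vs PFS):
          metric radius_um        rho      p_value n_used skipped_reason
   density_SOX10         - -0.9636364 1.852040e-06     11
 frequency_SOX10         - -0.9636364 1.852040e-06     11
     density_CD8         - -0.5454545 8.265096e-02     11
   frequency_CD8         -  0.9727273 5.142177e-07     11
  pair_statistic        45 -0.9545455 4.988899e-06     11
  pair_statistic       any -0.9636364 1.852040e-06     11
```

Reading the output: the programmed link is recovered — patients whose
SOX10⁺ density and SOX10–CD8 pairing (at 45 µm and at any distance)
expanded the most had the shortest PFS (strongly negative rho). CD8⁺
*density* was simulated unchanged, so its fold-change correlation is noise;
CD8⁺ *frequency* is a share of all nucleated cells and mirrors the SOX10
expansion, hence its positive rho. The paired pre-vs-post comparison for a
metric is available as, e.g.:

```r
print(report$wilcoxon[["density_SOX10"]])
#> Wilcoxon signed-rank: V = 41, p = 0.5195 (n = 11, exact)
```

(The expansion model is symmetric around zero fold-change at this slope, so
no systematic pre-vs-post shift is expected here.) `write_report(report,
dir)` emits deterministic TSV/JSON artifacts.

On the cohort side:

```r
tb  <- simulate_survival_cohort(surv_sim_config(n = 1000, seed = 7))
tb  <- filter_tcga_cohort(tb)
fit <- cox_per_iqr(tb$os_months, tb$os_event, tb$sox10_z)
ix  <- stratified_cox_interaction(tb, "immune_score", "sox10_z")
lr_test(ix$full, ix$reduced)
c_index_optimism(tb, c("immune_score", "sox10_z"), B = 200, seed = 7)
```

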
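# tilscore

Scoring of intra-tumoral lymphocytes (TILs) in colorectal cancer and
statistical assessment of their prognostic value for disease-specific
survival (DSS).

Quantitative immunohistochemistry yields, for each tumor, CD3+ and CD8+
cell counts and examined areas in three subregions of the whole
cross-section. From these, `tilscore` computes:

- **densities** `d = Σ counts / Σ areas` (cells/mm²) per marker;
- a **heterogeneity coefficient** — the coefficient of variation
  (sample SD / mean) of the three subregion densities, which is inversely
  related to density in real cohorts;
- **mid-rank cohort percentiles** `(rank − 0.5)/n × 100` and the
  **I-score** = (CD3 percentile + CD8 percentile)/2, an Immunoscore-style
  whole-section variant;
- exploratory **CD3−CD8 differences** and **CD3:CD8 ratios** on the density
  and percentile scales.

Downstream analysis mirrors the standard biomarker workflow: a
nonparametric association screen (Mann-Whitney / Kruskal-Wallis / Spearman,
Benjamini-Hochberg FDR within each metric family), a D'Agostino–Pearson
skewness/kurtosis normality omnibus, Kaplan-Meier and log-rank analysis,
univariable and jointly pT/pN/pM-adjusted Cox models (Efron ties), tertile
contrasts, and exhaustive **minimal-p cutpoint optimization** — dichotomize
at every observed value, keep both groups above a 10% size floor, pick the
split with the smallest log-rank p — plus a permutation guard that corrects
the optimism of that selection.

Because per-patient data for such cohorts are not public, the package
includes a seeded **synthetic-cohort generator** calibrated to published
cohort-level summaries (201 patients, ≈605 person-years of follow-up, mean/
median examined area 37.3/27.4 mm², right-skewed bimodal CD3 density,
kurtotic CD8 density, heterogeneity inversely proportional to density,
realistic covariate prevalences and stage/mutation/sex/smoking
associations). All estimators are validated against closed forms,
brute-force oracles, and calibration simulations on this generator.

## Worked example

```r
library(tilscore)
res <- run_pipeline(simulation_config(n_patients = 201, seed = 1),
                    verbose = FALSE)
print(res)
#> tilscore pipeline run — simulated (n=201, seed=1)
#>   201 tumors, 37 disease-specific deaths, 692 person-years
#>   validation: 4 of 4 distributional checks passed
#>   Cox models (univariable + stage-adjusted): 15 metric rows

res$cutpoints$cd8_density
#> Optimal cutpoint for cd8_density: > 15.79 (10th percentile)
#>   log-rank p = 0.00175; high-vs-low HR = 0.303 [0.137, 0.669]
#>   groups: 21 low / 180 high; 160 thresholds scanned (floor 10%)

head(res$cox_table[, c("term", "hr", "ci_low", "ci_high", "p",
                       "hr_adj", "p_adj")], 9)
#>                 term    hr ci_low ci_high       p hr_adj  p_adj
#> 1        cd3_density 0.999  0.997   1.001 0.40689  1.000 0.9032
#> 2            cd3_pct 0.995  0.983   1.006 0.35788  0.999 0.9189
#> 3            cd3_cov 1.729  0.355   8.409 0.49759  1.230 0.8120
#> 4 cd3_density_gt_246 0.448  0.174   1.150 0.09501  0.590 0.2875
#> 5        cd8_density 0.992  0.985   0.999 0.02342  0.993 0.0636
#> 6            cd8_pct 0.985  0.973   0.997 0.01392  0.987 0.0490
#> 7            cd8_cov 1.973  0.615   6.330 0.25329  1.495 0.5227
#> 8  cd8_density_gt_16 0.303  0.137   0.669 0.00316  0.371 0.0182
#> 9             iscore 0.987  0.975   1.001 0.06166  0.992 0.2407
```

Reading the output: hazard ratios below 1 mean higher lymphocyte
infiltration is protective — here one unit of CD8 density (1 cell/mm²)
multiplies the disease-specific hazard by 0.992 univariably (p = 0.023),
and the association weakens once pT/pN/pM enter the model (`hr_adj`,
`p_adj`), the expected behavior when stage and immune infiltration are
entangled. The optimal CD8 cutpoint row (`cd8_density_gt_16`) shows the
high-density group at 30% of the low-density group's hazard; because that
threshold was chosen to minimize p, `permutation_minp_check()` should be
used before taking its significance at face value.

`run_pipeline(..., output_dir = "dir")` additionally writes `panel.csv`,
`associations.csv` (+ group summaries), `cox_models.csv`,
`tertiles_cox.csv`, `km_curves.csv`, per-metric `cutpoint_scan_*.csv`, a
`cutpoint_summary.json`, `validation.csv` and `provenance.json` — all
deterministic given the seed. A thin shell wrapper lives at
`inst/scripts/til_pipeline.R`.

## Vignette

`vignettes/til-scoring.Rmd` documents the score definitions, the generative
model and its calibration, every numerical choice (percentile convention,
tie handling, group-size floor, convergence tolerances), the demonstration
regime for the stage-attenuation pattern, and known limitations.
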
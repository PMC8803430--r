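# tacesig

Transcriptomic signature discovery for predicting response to
transarterial chemoembolization (TACE) in hepatocellular carcinoma.

TACE is the standard first-line therapy for intermediate-stage liver
cancer, but one-month radiologic response rates vary widely between
patients, so a pre-treatment predictor of response has real clinical
value. `tacesig` implements, as a tested and reusable R pipeline, the
transcriptomic analysis used to build such a predictor from a
development cohort of responders and nonresponders:

1. **Expression preprocessing** — probe-to-gene collapsing (keep the
   probe with maximal average expression; drop ambiguous/blank
   annotations) and per-gene z-scoring (`collapse_probes()`,
   `zscore_genes()`).
2. **Differential expression** — moderated t-statistics with
   empirical-Bayes variance shrinkage
   (t̃_g = Δ_g / (s̃_g √(1/n₁ + 1/n₂)), with s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)
   and (d₀, s₀²) estimated by moment matching on log s²_g), then
   Benjamini–Hochberg control with the strict thresholds |log2FC| > 1
   and q < 0.05 (`moderated_t()`, `filter_degs()`).
3. **Per-sample gene-set scoring** — a rank-based single-sample
   enrichment score (integrated weighted Kolmogorov–Smirnov walk,
   weights rank^τ, centred at its analytic null mean) with Welch
   contrasts between response groups (`sample_enrichment()`,
   `contrast_sets()`).
4. **Stability feature selection** — the core procedure: R = 10
   stratified 80/20 splits per model family (lasso-logistic, linear
   SVM, neural network, random forest, gradient-boosted trees), per-gene
   importance ranks per split, one *occurrence* whenever a gene ranks in
   the top 20% of the DEG universe, and retention of genes with
   occurrence ≥ 8 that are also present in the external cohort
   (`run_iterations()`, `accumulate_occurrence()`, `select_genes()`).
5. **Signature fitting** — families raced by 10-round averaged AUC /
   F1 / accuracy / Youden / sensitivity / specificity / PPV / NPV; the
   final linear model exposes per-gene weights (positive ⇒ pushes toward
   nonresponse) and a Platt-calibrated probability, so external cohorts
   are called at a 0.5 threshold (`compare_models()`, `fit_final()`,
   `predict_cohort()`).
6. **Survival stratification** — Kaplan–Meier curves, log-rank test,
   Cox regression (Breslow ties) and IPCW time-dependent ROC at 12/36/60
   months for the predicted groups (`km_estimate()`, `logrank_test()`,
   `cox_fit()`, `time_dependent_roc()`).
7. **Microenvironment** — NNLS cell-fraction deconvolution against a
   marker signature matrix and the mRNA stemness index (Spearman
   correlation with stemness weights, min-max scaled per cohort)
   (`deconvolve()`, `stemness_index()`).
8. **Synthetic cohorts** — first-class generators with planted ground
   truth (differential genes, label-driving genes, score-dependent
   survival, known mixtures, stemness gradients) so every stage is
   testable offline (`generate_cohort()`, `generate_survival()`,
   `generate_mixtures()`).

## Worked example

```r
library(tacesig)

cfg <- pipeline_config(
  out_dir = "run", seed = 1,
  simulate = list(n_resp = 81, n_nonresp = 66, n_genes = 2000,
                  n_deg = 100, effect = 2, n_informative = 10,
                  noise_sd = 1),
  families = model_families(), rounds = 10, min_occurrence = 8,
  survival_beta = 1.5, censor_rate = 0.2)
res <- run_pipeline(cfg)
```

On this synthetic cohort (81 responders vs 66 nonresponders, 100 planted
differential genes of which 10 drive the label) the run prints, stage by
stage, and ends with:

```
selected genes: 18 (G0098, G0042, G0056, G0079, G0060...)
winning family: lasso_logistic | mean AUCs: lasso_logistic=1.000 linear_svm=1.000 ann=1.000 random_forest=1.000 xgboost_tree=0.999
external survival split: log-rank p = 3.52e-25, HR = 8.59
```

meaning: 18 genes passed the occurrence ≥ 8 filter; at this planted
effect size every family separates the held-out test folds essentially
perfectly, and the tie is broken by the fixed family order; and on an
independently simulated external cohort whose hazard depends on the
planted score (log HR 1.5 per unit), the predicted response and
nonresponse groups show strongly divergent survival. Stage artifacts
(DEG table, per-family occurrence ledgers mirroring the
gene/occurrence/ranking-sum/average-rank layout, the serialized
signature with weights and calibrator, predictions, survival results)
land under `run/`, with checksums in `run/run_manifest.json`;
`run_pipeline(cfg, resume = TRUE)` recomputes only stages whose outputs
are missing or stale.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main analysis from scratch: it simulates the
development and external cohorts at the study's group sizes, runs the
full eight-stage pipeline (all five model families, 10 iterations,
top-20% flagging, occurrence ≥ 8), prints the selection, model-race and
survival summaries, and writes the acceptance JSON to `--out`.
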
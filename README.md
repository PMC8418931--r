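# adrrisk

Risk-level classification of post-marketing drugs from spontaneous
adverse-drug-reaction (ADR) reports.

Regulators divide drugs into three risk levels — prescription (**Rx**),
over-the-counter class A (**OTC-A**) and class B (**OTC-B**) — and
periodically re-evaluate whether a drug should switch status.
Spontaneous reporting systems collect the evidence for that decision,
but as raw data they are duplicated, incomplete, extremely sparse and
heavily imbalanced (few drugs are low-risk). `adrrisk` implements a
complete classification pipeline for this setting, for
pharmacovigilance researchers and methodologists who want a reproducible
benchmark of disproportionality-based risk classification:

1. **ETL** — clean spontaneous reports (drop records without a drug or
   ADR term, deduplicate exact report/drug/ADR triples), standardize
   names and aggregate into a drug × ADR mention count table.
2. **Signal detection** — per drug–ADR pair, the 2×2 contingency table
   (A, B, C, D) and the proportional reporting ratio

   PRR = (A / (A + B)) / (C / (C + D)),

   giving a drugs × ADR-terms feature matrix with class labels 0/1/2.
3. **Feature enhancement (FS_GAN)** — rank ADR features by random-forest
   Gini importance Im(f_i) = Σ_j Im_j^Gini, keep the top k = 200, train a
   small GAN (min_G max_D V(D, G)) on the selected submatrix and append
   one generated feature row per drug: 751 + 200 = 951 features at the
   reference scale, with no original feature removed.
4. **Minority expansion** — SMOTE from first principles: imbalance ratio
   IR = N⁺/N⁻, oversampling rate K = ⌊IR⌋, k = 5 nearest minority
   neighbors by Euclidean distance, synthetic samples
   x_new = x + u · (x̄ − x) with u ~ U(0, 1), grown until all classes
   match the majority count (887/887/887 = 2661 at reference scale).
5. **Random forest classification and evaluation** — 100 Gini trees grown
   to purity, ⌊√d⌋ features per split, prediction by vote; evaluation
   reports the confusion matrix, per-class precision/recall/F1, accuracy,
   macro and weighted averages, and one-vs-rest ROC curves with macro AUC.

The three experiment designs — Model 1 (RF), Model 2 (SMOTE + RF),
Model 3 (FS_GAN + SMOTE + RF) — quantify what balancing and feature
enhancement each contribute. Because real regulatory reporting databases
are confidential, the package ships a seeded synthetic-report generator
that reproduces the statistical structure of such an extract (class
composition 887/113/47, 751-term vocabulary, ~1.7% matrix density,
duplicate/incomplete records), so the whole pipeline is testable and
reproducible end to end. See the methods vignette
(`vignettes/drug-risk-classification.Rmd`) for the model details and
design choices.

## Worked example

```r
library(adrrisk)

# a corpus two orders of magnitude smaller than a real extract
cfg <- generator_config(n_rx = 120, n_otc_a = 40, n_otc_b = 25,
                        n_adr_terms = 200, reports_per_drug_mean = 50,
                        seed = 42)
catalog <- generate_catalog(cfg)
reports <- generate_reports(cfg, catalog)

cleaned <- clean_reports(reports)
cleaned$log
#> $raw
#> [1] 9605
#> $kept
#> [1] 9235
#> $incomplete
#> [1] 185
#> $duplicate
#> [1] 185

tab <- attach_labels(aggregate_counts(cleaned$reports), catalog$drugs)
sm <- build_signal_matrix(tab)
sm
#> PRR signal matrix: 185 drugs x 200 ADR terms (2.09% nonzero)
#> class counts: 0=120 1=40 2=25

res <- run_experiment(sm, config = experiment_config(
  model = 3, top_k = 50, seed = 7,
  gan = gan_config(epochs = 300)))
res
#> Model 3 (augment_first protocol): held-out evaluation
#> evaluation on 108 samples: accuracy 93.52%
#>  class precision recall   f1
#>      0      0.84   1.00 0.91
#>      1      1.00   0.86 0.93
#>      2      1.00   0.94 0.97
#> macro    P/R/F1: 0.95 0.94 0.94
#> weighted P/R/F1: 0.95 0.94 0.94
#> macro AUC (one-vs-rest): 0.99

validate_on_source(res)$accuracy
#> [1] 0.9621622
```

The cleaning log shows the injected incomplete and duplicate records
being removed; the signal matrix is ~2% nonzero, as configured. After
feature enhancement and SMOTE, the balanced 360-sample set is split
70/30 and the forest classifies the 108 held-out
samples (original and SMOTE-synthetic) at 93.5% accuracy with high minority-class recall — on this
generator, the signature of the full Model-3 design; Model 1 on the same
matrix leaves minority recall far lower (try `model = 1`). Validating the
trained model on all 185 original drugs (training data overlaps this set,
so the number is optimistic by construction) classifies 96.2% correctly.

A command-line front end over the same functions is installed at
`inst/cli/adrrisk.R`:

```sh
Rscript inst/cli/adrrisk.R simulate --out data/
Rscript inst/cli/adrrisk.R run-experiment --reports data/reports.csv \
    --labels data/labels.csv --model 3 --seed 1 --out results/
```

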
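# liverCRD

Quantifying circadian rhythm disruption (CRD) in liver cancer
transcriptomes, and turning it into prognosis.

Tumors with a disrupted circadian clock behave differently — in metabolism,
immune context, mutational landscape and survival — but "disruption" is not
a column in an expression matrix. `liverCRD` is an R package for
transcriptomics researchers that measures it the way the underlying
analysis framework does: as the per-sample enrichment of a
circadian-rhythm-related gene (CRG) signature, calibrated against an
expression-matched random background, and linked to outcome through a
published 14-gene risk model and from-definition survival statistics.

## What the package computes

**CRD score.** For each sample (cell or bulk sample), a single-sample GSEA
running-sum statistic: rank all `G` genes by expression and accumulate, at
each list position, the normalized rank-weight mass of signature genes seen
(`P_in`, weights `rank^alpha`, `alpha = 0.25`) minus the fraction of
non-signature genes seen (`P_out`); the score is `sum(P_in - P_out)`.

**Calibrated abnormality call.** Genes are split into 50 average-expression
bins; 1000 random gene sets matching the signature's per-bin frequencies
(and hence its size `K`) are scored identically, giving each sample an
empirical null distribution, background level and p-value. Samples above
the 75% quartile of observed scores are called CRD-abnormal.

**CRD risk score.** The published 14-gene linear model

```
risk = 0.112*ENO1 + 0.077*STMN1 + 0.108*SLC1A7 + 0.055*RAB13 + 0.019*SRPRB
     + 0.019*UGDH - 0.039*RCAN2 + 0.201*HILPDA + 0.042*WEE1 + 0.159*HSPA8
     + 0.022*BAMBI - 0.383*P2RX1 - 0.053*UBB + 0.048*MAFG
```

with median stratification into high/low risk, plus a from-scratch
L1-penalized Cox path fitter (`fit_lasso_cox`: Breslow partial likelihood,
coordinate descent, cross-validated deviance with the minimum criterion)
for re-deriving such signatures on new cohorts.

**Survival and mutation statistics.** Kaplan–Meier, log-rank, Newton–Raphson
Cox fits, IPCW time-dependent AUC; MAF variant classification
(nonsynonymous = mutated, silent/intron/UTR/intergenic = wild-type),
one-sided z and chi-square mutation-frequency tests between CRD groups,
pairwise Fisher co-occurrence/exclusivity, hypergeometric
over-representation, Benjamini–Hochberg adjustment.

**Synthetic data.** Generators for expression (spiked signature in a
"high-CRD" subset), proportional-hazards survival and grouped mutation
tables with known ground truth, so the whole pipeline is testable without
any external accession.

## Worked example

Score a synthetic cohort with a known spiked subset, call abnormality, and
relate the calls to survival:

```r
library(liverCRD)

cfg <- synthetic_config(seed = 1, n_genes = 1000, n_samples = 200,
                        signature_size = 40, spike_effect = 2)
gen <- generate_expression(cfg)
res <- crd_score(gen$expr, gen$signature, n_iterations = 500, seed = 1)
head(res$table, 4)
#>   sample score null_mean null_sd empirical_p category
#> 1  S0001  94.8       145    29.4       0.964   normal
#> 2  S0002  82.4       138    31.1       0.954   normal
#> 3  S0003  45.0       127    30.0       0.996   normal
#> 4  S0004 358.5       141    32.2       0.002 abnormal
```

Each row is one sample: its enrichment `score`, the mean and SD of its
1000-set matched null (`null_mean`, `null_sd`), the empirical p-value of
the observed score against that null, and the quartile-threshold call
(here the threshold is 188.3). The calls recover the planted truth
perfectly on this cohort:

```r
table(truth = gen$labels[res$table$sample], call = res$table$category)
#>             call
#> truth        abnormal normal
#>   background        0    150
#>   spiked           50      0
```

Tie the CRD call to outcome with the survival machinery (here survival is
simulated so that the spiked group carries a log-hazard of +1):

```r
lp <- ifelse(gen$labels == "spiked", 1, 0)
surv <- generate_survival(setNames(lp - mean(lp), names(gen$labels)),
                          lambda0 = 1/800, censor_rate = 0.25, seed = 2)
grp <- setNames(ifelse(res$table$category == "abnormal", "high", "low"),
                res$table$sample)
logrank_test(surv, grp)
#> Log-rank test: chi-square = 20.93 on 1 df, p = 4.762e-06
vapply(km_estimate(surv, grp), median_survival, numeric(1))
#> high  low
#>  361  718
```

The abnormal-CRD group's median survival (361 days vs 718) and the
log-rank p-value quantify the planted effect. The published risk model is
available as a constant:

```r
published_livercrd_model()
#> RiskModel (published 14-gene liver CRD signature): 14 genes
#>   ENO1  STMN1 SLC1A7  RAB13  SRPRB   UGDH  RCAN2 HILPDA   WEE1  HSPA8 ...
#>  0.112  0.077  0.108  0.055  0.019  0.019 -0.039  0.201  0.042  0.159 ...
```

`risk_score()` evaluates it per sample, `stratify_by_median()` splits the
cohort, and `time_dependent_auc()` reports discrimination at chosen
horizons. `run_pipeline()` wires all stages together from a JSON config and
writes TSV/JSON outputs plus a reproducibility manifest;
`inst/scripts/crd-pipeline.R` is a command-line wrapper with `simulate` and
`run` subcommands.

## Package layout

- `R/io.R` — validated containers (expression matrix, signatures, survival
  and MAF tables) and TSV/MTX/GMT/JSON readers and writers
- `R/crd_scoring.R` — ssGSEA scoring, expression bins, matched background,
  thresholding and categorization
- `R/risk_model.R` — published model, risk scoring, median stratification,
  L1-penalized Cox path with cross-validation (compiled inner loop in
  `src/`)
- `R/survival_stats.R` — Kaplan–Meier, log-rank, Cox, time-dependent AUC
- `R/enrichment_mutation.R` — variant classification, frequency and
  co-occurrence tests, ORA, BH
- `R/synthetic.R`, `R/pipeline.R` — ground-truth generators and the
  end-to-end pipeline
- `vignettes/crd-methods.Rmd` — the model, its assumptions, parameter
  choices and limitations
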
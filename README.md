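# risisr

Robust discovery and validation of binary tumor expression subtypes.

High-grade serous ovarian tumors show no single obvious expression
clustering, so the question is not "which cluster does each tumor belong
to?" but "is there a reproducible binary partition at all — and does it
travel to other cohorts and platforms?". `risisr` implements a complete,
deterministic workflow for that question:

* **rISIS discovery** — a seeded, greedy search for binary sample
  partitions, each supported by a gene module: per-gene pooled-variance
  t statistics `t_g` (with a variance floor `s0`), module = the `m = 100`
  genes with largest `|t_g|`, split score `S = mean(t_g^2)` over the
  module. Significance comes from a permutation null (per-gene independent
  shuffles, full search re-run per draw, maximum score recorded), so "no
  subtype found" is a possible and honest answer.
* **Bootstrap stability selection** — the search is repeated on random
  training subsets; classifiers trained on rediscovered partitions predict
  held-out samples; partitions whose predicted labels are >95% consistent
  are retained and then confirmed on an untouched model-selection set.
* **Cross-omics confirmation** — nearest shrunken centroid (PAM)
  classification with nested cross-validation tests whether microRNA
  profiles predict the mRNA-defined partitions
  (soft-thresholding `d' = sign(d) max(0, |d| - Δ)`, inner folds choose Δ).
* **Portable subtype score** — per-gene robust scaling to [-1, 1]
  (2.5%/97.5% quantile clipping), score
  `sum(w_g x_g) / sum(|w_g|)` from the split-1 discriminant weights,
  Gaussian-mixture fit with `BIC = -2 loglik + (3k - 1) log(n)` to decide
  whether the score distribution is bimodal, posterior > 0.5 calls of the
  *angiogenic* (upper) vs *non-angiogenic* component.
* **Clinical statistics** — Kaplan–Meier/logrank, Cox hazard ratios with
  Wald intervals (Efron ties), exact and Monte Carlo Fisher tests,
  integer-percent subtype proportions.
* **Synthetic cohorts** — a generator emulating the study structure
  (129 samples, ~12,000 genes, 12 duplicate arrays, four planted
  100-gene-module splits, 743 microRNAs, exponential survival with
  subtype-dependent hazard, clinical covariates), so the whole pipeline is
  testable offline.

## Worked example

```r
library(risisr)

spec <- cohort_spec(n_samples = 70, n_genes = 500, n_duplicates = 4,
                    planted_splits = list(planted_split(0.3, 60, 3)),
                    n_mirna = 80, mirna_informative = 20, mirna_effect = 3,
                    hr = 1.8, seed = 1)
cohort <- generate_cohort(spec)

norm   <- quantile_normalize(cohort$expression)
genes  <- filter_variable_genes(norm, cohort$duplicate_pairs, k = 250)
mat    <- norm[genes$gene, setdiff(colnames(norm),
                                   cohort$duplicate_pairs$duplicate)]

splits <- search_splits(mat, m = 60, n_perm = 50, seed = 2)
splits[[1]]
#> <bipartition> g1 = 21 / 70 samples; score = 35.579; p = 0.0196

stable <- bootstrap_stability(mat, splits, n_boot = 30, m = 60, seed = 3)
glance(stable[[1]])
#> # A tibble: 1 x 8
#>   score p_value  n_g0  n_g1 module_size stability matched_fraction n_boot
#> 1  35.6  0.0196    49    21          60         1                1     30
```

The search finds the planted minority class (21 of 70 samples) with
permutation p ≈ 0.02, and every one of 30 bootstrap replicates rediscovers
it and reproduces its labels on the held-out samples (stability 1), so it
clears the >0.95 retention bar.

```r
scores <- signature_score(robust_scale(mat), splits[[1]]$weights)
fit    <- gmm_bic(scores$score, k_max = 3, seed = 4)
fit
#> <gmm_fit> chosen k = 2 (BIC over k = 1..3)
#>       k loglik    bic
#> 1     1  -36.8   82.1
#> 2     2   80.5 -140.
#> 3     3   83.7 -133.

calls <- classify_subtype(scores, fit)
calls
#> <subtype_calls> boundary = 0.224; angiogenic = 21, non-angiogenic = 49
```

BIC prefers two score components — the distribution is genuinely bimodal —
and the posterior calls split the cohort 21/49, exactly the planted
partition (agreement 1.00 with the simulated truth).

```r
surv <- dplyr::inner_join(cohort$survival, tidy(calls), by = "sample")
surv$group <- surv$call
cox_hr(surv, reference = "non-angiogenic")
#> # A tibble: 1 x 7
#>   term                            hr conf_low conf_high p_value     n n_event
#> 1 angiogenic vs non-angiogenic  2.14     1.14      4.01  0.0173    70      40
```

The called angiogenic subtype carries the elevated hazard the generator
planted (true HR 1.8; estimate 2.14, 95% CI [1.14, 4.01], logrank
p = 0.015).

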
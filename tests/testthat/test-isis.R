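test_that("the split score is symmetric, sized, and order-invariant", {
  co <- small_cohort(n = 50, genes = 120, effect = 2.5, seed = 13)
  mat <- bio_matrix(co)
  lab <- truth_labels(co, samples = colnames(mat))
  sc <- split_score(mat, lab, m = 40)
  expect_gte(sc$score, 0)
  expect_equal(nrow(sc$module), 40)

  swapped <- ifelse(lab == "g1", "g0", "g1")
  expect_equal(split_score(mat, swapped, m = 40)$score, sc$score)

  set.seed(1)
  gp <- sample(nrow(mat)); spb <- sample(ncol(mat))
  sc2 <- split_score(mat[gp, spb], lab[colnames(mat)[spb]], m = 40)
  expect_equal(sc2$score, sc$score)
  expect_setequal(sc2$module$gene, sc$module$gene)

  expect_error(split_score(mat, c("g1", rep("g0", ncol(mat) - 1)), m = 10),
               "at least 2")
})

test_that("a planted split scores far above random labelings", {
  co <- small_cohort(n = 60, genes = 150, effect = 3, module = 40, seed = 17)
  mat <- bio_matrix(co)
  lab <- truth_labels(co, samples = colnames(mat))
  planted <- split_score(mat, lab, m = 40)$score
  set.seed(2)
  random_max <- max(vapply(1:100, function(i) {
    split_score(mat, sample(unname(lab)), m = 40)$score
  }, numeric(1)))
  expect_gt(planted, random_max)
})

test_that("refined search matches exhaustive bipartition enumeration on toys", {
  # 8 samples: brute force over all bipartitions with both classes >= 2
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 8), 6, 8,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
    s0 <- median(apply(X, 1, var))
    best_brute <- 0
    for (code in 1:(2^7 - 1)) {         # sample 1 fixed to class 0
      bits <- as.integer(intToBits(code))[1:7]
      lab01 <- c(0L, bits)
      if (sum(lab01) < 2 || sum(lab01) > 6) next
      sc <- split_score(X, ifelse(lab01 == 1, "g1", "g0"), m = 3, s0 = s0)
      best_brute <- max(best_brute, sc$score)
    }
    found <- search_splits(X, m = 3, min_group_size = 2, n_perm = 0,
                           seed = 1, all_thresholds = TRUE, max_splits = 1)
    expect_gte(found[[1]]$score, best_brute - 1e-9)
  }
})

test_that("the search is deterministic given a seed", {
  co <- small_cohort(n = 40, genes = 100, effect = 2.5, module = 30, seed = 19)
  mat <- bio_matrix(co)
  a <- search_splits(mat, m = 30, n_perm = 10, seed = 8)
  b <- search_splits(mat, m = 30, n_perm = 10, seed = 8)
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$labels, b[[i]]$labels)
    expect_equal(a[[i]]$score, b[[i]]$score)
    expect_equal(a[[i]]$pvalue, b[[i]]$pvalue)
  }
})

test_that("an infeasible minimum group size is rejected", {
  co <- small_cohort(n = 30, genes = 50, seed = 23)
  expect_error(search_splits(bio_matrix(co), min_group_size = 20), "exceeds")
})

test_that("the diagonal discriminant separates and generalizes", {
  tc <- two_class_matrix(n0 = 40, n1 = 20, genes = 80, n_inf = 20,
                         shift = 2, seed = 3)
  model <- lda_train(tc$mat, tc$labels, m = 20)
  # weight signs match the group mean differences for every module gene
  for (g in model$coefs$gene) {
    d <- mean(tc$mat[g, tc$labels == "g1"]) -
      mean(tc$mat[g, tc$labels == "g0"])
    expect_equal(sign(model$coefs$weight[model$coefs$gene == g]), sign(d))
  }
  # held-out accuracy at a 2-sigma shift
  tc2 <- two_class_matrix(n0 = 40, n1 = 20, genes = 80, n_inf = 20,
                          shift = 2, seed = 4)
  pred <- lda_predict(model, tc2$mat)
  expect_gte(mean(pred$label == tc2$labels), 0.9)

  # perfectly separated classes give zero training error
  sep <- two_class_matrix(n0 = 10, n1 = 10, genes = 20, n_inf = 20,
                          shift = 10, seed = 5)
  msep <- lda_train(sep$mat, sep$labels, m = 20)
  expect_equal(mean(lda_predict(msep, sep$mat)$label == sep$labels), 1)
})

test_that("prediction handles missing module genes by renormalizing", {
  tc <- two_class_matrix(n0 = 40, n1 = 20, genes = 60, n_inf = 30,
                         shift = 4, seed = 6)
  model <- lda_train(tc$mat, tc$labels, m = 30)
  full <- lda_predict(model, tc$mat)
  set.seed(7)
  drop <- sample(model$coefs$gene, 15)
  sub <- tc$mat[setdiff(rownames(tc$mat), drop), ]
  expect_warning(part <- lda_predict(model, sub), "renormalized")
  expect_gte(mean(part$label == full$label), 0.8)
  none <- tc$mat[setdiff(rownames(tc$mat), model$coefs$gene), ]
  expect_error(lda_predict(model, none), "missing")
})

test_that("duplicate arrays get identical predictions at vanishing noise", {
  co <- generate_cohort(cohort_spec(
    n_samples = 40, n_genes = 100, n_duplicates = 6,
    planted_splits = list(planted_split(0.3, 30, 3)), noise_sd = 0.01,
    n_mirna = 10, mirna_informative = 0, seed = 29))
  mat <- bio_matrix(co)
  lab <- truth_labels(co, samples = colnames(mat))
  model <- lda_train(mat, lab, m = 30)
  pred <- lda_predict(model, co$expression)
  lab_of <- stats::setNames(pred$label, pred$sample)
  expect_identical(unname(lab_of[co$duplicate_pairs$sample]),
                   unname(lab_of[co$duplicate_pairs$duplicate]))
})
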
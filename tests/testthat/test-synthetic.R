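test_that("a cohort without planted splits has calibrated gene-wise t-tests", {
  co <- generate_cohort(cohort_spec(
    n_samples = 60, n_genes = 2000, n_duplicates = 0,
    planted_splits = list(), n_mirna = 10, mirna_informative = 0, seed = 7))
  mat <- co$expression
  grp <- rep(c(TRUE, FALSE), length.out = ncol(mat))
  p <- apply(mat, 1, function(x) stats::t.test(x[grp], x[!grp])$p.value)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("the default cohort has the documented structure", {
  co <- generate_cohort(cohort_spec(seed = 2))
  expect_equal(nrow(co$expression), 12000)
  expect_equal(ncol(co$expression), 129 + 12)
  expect_equal(nrow(co$truth), 129)
  expect_equal(nrow(co$duplicate_pairs), 12)
  expect_length(co$modules, 4)
  expect_true(all(lengths(co$modules) == 100))
  # planted modules are pairwise disjoint
  all_genes <- unlist(co$modules)
  expect_equal(anyDuplicated(all_genes), 0)
  expect_equal(nrow(co$mirna), 743)
  expect_equal(rownames(co$mirna)[1], "mir0001")
  # duplicate arrays are extra columns of existing samples
  expect_true(all(co$duplicate_pairs$sample %in% co$truth$sample))
  expect_true(all(co$duplicate_pairs$duplicate %in% colnames(co$expression)))
})

test_that("cohorts are reproducible by seed and vary across seeds", {
  s <- cohort_spec(n_samples = 30, n_genes = 100, n_duplicates = 2,
                   planted_splits = list(planted_split(0.3, 10, 2)),
                   n_mirna = 20, mirna_informative = 5, seed = 11)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$expression, b$expression)
  expect_identical(a$survival, b$survival)
  s2 <- s; s2$seed <- 12L
  c <- generate_cohort(s2)
  expect_false(identical(a$expression, c$expression))
})

test_that("planted between-class separation matches the generating shift", {
  co <- small_cohort(n = 100, genes = 300, effect = 3, module = 50, seed = 5)
  lab <- truth_labels(co)
  mat <- bio_matrix(co)
  mod <- co$modules$split1
  sep <- rowMeans(mat[mod, lab == "g1", drop = FALSE]) -
    rowMeans(mat[mod, lab == "g0", drop = FALSE])
  expect_equal(mean(sep), 3, tolerance = 0.05)
})

test_that("duplicate arrays correlate more than random sample pairs", {
  # with four planted splits a random pair rarely shares all class
  # memberships, while a duplicate pair shares them by construction
  co <- generate_cohort(cohort_spec(
    n_samples = 60, n_genes = 400, n_duplicates = 8,
    planted_splits = default_planted_splits(effect = 3),
    n_mirna = 10, mirna_informative = 0, seed = 9))
  dp <- co$duplicate_pairs
  dup_cor <- mapply(function(a, b) cor(co$expression[, a], co$expression[, b]),
                    dp$sample, dp$duplicate)
  set.seed(1)
  bio <- setdiff(colnames(co$expression), dp$duplicate)
  rand_cor <- replicate(100, {
    p <- sample(bio, 2)
    cor(co$expression[, p[1]], co$expression[, p[2]])
  })
  expect_gt(mean(dup_cor), mean(rand_cor) + 0.02)
  expect_gt(min(dup_cor), stats::quantile(rand_cor, 0.5))
})

test_that("module requests beyond the gene count are rejected", {
  expect_error(
    cohort_spec(n_genes = 150,
                planted_splits = list(planted_split(0.3, 100),
                                      planted_split(0.3, 100))),
    "150")
})

test_that("survival generation respects its degenerate-input contracts", {
  lab <- stats::setNames(rep(c("g0", "g1"), 10), sprintf("s%02d", 1:20))
  expect_error(generate_survival(lab, baseline_rate = 0), "baseline_rate")
  expect_error(generate_survival(lab, hr = -1), "hr")
  all_g0 <- stats::setNames(rep("g0", 10), sprintf("s%02d", 1:10))
  expect_error(generate_survival(all_g0), "non-empty")
})

test_that("survival times achieve the target censoring and null calibration", {
  lab <- stats::setNames(rep(c("g0", "g1"), 500), sprintf("s%04d", 1:1000))
  sv <- generate_survival(lab, hr = 1, baseline_rate = 0.2,
                          censor_frac = 0.3, seed = 3)
  expect_equal(1 - mean(sv$event), 0.3, tolerance = 0.05)
  # under hr = 1 the logrank p-value is approximately uniform
  p <- vapply(1:60, function(r) {
    s <- generate_survival(stats::setNames(rep(c("g0", "g1"), 40),
                                           sprintf("s%03d", 1:80)),
                           hr = 1, baseline_rate = 0.2, censor_frac = 0.3,
                           seed = 1000 + r)
    km_logrank(s)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("microRNA layer shifts only the informative features", {
  lab <- stats::setNames(rep(c("g0", "g1"), c(30, 20)), sprintf("s%02d", 1:50))
  m <- generate_mirna(lab, n_mirna = 100, n_informative = 10, effect = 3,
                      seed = 4)
  expect_equal(dim(m), c(100, 50))
  expect_equal(rownames(m)[c(1, 100)], c("mir0001", "mir0100"))
  info <- attr(m, "informative")
  expect_length(info, 10)
  sep <- rowMeans(m[, lab == "g1"]) - rowMeans(m[, lab == "g0"])
  expect_gt(min(sep[info]), 2)
  expect_lt(max(abs(sep[setdiff(rownames(m), info)])), 1.5)
  expect_error(generate_mirna(lab, n_mirna = 10, n_informative = 11),
               "exceeds")
})
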
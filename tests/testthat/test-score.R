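test_that("probe collapsing keeps the most variable probe per gene", {
  set.seed(1)
  X <- matrix(rnorm(40), 4, 10,
              dimnames = list(c("p1", "p2", "p3", "p4"), paste0("s", 1:10)))
  X["p2", ] <- X["p2", ] * 5          # higher variance than p1
  id_map <- tibble::tibble(probe = c("p1", "p2", "p3", "p4"),
                           gene = c("GA", "GA", "GB", "GC"))
  out <- map_genes(X, id_map)
  expect_setequal(rownames(out), c("GA", "GB", "GC"))
  expect_equal(unname(out["GA", ]), unname(X["p2", ]))

  # identity map leaves values untouched
  idm <- tibble::tibble(probe = rownames(X), gene = rownames(X))
  expect_equal(map_genes(X, idm)[rownames(X), ], X)

  expect_error(map_genes(X, id_map, signature = c("ZZ1", "ZZ2")),
               "signature")
})

test_that("robust scaling maps clip quantiles to the interval ends", {
  # 41 values: the 2.5% quantile falls exactly on the 2nd order statistic
  x <- seq(0, 40)
  m <- rbind(a = x, b = rep(5, 41))
  colnames(m) <- paste0("s", 1:41)
  sc <- robust_scale(m, q = 0.025)
  expect_true(all(sc >= -1 & sc <= 1))
  expect_equal(unname(sc["a", order(x)[2]]), -1)
  expect_equal(unname(sc["a", order(x)[40]]), 1)
  expect_true(all(sc["b", ] == 0))     # constant gene maps to zero
  expect_error(robust_scale(m, q = 0.5), "below 0.5")
})

test_that("robust scaling is invariant under positive affine transforms", {
  set.seed(2)
  m <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  sc <- robust_scale(m)
  for (r in 1:5) {
    a <- runif(10, 0.1, 5); b <- rnorm(10, 0, 10)
    m2 <- m * a + b
    expect_equal(robust_scale(m2), sc, tolerance = 1e-10)
  }
})

test_that("the signature score behaves at its extremes and under negation", {
  genes <- paste0("g", 1:5)
  w <- stats::setNames(c(2, 1, 3, 0.5, 1), genes)
  m <- matrix(1, 5, 3, dimnames = list(genes, c("a", "b", "c")))
  expect_equal(signature_score(m, w)$score, rep(1, 3))
  expect_equal(signature_score(m, -w)$score, rep(-1, 3))
  set.seed(3)
  m2 <- matrix(runif(15, -1, 1), 5, 3, dimnames = dimnames(m))
  s <- signature_score(m2, w)$score
  expect_equal(signature_score(m2, -w)$score, -s)
  expect_true(all(abs(s) <= 1))
  # missing genes are excluded from both sums
  expect_warning(s3 <- signature_score(m2[1:3, ], w), "missing")
  manual <- colSums(w[1:3] * m2[1:3, ]) / sum(abs(w[1:3]))
  expect_equal(s3$score, unname(manual))
  expect_error(signature_score(m2, c(zz = 1)), "no signature gene")
})

test_that("the class separation of scores grows with the planted effect", {
  margin_at <- function(effect) {
    co <- small_cohort(n = 60, genes = 200, effect = effect, module = 40,
                       seed = 61)
    mat <- bio_matrix(co)
    lab <- truth_labels(co, samples = colnames(mat))
    model <- lda_train(mat, lab, m = 40)
    w <- stats::setNames(model$coefs$weight, model$coefs$gene)
    sc <- signature_score(robust_scale(mat), w)
    mean(sc$score[lab == "g1"]) - mean(sc$score[lab == "g0"])
  }
  margins <- vapply(c(0.5, 1.5, 3), margin_at, numeric(1))
  expect_true(all(diff(margins) > 0))
})

test_that("EM log-likelihood is monotone and BIC picks the right k", {
  set.seed(5)
  uni <- rnorm(500)
  g1 <- gmm_bic(uni, k_max = 4, n_restarts = 3, seed = 6)
  expect_equal(g1$k, 1)
  bim <- c(rnorm(300, -2), rnorm(200, 2))
  g2 <- gmm_bic(bim, k_max = 4, n_restarts = 3, seed = 6)
  expect_equal(g2$k, 2)
  for (f in g2$fits) {
    expect_true(all(diff(f$loglik_trace) >= -1e-8))
  }
  expect_error(gmm_bic(rnorm(10)), "at least 20")
  expect_error(gmm_bic(rnorm(19), k_max = 5), "at least")
})

test_that("the mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(7)
  x <- c(rnorm(400, -1.5, 0.7), rnorm(300, 1.8, 0.9))
  g <- gmm_bic(x, k_max = 3, n_restarts = 5, seed = 8)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(g$k, 2)
  expect_equal(sort(g$mixture$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(g$mixture$loglik, mc$loglik, tolerance = 0.01)
})

test_that("subtype calls split at the mixture boundary", {
  mix <- list(weight = c(0.5, 0.5), mean = c(-2, 2), var = c(1, 1))
  calls <- classify_subtype(seq(-4, 4, by = 0.5), mix)
  expect_false(calls$no_subtype)
  expect_equal(calls$boundary, 0, tolerance = 1e-6)
  expect_equal(calls$calls$call[calls$calls$score == 2], "angiogenic")
  expect_equal(calls$calls$call[calls$calls$score == -2], "non-angiogenic")
  # single component: flagged, no calls
  none <- classify_subtype(rnorm(30), list(weight = 1, mean = 0, var = 1))
  expect_true(none$no_subtype)
  expect_true(all(is.na(none$calls$call)))
})

test_that("scoring recovers the planted subtype end to end", {
  co <- small_cohort(n = 120, genes = 300, effect = 2.5, module = 60,
                     fraction = 0.3, seed = 67)
  mat <- bio_matrix(co)
  lab <- truth_labels(co, samples = colnames(mat))
  splits <- search_splits(mat, m = 60, n_perm = 0, seed = 10, max_splits = 1)
  w <- splits[[1]]$weights
  sc <- signature_score(robust_scale(mat), w)
  g <- gmm_bic(sc$score, k_max = 3, n_restarts = 3, seed = 11)
  expect_gte(g$k, 2)
  calls <- classify_subtype(sc, g)
  pred_ang <- calls$calls$call == "angiogenic"
  ag <- label_agreement(pred_ang, lab[calls$calls$sample] == "g1")
  expect_gte(ag, 0.9)
  # upper-component weight tracks the planted minority fraction
  upper <- which.max(g$mixture$mean)
  planted_frac <- mean(lab == "g1")
  expect_lt(abs(g$mixture$weight[upper] - planted_frac), 0.15)
})
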
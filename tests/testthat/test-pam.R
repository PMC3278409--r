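# Independent plain nearest-centroid oracle on standardized features, with
# the same pooled-sd standardization and prior term as the PAM discriminant.
nc_oracle_predict <- function(Xtr, ytr, Xte) {
  classes <- sort(unique(ytr))
  n <- ncol(Xtr)
  cent <- sapply(classes, function(k) rowMeans(Xtr[, ytr == k, drop = FALSE]))
  ss <- 0
  for (k in classes) {
    xk <- Xtr[, ytr == k, drop = FALSE]
    ss <- ss + rowSums((xk - rowMeans(xk))^2)
  }
  s <- sqrt(ss / (n - length(classes)))
  s0 <- median(s)
  pri <- table(ytr)[classes] / n
  apply(Xte, 2, function(x) {
    d <- sapply(seq_along(classes), function(j) {
      sum((x - cent[, j])^2 / (s + s0)^2) - 2 * log(pri[j])
    })
    classes[which.min(d)]
  })
}

test_that("unshrunken PAM agrees with an independent nearest-centroid oracle", {
  for (seed in 1:5) {
    tc <- two_class_matrix(n0 = 15, n1 = 10, genes = 30, n_inf = 8,
                           shift = 1.5, seed = seed)
    fit <- pam_fit(tc$mat, tc$labels, delta = 0)
    tc2 <- two_class_matrix(n0 = 12, n1 = 8, genes = 30, n_inf = 8,
                            shift = 1.5, seed = seed + 100)
    expect_equal(pam_predict(fit, tc2$mat)$label,
                 unname(nc_oracle_predict(tc$mat, tc$labels, tc2$mat)))
  }
})

test_that("full shrinkage collapses to the prior-favored class", {
  tc <- two_class_matrix(n0 = 30, n1 = 10, genes = 40, n_inf = 10,
                         shift = 2, seed = 9)
  fit0 <- pam_fit(tc$mat, tc$labels, delta = 0)
  big <- max(abs(fit0$d)) + 1
  fit <- pam_fit(tc$mat, tc$labels, delta = big)
  expect_length(fit$surviving, 0)
  pred <- pam_predict(fit, tc$mat)
  expect_true(all(pred$label == "g0"))  # majority class has the larger prior
})

test_that("ties in the discriminant go to the lexicographically first class", {
  X <- matrix(c(1, 1, 1.2, 0.8, 3, 3, 3.2, 2.8), 2, 4,
              dimnames = list(c("f1", "f2"), c("a", "b", "c", "d")))
  fit <- pam_fit(X, c("g0", "g0", "g1", "g1"), delta = 0,
                 priors = c(0.5, 0.5))
  # a sample exactly midway between both centroids is a tie
  mid <- matrix((fit$centroids[, 1] + fit$centroids[, 2]) / 2,
                ncol = 1, dimnames = list(rownames(X), "mid"))
  p <- pam_predict(fit, mid)
  expect_equal(p$label, "g0")
  expect_equal(p$score_g0, p$score_g1, tolerance = 1e-12)
})

test_that("a sample at a shrunken centroid is assigned to that class", {
  tc <- two_class_matrix(n0 = 20, n1 = 20, genes = 25, n_inf = 10,
                         shift = 2, seed = 10)
  fit <- pam_fit(tc$mat, tc$labels, delta = 0.5, priors = c(0.5, 0.5))
  at_cent <- matrix(fit$centroids[, "g1"], ncol = 1,
                    dimnames = list(rownames(tc$mat), "x"))
  expect_equal(pam_predict(fit, at_cent)$label, "g1")
})

test_that("nested CV conserves class sizes and nails separable data", {
  tc <- two_class_matrix(n0 = 40, n1 = 20, genes = 60, n_inf = 15,
                         shift = 4, seed = 11)
  cv <- pam_nested_cv(tc$mat, tc$labels, outer_k = 5, inner_k = 3,
                      n_delta = 15, seed = 12)
  expect_equal(unname(rowSums(cv$confusion)), c(40, 20))
  expect_true(all(cv$errors$error < 0.05))
  # consensus features are a subset of every fold's surviving set
  # (by construction of the intersection) and recover the informative ones
  informative <- sprintf("f%03d", 1:15)
  expect_gte(length(intersect(cv$consensus_features, informative)) / 15, 0.8)
  # deterministic under the same seed, invariant to feature order
  cv2 <- pam_nested_cv(tc$mat, tc$labels, outer_k = 5, inner_k = 3,
                       n_delta = 15, seed = 12)
  expect_identical(cv$confusion, cv2$confusion)
  set.seed(13)
  cv3 <- pam_nested_cv(tc$mat[sample(nrow(tc$mat)), ], tc$labels,
                       outer_k = 5, inner_k = 3, n_delta = 15, seed = 12)
  expect_identical(cv$confusion, cv3$confusion)
})

test_that("uninformative features give errors near the no-signal bound", {
  tc <- two_class_matrix(n0 = 40, n1 = 20, genes = 60, n_inf = 0,
                         shift = 0, seed = 14)
  cv <- pam_nested_cv(tc$mat, tc$labels, outer_k = 5, inner_k = 3,
                      n_delta = 15, seed = 15)
  overall <- 1 - sum(diag(cv$confusion)) / sum(cv$confusion)
  # minority proportion is 1/3; allow wide stochastic slack around it
  expect_gt(overall, 0.1)
  expect_lt(overall, 0.55)
})

test_that("degenerate inputs are rejected", {
  tc <- two_class_matrix(seed = 16)
  expect_error(pam_fit(tc$mat, rep("g0", ncol(tc$mat))), "two classes")
  expect_error(pam_nested_cv(tc$mat, tc$labels, outer_k = 40), "fewer")
  fit <- pam_fit(tc$mat, tc$labels)
  expect_error(pam_predict(fit, tc$mat[1:5, ]), "features")
})

test_that("per-class error rates reproduce the published arithmetic", {
  split1 <- matrix(c(80, 3, 16, 30), 2,
                   dimnames = list(c("g0", "g1"), c("g0", "g1")))
  e1 <- per_class_error(split1)
  expect_equal(round(e1$error, 3), c(0.167, 0.091))
  split2 <- matrix(c(71, 17, 12, 29), 2,
                   dimnames = list(c("g0", "g1"), c("g0", "g1")))
  e2 <- per_class_error(split2)
  expect_equal(round(e2$error, 2), c(0.14, 0.37))
  ident <- diag(5); dimnames(ident) <- list(letters[1:5], letters[1:5])
  expect_true(all(per_class_error(ident)$error == 0))
  bad <- matrix(c(0, 1, 0, 2), 2)
  expect_error(per_class_error(bad), "empty")
})
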
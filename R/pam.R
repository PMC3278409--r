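#' Fit a nearest shrunken centroid (PAM) classifier
#'
#' Standardized class-versus-overall centroid differences
#' `d_kg = (xbar_kg - xbar_g) / (m_k (s_g + s0))`, with pooled within-class
#' standard deviations `s_g`, offset `s0` (median of `s_g`), and
#' `m_k = sqrt(1/n_k - 1/n)`, are soft-thresholded at `delta`:
#' `d'_kg = sign(d_kg) max(0, |d_kg| - delta)`. Shrunken centroids are
#' reconstructed as `xbar_g + m_k (s_g + s0) d'_kg`. Features with a
#' nonzero shrunken difference in any class survive.
#'
#' @param mat Features x samples matrix.
#' @param labels Class labels (named vector, tibble with `sample`/`label`,
#'   or vector aligned to columns); at least two samples per class.
#' @param delta Shrinkage threshold (>= 0). `delta = 0` recovers the plain
#'   nearest-centroid rule on standardized features.
#' @param priors Class priors; default empirical proportions.
#' @return A `pam_model`.
#' @export
pam_fit <- function(mat, labels, delta = 0, priors = NULL) {
  .check_matrix(mat)
  if (delta < 0) abort("`delta` must be >= 0.")
  lab <- .pam_labels(labels, colnames(mat))
  classes <- sort(unique(lab))
  if (length(classes) < 2) abort("need at least two classes.")
  counts <- table(lab)[classes]
  if (any(counts < 2)) abort("every class needs at least 2 samples.")
  n <- ncol(mat)
  overall <- rowMeans(mat)
  cent <- vapply(classes, function(k) rowMeans(mat[, lab == k, drop = FALSE]),
                 numeric(nrow(mat)))
  ss <- Reduce(`+`, lapply(classes, function(k) {
    xk <- mat[, lab == k, drop = FALSE]
    rowSums((xk - rowMeans(xk))^2)
  }))
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(counts) - 1 / n)
  d <- sweep(cent - overall, 1, s + s0, "/")
  d <- sweep(d, 2, mk, "/")
  if (is.null(priors)) priors <- as.numeric(counts) / n
  model <- structure(
    list(classes = classes, overall = overall, s = s, s0 = s0, mk = mk,
         d = d, priors = stats::setNames(priors, classes), delta = NA_real_,
         features = rownames(mat)),
    class = "pam_model")
  .pam_shrink(model, delta)
}

# Apply a shrinkage level to a fitted model (cheap; used by the delta grid).
.pam_shrink <- function(model, delta) {
  dsh <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  shrunk <- model$overall +
    sweep(sweep(dsh, 2, model$mk, "*"), 1, model$s + model$s0, "*")
  model$delta <- delta
  model$d_shrunk <- dsh
  model$centroids <- shrunk
  model$surviving <- model$features[rowSums(abs(dsh) > 0) > 0]
  model
}

.pam_labels <- function(labels, samples) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$label), labels$sample)
  }
  if (!is.null(names(labels))) {
    missing <- setdiff(samples, names(labels))
    if (length(missing) > 0) {
      abort(sprintf("labels missing for sample %s.", missing[1]))
    }
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    abort("unnamed labels must align with the matrix columns.")
  }
  as.character(labels)
}

#' Predict classes with a PAM model
#'
#' Assigns each sample to the class minimizing the discriminant
#' `sum_g (x_g - centroid_kg)^2 / (s_g + s0)^2 - 2 log(prior_k)`. Ties are
#' broken deterministically in favor of the lexicographically first class.
#'
#' @param model A `pam_model`.
#' @param mat Features x samples matrix; features must match the model.
#' @return Tibble with `sample`, `label`, and one discriminant-score column
#'   per class (`score_<class>`).
#' @export
pam_predict <- function(model, mat) {
  .check_matrix(mat)
  if (!all(model$features %in% rownames(mat))) {
    abort("matrix features do not match the model's features.")
  }
  X <- mat[model$features, , drop = FALSE]
  denom <- (model$s + model$s0)^2
  scores <- vapply(seq_along(model$classes), function(j) {
    colSums((X - model$centroids[, j])^2 / denom) - 2 * log(model$priors[j])
  }, numeric(ncol(X)))
  scores <- matrix(scores, ncol = length(model$classes),
                   dimnames = list(colnames(X), model$classes))
  # ties go to the lexicographically first class (classes are sorted)
  pick <- apply(scores, 1, which.min)
  out <- tibble::tibble(sample = colnames(X),
                        label = model$classes[pick])
  for (j in seq_along(model$classes)) {
    out[[paste0("score_", model$classes[j])]] <- unname(scores[, j])
  }
  out
}

#' Nested cross-validation for a PAM classifier
#'
#' Outer stratified folds provide the unbiased error estimate; within each
#' outer training set, inner stratified folds choose the shrinkage `delta`
#' minimizing the inner CV error over an evenly spaced grid from 0 to the
#' largest standardized centroid difference (ties resolved toward the
#' larger, i.e. sparser, `delta`). Outer-fold test predictions are pooled
#' into a single confusion matrix; consensus features are the intersection
#' of the surviving features of all outer-fold models.
#'
#' @param mat Features x samples matrix.
#' @param labels Class labels.
#' @param outer_k,inner_k Fold counts (each >= 2); every class must have at
#'   least `outer_k` samples.
#' @param n_delta Size of the shrinkage grid.
#' @param seed Integer seed (controls fold assignment).
#' @return A `pam_cv` object: `confusion` (true x predicted matrix),
#'   `errors` (tibble of per-class error rates from [per_class_error()]),
#'   `consensus_features`, `fold_deltas`, `predictions`.
#' @export
pam_nested_cv <- function(mat, labels, outer_k = 10, inner_k = 5,
                          n_delta = 30, seed = 1) {
  .check_matrix(mat)
  if (outer_k < 2 || inner_k < 2) abort("fold counts must be >= 2.")
  lab <- .pam_labels(labels, colnames(mat))
  classes <- sort(unique(lab))
  counts <- table(lab)[classes]
  if (any(counts < outer_k)) {
    abort(sprintf("class `%s` has %d samples, fewer than outer_k = %d.",
                  names(counts)[which.min(counts)], min(counts), outer_k))
  }
  set.seed(seed)
  folds <- .stratified_folds(lab, outer_k)
  pred_all <- character(length(lab))
  fold_deltas <- numeric(outer_k)
  surviving <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    test_idx <- which(folds == f)
    tr_idx <- which(folds != f)
    Xtr <- mat[, tr_idx, drop = FALSE]
    ytr <- lab[tr_idx]
    base <- pam_fit(Xtr, ytr, delta = 0)
    grid <- seq(0, max(abs(base$d)), length.out = n_delta)
    inner <- .stratified_folds(ytr, inner_k)
    err <- numeric(length(grid))
    for (g in seq_len(inner_k)) {
      it <- which(inner == g)
      fit <- pam_fit(Xtr[, -it, drop = FALSE], ytr[-it], delta = 0)
      for (d in seq_along(grid)) {
        p <- pam_predict(.pam_shrink(fit, grid[d]),
                         Xtr[, it, drop = FALSE])
        err[d] <- err[d] + sum(p$label != ytr[it])
      }
    }
    best <- max(grid[err == min(err)])      # ties -> larger delta
    fold_deltas[f] <- best
    final <- .pam_shrink(base, best)
    surviving[[f]] <- final$surviving
    pred_all[test_idx] <- pam_predict(final, mat[, test_idx, drop = FALSE])$label
  }
  confusion <- table(factor(lab, classes), factor(pred_all, classes))
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(true = classes, predicted = classes))
  structure(
    list(confusion = confusion, errors = per_class_error(confusion),
         consensus_features = sort(Reduce(intersect, surviving)),
         fold_deltas = fold_deltas,
         predictions = tibble::tibble(sample = colnames(mat), true = lab,
                                      predicted = pred_all)),
    class = "pam_cv")
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin into k folds.
.stratified_folds <- function(lab, k) {
  folds <- integer(length(lab))
  for (cl in unique(lab)) {
    idx <- sample(which(lab == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Per-class error rates from a confusion matrix
#'
#' For each true class (row), the off-diagonal row mass divided by the row
#' sum. Rates are returned unrounded; round to 2-3 decimals for reporting.
#'
#' @param confusion Square matrix of counts, true classes in rows.
#' @return Tibble with `class`, `n`, `error`.
#' @export
per_class_error <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    abort("`confusion` must be square (true x predicted).")
  }
  if (any(confusion < 0) || any(confusion != round(confusion))) {
    abort("`confusion` must contain nonnegative integer counts.")
  }
  rs <- rowSums(confusion)
  if (any(rs == 0)) abort("empty true-class row in the confusion matrix.")
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- paste0("class", seq_len(nrow(confusion)))
  tibble::tibble(class = cls, n = as.integer(rs),
                 error = unname(1 - diag(confusion) / rs))
}

#' @export
print.pam_cv <- function(x, ...) {
  cat("<pam_cv> nested cross-validation\n")
  print(x$confusion)
  err <- x$errors
  cat(sprintf("  per-class error: %s\n",
              paste(sprintf("%s = %.3f", err$class, err$error),
                    collapse = ", ")))
  cat(sprintf("  consensus features: %d\n", length(x$consensus_features)))
  invisible(x)
}
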
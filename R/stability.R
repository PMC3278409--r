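#' Bootstrap classification stability of discovered splits
#'
#' For each replicate, a random subset of the samples is drawn (without
#' replacement, size `floor(train_fraction * n)`), the split search is
#' re-run on that subset, and every discovered split is matched to each
#' base split by maximal label agreement (after class matching) on the
#' shared samples. When a match (agreement >= `match_threshold`) is found,
#' a diagonal discriminant trained on the replicate split predicts the
#' replicate's held-out samples, and the agreement between those
#' predictions and the base split's labels — with class orientation fixed
#' by the matching step — is recorded. A base split's stability is the mean
#' of these held-out agreements over matched replicates; the fraction of
#' replicates producing a match is reported alongside. With
#' `train_fraction = 1` there are no held-out samples and in-sample
#' predictions are used, so an exactly rediscoverable split has stability 1.
#'
#' @param mat Genes x samples matrix (the full training set).
#' @param base_splits List of `bipartition` objects from [search_splits()]
#'   on `mat`.
#' @param n_boot Number of bootstrap replicates (>= 10).
#' @param train_fraction Fraction of samples drawn per replicate.
#' @param m Module size used by the replicate searches.
#' @param match_threshold Agreement needed to match a replicate split to a
#'   base split.
#' @param n_perm Permutation draws inside the replicate searches; 0 (the
#'   default) skips the significance filter, significance having been
#'   established on the full data.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [search_splits()] (e.g.
#'   `min_group_size`).
#' @return List of `stable_split` objects (base split + `stability`,
#'   `matched_fraction`, `n_boot`).
#' @export
bootstrap_stability <- function(mat, base_splits, n_boot = 100,
                                train_fraction = 0.63, m = 100,
                                match_threshold = 0.75, n_perm = 0,
                                seed = 1, ...) {
  .check_matrix(mat)
  if (n_boot < 10) abort("`n_boot` must be at least 10.")
  if (train_fraction <= 0 || train_fraction > 1) {
    abort("`train_fraction` must lie in (0, 1].")
  }
  if (length(base_splits) == 0) return(list())
  samples <- colnames(mat)
  n <- length(samples)
  base01 <- lapply(base_splits, function(b) {
    stats::setNames(.labels01(b$labels, samples), samples)
  })
  agree_sum <- numeric(length(base_splits))
  agree_n <- integer(length(base_splits))
  matched <- integer(length(base_splits))

  n_sub <- max(4L, floor(train_fraction * n))
  for (b in seq_len(n_boot)) {
    rs <- .derive_seed(seed, 7000L + b)
    set.seed(rs)
    sub <- sort(sample(samples, min(n_sub, n)))
    held <- setdiff(samples, sub)
    found <- tryCatch(
      search_splits(mat[, sub, drop = FALSE], m = m, n_perm = n_perm,
                    seed = .derive_seed(rs, 13L), ...),
      error = function(e) list())
    if (length(found) == 0) next
    for (i in seq_along(base_splits)) {
      base_sub <- base01[[i]][sub]
      best <- NULL
      best_ag <- -1
      for (f in found) {
        f01 <- .labels01(f$labels, sub)
        ma <- .matched_agreement(f01, unname(base_sub))
        if (ma$agreement > best_ag) {
          best_ag <- ma$agreement
          best <- list(split = f, flipped = ma$flipped)
        }
      }
      if (best_ag < match_threshold) next
      matched[i] <- matched[i] + 1L
      model <- best$split$model
      eval_ids <- if (length(held) > 0) held else sub
      pred <- lda_predict(model, mat[, eval_ids, drop = FALSE])
      pred01 <- as.integer(pred$label == "g1")
      if (best$flipped) pred01 <- 1L - pred01
      agr <- mean(pred01 == unname(base01[[i]][eval_ids]))
      agree_sum[i] <- agree_sum[i] + agr
      agree_n[i] <- agree_n[i] + 1L
    }
  }

  purrr::map(seq_along(base_splits), function(i) {
    structure(
      list(base = base_splits[[i]],
           stability = if (agree_n[i] > 0) agree_sum[i] / agree_n[i] else NA_real_,
           matched_fraction = matched[i] / n_boot,
           n_boot = as.integer(n_boot)),
      class = "stable_split")
  })
}

#' @export
print.stable_split <- function(x, ...) {
  cat(sprintf(
    "<stable_split> stability = %s (matched %.0f%% of %d replicates)\n",
    ifelse(is.na(x$stability), "NA", sprintf("%.3f", x$stability)),
    100 * x$matched_fraction, x$n_boot))
  print(x$base)
  invisible(x)
}

#' Retain splits whose stability clears the bar
#'
#' Keeps splits with stability strictly greater than `threshold` (a split
#' at exactly the threshold is dropped); order is preserved and splits with
#' undefined stability (never matched) are dropped.
#'
#' @param splits List of `stable_split` objects.
#' @param threshold Stability bar (default 0.95).
#' @return Filtered list.
#' @export
retain_stable <- function(splits, threshold = 0.95) {
  Filter(function(s) {
    !is.na(s$stability) && s$stability > threshold
  }, splits)
}

#' Confirm retained splits on the model-selection samples
#'
#' A discriminant trained on the full training labels predicts the
#' model-selection samples; the bootstrap-stability machinery is then
#' re-run on the model-selection matrix with those predictions as the base
#' split, and a split is confirmed iff its holdout stability strictly
#' exceeds `threshold`.
#'
#' @param retained List of `stable_split` objects from [retain_stable()].
#' @param train_mat Training genes x samples matrix.
#' @param model_mat Model-selection matrix; samples must be disjoint from
#'   `train_mat`.
#' @param n_boot Bootstrap replicates on the model-selection set.
#' @param threshold Stability bar.
#' @param m Module size used by the replicate searches.
#' @param seed Integer seed.
#' @param ... Passed to [search_splits()] inside the bootstrap.
#' @return List of confirmed `stable_split` objects carrying the holdout
#'   stability as `holdout_stability` and the predicted model-selection
#'   labels as `holdout_labels`.
#' @export
confirm_on_holdout <- function(retained, train_mat, model_mat, n_boot = 100,
                               threshold = 0.95, m = 100, seed = 1, ...) {
  .check_matrix(train_mat)
  .check_matrix(model_mat)
  overlap <- intersect(colnames(train_mat), colnames(model_mat))
  if (length(overlap) > 0) {
    abort(sprintf("training and model-selection samples overlap (e.g. %s).",
                  overlap[1]))
  }
  confirmed <- list()
  for (s in retained) {
    pred <- lda_predict(s$base$model, model_mat)
    n1 <- sum(pred$label == "g1")
    if (min(n1, nrow(pred) - n1) < 2) next   # split absent from holdout
    hold_bp <- new_bipartition(model_mat, pred$label, m = s$base$m)
    st <- bootstrap_stability(model_mat, list(hold_bp), n_boot = n_boot,
                              m = m, seed = .derive_seed(seed, 31L),
                              ...)[[1]]
    if (!is.na(st$stability) && st$stability > threshold) {
      s$holdout_stability <- st$stability
      s$holdout_labels <- pred
      confirmed[[length(confirmed) + 1L]] <- s
    }
  }
  confirmed
}
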
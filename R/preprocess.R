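#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution:
#' each sample's sorted values are replaced by the mean order-statistic
#' vector, preserving within-sample ranks; ties receive the mean of the
#' values they would otherwise take. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat Numeric genes x samples matrix with at least two samples.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  .check_matrix(mat)
  if (ncol(mat) < 2) abort("quantile normalization needs >= 2 samples.")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Variance-stabilizing surrogate transform
#'
#' A monotone `log2(x + 1)` for raw-scale intensities, or the identity for
#' data already on a stabilized (log-like) scale. This stands in for
#' platform-specific model-based stabilization: downstream steps only
#' require an approximately variance-stabilized monotone scale.
#'
#' @param mat Numeric genes x samples matrix.
#' @param raw_scale If `TRUE`, values must be nonnegative and are
#'   `log2(x + 1)`-transformed; if `FALSE` the matrix is returned unchanged.
#' @return Transformed matrix.
#' @export
vst_surrogate <- function(mat, raw_scale = TRUE) {
  .check_matrix(mat)
  if (!raw_scale) return(mat)
  if (any(mat < 0)) abort("raw-scale input must be nonnegative.")
  log2(mat + 1)
}

#' Select highly variable genes with low duplicate variability
#'
#' Genes whose mean absolute within-duplicate-pair difference exceeds the
#' `dup_quantile` quantile of that statistic are excluded; among the
#' survivors the `k` genes with largest cross-sample variance are returned.
#' Variance is computed with the second copy of each duplicate pair
#' excluded, so technical replicates are not double counted. Ordering is
#' deterministic: decreasing variance, ties broken by gene ID.
#'
#' @param mat Genes x arrays matrix (duplicate columns included).
#' @param dup_pairs Tibble with columns `sample` and `duplicate` naming the
#'   two arrays of each duplicated sample; required when `dup_quantile < 1`.
#' @param k Number of genes to return.
#' @param dup_quantile Quantile of the duplicate-variability statistic above
#'   which genes are excluded (1 disables the filter).
#' @return Tibble with `gene`, `variance`, `dup_stat`, ordered as selected.
#' @export
filter_variable_genes <- function(mat, dup_pairs = NULL, k = 1000,
                                  dup_quantile = 0.75) {
  .check_matrix(mat)
  .assert_count(k, "k")
  if (k > nrow(mat)) abort("`k` exceeds the number of genes.")
  has_dups <- !is.null(dup_pairs) && nrow(dup_pairs) > 0
  if (dup_quantile < 1 && !has_dups) {
    abort("`dup_pairs` is required when `dup_quantile` < 1.")
  }

  dup_stat <- rep(NA_real_, nrow(mat))
  keep <- rep(TRUE, nrow(mat))
  dup_cols <- character()
  if (has_dups) {
    if (!all(c(dup_pairs$sample, dup_pairs$duplicate) %in% colnames(mat))) {
      abort("duplicate-pair members missing from the matrix columns.")
    }
    diffs <- abs(mat[, dup_pairs$sample, drop = FALSE] -
                   mat[, dup_pairs$duplicate, drop = FALSE])
    dup_stat <- rowMeans(diffs)
    dup_cols <- dup_pairs$duplicate
    if (dup_quantile < 1) {
      thr <- stats::quantile(dup_stat, dup_quantile, names = FALSE)
      keep <- dup_stat <= thr
    }
  }

  bio <- mat[, setdiff(colnames(mat), dup_cols), drop = FALSE]
  v <- apply(bio, 1, stats::var)
  survivors <- rownames(mat)[keep]
  if (k > length(survivors)) {
    abort(sprintf(
      "requested k = %d genes but only %d survive the duplicate filter.",
      k, length(survivors)))
  }
  ord <- order(-v[survivors], survivors)
  sel <- survivors[ord][seq_len(k)]
  tibble::tibble(gene = sel, variance = unname(v[sel]),
                 dup_stat = unname(dup_stat[match(sel, rownames(mat))]))
}

#' Partition samples into training and model-selection sets
#'
#' Draws `n_train` biological samples into the training side; both members
#' of any duplicate pair always land on the same side (duplicates follow
#' their source sample).
#'
#' @param samples Character vector of array/sample IDs.
#' @param n_train Number of biological samples in the training set.
#' @param dup_pairs Optional tibble (`sample`, `duplicate`).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `model_selection`.
#' @export
split_train_model_selection <- function(samples, n_train = 82,
                                        dup_pairs = NULL, seed = 1) {
  if (n_train <= 1) abort("`n_train` must exceed 1.")
  dup_of <- character()
  if (!is.null(dup_pairs) && nrow(dup_pairs) > 0) {
    dup_of <- stats::setNames(dup_pairs$duplicate, dup_pairs$sample)
  }
  bio <- setdiff(samples, dup_of)
  if (n_train >= length(bio)) {
    abort(sprintf("`n_train` (%d) must be below the %d biological samples.",
                  n_train, length(bio)))
  }
  set.seed(seed)
  train_bio <- sort(sample(bio, n_train))
  attach_dups <- function(ids) {
    extra <- unname(dup_of[names(dup_of) %in% ids])
    sort(c(ids, extra[extra %in% samples]))
  }
  list(train = attach_dups(train_bio),
       model_selection = attach_dups(sort(setdiff(bio, train_bio))))
}
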
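#' Score a bipartition by its best discriminating gene module
#'
#' Per-gene two-sample t statistics with pooled variance and an additive
#' variance floor `s0` are computed between the two classes; the module is
#' the `m` genes with largest absolute t, and the score is the mean squared
#' t statistic over the module. The score is symmetric under swapping the
#' class labels.
#'
#' @param mat Genes x samples matrix.
#' @param labels `g0`/`g1` labels (tibble, named vector, or vector aligned
#'   to columns).
#' @param m Module size.
#' @param s0 Variance floor; defaults to the median per-gene variance.
#' @return List with `score` (nonnegative scalar) and `module` (tibble
#'   `gene`, `t`, ordered by decreasing `|t|`, ties by gene ID).
#' @export
split_score <- function(mat, labels, m = 100, s0 = NULL) {
  .check_matrix(mat)
  lab01 <- .labels01(labels, colnames(mat))
  if (min(sum(lab01 == 1), sum(lab01 == 0)) < 2) {
    abort("each class must contain at least 2 samples.")
  }
  if (is.null(s0)) s0 <- .variance_floor(mat)
  res <- cpp_split_score(mat, lab01, as.integer(m), s0)
  t <- as.numeric(res$t)
  names(t) <- rownames(mat)
  ord <- order(-abs(t), names(t))
  mod <- ord[seq_len(min(m, length(t)))]
  list(score = res$score,
       module = tibble::tibble(gene = names(t)[mod], t = unname(t[mod])))
}

# Candidate seeds: 2-means on each of the leading principal components, and
# largest-gap threshold splits on the most variable genes. Returns an
# integer matrix (samples x candidates), deduplicated up to label swap.
.seed_candidates <- function(mat, min_group, n_pcs = 10, n_gap_genes = 200,
                             all_thresholds = FALSE) {
  n <- ncol(mat)
  seeds <- list()

  n_pcs <- min(n_pcs, n - 1)
  pr <- tryCatch(
    stats::prcomp(t(mat), center = TRUE, scale. = FALSE, rank. = n_pcs),
    error = function(e) NULL)
  if (!is.null(pr)) {
    for (j in seq_len(ncol(pr$x))) {
      km <- stats::kmeans(pr$x[, j], centers = 2, nstart = 5)
      seeds[[length(seeds) + 1L]] <- as.integer(km$cluster == 1)
    }
  }

  v <- apply(mat, 1, stats::var)
  top <- order(-v, rownames(mat))[seq_len(min(n_gap_genes, nrow(mat)))]
  lo <- max(min_group, 2L)
  if (n - 2 * lo >= 0) {
    for (g in top) {
      x <- sort(mat[g, ])
      pos <- lo:(n - lo)             # cut after position pos
      if (all_thresholds) {
        for (cut in pos) {
          thr <- (x[cut] + x[cut + 1]) / 2
          seeds[[length(seeds) + 1L]] <- as.integer(mat[g, ] > thr)
        }
      } else {
        gaps <- x[pos + 1] - x[pos]
        cut <- pos[which.max(gaps)]
        thr <- (x[cut] + x[cut + 1]) / 2
        seeds[[length(seeds) + 1L]] <- as.integer(mat[g, ] > thr)
      }
    }
  }

  seeds <- Filter(function(s) {
    k <- sum(s)
    k >= 2 && (length(s) - k) >= 2
  }, seeds)
  if (length(seeds) == 0) return(matrix(integer(), nrow = n, ncol = 0))
  sm <- do.call(cbind, seeds)
  # canonical orientation (first sample in class 0), then drop exact dups
  for (j in seq_len(ncol(sm))) if (sm[1, j] == 1L) sm[, j] <- 1L - sm[, j]
  sm[, !duplicated(t(sm)), drop = FALSE]
}

# Refine all seeds on a matrix; returns list(labels = matrix, scores).
.refine_candidates <- function(mat, min_group, m, s0, max_sweeps,
                               all_thresholds = FALSE) {
  seeds <- .seed_candidates(mat, min_group, all_thresholds = all_thresholds)
  if (ncol(seeds) == 0) {
    return(list(labels = seeds, scores = numeric()))
  }
  cpp_refine_many(mat, seeds, as.integer(m), s0, as.integer(min_group),
                  as.integer(max_sweeps))
}

#' Search for statistically supported binary partitions
#'
#' Candidate bipartitions are seeded from 2-means on the top principal
#' components and from largest-gap threshold splits on the most variable
#' genes, then refined by greedy single-sample reassignment that maximizes
#' the module t-squared score (see [split_score()]) until a fixed point
#' (capped at `max_sweeps` sweeps). Significance is assessed against a
#' permutation null that destroys gene-sample association (each gene's
#' values are independently permuted across samples) and re-runs the full
#' seeded search, taking the maximum refined score per draw so that
#' selection over many candidates is accounted for. Surviving splits are
#' deduplicated by label agreement and returned sorted by score; an empty
#' list is a valid outcome.
#'
#' @param mat Genes x samples matrix, already filtered to informative genes.
#' @param m Module size supporting each split.
#' @param max_splits Maximum number of splits to report.
#' @param min_group_size Minimum class size; default `max(5, 10%)` of
#'   samples.
#' @param redundancy_max Two splits agreeing (after class matching) more
#'   than this are considered the same; the higher-scoring one is kept.
#' @param n_perm Permutation draws for the null (0 skips the significance
#'   filter).
#' @param alpha Significance level; candidates with permutation `p >= alpha`
#'   are discarded.
#' @param seed Integer seed; the search is deterministic given the seed.
#' @param max_sweeps Refinement sweep cap.
#' @param all_thresholds Seed from every single-gene threshold cut instead
#'   of only each gene's largest gap (exhaustive seeding; intended for
#'   small matrices).
#' @return List of `bipartition` objects sorted by decreasing score.
#' @export
search_splits <- function(mat, m = 100, max_splits = 6,
                          min_group_size = NULL, redundancy_max = 0.8,
                          n_perm = 100, alpha = 0.05, seed = 1,
                          max_sweeps = 50, all_thresholds = FALSE) {
  .check_matrix(mat)
  n <- ncol(mat)
  if (is.null(min_group_size)) min_group_size <- max(5L, ceiling(0.1 * n))
  if (min_group_size > n / 2) {
    abort(sprintf("`min_group_size` (%d) exceeds half the %d samples.",
                  min_group_size, n))
  }
  s0 <- .variance_floor(mat)
  set.seed(seed)
  ref <- .refine_candidates(mat, min_group_size, m, s0, max_sweeps,
                            all_thresholds = all_thresholds)
  if (length(ref$scores) == 0) return(list())

  # collapse refined candidates that converged to identical label vectors
  canon <- ref$labels
  for (j in seq_len(ncol(canon))) {
    if (canon[1, j] == 1L) canon[, j] <- 1L - canon[, j]
  }
  keep <- !duplicated(t(canon))
  labs <- canon[, keep, drop = FALSE]
  scores <- ref$scores[keep]

  pvals <- rep(NA_real_, length(scores))
  if (n_perm > 0) {
    null_max <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      set.seed(.derive_seed(seed, b))
      perm <- mat
      for (g in seq_len(nrow(perm))) perm[g, ] <- perm[g, sample.int(n)]
      pref <- .refine_candidates(perm, min_group_size, m, s0, max_sweeps,
                                 all_thresholds = all_thresholds)
      null_max[b] <- if (length(pref$scores)) max(pref$scores) else 0
    }
    pvals <- vapply(scores, function(s) {
      (1 + sum(null_max >= s)) / (n_perm + 1)
    }, numeric(1))
    sig <- pvals < alpha
    labs <- labs[, sig, drop = FALSE]
    scores <- scores[sig]
    pvals <- pvals[sig]
  }
  if (length(scores) == 0) return(list())

  # agreement-based deduplication, highest score wins
  ord <- order(-scores)
  chosen <- integer()
  for (j in ord) {
    dup <- any(vapply(chosen, function(i) {
      .matched_agreement(labs[, i], labs[, j])$agreement > redundancy_max
    }, logical(1)))
    if (!dup) chosen <- c(chosen, j)
    if (length(chosen) >= max_splits) break
  }

  lapply(chosen, function(j) {
    new_bipartition(mat, labs[, j], m = m, s0 = s0, pvalue = pvals[j])
  })
}

# Build a bipartition object from 0/1 labels; class 1 is forced to be the
# smaller class, the module and weights are recomputed on `mat`.
#' Construct a bipartition from sample labels
#'
#' @param mat Genes x samples matrix.
#' @param labels `g0`/`g1` labels (any accepted form) or a 0/1 vector.
#' @param m Module size.
#' @param s0 Variance floor (default: median gene variance of `mat`).
#' @param pvalue Optional permutation p-value to attach.
#' @return A `bipartition` object.
#' @export
new_bipartition <- function(mat, labels, m = 100, s0 = NULL, pvalue = NA_real_) {
  .check_matrix(mat)
  lab01 <- if (is.numeric(labels) && is.null(names(labels)) &&
               all(labels %in% c(0, 1))) {
    as.integer(labels)
  } else {
    .labels01(labels, colnames(mat))
  }
  if (sum(lab01 == 1) > sum(lab01 == 0)) lab01 <- 1L - lab01
  if (is.null(s0)) s0 <- .variance_floor(mat)
  sc <- split_score(mat, ifelse(lab01 == 1, "g1", "g0"), m = m, s0 = s0)
  bp <- structure(
    list(labels = tibble::tibble(sample = colnames(mat),
                                 label = ifelse(lab01 == 1, "g1", "g0")),
         module = sc$module, score = sc$score, pvalue = pvalue,
         s0 = s0, m = as.integer(m)),
    class = "bipartition")
  bp$model <- lda_train(mat, bp)
  bp$weights <- stats::setNames(bp$model$coefs$weight, bp$model$coefs$gene)
  bp
}

#' @export
print.bipartition <- function(x, ...) {
  n1 <- sum(x$labels$label == "g1")
  cat(sprintf("<bipartition> g1 = %d / %d samples; score = %.3f; p = %s\n",
              n1, nrow(x$labels), x$score,
              ifelse(is.na(x$pvalue), "NA", format(x$pvalue, digits = 3))))
  invisible(x)
}

#' Train a diagonal linear discriminant on a split's gene module
#'
#' Per-gene weights are `(mean_g1 - mean_g0) / (s_g^2 + s0)` with pooled
#' within-class variances `s_g^2`; gene centers are class-mean midpoints.
#' The decision threshold on the projection `sum_g w_g (x_g - center_g)` is
#' placed at the equal-error point of the training projections.
#'
#' @param mat Genes x samples matrix.
#' @param bipartition A `bipartition` (its module is used) or `g0`/`g1`
#'   labels, in which case the `m` most discriminating genes are selected.
#' @param m Module size when raw labels are given.
#' @param s0 Variance floor; default median gene variance.
#' @return A `dlda_model` with tibble `coefs` (`gene`, `weight`, `center`)
#'   and the decision `threshold`.
#' @export
lda_train <- function(mat, bipartition, m = 100, s0 = NULL) {
  .check_matrix(mat)
  if (is.null(s0)) s0 <- .variance_floor(mat)
  if (inherits(bipartition, "bipartition")) {
    lab01 <- .labels01(bipartition$labels, colnames(mat))
    module <- bipartition$module$gene
    s0 <- bipartition$s0
  } else {
    lab01 <- .labels01(bipartition, colnames(mat))
    module <- split_score(mat, bipartition, m = m, s0 = s0)$module$gene
  }
  if (!all(module %in% rownames(mat))) {
    abort("module genes missing from the matrix.")
  }
  X <- mat[module, , drop = FALSE]
  x1 <- X[, lab01 == 1, drop = FALSE]
  x0 <- X[, lab01 == 0, drop = FALSE]
  if (ncol(x1) < 2 || ncol(x0) < 2) abort("each class needs >= 2 samples.")
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  n1 <- ncol(x1); n0 <- ncol(x0)
  ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  sp2 <- ss / (n1 + n0 - 2)
  w <- (m1 - m0) / (sp2 + s0)
  if (all(w == 0)) abort("degenerate module: all discriminant weights zero.")
  center <- (m1 + m0) / 2
  proj <- colSums(w * (X - center))
  model <- structure(
    list(coefs = tibble::tibble(gene = module, weight = unname(w),
                                center = unname(center)),
         threshold = .equal_error_threshold(proj, lab01),
         total_abs_weight = sum(abs(w))),
    class = "dlda_model")
  model
}

# Threshold minimizing |err(g0 above) - err(g1 below)|, ties by total error
# then by value; candidates are midpoints of adjacent sorted projections.
.equal_error_threshold <- function(proj, lab01) {
  o <- order(proj)
  p <- proj[o]
  cand <- unique(c(p[1] - 1, (p[-1] + p[-length(p)]) / 2, p[length(p)] + 1))
  err0 <- vapply(cand, function(th) mean(proj[lab01 == 0] > th), numeric(1))
  err1 <- vapply(cand, function(th) mean(proj[lab01 == 1] <= th), numeric(1))
  sc <- abs(err0 - err1)
  tot <- err0 + err1
  best <- order(sc, tot, cand)[1]
  cand[best]
}

#' Classify samples with a trained diagonal discriminant
#'
#' Module genes absent from the matrix are dropped with a warning and the
#' projection is rescaled by the ratio of total absolute weight to the
#' weight actually available, keeping projections comparable with the
#' trained threshold.
#'
#' @param model A `dlda_model`.
#' @param mat Genes x samples matrix.
#' @return Tibble with `sample`, `projection`, `label` (`g1` iff projection
#'   exceeds the threshold).
#' @export
lda_predict <- function(model, mat) {
  .check_matrix(mat)
  coefs <- model$coefs
  present <- coefs$gene %in% rownames(mat)
  if (!any(present)) abort("all module genes are missing from the matrix.")
  if (!all(present)) {
    warn(sprintf("%d of %d module genes missing; weights renormalized.",
                 sum(!present), length(present)))
    coefs <- coefs[present, , drop = FALSE]
  }
  X <- mat[coefs$gene, , drop = FALSE]
  proj <- colSums(coefs$weight * (X - coefs$center))
  scale <- model$total_abs_weight / sum(abs(coefs$weight))
  proj <- proj * scale
  tibble::tibble(sample = colnames(mat), projection = unname(proj),
                 label = ifelse(proj > model$threshold, "g1", "g0"))
}
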
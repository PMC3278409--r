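#' Collapse probe-level rows onto a shared gene namespace
#'
#' Probes mapping to the same gene are summarized by the single probe with
#' the largest cross-sample variance; unmapped probes are dropped (their
#' count is reported in a message).
#'
#' @param mat Probes x samples matrix.
#' @param id_map Tibble/data frame with columns `probe` and `gene`
#'   (many-to-one).
#' @param signature Optional character vector of signature genes; an error
#'   is raised if the mapped matrix shares no gene with it.
#' @return Genes x samples matrix.
#' @export
map_genes <- function(mat, id_map, signature = NULL) {
  .check_matrix(mat)
  if (!all(c("probe", "gene") %in% names(id_map))) {
    abort("`id_map` needs columns `probe` and `gene`.")
  }
  id_map <- dplyr::distinct(tibble::as_tibble(id_map[c("probe", "gene")]))
  if (anyDuplicated(id_map$probe)) {
    abort("`id_map` must be many-to-one: a probe maps to a single gene.")
  }
  mapped <- id_map[id_map$probe %in% rownames(mat), , drop = FALSE]
  n_drop <- nrow(mat) - nrow(mapped)
  if (n_drop > 0) message(sprintf("dropping %d unmapped probe(s).", n_drop))
  if (nrow(mapped) == 0) abort("no probe in the matrix is mapped.")
  v <- apply(mat[mapped$probe, , drop = FALSE], 1, stats::var)
  pick <- mapped |>
    dplyr::mutate(variance = unname(v[.data$probe])) |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(dplyr::desc(.data$variance), .data$probe,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  out <- mat[pick$probe, , drop = FALSE]
  rownames(out) <- pick$gene
  out <- out[order(rownames(out)), , drop = FALSE]
  if (!is.null(signature) && length(intersect(rownames(out), signature)) == 0) {
    abort("no signature gene present after mapping.")
  }
  out
}

#' Robustly scale each gene to the range \[-1, 1\]
#'
#' Per gene, values are clipped at the `q` and `1 - q` quantiles and those
#' two quantiles are mapped affinely to -1 and +1. The map is insensitive
#' to outliers beyond the clip points and equivariant under positive affine
#' transforms of the input. Constant genes map to 0 everywhere.
#'
#' @param mat Genes x samples matrix with at least 3 samples.
#' @param q Tail proportion clipped on each side (default 0.025); must be
#'   below 0.5.
#' @return Matrix of the same shape with values in `[-1, 1]`.
#' @export
robust_scale <- function(mat, q = 0.025) {
  .check_matrix(mat)
  if (q >= 0.5) abort("`q` must be below 0.5.")
  if (ncol(mat) < 3) abort("robust scaling needs >= 3 samples.")
  lo <- apply(mat, 1, stats::quantile, probs = q, names = FALSE)
  hi <- apply(mat, 1, stats::quantile, probs = 1 - q, names = FALSE)
  rng <- hi - lo
  out <- (pmin(pmax(mat, lo), hi) - lo) / ifelse(rng > 0, rng, 1) * 2 - 1
  out[rng == 0, ] <- 0
  dimnames(out) <- dimnames(mat)
  out
}

#' Weighted signature score per sample
#'
#' `score_s = sum_g w_g x_gs / sum_g |w_g|` over the signature genes
#' present in the matrix; with inputs scaled to `[-1, 1]` the score also
#' lies in `[-1, 1]`. Positive weights mark genes higher in the angiogenic
#' class, so larger scores are more angiogenic. Signature genes absent from
#' the matrix are excluded from both sums (with a warning).
#'
#' @param scaled_mat Genes x samples matrix, typically from
#'   [robust_scale()].
#' @param weights Named numeric vector of signature weights.
#' @return Tibble with `sample` and `score`.
#' @export
signature_score <- function(scaled_mat, weights) {
  .check_matrix(scaled_mat)
  if (is.null(names(weights))) abort("`weights` must be named by gene.")
  genes <- intersect(names(weights), rownames(scaled_mat))
  if (length(genes) == 0) {
    abort("no signature gene present in the matrix.")
  }
  if (length(genes) < length(weights)) {
    warn(sprintf("%d of %d signature genes missing from the matrix.",
                 length(weights) - length(genes), length(weights)))
  }
  w <- weights[genes]
  sc <- colSums(w * scaled_mat[genes, , drop = FALSE]) / sum(abs(w))
  tibble::tibble(sample = colnames(scaled_mat), score = unname(sc))
}

#' Fit univariate Gaussian mixtures and choose the component count by BIC
#'
#' For each `k` in `1..k_max`, an EM-fitted mixture of `k` Gaussians
#' (k-means initialization, `n_restarts` restarts, convergence tolerance
#' 1e-6 on the log-likelihood) is scored by
#' `BIC = -2 loglik + (3k - 1) log(n)`; the best `k` minimizes BIC. The
#' log-likelihood trace of every EM run is retained (it is non-decreasing
#' by construction).
#'
#' @param scores Numeric vector (>= 20 values and >= `4 * k_max`).
#' @param k_max Largest component count considered.
#' @param n_restarts EM restarts per `k`.
#' @param seed Integer seed.
#' @return A `gmm_fit`: `k` (chosen), `fits` (per-k parameter lists),
#'   `bic` (tibble `k`, `loglik`, `bic`), `mixture` (the chosen fit).
#' @export
gmm_bic <- function(scores, k_max = 5, n_restarts = 5, seed = 1) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) abort("`scores` must be finite.")
  n <- length(scores)
  if (n < 20) abort("need at least 20 scores.")
  if (n < 4 * k_max) {
    abort(sprintf("need at least 4 * k_max = %d scores, got %d.",
                  4 * k_max, n))
  }
  set.seed(seed)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- .em_univariate(scores, k)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    fits[[k]] <- best
  }
  bic_tbl <- tibble::tibble(
    k = seq_len(k_max),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    bic = vapply(seq_len(k_max), function(k) {
      -2 * fits[[k]]$loglik + (3 * k - 1) * log(n)
    }, numeric(1)))
  k_best <- bic_tbl$k[which.min(bic_tbl$bic)]
  structure(
    list(k = k_best, fits = fits, bic = bic_tbl,
         mixture = fits[[k_best]], scores = scores),
    class = "gmm_fit")
}

# One EM run for a k-component univariate Gaussian mixture. Initialization
# is k-means on the data (random starting centers from the RNG stream).
.em_univariate <- function(x, k, tol = 1e-6, max_iter = 500) {
  n <- length(x)
  var_floor <- max(stats::var(x), .Machine$double.eps) * 1e-6
  if (k == 1) {
    mu <- mean(x)
    v <- stats::var(x) * (n - 1) / n
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(list(k = 1, weight = 1, mean = mu, var = v, loglik = ll,
                loglik_trace = ll))
  }
  km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1))
  mu <- as.numeric(km$centers)
  v <- vapply(seq_len(k), function(j) {
    xs <- x[km$cluster == j]
    max(stats::var(xs) * (length(xs) - 1) / max(length(xs), 1),
        var_floor, na.rm = TRUE)
  }, numeric(1))
  w <- as.numeric(table(factor(km$cluster, seq_len(k)))) / n
  w <- pmax(w, 1e-8); w <- w / sum(w)
  trace <- numeric()
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(x, mu[j], sqrt(v[j]))
    }, numeric(n))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- vapply(seq_len(k), function(j) {
      max(sum(resp[, j] * (x - mu[j])^2) / nk[j], var_floor)
    }, numeric(1))
  }
  ord <- order(mu)
  list(k = k, weight = w[ord], mean = mu[ord], var = v[ord],
       loglik = trace[length(trace)], loglik_trace = trace)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> chosen k = %d (BIC over k = 1..%d)\n",
              x$k, max(x$bic$k)))
  print(x$bic, n = nrow(x$bic))
  invisible(x)
}

#' Call subtypes from a score mixture
#'
#' Components are merged into an "upper" component (the one with the
#' highest mean) versus the rest; a sample is called angiogenic iff the
#' posterior probability of the upper component exceeds 0.5. The decision
#' boundary (the score where that posterior crosses 0.5 between the two
#' top component means) is reported. With a single-component mixture no
#' calls are made and the result is flagged `no_subtype`.
#'
#' @param scores Tibble (`sample`, `score`) from [signature_score()] or a
#'   numeric vector (optionally named).
#' @param mixture A `gmm_fit` (its chosen mixture is used) or a mixture
#'   parameter list with `weight`, `mean`, `var`.
#' @return A `subtype_calls` object: tibble `calls` (`sample`, `score`,
#'   `p_upper`, `call`), `boundary`, `no_subtype`.
#' @export
classify_subtype <- function(scores, mixture) {
  if (is.data.frame(scores)) {
    ids <- scores$sample
    x <- scores$score
  } else {
    x <- as.numeric(scores)
    ids <- if (!is.null(names(scores))) names(scores) else
      sprintf("s%04d", seq_along(x))
  }
  mix <- if (inherits(mixture, "gmm_fit")) mixture$mixture else mixture
  k <- length(mix$mean)
  if (k < 2) {
    return(structure(
      list(calls = tibble::tibble(sample = ids, score = x,
                                  p_upper = NA_real_, call = NA_character_),
           boundary = NA_real_, no_subtype = TRUE),
      class = "subtype_calls"))
  }
  upper <- which.max(mix$mean)
  post_upper <- function(xx) {
    dens <- vapply(seq_len(k), function(j) {
      mix$weight[j] * stats::dnorm(xx, mix$mean[j], sqrt(mix$var[j]))
    }, numeric(length(xx)))
    dens <- matrix(dens, ncol = k)
    tot <- rowSums(dens)
    ifelse(tot > 0, dens[, upper] / tot, 0)
  }
  p <- post_upper(x)
  call <- ifelse(p > 0.5, "angiogenic", "non-angiogenic")
  lower_mean <- max(mix$mean[-upper])
  boundary <- tryCatch(
    stats::uniroot(function(z) post_upper(z) - 0.5,
                   lower = lower_mean, upper = mix$mean[upper])$root,
    error = function(e) {
      grid <- seq(min(x), max(x), length.out = 2001)
      pg <- post_upper(grid)
      cross <- which(diff(pg > 0.5) != 0)
      if (length(cross)) grid[cross[length(cross)]] else NA_real_
    })
  structure(
    list(calls = tibble::tibble(sample = ids, score = x, p_upper = p,
                                call = call),
         boundary = boundary, no_subtype = FALSE),
    class = "subtype_calls")
}

#' @export
print.subtype_calls <- function(x, ...) {
  if (x$no_subtype) {
    cat("<subtype_calls> unimodal score distribution: no subtype called\n")
  } else {
    tab <- table(x$calls$call)
    cat(sprintf("<subtype_calls> boundary = %.3f; %s\n", x$boundary,
                paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}
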
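#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize discovered splits
#'
#' `tidy()` returns the per-sample labels; `glance()` a one-row summary
#' (score, permutation p, class sizes, module size).
#'
#' @param x A `bipartition`.
#' @param ... Unused.
#' @name tidy.bipartition
#' @export
tidy.bipartition <- function(x, ...) x$labels

#' @rdname tidy.bipartition
#' @export
glance.bipartition <- function(x, ...) {
  tibble::tibble(
    score = x$score, p_value = x$pvalue,
    n_g0 = sum(x$labels$label == "g0"),
    n_g1 = sum(x$labels$label == "g1"),
    module_size = nrow(x$module))
}

#' @export
tidy.dlda_model <- function(x, ...) x$coefs

#' @export
glance.dlda_model <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$coefs), threshold = x$threshold,
                 total_abs_weight = x$total_abs_weight)
}

#' @export
glance.stable_split <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$base),
    tibble::tibble(stability = x$stability,
                   matched_fraction = x$matched_fraction,
                   n_boot = x$n_boot))
}

#' @export
tidy.pam_cv <- function(x, ...) {
  tibble::as_tibble(as.table(x$confusion)) |>
    stats::setNames(c("true", "predicted", "n"))
}

#' @export
glance.pam_cv <- function(x, ...) {
  tibble::tibble(
    overall_error = 1 - sum(diag(x$confusion)) / sum(x$confusion),
    n = sum(x$confusion),
    n_consensus_features = length(x$consensus_features))
}

#' @export
tidy.gmm_fit <- function(x, ...) {
  mix <- x$mixture
  tibble::tibble(component = seq_len(x$k), weight = mix$weight,
                 mean = mix$mean, variance = mix$var)
}

#' @export
glance.gmm_fit <- function(x, ...) {
  best <- x$bic[x$bic$k == x$k, ]
  tibble::tibble(k = x$k, loglik = best$loglik, bic = best$bic,
                 n = length(x$scores))
}

#' @export
tidy.subtype_calls <- function(x, ...) x$calls

#' @export
glance.subtype_calls <- function(x, ...) {
  tibble::tibble(
    no_subtype = x$no_subtype, boundary = x$boundary,
    n_angiogenic = sum(x$calls$call == "angiogenic", na.rm = TRUE),
    n_non_angiogenic = sum(x$calls$call == "non-angiogenic", na.rm = TRUE))
}

#' @export
tidy.km_result <- function(x, ...) x$curves

#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p_value = x$p_value)
}
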
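#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the score distribution with its fitted mixture
#'
#' Histogram of the subtype scores overlaid with the density of each
#' fitted Gaussian component (scaled by its weight) and their sum.
#'
#' @param object A `gmm_fit`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmm_fit <- function(object, bins = 40, ...) {
  scores <- tibble::tibble(score = object$scores)
  mix <- object$mixture
  grid <- seq(min(object$scores), max(object$scores), length.out = 400)
  comp <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble::tibble(score = grid, component = factor(j),
                   density = mix$weight[j] *
                     stats::dnorm(grid, mix$mean[j], sqrt(mix$var[j])))
  })
  total <- comp |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", color = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density,
                                    color = .data$component)) +
    ggplot2::geom_line(data = total, ggplot2::aes(y = .data$density),
                       linewidth = 1) +
    ggplot2::labs(x = "subtype score", y = "density",
                  title = sprintf("Score distribution (BIC-chosen k = %d)",
                                  object$k)) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves per group
#'
#' @param object A `km_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_result <- function(object, ...) {
  curves <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, g) {
      tibble::add_row(d, time = 0, n_risk = max(d$n_risk),
                      n_event = 0, surv = 1, .before = 1)
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  subtitle = sprintf("logrank p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a split's module expression
#'
#' Genes of the supporting module in rows, samples in columns (grouped by
#' class), expression centered per gene.
#'
#' @param object A `bipartition`.
#' @param mat The genes x samples matrix the split was discovered on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bipartition <- function(object, mat, ...) {
  .check_matrix(mat)
  genes <- intersect(object$module$gene, rownames(mat))
  ord <- object$labels |>
    dplyr::arrange(.data$label, .data$sample)
  X <- mat[genes, ord$sample, drop = FALSE]
  X <- X - rowMeans(X)
  df <- tibble::as_tibble(X, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample",
                        values_to = "expression") |>
    dplyr::mutate(sample = factor(.data$sample, levels = ord$sample),
                  gene = factor(.data$gene, levels = rev(genes)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$gene,
                                   fill = .data$expression)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "yellow") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = "samples (g0 then g1)", y = "module genes")
}
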
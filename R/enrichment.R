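#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then tab-separated member gene
#' IDs.
#'
#' @param path Path to a GMT file.
#' @return Tibble with `set`, `description`, and list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("empty GMT file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", bad[1]))
  }
  out <- tibble::tibble(
    set = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)])))
  if (anyDuplicated(out$set)) abort("duplicate set names in GMT file.")
  out
}

#' Hypergeometric over-representation of a gene module in gene sets
#'
#' Each set is intersected with the universe; the upper-tail
#' hypergeometric p-value of its overlap with the module is computed, and
#' Benjamini-Hochberg q-values control the FDR across sets. Sets with
#' `q < fdr` are flagged.
#'
#' @param module Character vector of module gene IDs (must be contained in
#'   the universe).
#' @param sets A tibble from [read_gmt()], or a named list of gene-ID
#'   vectors.
#' @param universe Character vector of all assayed gene IDs.
#' @param fdr FDR flag threshold (default 0.10).
#' @return Tibble with `set`, `set_size`, `overlap`, `p_value`, `q_value`,
#'   `significant`, sorted by `p_value`.
#' @export
hypergeom_enrich <- function(module, sets, universe, fdr = 0.10) {
  universe <- unique(universe)
  module <- unique(module)
  if (length(universe) == 0) abort("`universe` is empty.")
  if (length(module) == 0) abort("`module` is empty.")
  if (!all(module %in% universe)) {
    abort("`module` must be a subset of `universe`.")
  }
  if (is.data.frame(sets)) {
    set_list <- stats::setNames(sets$genes, sets$set)
  } else {
    set_list <- sets
  }
  if (length(set_list) == 0) abort("no gene sets supplied.")
  N <- length(universe)
  n <- length(module)
  res <- purrr::map_dfr(names(set_list), function(nm) {
    g <- intersect(set_list[[nm]], universe)
    K <- length(g)
    k <- length(intersect(g, module))
    # upper tail: P(overlap >= k)
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = K, overlap = k, p_value = p)
  })
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr
  dplyr::arrange(res, .data$p_value, .data$set)
}
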
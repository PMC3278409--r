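#' Read an expression matrix from TSV
#'
#' Expects a header row of sample IDs, a first column of gene IDs, and
#' numeric cells. Ragged rows, non-numeric cells and duplicated gene IDs
#' are reported with the offending line/ID.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric genes x samples matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("empty file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) abort(sprintf("no data rows in %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  bad <- which(lengths(fields) != width)
  if (length(bad) > 0) {
    abort(sprintf("ragged row at line %d of %s (expected %d fields, got %d).",
                  bad[1], path, width, lengths(fields)[bad[1]]))
  }
  header <- fields[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) abort("duplicated sample IDs in header.")
  genes <- vapply(fields[-1], `[[`, character(1), 1)
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated gene ID `%s`.", dup[1]))
  }
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(genes)) {
    v <- suppressWarnings(as.numeric(fields[[i + 1]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(sprintf("non-numeric cell at line %d, column %d (`%s`).",
                    i + 1, j + 1, fields[[i + 1]][j + 1]))
    }
    vals[i, ] <- v
  }
  vals
}

#' Write an expression matrix as TSV
#'
#' First column `gene`, header row of sample IDs.
#'
#' @param mat Genes x samples matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(mat, path) {
  .check_matrix(mat)
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `expression.tsv` and `mirna.tsv` matrices, a `phenotype.tsv`
#' (sample, survival, clinical covariates, truth labels) and
#' `duplicate_pairs.tsv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    abort("`cohort` must be a synthetic_cohort.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_expression(cohort$mirna, file.path(dir, "mirna.tsv"))
  pheno <- cohort$survival |>
    dplyr::select("sample", "time", "event") |>
    dplyr::left_join(cohort$clinical, by = "sample") |>
    dplyr::left_join(cohort$truth, by = "sample")
  readr::write_tsv(pheno, file.path(dir, "phenotype.tsv"))
  readr::write_tsv(cohort$duplicate_pairs,
                   file.path(dir, "duplicate_pairs.tsv"))
  invisible(dir)
}
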
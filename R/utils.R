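#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @useDynLib risisr, .registration = TRUE
NULL

# Validate a genes x samples expression matrix.
.check_matrix <- function(mat, arg = "mat") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples).", arg))
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(mat))) {
    abort(sprintf("`%s` has duplicated gene IDs.", arg))
  }
  if (anyDuplicated(colnames(mat))) {
    abort(sprintf("`%s` has duplicated sample IDs.", arg))
  }
  if (!all(is.finite(mat))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(mat)
}

# Accept labels as a tibble (sample, label), a named vector, or a plain vector
# aligned to `samples`; return an integer 0/1 vector (1 = "g1").
.labels01 <- function(labels, samples) {
  if (is.data.frame(labels)) {
    if (!all(c("sample", "label") %in% names(labels))) {
      abort("label data frames need columns `sample` and `label`.")
    }
    lab <- stats::setNames(as.character(labels$label), labels$sample)
    labels <- lab
  }
  if (!is.null(names(labels))) {
    missing <- setdiff(samples, names(labels))
    if (length(missing) > 0) {
      abort(sprintf("labels missing for %d sample(s), e.g. %s.",
                    length(missing), missing[1]))
    }
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    abort("unnamed labels must have one entry per sample.")
  }
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    abort(sprintf("expected exactly two classes, got %d.", length(lev)))
  }
  if (all(lev == c("g0", "g1"))) {
    as.integer(labels == "g1")
  } else {
    as.integer(labels == lev[2])
  }
}

# Agreement between two binary label vectors after optimal class matching.
# Returns the agreement and whether the optimal matching flips classes.
.matched_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  m <- mean(a == b)
  if (m >= 1 - m) list(agreement = m, flipped = FALSE)
  else list(agreement = 1 - m, flipped = TRUE)
}

# Deterministic derived seeds (kept below 2^31).
.derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483647)
}

.assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Variance floor used throughout the discriminant machinery.
.variance_floor <- function(mat) {
  v <- stats::median(apply(mat, 1, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1e-8
  v
}
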
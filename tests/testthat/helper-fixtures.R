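# Small in-code fixtures shared across the suite.

# A compact cohort with one strong planted split.
small_cohort <- function(n = 80, genes = 300, effect = 3, fraction = 0.3,
                         module = 50, dups = 0, seed = 42) {
  generate_cohort(cohort_spec(
    n_samples = n, n_genes = genes, n_duplicates = dups,
    planted_splits = list(planted_split(fraction, module, effect)),
    n_mirna = 60, mirna_informative = 10, seed = seed))
}

# Expression matrix of the biological (non-duplicate) arrays.
bio_matrix <- function(cohort) {
  cohort$expression[, setdiff(colnames(cohort$expression),
                              cohort$duplicate_pairs$duplicate),
                    drop = FALSE]
}

# Truth labels of a planted split as a named vector over given samples.
truth_labels <- function(cohort, split = 1, samples = NULL) {
  lab <- stats::setNames(cohort$truth[[paste0("split", split)]],
                         cohort$truth$sample)
  if (!is.null(samples)) lab <- lab[samples]
  lab
}

# Agreement between g0/g1 label vectors after optimal class matching.
label_agreement <- function(a, b) {
  m <- mean(a == b)
  max(m, 1 - m)
}

# A random labelled matrix for classifier tests: `shift` added to the first
# `n_inf` features of class g1.
two_class_matrix <- function(n0 = 30, n1 = 15, genes = 60, n_inf = 10,
                             shift = 0, seed = 1) {
  set.seed(seed)
  n <- n0 + n1
  lab <- rep(c("g0", "g1"), c(n0, n1))
  X <- matrix(rnorm(genes * n), genes, n,
              dimnames = list(sprintf("f%03d", seq_len(genes)),
                              sprintf("s%03d", seq_len(n))))
  if (n_inf > 0 && shift != 0) {
    X[seq_len(n_inf), lab == "g1"] <- X[seq_len(n_inf), lab == "g1"] + shift
  }
  list(mat = X, labels = stats::setNames(lab, colnames(X)))
}
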
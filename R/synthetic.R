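#' Describe a planted binary partition
#'
#' A planted split assigns a minority class (`g1`) to a fraction of the
#' cohort and shifts the mean expression of a dedicated gene module in that
#' class. Modules of distinct planted splits are disjoint.
#'
#' @param fraction_g1 Proportion of samples in the minority class,
#'   strictly between 0 and 0.5.
#' @param module_size Number of genes in the supporting module.
#' @param effect Mean shift (in units of the noise standard deviation when
#'   `noise_sd = 1`) applied to module genes in `g1` samples.
#' @return A `planted_split` list.
#' @export
planted_split <- function(fraction_g1, module_size = 100, effect = 2.5) {
  if (!is.numeric(fraction_g1) || fraction_g1 <= 0 || fraction_g1 >= 0.5) {
    abort("`fraction_g1` must lie strictly between 0 and 0.5.")
  }
  .assert_count(module_size, "module_size")
  if (!is.numeric(effect) || !is.finite(effect)) abort("`effect` must be finite.")
  structure(
    list(fraction_g1 = fraction_g1, module_size = as.integer(module_size),
         effect = effect),
    class = "planted_split"
  )
}

#' Default set of four planted splits
#'
#' Four disjoint 100-gene modules with minority fractions between roughly a
#' quarter and forty percent of the cohort, mirroring the class sizes a
#' binary class-discovery run on a tumor cohort typically reports.
#'
#' @param effect Mean shift shared by all four splits.
#' @return List of four [planted_split()] objects.
#' @export
default_planted_splits <- function(effect = 2.5) {
  list(
    planted_split(0.26, 100, effect),
    planted_split(0.31, 100, effect),
    planted_split(0.36, 100, effect),
    planted_split(0.41, 100, effect)
  )
}

#' Specify a synthetic expression cohort
#'
#' The defaults emulate the structure of a duplicate-bearing ovarian tumor
#' expression study: roughly 12,000 genes measured on 129 tumor samples with
#' twelve samples assayed in duplicate, up to four planted binary partitions
#' each supported by a disjoint 100-gene module, 743 microRNAs of which a
#' subset tracks the first partition, exponential survival with a
#' subtype-dependent hazard, and categorical clinical covariates.
#'
#' @param n_samples Number of biological samples.
#' @param n_genes Number of genes.
#' @param n_duplicates Number of samples assayed twice; duplicate arrays are
#'   appended as extra columns (suffix `_rep2`) and recorded in a pair table.
#' @param planted_splits List of [planted_split()] objects (may be empty).
#' @param noise_sd Expression noise standard deviation.
#' @param baseline_mean,baseline_sd Gene baseline distribution on a
#'   log2-like intensity scale.
#' @param n_mirna Number of microRNA features.
#' @param mirna_informative Number of microRNAs mean-shifted between the
#'   classes of the first planted split.
#' @param mirna_effect Size of that shift.
#' @param hr Hazard ratio of the first planted split's `g1` class versus `g0`.
#' @param baseline_rate Baseline exponential event rate (events per time unit).
#' @param censor_frac Target fraction of censored samples.
#' @param clinical_log_or Log odds-ratio tying clinical categories to the
#'   first split's classes (0 = no association).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 129, n_genes = 12000, n_duplicates = 12,
                        planted_splits = default_planted_splits(),
                        noise_sd = 1, baseline_mean = 8, baseline_sd = 1.5,
                        n_mirna = 743, mirna_informative = 40,
                        mirna_effect = 2, hr = 1.3, baseline_rate = 0.1,
                        censor_frac = 0.3, clinical_log_or = 0, seed = 1) {
  .assert_count(n_samples, "n_samples", 4L)
  .assert_count(n_genes, "n_genes")
  .assert_count(n_duplicates, "n_duplicates", 0L)
  if (n_duplicates > n_samples) abort("`n_duplicates` cannot exceed `n_samples`.")
  if (!is.list(planted_splits) ||
      !all(vapply(planted_splits, inherits, logical(1), "planted_split"))) {
    abort("`planted_splits` must be a list of planted_split objects.")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("`noise_sd` must be > 0.")
  total_module <- sum(vapply(planted_splits, function(s) s$module_size, 1L))
  if (total_module > n_genes) {
    abort(sprintf(
      "planted modules need %d genes but the cohort has only %d.",
      total_module, n_genes))
  }
  .assert_count(n_mirna, "n_mirna", 0L)
  .assert_count(mirna_informative, "mirna_informative", 0L)
  if (mirna_informative > n_mirna) {
    abort("`mirna_informative` cannot exceed `n_mirna`.")
  }
  if (!is.numeric(censor_frac) || censor_frac < 0 || censor_frac >= 1) {
    abort("`censor_frac` must lie in [0, 1).")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         n_duplicates = as.integer(n_duplicates),
         planted_splits = planted_splits, noise_sd = noise_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         n_mirna = as.integer(n_mirna),
         mirna_informative = as.integer(mirna_informative),
         mirna_effect = mirna_effect, hr = hr,
         baseline_rate = baseline_rate, censor_frac = censor_frac,
         clinical_log_or = clinical_log_or, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Expression is `X[g, s] = mu_g + sum_k delta_k [g in module_k][s in g1_k]
#' + eps` with `eps ~ Normal(0, noise_sd^2)` and gene baselines `mu_g ~
#' Normal(baseline_mean, baseline_sd^2)`. Duplicate arrays are re-noised
#' copies of their source sample's signal, appended as extra columns.
#' Survival, microRNA, and clinical layers are tied to the first planted
#' split (when present).
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` list with elements `expression` (matrix,
#'   genes x arrays, duplicates included), `mirna` (matrix over biological
#'   samples), `truth` (tibble sample x split label), `modules` (named list
#'   of planted module gene IDs), `duplicate_pairs` (tibble `sample`,
#'   `duplicate`), `survival` and `clinical` tibbles, and the `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  set.seed(spec$seed)
  n <- spec$n_samples
  G <- spec$n_genes
  samples <- sprintf("s%04d", seq_len(n))
  genes <- sprintf("g%05d", seq_len(G))

  mu <- stats::rnorm(G, spec$baseline_mean, spec$baseline_sd)
  signal <- matrix(mu, nrow = G, ncol = n, dimnames = list(genes, samples))

  n_splits <- length(spec$planted_splits)
  truth <- tibble::tibble(sample = samples)
  modules <- list()
  if (n_splits > 0) {
    pool <- sample(genes)   # disjoint modules drawn from a shuffled pool
    used <- 0L
    for (k in seq_len(n_splits)) {
      ps <- spec$planted_splits[[k]]
      module_k <- sort(pool[used + seq_len(ps$module_size)])
      used <- used + ps$module_size
      n1 <- max(2L, round(ps$fraction_g1 * n))
      g1 <- sample(samples, n1)
      lab <- ifelse(samples %in% g1, "g1", "g0")
      truth[[paste0("split", k)]] <- lab
      modules[[paste0("split", k)]] <- module_k
      signal[module_k, lab == "g1"] <-
        signal[module_k, lab == "g1"] + ps$effect * spec$noise_sd
    }
  }

  expr <- signal + matrix(stats::rnorm(G * n, 0, spec$noise_sd), G, n)

  dup_pairs <- tibble::tibble(sample = character(), duplicate = character())
  if (spec$n_duplicates > 0) {
    src <- sort(sample(samples, spec$n_duplicates))
    dup_ids <- paste0(src, "_rep2")
    dup <- signal[, src, drop = FALSE] +
      matrix(stats::rnorm(G * spec$n_duplicates, 0, spec$noise_sd),
             G, spec$n_duplicates)
    colnames(dup) <- dup_ids
    expr <- cbind(expr, dup)
    dup_pairs <- tibble::tibble(sample = src, duplicate = dup_ids)
  }

  split1 <- if (n_splits > 0) truth$split1 else rep("g0", n)
  mirna <- generate_mirna(
    stats::setNames(split1, samples),
    n_mirna = spec$n_mirna, n_informative = spec$mirna_informative,
    effect = spec$mirna_effect, noise_sd = spec$noise_sd,
    baseline_mean = spec$baseline_mean, baseline_sd = spec$baseline_sd,
    seed = .derive_seed(spec$seed, 101L)
  )

  survival <- if (n_splits > 0) {
    generate_survival(stats::setNames(split1, samples), hr = spec$hr,
                      baseline_rate = spec$baseline_rate,
                      censor_frac = spec$censor_frac,
                      seed = .derive_seed(spec$seed, 202L))
  } else {
    generate_survival(stats::setNames(rep(c("g0", "g1"), length.out = n),
                                      samples),
                      hr = 1, baseline_rate = spec$baseline_rate,
                      censor_frac = spec$censor_frac,
                      seed = .derive_seed(spec$seed, 202L))
  }

  clinical <- .generate_clinical(samples, split1, spec$clinical_log_or,
                                 seed = .derive_seed(spec$seed, 303L))

  structure(
    list(expression = expr, mirna = mirna, truth = truth, modules = modules,
         duplicate_pairs = dup_pairs, survival = survival,
         clinical = clinical, spec = spec),
    class = "synthetic_cohort"
  )
}

#' Simulate survival records for a labelled cohort
#'
#' Event times are exponential with rate `baseline_rate` in `g0` and
#' `hr * baseline_rate` in `g1`; censoring is independent uniform on
#' `[0, T]` with `T` solved so that the expected censored fraction is
#' approximately `censor_frac`.
#'
#' @param labels Named character vector (or tibble with `sample`, `label`)
#'   of `g0`/`g1` class labels.
#' @param hr Hazard ratio of `g1` versus `g0`; must be positive.
#' @param baseline_rate Exponential event rate in `g0`; must be positive.
#' @param censor_frac Target censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble with `sample`, `time`, `event` (1 = observed), `group`.
#' @export
generate_survival <- function(labels, hr = 1.3, baseline_rate = 0.1,
                              censor_frac = 0.3, seed = 1) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$label), labels$sample)
  }
  if (is.null(names(labels))) abort("`labels` must be named by sample ID.")
  if (!is.numeric(hr) || hr <= 0) abort("`hr` must be > 0.")
  if (!is.numeric(baseline_rate) || baseline_rate <= 0) {
    abort("`baseline_rate` must be > 0.")
  }
  lab <- as.character(labels)
  if (!any(lab == "g0") || !any(lab == "g1")) {
    abort("both groups (`g0`, `g1`) must be non-empty.")
  }
  set.seed(seed)
  rate <- ifelse(lab == "g1", hr * baseline_rate, baseline_rate)
  t_event <- stats::rexp(length(lab), rate)
  if (censor_frac > 0) {
    mean_rate <- mean(rate)
    # P(censored) for Exp(l) vs U(0, T) is (1 - exp(-l T)) / (l T),
    # which decreases from 1 (T -> 0) to 0 (T -> Inf)
    cens_prob <- function(Tmax) (1 - exp(-mean_rate * Tmax)) / (mean_rate * Tmax)
    Tmax <- stats::uniroot(function(Tm) cens_prob(Tm) - censor_frac,
                           lower = 1e-6, upper = 1e6 / mean_rate)$root
    t_cens <- stats::runif(length(lab), 0, Tmax)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, length(lab))
  }
  tibble::tibble(sample = names(labels), time = time, event = event,
                 group = lab)
}

#' Simulate a microRNA matrix tied to a binary partition
#'
#' `n_informative` features are mean-shifted by `effect` between the two
#' classes; the remaining features are pure noise around their baselines.
#'
#' @param labels Named `g0`/`g1` labels covering all samples.
#' @param n_mirna Total number of microRNA features.
#' @param n_informative Number of shifted features (must not exceed
#'   `n_mirna`).
#' @param effect Mean shift applied to informative features in `g1`.
#' @param noise_sd,baseline_mean,baseline_sd Noise and baseline parameters.
#' @param seed Integer seed.
#' @return Matrix `n_mirna` x samples with feature IDs `mir0001`, ...
#' @export
generate_mirna <- function(labels, n_mirna = 743, n_informative = 40,
                           effect = 2, noise_sd = 1, baseline_mean = 8,
                           baseline_sd = 1.5, seed = 1) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$label), labels$sample)
  }
  if (is.null(names(labels))) abort("`labels` must be named by sample ID.")
  if (n_informative > n_mirna) {
    abort(sprintf("`n_informative` (%d) exceeds `n_mirna` (%d).",
                  n_informative, n_mirna))
  }
  set.seed(seed)
  n <- length(labels)
  ids <- sprintf("mir%04d", seq_len(n_mirna))
  mu <- stats::rnorm(n_mirna, baseline_mean, baseline_sd)
  m <- matrix(mu, n_mirna, n, dimnames = list(ids, names(labels))) +
    matrix(stats::rnorm(n_mirna * n, 0, noise_sd), n_mirna, n)
  if (n_informative > 0 && any(labels == "g1")) {
    info <- sample(ids, n_informative)
    m[info, labels == "g1"] <- m[info, labels == "g1"] + effect * noise_sd
    attr(m, "informative") <- sort(info)
  }
  m
}

# Clinical covariates from fixed category frequencies; a nonzero log
# odds-ratio tilts grade upward and debulking toward suboptimal in g1.
.generate_clinical <- function(samples, split1, log_or, seed) {
  set.seed(seed)
  grade_p <- c(`1` = 0.05, `2` = 0.22, `3` = 0.69, `4` = 0.04)
  stage_p <- c(`1` = 0.05, `2` = 0.07, `3` = 0.66, `4` = 0.22)
  deb_p <- c(optimal = 0.54, suboptimal = 0.46)
  tilt <- function(p, z, on) {
    if (!on) return(p)
    w <- p * exp(log_or * (z - mean(z)))
    w / sum(w)
  }
  draw <- function(p, z) {
    vapply(split1, function(l) {
      pp <- tilt(p, z, l == "g1")
      sample(names(p), 1, prob = pp)
    }, character(1), USE.NAMES = FALSE)
  }
  tibble::tibble(
    sample = samples,
    grade = draw(grade_p, seq_along(grade_p)),
    stage = draw(stage_p, seq_along(stage_p)),
    debulking = draw(deb_p, c(0, 1)),
    age = round(stats::rnorm(length(samples), 62, 10))
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d genes x %d arrays (%d samples + %d duplicates)\n",
    nrow(x$expression), ncol(x$expression), x$spec$n_samples,
    x$spec$n_duplicates))
  cat(sprintf("  planted splits: %d; miRNA features: %d\n",
              length(x$modules), nrow(x$mirna)))
  invisible(x)
}
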
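#' Kaplan-Meier curves and two-sample logrank test
#'
#' Product-limit survival estimates per group and the two-sample logrank
#' chi-square (1 df), via the `survival` package.
#'
#' @param surv Tibble/data frame with columns `time` (nonnegative), `event`
#'   (0/1), `group` (exactly two levels for the test).
#' @return A `km_result`: `curves` (tibble `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `chisq`, `df`, `p_value`.
#' @export
km_logrank <- function(surv) {
  .check_survival(surv)
  groups <- sort(unique(surv$group))
  if (length(groups) != 2) abort("logrank comparison needs exactly two groups.")
  if (sum(surv$event) == 0) abort("no events observed.")
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = surv)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble::tibble(
    group = sub("^group=", "", strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = surv)
  structure(
    list(curves = curves, chisq = unname(sd$chisq), df = 1,
         p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
    class = "km_result")
}

#' Cox proportional-hazards ratio between two groups
#'
#' Fits a single-covariate Cox model by partial likelihood (Efron tie
#' handling) and reports the hazard ratio with its Wald 95% confidence
#' interval `exp(beta +- 1.96 se)` and p-value. Monotone likelihood
#' (complete separation of the groups) is detected and flagged with a
#' warning.
#'
#' @param surv Tibble with `time`, `event`, and a two-level `group`; the
#'   hazard ratio is for the non-reference level versus the reference.
#' @param reference Group level used as the baseline; defaults to the
#'   first sorted level.
#' @return Tibble with `term`, `hr`, `conf_low`, `conf_high`, `p_value`,
#'   `n`, `n_event`.
#' @export
cox_hr <- function(surv, reference = NULL) {
  .check_survival(surv)
  groups <- sort(unique(surv$group))
  if (length(groups) < 2) abort("`group` must have two levels.")
  if (length(groups) > 2) abort("only a binary group comparison is supported.")
  if (!is.null(reference)) {
    if (!reference %in% groups) abort("`reference` is not a group level.")
    groups <- c(reference, setdiff(groups, reference))
  }
  surv$group <- factor(surv$group, groups)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, data = surv,
                    ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|Loglik converged", conditionMessage(w))) {
        warn("monotone likelihood: the groups may be completely separated.")
        invokeRestart("muffleWarning")
      }
    })
  if (fit$iter >= 50) {
    abort(sprintf("Cox fit did not converge in 50 iterations (beta = %.3f).",
                  unname(stats::coef(fit))))
  }
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  tibble::tibble(
    term = paste0(groups[2], " vs ", groups[1]),
    hr = exp(beta),
    conf_low = exp(beta - 1.96 * se),
    conf_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    n = nrow(surv), n_event = sum(surv$event))
}

.check_survival <- function(surv) {
  if (!all(c("time", "event", "group") %in% names(surv))) {
    abort("survival data needs columns `time`, `event`, `group`.")
  }
  if (any(!is.finite(surv$time)) || any(surv$time < 0)) {
    abort("`time` must be finite and nonnegative.")
  }
  if (!all(surv$event %in% c(0, 1))) abort("`event` must be 0/1.")
  invisible(surv)
}

#' Fisher's exact test for subtype-by-category tables
#'
#' 2x2 tables get the exact two-sided p-value (sum of the probabilities of
#' all tables, under fixed margins, no more probable than the observed
#' one); larger tables get a Monte Carlo p over `n_mc` tables drawn with
#' fixed margins, with the add-one correction `(k + 1) / (n_mc + 1)`. Rows
#' or columns with zero margins are dropped with a warning; if fewer than
#' two rows or columns remain, p = 1.
#'
#' @param tab Matrix of nonnegative integer counts.
#' @param n_mc Monte Carlo draws for tables larger than 2x2.
#' @param seed Integer seed (Monte Carlo case only).
#' @return Tibble with `p_value`, `method`, `n_mc`.
#' @export
fisher_assoc <- function(tab, n_mc = 1e5, seed = 1) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must contain nonnegative integer counts.")
  }
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warn(sprintf("dropping %d zero-margin row(s) and %d column(s).",
                 sum(zr), sum(zc)))
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(tibble::tibble(p_value = 1, method = "degenerate", n_mc = NA_integer_))
  }
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    p <- stats::fisher.test(tab)$p.value
    tibble::tibble(p_value = p, method = "exact", n_mc = NA_integer_)
  } else {
    set.seed(seed)
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
    tibble::tibble(p_value = p, method = "monte-carlo",
                   n_mc = as.integer(n_mc))
  }
}

#' Per-category proportion of angiogenic samples
#'
#' For a subtype-by-category table whose first row counts angiogenic
#' samples, returns each column's angiogenic proportion as a percent
#' rounded to the nearest integer. Columns with zero total get `NA`.
#'
#' @param tab Matrix with rows (angiogenic, non-angiogenic) and one column
#'   per clinical category.
#' @return Tibble with `category`, `n_angiogenic`, `n_total`, `percent`.
#' @export
subtype_proportions <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2) {
    abort("`tab` must have two rows: angiogenic then non-angiogenic.")
  }
  if (any(tab < 0)) abort("counts must be nonnegative.")
  tot <- colSums(tab)
  cats <- colnames(tab)
  if (is.null(cats)) cats <- paste0("cat", seq_len(ncol(tab)))
  tibble::tibble(
    category = cats,
    n_angiogenic = as.integer(unname(tab[1, ])),
    n_total = as.integer(unname(tot)),
    percent = unname(ifelse(tot > 0, round(100 * tab[1, ] / tot), NA_real_)))
}
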
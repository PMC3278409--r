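#' Assemble a pipeline configuration
#'
#' One global `seed` drives every stage; per-stage seeds are derived from
#' it by fixed offsets, so a configuration fully determines the run. The
#' configuration round-trips through YAML unchanged (see
#' [read_pipeline_config()]).
#'
#' @param seed Global integer seed (required).
#' @param cohort Either a [cohort_spec()] used to simulate the cohort, or
#'   `NULL` when `expression_file` points at an existing matrix.
#' @param expression_file,mirna_file,phenotype_file,dup_pairs_file Optional
#'   input paths used instead of simulation.
#' @param gmt_file Optional GMT file for the enrichment stage (skipped when
#'   absent).
#' @param out_dir Directory for intermediate artifacts.
#' @param k Number of variable genes kept by the filter.
#' @param dup_quantile Duplicate-variability exclusion quantile.
#' @param m Module size per split.
#' @param n_train Training-set size (biological samples).
#' @param max_splits,n_perm,alpha Split-search parameters.
#' @param n_boot,train_fraction,stability_threshold Bootstrap-stability
#'   parameters.
#' @param outer_k,inner_k,n_delta Nested-CV parameters for the microRNA
#'   confirmation.
#' @param k_max,n_restarts Mixture-model parameters for the score stage.
#' @param raw_scale Whether expression input is on a raw (nonnegative)
#'   scale needing the log2 surrogate transform.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            cohort = cohort_spec(seed = seed),
                            expression_file = NULL, mirna_file = NULL,
                            phenotype_file = NULL, dup_pairs_file = NULL,
                            gmt_file = NULL, out_dir = tempfile("risisr_run_"),
                            k = 1000, dup_quantile = 0.75, m = 100,
                            n_train = 82, max_splits = 6, n_perm = 100,
                            alpha = 0.05, n_boot = 100, train_fraction = 0.63,
                            stability_threshold = 0.95, outer_k = 10,
                            inner_k = 5, n_delta = 30, k_max = 5,
                            n_restarts = 5, raw_scale = FALSE) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  .assert_count(seed, "seed", 0L)
  cfg <- list(
    seed = as.integer(seed), cohort = cohort,
    expression_file = expression_file, mirna_file = mirna_file,
    phenotype_file = phenotype_file, dup_pairs_file = dup_pairs_file,
    gmt_file = gmt_file, out_dir = out_dir, k = k,
    dup_quantile = dup_quantile, m = m, n_train = n_train,
    max_splits = max_splits, n_perm = n_perm, alpha = alpha,
    n_boot = n_boot, train_fraction = train_fraction,
    stability_threshold = stability_threshold, outer_k = outer_k,
    inner_k = inner_k, n_delta = n_delta, k_max = k_max,
    n_restarts = n_restarts, raw_scale = raw_scale)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) abort("configuration is missing `seed`.")
  cohort <- if (!is.null(raw$cohort)) {
    ps <- lapply(raw$cohort$planted_splits, function(p) {
      planted_split(p$fraction_g1, p$module_size, p$effect)
    })
    args <- raw$cohort
    args$planted_splits <- ps
    do.call(cohort_spec, args)
  } else if (is.null(raw$expression_file)) {
    cohort_spec(seed = raw$seed)
  } else NULL
  raw$cohort <- NULL
  do.call(pipeline_config, c(list(cohort = cohort), raw))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$cohort)) {
    sp <- unclass(cfg$cohort)
    sp$planted_splits <- lapply(sp$planted_splits, unclass)
    cfg$cohort <- sp
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full discovery-to-association pipeline
#'
#' Chains the stages deterministically: simulate (or read inputs),
#' normalize and filter, split the samples into training and
#' model-selection sets, discover splits, gate them by bootstrap stability
#' and holdout confirmation, confirm the first split from microRNA
#' profiles by nested-CV PAM, score and classify every sample with the
#' split-1 signature, test survival and clinical associations of the
#' calls, and (when a GMT file is configured) test module enrichment.
#' All intermediate artifacts are written under `config$out_dir` together
#' with a manifest recording the package version, seeds and parameters.
#'
#' @param config A [pipeline_config()].
#' @return A named list of stage results (also written to disk), invisibly
#'   the same object.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  if (is.null(config$seed)) abort("configuration is missing `seed`.")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(name) message(sprintf("[risisr] stage: %s", name))
  run_stage <- function(name, fn) {
    log_stage(name)
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  res <- list()

  # --- inputs -------------------------------------------------------------
  res$cohort <- run_stage("simulate", function() {
    if (!is.null(config$expression_file)) {
      expr <- read_expression(config$expression_file)
      mirna <- if (!is.null(config$mirna_file))
        read_expression(config$mirna_file) else NULL
      pheno <- if (!is.null(config$phenotype_file))
        readr::read_tsv(config$phenotype_file, show_col_types = FALSE) else NULL
      dups <- if (!is.null(config$dup_pairs_file))
        readr::read_tsv(config$dup_pairs_file, show_col_types = FALSE) else
          tibble::tibble(sample = character(), duplicate = character())
      list(expression = expr, mirna = mirna, phenotype = pheno,
           duplicate_pairs = dups, simulated = FALSE)
    } else {
      cohort <- generate_cohort(config$cohort)
      write_cohort(cohort, file.path(out, "cohort"))
      pheno <- cohort$survival |>
        dplyr::left_join(cohort$clinical, by = "sample") |>
        dplyr::left_join(cohort$truth, by = "sample")
      list(expression = cohort$expression, mirna = cohort$mirna,
           phenotype = pheno, duplicate_pairs = cohort$duplicate_pairs,
           simulated = TRUE)
    }
  })

  # --- preprocess ---------------------------------------------------------
  res$preprocess <- run_stage("preprocess", function() {
    expr <- vst_surrogate(res$cohort$expression, raw_scale = config$raw_scale)
    expr <- quantile_normalize(expr)
    dup_q <- if (nrow(res$cohort$duplicate_pairs) > 0)
      config$dup_quantile else 1
    genes <- filter_variable_genes(expr, res$cohort$duplicate_pairs,
                                   k = config$k, dup_quantile = dup_q)
    filtered <- expr[genes$gene, , drop = FALSE]
    write_expression(filtered, file.path(out, "filtered.tsv"))
    parts <- split_train_model_selection(
      colnames(expr), n_train = config$n_train,
      dup_pairs = res$cohort$duplicate_pairs,
      seed = .derive_seed(config$seed, 1L))
    list(normalized = expr, filtered = filtered, genes = genes,
         partition = parts)
  })

  bio <- setdiff(colnames(res$preprocess$filtered),
                 res$cohort$duplicate_pairs$duplicate)
  train_ids <- intersect(res$preprocess$partition$train, bio)
  model_ids <- intersect(res$preprocess$partition$model_selection, bio)
  train_mat <- res$preprocess$filtered[, train_ids, drop = FALSE]
  model_mat <- res$preprocess$filtered[, model_ids, drop = FALSE]

  # --- discover -----------------------------------------------------------
  res$splits <- run_stage("discover", function() {
    sp <- search_splits(train_mat, m = config$m,
                        max_splits = config$max_splits,
                        n_perm = config$n_perm, alpha = config$alpha,
                        seed = .derive_seed(config$seed, 2L))
    .write_splits_json(sp, file.path(out, "splits.json"))
    sp
  })

  # --- stability ----------------------------------------------------------
  res$stability <- run_stage("stability", function() {
    st <- bootstrap_stability(train_mat, res$splits,
                              n_boot = config$n_boot,
                              train_fraction = config$train_fraction,
                              seed = .derive_seed(config$seed, 3L),
                              m = config$m)
    retained <- retain_stable(st, config$stability_threshold)
    confirmed <- confirm_on_holdout(retained, train_mat, model_mat,
                                    n_boot = config$n_boot,
                                    threshold = config$stability_threshold,
                                    seed = .derive_seed(config$seed, 4L),
                                    m = config$m)
    jsonlite::write_json(
      lapply(st, function(s) list(stability = s$stability,
                                  matched_fraction = s$matched_fraction)),
      file.path(out, "stability.json"), auto_unbox = TRUE, digits = NA)
    list(all = st, retained = retained, confirmed = confirmed)
  })

  confirmed <- res$stability$confirmed
  if (length(confirmed) == 0) {
    message("[risisr] no split confirmed; downstream stages skipped.")
    .write_manifest(config, res, out)
    return(invisible(res))
  }
  split1 <- confirmed[[1]]$base

  # --- mirna-validate -----------------------------------------------------
  res$mirna_cv <- run_stage("mirna-validate", function() {
    if (is.null(res$cohort$mirna)) return(NULL)
    mir <- res$cohort$mirna
    full_labels <- .full_cohort_labels(split1, confirmed[[1]],
                                      res$preprocess$filtered, bio)
    common <- intersect(colnames(mir), names(full_labels))
    lab <- full_labels[common]
    ok <- min(table(lab)) >= config$outer_k
    outer_k <- if (ok) config$outer_k else max(2, min(table(lab)))
    cv <- pam_nested_cv(mir[, common, drop = FALSE], lab,
                        outer_k = outer_k, inner_k = config$inner_k,
                        n_delta = config$n_delta,
                        seed = .derive_seed(config$seed, 5L))
    utils::write.table(cv$confusion, file.path(out, "mirna_confusion.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    cv
  })

  # --- score --------------------------------------------------------------
  res$score <- run_stage("score", function() {
    scaled <- robust_scale(res$preprocess$normalized[, bio, drop = FALSE])
    weights <- stats::setNames(split1$model$coefs$weight,
                               split1$model$coefs$gene)
    sc <- signature_score(scaled, weights)
    gmm <- gmm_bic(sc$score, k_max = config$k_max,
                   n_restarts = config$n_restarts,
                   seed = .derive_seed(config$seed, 6L))
    calls <- classify_subtype(sc, gmm)
    readr::write_tsv(calls$calls, file.path(out, "scores.tsv"))
    list(scores = sc, gmm = gmm, calls = calls)
  })

  # --- associate ----------------------------------------------------------
  res$clinical <- run_stage("associate", function() {
    if (is.null(res$cohort$phenotype) || res$score$calls$no_subtype) {
      return(NULL)
    }
    df <- dplyr::inner_join(res$score$calls$calls, res$cohort$phenotype,
                            by = "sample")
    surv <- tibble::tibble(sample = df$sample, time = df$time,
                           event = df$event, group = df$call)
    km <- km_logrank(surv)
    cox <- cox_hr(surv, reference = "non-angiogenic")
    assoc <- list()
    for (covar in intersect(c("grade", "stage", "debulking"), names(df))) {
      tab <- table(factor(df$call, c("angiogenic", "non-angiogenic")),
                   df[[covar]])
      tab <- matrix(as.integer(tab), nrow = 2,
                    dimnames = list(rownames(tab), colnames(tab)))
      assoc[[covar]] <- list(
        table = tab,
        fisher = fisher_assoc(tab, seed = .derive_seed(config$seed, 7L)),
        proportions = subtype_proportions(tab))
    }
    clin <- list(km = km, cox = cox, associations = assoc)
    jsonlite::write_json(
      list(logrank_p = km$p_value, hr = cox$hr,
           hr_ci = c(cox$conf_low, cox$conf_high),
           fisher_p = lapply(assoc, function(a) a$fisher$p_value)),
      file.path(out, "clinical.json"), auto_unbox = TRUE, digits = NA)
    clin
  })

  # --- enrich -------------------------------------------------------------
  res$enrichment <- run_stage("enrich", function() {
    if (is.null(config$gmt_file)) return(NULL)
    sets <- read_gmt(config$gmt_file)
    universe <- rownames(res$preprocess$normalized)
    enr <- hypergeom_enrich(split1$module$gene, sets, universe)
    readr::write_tsv(enr, file.path(out, "enrichment.tsv"))
    enr
  })

  .write_manifest(config, res, out)
  invisible(res)
}

# Labels for all biological samples: training labels from the split itself,
# model-selection labels from the holdout predictions.
.full_cohort_labels <- function(split1, confirmed, filtered, bio) {
  lab <- stats::setNames(split1$labels$label, split1$labels$sample)
  if (!is.null(confirmed$holdout_labels)) {
    hl <- confirmed$holdout_labels
    lab <- c(lab, stats::setNames(hl$label, hl$sample))
  }
  lab[intersect(bio, names(lab))]
}

.write_splits_json <- function(splits, path) {
  jsonlite::write_json(
    lapply(splits, function(s) {
      list(labels = stats::setNames(as.list(s$labels$label),
                                    s$labels$sample),
           module = s$module$gene,
           t = s$module$t,
           weights = stats::setNames(as.list(unname(s$weights)),
                                     names(s$weights)),
           score = s$score, pvalue = s$pvalue)
    }),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.write_manifest <- function(config, res, out) {
  manifest <- list(
    package = "risisr",
    version = as.character(utils::packageVersion("risisr")),
    seed = config$seed,
    parameters = unclass(config)[c("k", "dup_quantile", "m", "n_train",
                                   "max_splits", "n_perm", "alpha", "n_boot",
                                   "train_fraction", "stability_threshold",
                                   "outer_k", "inner_k", "n_delta", "k_max",
                                   "n_restarts")],
    stages_run = names(Filter(Negate(is.null), res)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
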
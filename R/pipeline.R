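# End-to-end orchestration: simulate -> predict (both models) -> evaluate,
# as a reproducible, config-driven run with caching and a provenance
# manifest.

#' Validate a pipeline run configuration
#'
#' A run config is a plain list (loadable from YAML via
#' `yaml::read_yaml()`): fields `seed` (master seed; stage seeds are derived
#' by fixed offsets), `out_dir`, `cohort` (either a list of [synth_config()]
#' arguments or `list(dir = ...)` pointing at an existing cohort
#' directory), `models` (subset of `"analytical"`, `"gmha"`), `weights`,
#' `bands`, `analyses` (subset of accuracy, shuffle, age, groups, panss,
#' modelcompare, strength, variability), `alpha`, and optional `gmha`
#' (a list of [gmha_config()] arguments).
#'
#' @param config List as described.
#' @return The validated config (with defaults filled), invisibly classed
#'   `scfc_run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$seed)) stop_scfc("scfc_config_error", "config needs a seed")
  if (is.null(config$out_dir))
    stop_scfc("scfc_config_error", "config needs out_dir")
  if (is.null(config$cohort))
    stop_scfc("scfc_config_error", "config needs a cohort source")
  if (!is.null(config$cohort$dir) && !dir.exists(config$cohort$dir))
    stop_scfc("scfc_config_error", "cohort directory %s does not exist",
              config$cohort$dir)
  config$models <- config$models %||% "analytical"
  bad <- setdiff(config$models, c("analytical", "gmha"))
  if (length(bad)) stop_scfc("scfc_config_error", "unknown model(s): %s",
                             paste(bad, collapse = ", "))
  config$weights <- config$weights %||% "FA"
  config$bands <- config$bands %||% fc_bands()
  config$analyses <- config$analyses %||%
    c("accuracy", "groups", "strength", "variability")
  known <- c("accuracy", "shuffle", "age", "groups", "panss", "modelcompare",
             "strength", "variability")
  bad <- setdiff(config$analyses, known)
  if (length(bad)) stop_scfc("scfc_config_error", "unknown analyses: %s",
                             paste(bad, collapse = ", "))
  config$alpha <- config$alpha %||% 0.05
  structure(config, class = "scfc_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_checksums <- function(files) {
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}

#' Run the full pipeline
#'
#' Executes the configured stages in order -- cohort simulation (or
#' loading), analytical and/or autoencoder prediction, and the statistical
#' evaluation -- writing per-stage CSV outputs plus a JSON run manifest with
#' input/output checksums and realized seeds. A rerun with an unchanged
#' config reuses cached stage outputs whose checksums match.
#'
#' @param config A list accepted by [validate_run_config()].
#' @return The run manifest (list), invisibly; written to
#'   `out_dir/run_manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(cohort = subseed(config$seed, 11L),
                gmha = subseed(config$seed, 23L),
                evaluate = subseed(config$seed, 37L))
  manifest <- list(config = unclass(config), seeds = seeds,
                   package_version = as.character(utils::packageVersion("scfcmap")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())

  # --- stage: cohort ----
  cohort_dir <- config$cohort$dir
  if (is.null(cohort_dir)) {
    cohort_dir <- file.path(out, "cohort")
    cache_ok <- file.exists(file.path(cohort_dir, "manifest.csv")) &&
      file.exists(file.path(cohort_dir, "cohort_config.json")) &&
      identical(jsonlite::read_json(file.path(cohort_dir, "cohort_config.json"),
                                    simplifyVector = TRUE)$seed_used,
                seeds$cohort)
    if (!cache_ok) {
      sc_args <- config$cohort
      sc_args$seed <- seeds$cohort
      coh <- generate_cohort(do.call(synth_config, sc_args))
      write_cohort(coh, cohort_dir)
      jsonlite::write_json(list(seed_used = seeds$cohort),
                           file.path(cohort_dir, "cohort_config.json"),
                           auto_unbox = TRUE)
    }
    # always work from the on-disk representation so cached and fresh runs
    # are bit-identical downstream
    coh <- read_cohort(cohort_dir)
    manifest$stages$cohort <- list(dir = cohort_dir, cached = cache_ok)
  } else {
    coh <- read_cohort(cohort_dir)
    manifest$stages$cohort <- list(dir = cohort_dir, cached = TRUE)
  }

  ids_h <- vapply(Filter(function(s) s$group == "healthy", coh$subjects),
                  function(s) s$id, "")
  ids_p <- vapply(Filter(function(s) s$group == "psychosis", coh$subjects),
                  function(s) s$id, "")

  # --- stage: predictions ----
  records <- list()
  if ("analytical" %in% config$models) {
    rec_path <- file.path(out, "records_analytical.csv")
    records$analytical <- predict_cohort_analytical(
      coh, weights = config$weights, bands = config$bands)
    utils::write.csv(records$analytical, rec_path, row.names = FALSE)
    manifest$stages$analytical <- list(file = rec_path,
                                       n_records = nrow(records$analytical))
  }
  gmha_models <- list()
  if ("gmha" %in% config$models) {
    gargs <- config$gmha %||% list()
    gargs$seed <- gargs$seed %||% seeds$gmha
    gcfg <- do.call(gmha_config, gargs)
    rec <- list()
    for (w in config$weights) for (b in config$bands) {
      mdl <- train_gmha(coh, b, w, gcfg)
      gmha_models[[paste(b, w, sep = ".")]] <- mdl
      rec[[paste(b, w, sep = ".")]] <- mdl$records[, c("subject", "model",
                                                       "band", "weight", "r")]
      if (length(ids_p) > 0) {
        ext <- predict_external(mdl, coh, ids_p)
        rec[[paste(b, w, "pat", sep = ".")]] <- ext$records
      }
    }
    records$gmha <- do.call(rbind, rec)
    rec_path <- file.path(out, "records_gmha.csv")
    utils::write.csv(records$gmha, rec_path, row.names = FALSE)
    manifest$stages$gmha <- list(file = rec_path,
                                 n_records = nrow(records$gmha))
  }
  all_records <- do.call(rbind, lapply(records, function(r)
    r[, c("subject", "model", "band", "weight", "r")]))
  rownames(all_records) <- NULL

  # --- stage: evaluation ----
  report_dir <- file.path(out, "report")
  dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
  evaluate_records(all_records, coh, config, report_dir,
                   seed = seeds$evaluate)
  manifest$stages$evaluate <- list(dir = report_dir,
                                   analyses = config$analyses)

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$checksums <- stage_checksums(
    list.files(out, recursive = TRUE, full.names = TRUE, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# The evaluation battery over a record table; writes one CSV per analysis.
evaluate_records <- function(records, coh, config, report_dir, seed = 1) {
  alpha <- config$alpha
  ids_h <- vapply(Filter(function(s) s$group == "healthy", coh$subjects),
                  function(s) s$id, "")
  ids_p <- vapply(Filter(function(s) s$group == "psychosis", coh$subjects),
                  function(s) s$id, "")
  summary_json <- list()

  if ("accuracy" %in% config$analyses) {
    agg <- stats::aggregate(r ~ model + band + weight, data = records,
                            FUN = function(x) c(mean = mean(x), sd = sd(x),
                                                n = length(x)))
    acc <- do.call(data.frame, agg)
    names(acc) <- c("model", "band", "weight", "mean_r", "sd_r", "n")
    utils::write.csv(acc, file.path(report_dir, "accuracy.csv"),
                     row.names = FALSE)
  }
  if ("shuffle" %in% config$analyses) {
    sh <- shuffle_individuality(coh, weight = config$weights[1],
                                band = config$bands[1],
                                n_perm = config$n_perm %||% 500, seed = seed)
    utils::write.csv(sh, file.path(report_dir, "shuffle.csv"),
                     row.names = FALSE)
  }
  if ("age" %in% config$analyses) {
    ages <- setNames(vapply(coh$subjects, function(s) s$age, 0),
                     vapply(coh$subjects, function(s) s$id, ""))
    for (mdl in unique(records$model)) {
      sub <- records[records$model == mdl & records$subject %in% ids_h, ]
      ac <- age_correlation(sub, ages, alpha = alpha)
      utils::write.csv(ac, file.path(report_dir,
                                     paste0("age_", mdl, ".csv")),
                       row.names = FALSE)
      summary_json[[paste0("age_threshold_", mdl)]] <- attr(ac, "threshold")
    }
  }
  if ("groups" %in% config$analyses && length(ids_p) > 0) {
    for (mdl in unique(records$model)) {
      sub <- records[records$model == mdl, ]
      conds <- unique(sub[, c("band", "weight")])
      rows <- lapply(seq_len(nrow(conds)), function(i) {
        rs <- sub[sub$band == conds$band[i] & sub$weight == conds$weight[i], ]
        mw <- mannwhitney(rs$r[rs$subject %in% ids_h],
                          rs$r[rs$subject %in% ids_p])
        data.frame(band = conds$band[i], weight = conds$weight[i],
                   U = mw$U, p_value = mw$p_value, cohens_d = mw$cohens_d)
      })
      gc_ <- do.call(rbind, rows)
      fdr <- bh_fdr(gc_$p_value, alpha = alpha)
      gc_$significant <- fdr$significant
      utils::write.csv(gc_, file.path(report_dir,
                                      paste0("groups_", mdl, ".csv")),
                       row.names = FALSE)
      summary_json[[paste0("groups_threshold_", mdl)]] <- fdr$threshold
    }
  }
  if ("panss" %in% config$analyses && length(ids_p) >= 3) {
    panss <- do.call(rbind, lapply(
      Filter(function(s) s$group == "psychosis", coh$subjects),
      function(s) data.frame(id = s$id, total = s$panss$total,
                             positive = s$panss$positive,
                             negative = s$panss$negative,
                             general = s$panss$general)))
    for (mdl in unique(records$model)) {
      sp <- spearman_panss(records[records$subject %in% ids_p, ], panss,
                           model = mdl)
      utils::write.csv(sp, file.path(report_dir,
                                     paste0("panss_", mdl, ".csv")),
                       row.names = FALSE)
    }
  }
  if ("modelcompare" %in% config$analyses &&
      all(c("analytical", "gmha") %in% records$model) && length(ids_p) > 0) {
    conds <- unique(records[, c("band", "weight")])
    rows <- lapply(seq_len(nrow(conds)), function(i) {
      rs <- records[records$band == conds$band[i] &
                      records$weight == conds$weight[i] &
                      records$subject %in% ids_p, ]
      pt <- exact_label_permutation(rs$r[rs$model == "gmha"],
                                    rs$r[rs$model == "analytical"],
                                    sided = "two", seed = seed)
      data.frame(band = conds$band[i], weight = conds$weight[i],
                 observed = pt$observed, p_value = pt$p_value)
    })
    mc <- do.call(rbind, rows)
    fdr <- bh_fdr(mc$p_value, alpha = alpha)
    mc$significant <- fdr$significant
    utils::write.csv(mc, file.path(report_dir, "modelcompare.csv"),
                     row.names = FALSE)
    summary_json$modelcompare_threshold <- fdr$threshold
  }
  if ("strength" %in% config$analyses && length(ids_p) > 0) {
    st <- compare_total_strength(coh, alpha = alpha)
    utils::write.csv(st, file.path(report_dir, "strength.csv"),
                     row.names = FALSE)
    summary_json$strength_threshold <- attr(st, "threshold")
  }
  if ("variability" %in% config$analyses && length(ids_h) >= 3) {
    ev <- edge_variability(coh)
    utils::write.csv(data.frame(band = names(ev$median),
                                median_sd = as.numeric(ev$median)),
                     file.path(report_dir, "variability.csv"),
                     row.names = FALSE)
    if (is.data.frame(ev$tests))
      utils::write.csv(ev$tests, file.path(report_dir,
                                           "variability_tests.csv"),
                       row.names = FALSE)
  }
  summary_json$alpha <- alpha
  jsonlite::write_json(summary_json, file.path(report_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report_dir)
}

#' Summarize a completed report directory
#'
#' Reads the evaluation CSVs back and formats a deterministic console /
#' markdown table of the per-(model, band, weight) correlation
#' distributions and all test outcomes; numbers match the CSVs exactly.
#'
#' @param report_dir Path written by [run_pipeline()].
#' @param print Print the table to the console?
#' @return data.frame of the accuracy summary (invisibly when `print`).
#' @export
report_summary <- function(report_dir, print = TRUE) {
  acc_path <- file.path(report_dir, "accuracy.csv")
  if (!file.exists(acc_path))
    stop_scfc("scfc_io_error", "incomplete report directory: no accuracy.csv")
  acc <- utils::read.csv(acc_path)
  if (print && nrow(acc) > 0) {
    cat(sprintf("%-11s %-6s %-4s %9s %9s %5s\n",
                "model", "band", "wt", "mean_r", "sd_r", "n"))
    for (i in seq_len(nrow(acc)))
      cat(sprintf("%-11s %-6s %-4s %9.6g %9.6g %5d\n", acc$model[i],
                  acc$band[i], acc$weight[i], acc$mean_r[i], acc$sd_r[i],
                  acc$n[i]))
    for (f in list.files(report_dir, pattern = "^(groups|modelcompare).*csv$",
                         full.names = TRUE)) {
      df <- utils::read.csv(f)
      cat("\n--", basename(f), "--\n")
      print(df)
    }
  }
  invisible(acc)
}
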
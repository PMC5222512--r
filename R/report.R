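#' Assemble a run configuration
#'
#' Collects every knob of the full pipeline in one list so a run is fully
#' described by (config, seed): input paths (or a synthetic configuration),
#' the modelling metal panel, the Type I grid, subset sizes, regression
#' measures and methods, kernel hyperparameters, and the output directory.
#'
#' @param input_dir Directory holding `asd_metals.csv`, `nt_metals.csv`,
#'   `severity.csv`, `detection_limits.csv`; `NULL` to simulate instead.
#' @param synth_config A `utm_synth_config` used when `input_dir` is `NULL`;
#'   default [reference_config()].
#' @param out_dir Output directory for the report bundle.
#' @param metals_modeling Multivariate metal panel.
#' @param type_i_grid Allowed Type I errors for the classification table.
#' @param subset_sizes Regression subset sizes to enumerate.
#' @param regress_measures Severity columns to run the subset search on.
#' @param regress_methods `"linear"`, `"kernel"` or both.
#' @param kfda_sigma,kfda_lambda Fixed KFDA hyperparameters; `tune_kfda =
#'   TRUE` replaces them with the grid-search winners.
#' @param tune_kfda Tune KFDA by [tune_kfda()].
#' @param kpls_sigma Fixed KPLS width; `NULL` selects per subset.
#' @param standardize_scope `"train_fold"` or `"combined"` predictor scaling
#'   inside regression cross-validation.
#' @param classify_only Skip all severity-dependent stages.
#' @param seed Master seed (used only by synthetic generation; the analysis
#'   itself is deterministic).
#' @return A list of class `utm_run_config`.
#' @export
run_config <- function(input_dir = NULL, synth_config = reference_config(),
                       out_dir = "uritox-report",
                       metals_modeling = utm_metals_modeling,
                       type_i_grid = c(0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10),
                       subset_sizes = 1:4,
                       regress_measures = "ABC_total",
                       regress_methods = "linear",
                       kfda_sigma = NULL, kfda_lambda = 1e-2,
                       tune_kfda = FALSE, kpls_sigma = NULL,
                       standardize_scope = "train_fold",
                       classify_only = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "utm_run_config")
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Loads (or simulates) the cohort, applies detection-limit substitution,
#' and writes: `table2.csv` (per-metal group summary), `hotelling.csv`,
#' `table3.csv` (FDA/KFDA leave-one-out Type I/II grid), one
#' `table4_<measure>_<method>.csv` per requested subset search, `table6.csv`
#' (best result per measure), `loadings.csv` + `clusters.csv` (severity
#' PCA), and `manifest.json` recording the configuration, package version
#' and seed. Identical config and seed give identical bundles.
#'
#' @param config A `utm_run_config` from [run_config()].
#' @return Invisibly, a list with the in-memory results.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "utm_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage `", name, "` failed: ", conditionMessage(e)),
            class = "uritox_stage_error")
    })
  }

  dat <- stage("load", {
    if (is.null(config$input_dir)) {
      generate_cohort(config$synth_config, seed = config$seed)
    } else {
      read_cohort_tables(
        file.path(config$input_dir, "asd_metals.csv"),
        file.path(config$input_dir, "nt_metals.csv"),
        severity_path = {
          p <- file.path(config$input_dir, "severity.csv")
          if (file.exists(p) && !config$classify_only) p else NULL
        },
        detection_limits = file.path(config$input_dir, "detection_limits.csv"))
    }
  })
  cohort <- stage("substitution", substitute_below_detection(dat$cohort))
  severity <- if (config$classify_only) NULL else dat$severity

  table2 <- stage("univariate", group_summary(cohort))
  readr::write_csv(round_for_report(table2), file.path(config$out_dir, "table2.csv"))

  hotelling <- stage("hotelling", hotelling_t2(cohort, intersect(config$metals_modeling, cohort_metals(cohort))))
  readr::write_csv(hotelling, file.path(config$out_dir, "hotelling.csv"))

  metals <- intersect(config$metals_modeling, cohort_metals(cohort))
  fda_tr <- stage("fda", error_tradeoff_loo(cohort, "fda", metals,
                                            type_i_grid = config$type_i_grid))
  kfda_pars <- list(sigma = config$kfda_sigma, lambda = config$kfda_lambda)
  if (config$tune_kfda) {
    tuned <- stage("kfda_tuning", tune_kfda(cohort, metals,
                                            type_i_grid = config$type_i_grid))
    kfda_pars <- list(sigma = tuned$best_sigma, lambda = tuned$best_lambda)
    kfda_tr <- tuned$best
  } else {
    kfda_tr <- stage("kfda", error_tradeoff_loo(cohort, "kfda", metals,
                                                sigma = kfda_pars$sigma,
                                                lambda = kfda_pars$lambda,
                                                type_i_grid = config$type_i_grid))
  }
  table3 <- dplyr::bind_rows(
    dplyr::mutate(tidy(fda_tr), method = "fda", .before = 1),
    dplyr::mutate(tidy(kfda_tr), method = "kfda", .before = 1))
  readr::write_csv(dplyr::mutate(table3, dplyr::across(c("type_i", "type_ii"), ~round(.x, 2))),
                   file.path(config$out_dir, "table3.csv"))

  searches <- list()
  table6 <- NULL
  pca <- NULL
  clusters <- NULL
  if (!is.null(severity)) {
    reg <- stage("join", asd_regression_data(cohort, severity))
    for (meas in config$regress_measures) {
      for (meth in config$regress_methods) {
        key <- paste(meas, meth, sep = "_")
        searches[[key]] <- stage(paste0("subset_search:", key),
          subset_search(reg, meas, metals, method = meth,
                        sizes = config$subset_sizes, sigma = config$kpls_sigma,
                        scope = config$standardize_scope))
        readr::write_csv(
          dplyr::mutate(tidy(searches[[key]]),
                        dplyr::across(dplyr::where(is.numeric), ~signif(.x, 3))),
          file.path(config$out_dir, paste0("table4_", key, ".csv")))
      }
    }
    table6 <- purrr::map_dfr(searches, glance)
    readr::write_csv(dplyr::mutate(table6, best_r2_cv = signif(.data$best_r2_cv, 3)),
                     file.path(config$out_dir, "table6.csv"))

    meas_cols <- intersect(utm_measures_core, names(severity))
    if (length(meas_cols) >= 2) {
      pca <- stage("pca", fit_pca(severity, meas_cols))
      load_tbl <- tibble::as_tibble(pca$loadings[, 1:2], rownames = "measure")
      names(load_tbl)[2:3] <- c("PC1", "PC2")
      readr::write_csv(load_tbl, file.path(config$out_dir, "loadings.csv"))
      clusters <- cluster_measures(pca)
      readr::write_csv(clusters, file.path(config$out_dir, "clusters.csv"))
    }
  }

  manifest <- list(
    package = "uritox",
    version = as.character(utils::packageVersion("uritox")),
    seed = config$seed,
    input_dir = config$input_dir %||% "synthetic",
    metals_modeling = metals,
    type_i_grid = config$type_i_grid,
    subset_sizes = config$subset_sizes,
    regress_measures = config$regress_measures,
    regress_methods = config$regress_methods,
    kfda = kfda_pars,
    standardize_scope = config$standardize_scope
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

  invisible(list(cohort = cohort, severity = severity, table2 = table2,
                 hotelling = hotelling, fda = fda_tr, kfda = kfda_tr,
                 searches = searches, table6 = table6, pca = pca,
                 clusters = clusters, manifest = manifest))
}

# report-time rounding only; all computation upstream is unrounded
round_for_report <- function(table2) {
  dplyr::mutate(table2,
                dplyr::across(dplyr::starts_with("mean"), ~signif(.x, 3)),
                dplyr::across(dplyr::starts_with("q"), ~signif(.x, 3)),
                dplyr::across(dplyr::starts_with("pct"), ~round(.x, 1)),
                p_value = signif(.data$p_value, 2))
}

#' Validate a cohort and severity table
#'
#' Collects (rather than raises) data-quality issues: non-positive or
#' missing concentrations, censored cells that do not equal 2/3 of the
#' detection limit, censored cells without a known limit, severity ids
#' absent from the ASD panel, and negative severity scores.
#'
#' @param cohort A `utm_cohort`.
#' @param severity Optional `utm_severity`.
#' @return Tibble with `stage`, `participant_id`, `column`, `issue`; zero
#'   rows when the inputs are clean.
#' @export
validate_inputs <- function(cohort, severity = NULL) {
  issues <- list()
  add <- function(stage, id, column, issue) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      stage = stage, participant_id = id, column = column, issue = issue)
  }
  lod <- detection_limits(cohort)
  for (m in cohort_metals(cohort)) {
    v <- cohort[[m]]
    cen <- cohort[[paste0(m, "_censored")]]
    bad <- which(is.na(v) | v <= 0)
    for (i in bad) add("panel", cohort$participant_id[i], m,
                       "missing or non-positive concentration")
    if (any(cen)) {
      if (!m %in% names(lod) || is.na(lod[[m]])) {
        add("panel", NA_character_, m, "censored cells but no detection limit")
      } else {
        off <- which(cen & abs(v - 2 / 3 * lod[[m]]) > 1e-8 * max(lod[[m]], 1))
        for (i in off) add("panel", cohort$participant_id[i], m,
                           "censored cell not equal to 2/3 of the detection limit")
      }
    }
  }
  if (!is.null(severity)) {
    extra <- setdiff(severity$participant_id,
                     cohort$participant_id[cohort$group == "ASD"])
    for (id in extra) add("severity", id, "participant_id",
                          "severity id absent from the ASD panel")
    for (cl in setdiff(names(severity), "participant_id")) {
      neg <- which(severity[[cl]] < 0)
      for (i in neg) add("severity", severity$participant_id[i], cl,
                         "negative score")
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(stage = character(), participant_id = character(),
                   column = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
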
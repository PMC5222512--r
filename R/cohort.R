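#' Construct a cohort table of urinary metal concentrations
#'
#' A cohort is a tibble with one row per participant: a `participant_id`
#' column, a `group` column (`"ASD"` or `"NT"`), one numeric concentration
#' column per metal (mcg/g-creatinine), and one logical `<metal>_censored`
#' column flagging values reported below the laboratory detection limit.
#' Per-metal detection limits travel with the table as an attribute so that
#' censored cells can be substituted reproducibly.
#'
#' @param data A data frame with the columns described above.
#' @param metals Character vector of metal codes; defaults to every code in
#'   [utm_metals_all] present in `data`.
#' @param detection_limits Named numeric vector of detection limits
#'   (mcg/g-creatinine); names are metal codes. May omit metals that have no
#'   censored cells.
#' @return A tibble of class `utm_cohort`.
#' @export
new_cohort <- function(data, metals = NULL, detection_limits = numeric()) {
  data <- tibble::as_tibble(data)
  if (is.null(metals)) {
    metals <- intersect(utm_metals_all, names(data))
  }
  missing_cols <- setdiff(metals, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing metal column(s): ", paste(missing_cols, collapse = ", ")),
          class = "uritox_schema_error")
  }
  if (!"participant_id" %in% names(data)) {
    abort("Missing `participant_id` column.", class = "uritox_schema_error")
  }
  if (!"group" %in% names(data)) {
    abort("Missing `group` column.", class = "uritox_schema_error")
  }
  data$participant_id <- as.character(data$participant_id)
  if (anyDuplicated(data$participant_id)) {
    dup <- unique(data$participant_id[duplicated(data$participant_id)])
    abort(paste0("Duplicate participant id(s): ", paste(dup, collapse = ", ")),
          class = "uritox_validation_error")
  }
  bad_grp <- setdiff(unique(data$group), c("ASD", "NT"))
  if (length(bad_grp) > 0) {
    abort(paste0("Unknown group label(s): ", paste(bad_grp, collapse = ", ")),
          class = "uritox_validation_error")
  }
  for (m in metals) {
    cname <- paste0(m, "_censored")
    if (!cname %in% names(data)) data[[cname]] <- FALSE
    data[[cname]] <- as.logical(data[[cname]])
    if (!is.numeric(data[[m]])) {
      abort(paste0("Metal column `", m, "` is not numeric."),
            class = "uritox_schema_error")
    }
  }
  keep <- c("participant_id", "group", as.vector(rbind(metals, paste0(metals, "_censored"))))
  data <- data[, keep]
  structure(data,
            metals = metals,
            detection_limits = detection_limits,
            class = c("utm_cohort", class(tibble::tibble())))
}

#' @export
print.utm_cohort <- function(x, ...) {
  n_asd <- sum(x$group == "ASD")
  n_nt <- sum(x$group == "NT")
  cat("<utm_cohort> ", nrow(x), " participants (", n_asd, " ASD / ", n_nt,
      " NT), ", length(cohort_metals(x)), " metals\n", sep = "")
  NextMethod()
}

#' Accessors for cohort tables
#'
#' `cohort_metals()` returns the ordered metal codes; `detection_limits()`
#' the named vector of detection limits; `panel_matrix()` the numeric
#' concentration matrix (participants x metals, rownames = participant ids).
#'
#' @param cohort A `utm_cohort`.
#' @param metals Optional subset of metal codes for `panel_matrix()`.
#' @export
cohort_metals <- function(cohort) attr(cohort, "metals")

#' @rdname cohort_metals
#' @export
detection_limits <- function(cohort) attr(cohort, "detection_limits")

#' @rdname cohort_metals
#' @export
panel_matrix <- function(cohort, metals = cohort_metals(cohort)) {
  stopifnot(all(metals %in% cohort_metals(cohort)))
  m <- as.matrix(as.data.frame(cohort)[, metals, drop = FALSE])
  rownames(m) <- cohort$participant_id
  m
}

#' Read cohort and severity tables from CSV
#'
#' Reads the package's CSV dialect: one metals file per group with columns
#' `participant_id, group, <metal>, <metal>_censored, ...`, and a severity
#' file with `participant_id` plus one column per instrument. Rows containing
#' unparseable cells are rejected with a report naming the row and column.
#'
#' @param asd_metals_path,nt_metals_path Paths to the per-group metal CSVs.
#' @param severity_path Path to the severity CSV (ASD participants only).
#'   `NULL` skips severity loading.
#' @param detection_limits Either a named numeric vector (metal -> LOD) or a
#'   path to a two-column CSV `metal, lod`.
#' @return A list with elements `cohort` (a [new_cohort()] table) and
#'   `severity` (a `utm_severity` tibble or `NULL`).
#' @export
read_cohort_tables <- function(asd_metals_path, nt_metals_path,
                               severity_path = NULL,
                               detection_limits = numeric()) {
  if (is.character(detection_limits) && length(detection_limits) == 1) {
    lod_tbl <- readr::read_csv(detection_limits, show_col_types = FALSE)
    if (!all(c("metal", "lod") %in% names(lod_tbl))) {
      abort("Detection-limit file needs columns `metal` and `lod`.",
            class = "uritox_schema_error")
    }
    detection_limits <- setNames(lod_tbl$lod, lod_tbl$metal)
  }
  asd <- read_metal_csv(asd_metals_path, "ASD")
  nt <- read_metal_csv(nt_metals_path, "NT")
  if (!identical(names(asd), names(nt))) {
    abort("ASD and NT metal files have different columns.",
          class = "uritox_schema_error")
  }
  cohort <- new_cohort(dplyr::bind_rows(asd, nt),
                       detection_limits = detection_limits)
  severity <- NULL
  if (!is.null(severity_path)) {
    severity <- read_severity_csv(severity_path)
    extra <- setdiff(severity$participant_id,
                     cohort$participant_id[cohort$group == "ASD"])
    if (length(extra) > 0) {
      abort(paste0("Severity ids not in the ASD panel: ",
                   paste(extra, collapse = ", ")),
            class = "uritox_validation_error")
    }
  }
  list(cohort = cohort, severity = severity)
}

read_metal_csv <- function(path, group_label) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0 || !"participant_id" %in% names(raw)) {
    abort(paste0("File `", path, "` is empty or lacks `participant_id`."),
          class = "uritox_schema_error")
  }
  metals <- intersect(utm_metals_all, names(raw))
  if (length(metals) == 0) {
    abort(paste0("File `", path, "` contains no recognized metal column."),
          class = "uritox_schema_error")
  }
  out <- tibble::tibble(participant_id = raw$participant_id)
  out$group <- if ("group" %in% names(raw)) raw$group else group_label
  bad <- character()
  for (m in metals) {
    v <- suppressWarnings(as.numeric(raw[[m]]))
    miss <- which(is.na(v) & !is.na(raw[[m]]))
    if (length(miss) > 0) bad <- c(bad, paste0("row ", miss, " col ", m))
    out[[m]] <- v
    cname <- paste0(m, "_censored")
    if (cname %in% names(raw)) {
      cv <- parse_logical_cell(raw[[cname]])
      cbad <- which(is.na(cv) & !is.na(raw[[cname]]))
      if (length(cbad) > 0) bad <- c(bad, paste0("row ", cbad, " col ", cname))
      out[[cname]] <- cv
    } else {
      out[[cname]] <- FALSE
    }
  }
  if (length(bad) > 0) {
    abort(paste0("Unparseable cell(s) in `", path, "`: ",
                 paste(bad, collapse = "; ")),
          class = "uritox_parse_error")
  }
  out
}

parse_logical_cell <- function(x) {
  low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[low %in% c("true", "t", "1", "yes")] <- TRUE
  out[low %in% c("false", "f", "0", "no")] <- FALSE
  as.logical(out)
}

read_severity_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(raw) == 0 || !"participant_id" %in% names(raw)) {
    abort(paste0("Severity file `", path, "` is empty or lacks `participant_id`."),
          class = "uritox_schema_error")
  }
  raw$participant_id <- as.character(raw$participant_id)
  meas <- setdiff(names(raw), "participant_id")
  for (m in meas) {
    if (!is.numeric(raw[[m]])) {
      abort(paste0("Severity column `", m, "` is not numeric."),
            class = "uritox_schema_error")
    }
    if (any(raw[[m]] < 0, na.rm = TRUE)) {
      abort(paste0("Negative scores in severity column `", m, "`."),
            class = "uritox_validation_error")
    }
  }
  structure(tibble::as_tibble(raw),
            class = c("utm_severity", class(tibble::tibble())))
}

#' Write cohort and severity tables in the package CSV dialect
#'
#' Emits `asd_metals.csv`, `nt_metals.csv`, `severity.csv` (if present) and
#' `detection_limits.csv` under `dir`. Values round-trip bit-exactly through
#' [read_cohort_tables()].
#'
#' @param cohort A `utm_cohort`.
#' @param severity Optional `utm_severity` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_tables <- function(cohort, severity = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(asd = file.path(dir, "asd_metals.csv"),
             nt = file.path(dir, "nt_metals.csv"))
  readr::write_csv(tibble::as_tibble(cohort[cohort$group == "ASD", ]), paths[["asd"]])
  readr::write_csv(tibble::as_tibble(cohort[cohort$group == "NT", ]), paths[["nt"]])
  lod <- detection_limits(cohort)
  lod_path <- file.path(dir, "detection_limits.csv")
  readr::write_csv(tibble::tibble(metal = names(lod), lod = unname(lod)), lod_path)
  paths <- c(paths, lod = lod_path)
  if (!is.null(severity)) {
    sev_path <- file.path(dir, "severity.csv")
    readr::write_csv(tibble::as_tibble(severity), sev_path)
    paths <- c(paths, severity = sev_path)
  }
  invisible(paths)
}

#' Substitute left-censored cells with 2/3 of the detection limit
#'
#' Concentrations flagged below the detection limit are replaced with
#' two-thirds of that metal's detection limit, the standard single-value
#' substitution for left-censored biomonitoring panels. Uncensored cells are
#' untouched; the operation is idempotent.
#'
#' @param cohort A `utm_cohort`.
#' @return The cohort with censored cells substituted.
#' @export
substitute_below_detection <- function(cohort) {
  lod <- detection_limits(cohort)
  for (m in cohort_metals(cohort)) {
    flag <- cohort[[paste0(m, "_censored")]]
    if (any(flag)) {
      if (!m %in% names(lod) || is.na(lod[[m]])) {
        abort(paste0("Censored cells for `", m, "` but no detection limit supplied."),
              class = "uritox_config_error")
      }
      cohort[[m]][flag] <- 2 / 3 * lod[[m]]
    }
  }
  cohort
}

#' Subset a cohort to selected metals
#'
#' Column-subsets the panel, preserving row order and the stored metal order.
#' The canonical modelling subset is [utm_metals_modeling] (antimony
#' excluded).
#'
#' @param cohort A `utm_cohort`.
#' @param codes Metal codes to keep (must be a subset of the panel's metals).
#' @return A `utm_cohort` with only the requested metal columns.
#' @export
select_metals <- function(cohort, codes) {
  unknown <- setdiff(codes, cohort_metals(cohort))
  if (length(unknown) > 0) {
    abort(paste0("Unknown metal code(s): ", paste(unknown, collapse = ", ")),
          class = "uritox_lookup_error")
  }
  codes <- cohort_metals(cohort)[cohort_metals(cohort) %in% codes]
  keep <- c("participant_id", "group", as.vector(rbind(codes, paste0(codes, "_censored"))))
  structure(tibble::as_tibble(cohort)[, keep],
            metals = codes,
            detection_limits = detection_limits(cohort)[intersect(names(detection_limits(cohort)), codes)],
            class = class(cohort))
}

#' Standardize a metal panel to zero mean and unit variance
#'
#' Column means and standard deviations (n-1 denominator) are estimated on
#' `fit_rows` only; all rows are then transformed with those statistics, so
#' rows outside `fit_rows` (e.g. a held-out cross-validation sample) are
#' mapped by the same affine transform without refitting.
#'
#' @param cohort A `utm_cohort` (censoring already substituted).
#' @param metals Metal codes to standardize; default the full stored panel.
#' @param fit_rows Integer row indices used to estimate the statistics;
#'   default all rows.
#' @return An object of class `utm_standardized`: a list with `z` (tibble of
#'   z-scores plus `participant_id` and `group`), `center`, `scale`,
#'   `metals`, and `fit_rows`.
#' @export
standardize_panel <- function(cohort, metals = cohort_metals(cohort),
                              fit_rows = seq_len(nrow(cohort))) {
  if (length(fit_rows) == 0) {
    abort("`fit_rows` must be non-empty.", class = "uritox_parameter_error")
  }
  x <- panel_matrix(cohort, metals)
  ctr <- colMeans(x[fit_rows, , drop = FALSE])
  scl <- apply(x[fit_rows, , drop = FALSE], 2, sd)
  degenerate <- metals[scl == 0 | !is.finite(scl)]
  if (length(degenerate) > 0) {
    abort(paste0("Zero-variance metal column(s) in the fitting rows: ",
                 paste(degenerate, collapse = ", ")),
          class = "uritox_degenerate_error")
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(
    z = dplyr::bind_cols(tibble::tibble(participant_id = cohort$participant_id,
                                        group = cohort$group),
                         tibble::as_tibble(z)),
    center = ctr, scale = scl, metals = metals, fit_rows = fit_rows
  ), class = "utm_standardized")
}

#' @export
print.utm_standardized <- function(x, ...) {
  cat("<utm_standardized> ", nrow(x$z), " rows, ", length(x$metals),
      " metals; statistics fitted on ", length(x$fit_rows), " rows\n", sep = "")
  invisible(x)
}

#' Apply stored standardization statistics to new observations
#'
#' @param std A `utm_standardized` object.
#' @param x A numeric matrix or data frame with the standardized metals as
#'   columns (raw concentrations).
#' @return A numeric matrix of z-scores.
#' @export
apply_standardization <- function(std, x) {
  x <- as.matrix(as.data.frame(x)[, std$metals, drop = FALSE])
  sweep(sweep(x, 2, std$center), 2, std$scale, "/")
}

#' Invert standardization (z-scores back to concentrations)
#'
#' @param std A `utm_standardized` object.
#' @param z A numeric matrix of z-scores with the standardized metals as columns.
#' @return A numeric matrix of raw-scale values.
#' @export
invert_standardization <- function(std, z) {
  z <- as.matrix(as.data.frame(z)[, std$metals, drop = FALSE])
  sweep(sweep(z, 2, std$scale, "*"), 2, std$center, "+")
}

# z-score matrix helper used by the model fitters
standardized_matrix <- function(std) {
  as.matrix(as.data.frame(std$z)[, std$metals, drop = FALSE])
}
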
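#' Per-metal group summary (univariate comparison table)
#'
#' For each requested metal: group means and quartiles (linear interpolation
#' between order statistics), percent of values below the detection limit
#' per group, the percent difference of group means
#' `100 * (mean_ASD - mean_NT) / mean_NT` computed from unrounded means, and
#' a two-sided two-sample t-test p-value (pooled variance by default).
#'
#' @param cohort A `utm_cohort` with censoring already substituted.
#' @param metals Metal codes to summarize; default the full stored panel.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return A tibble with one row per metal: `metal`, `mean_asd`, `q25_asd`,
#'   `q75_asd`, `mean_nt`, `q25_nt`, `q75_nt`, `pct_below_lod_asd`,
#'   `pct_below_lod_nt`, `pct_difference`, `p_value`.
#' @export
group_summary <- function(cohort, metals = cohort_metals(cohort),
                          var_equal = TRUE) {
  unknown <- setdiff(metals, cohort_metals(cohort))
  if (length(unknown) > 0) {
    abort(paste0("Unknown metal code(s): ", paste(unknown, collapse = ", ")),
          class = "uritox_lookup_error")
  }
  asd <- cohort$group == "ASD"
  purrr::map_dfr(metals, function(m) {
    xa <- cohort[[m]][asd]
    xn <- cohort[[m]][!asd]
    ca <- cohort[[paste0(m, "_censored")]][asd]
    cn <- cohort[[paste0(m, "_censored")]][!asd]
    p <- if (sd(xa) == 0 && sd(xn) == 0 && mean(xa) == mean(xn)) 1 else {
      t.test(xa, xn, var.equal = var_equal)$p.value
    }
    tibble::tibble(
      metal = m,
      mean_asd = mean(xa), q25_asd = quantile(xa, 0.25, names = FALSE),
      q75_asd = quantile(xa, 0.75, names = FALSE),
      mean_nt = mean(xn), q25_nt = quantile(xn, 0.25, names = FALSE),
      q75_nt = quantile(xn, 0.75, names = FALSE),
      pct_below_lod_asd = 100 * mean(ca),
      pct_below_lod_nt = 100 * mean(cn),
      pct_difference = 100 * (mean(xa) - mean(xn)) / mean(xn),
      p_value = p
    )
  })
}

#' Two-sample Hotelling's T-squared test
#'
#' Multivariate generalization of the two-sample t-test: compares the group
#' mean vectors of the selected metal columns using the pooled covariance,
#' with the exact F transformation
#' `F = (n1 + n2 - p - 1) / ((n1 + n2 - 2) p) * T2` on `(p, n1 + n2 - p - 1)`
#' degrees of freedom.
#'
#' @param cohort A `utm_cohort`.
#' @param metals Metal codes to include; default the ten-metal modelling panel
#'   intersected with the stored panel.
#' @return A tibble with `statistic` (T-squared), `f`, `df1`, `df2`, `p_value`.
#' @export
hotelling_t2 <- function(cohort,
                         metals = intersect(utm_metals_modeling, cohort_metals(cohort))) {
  x <- panel_matrix(cohort, metals)
  g <- cohort$group
  x1 <- x[g == "ASD", , drop = FALSE]
  x2 <- x[g == "NT", , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x)
  if (n1 + n2 - 2 <= p) {
    abort("Pooled covariance is rank deficient: need n1 + n2 - 2 > #metals.",
          class = "uritox_rank_error")
  }
  d <- colMeans(x1) - colMeans(x2)
  s_pooled <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  sol <- tryCatch(solve(s_pooled, d), error = function(e) {
    abort("Pooled covariance is numerically singular.", class = "uritox_rank_error")
  })
  t2 <- (n1 * n2 / (n1 + n2)) * sum(d * sol)
  f_stat <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  df2 <- n1 + n2 - p - 1
  tibble::tibble(statistic = t2, f = f_stat, df1 = p, df2 = df2,
                 p_value = pf(f_stat, p, df2, lower.tail = FALSE))
}
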
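#' Diagnostic plots
#'
#' `autoplot()` methods give each result type a standard ggplot: the Type
#' I/II tradeoff curve, per-group discriminant-score densities, PCA loading
#' maps with cluster colours, subset-search R-squared against subset size,
#' and kernel density estimates. `plot_sensitivity()` draws one-at-a-time
#' response curves from [sensitivity_profile()].
#'
#' @param object The fitted object.
#' @param ... Unused.
#' @return A ggplot.
#' @name uritox-plots
NULL

#' @rdname uritox-plots
#' @export
autoplot.utm_tradeoff <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$type_i, y = .data$type_ii)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = object$fixed_grid, colour = "firebrick") +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = 3) +
    ggplot2::labs(x = "Type I error (NT misclassified as ASD)",
                  y = "Type II error (ASD misclassified as NT)",
                  title = paste0("Leave-one-out error tradeoff",
                                 if (!is.null(object$method)) paste0(" (", object$method, ")"))) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @rdname uritox-plots
#' @param from `"heldout"` (tradeoff objects) or `"training"` (discriminant
#'   models): which scores the densities describe.
#' @export
plot_score_densities <- function(object, from = NULL, ...) {
  if (inherits(object, "utm_tradeoff")) {
    scores <- object$scores
  } else if (inherits(object, "utm_discriminant")) {
    scores <- tibble::tibble(
      group = c(rep("ASD", length(object$training_scores_asd)),
                rep("NT", length(object$training_scores_nt))),
      score = c(object$training_scores_asd, object$training_scores_nt))
  } else {
    abort("Expected a `utm_tradeoff` or `utm_discriminant`.",
          class = "uritox_parameter_error")
  }
  dens <- purrr::map_dfr(c("ASD", "NT"), function(g) {
    s <- scores$score[scores$group == g]
    kde <- estimate_density(s, "gaussian")
    grid <- seq(min(scores$score) - 2 * kde$h, max(scores$score) + 2 * kde$h,
                length.out = 200)
    tibble::tibble(group = g, score = grid, density = kde_eval(kde, grid))
  })
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$score, y = .data$density,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = scores, ggplot2::aes(x = .data$score, colour = .data$group),
                      inherit.aes = FALSE, alpha = 0.5) +
    ggplot2::labs(x = "discriminant score", y = "estimated density") +
    ggplot2::theme_minimal()
}

#' @rdname uritox-plots
#' @export
autoplot.utm_pca <- function(object, ...) {
  cl <- cluster_measures(object)
  df <- tibble::as_tibble(object$loadings[, 1:2], rownames = "measure")
  names(df)[2:3] <- c("PC1", "PC2")
  df$cluster <- factor(ifelse(cl$is_outlier, "outlier",
                              paste0("cluster ", cl$cluster)))
  evr <- round(100 * object$explained_variance_ratio[1:2], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$cluster, label = .data$measure)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, show.legend = FALSE, size = 3) +
    ggplot2::labs(x = paste0("PC1 (", evr[1], "%)"),
                  y = paste0("PC2 (", evr[2], "%)"),
                  title = "Severity-measure loadings") +
    ggplot2::theme_minimal()
}

#' @rdname uritox-plots
#' @export
autoplot.utm_subset_search <- function(object, ...) {
  df <- object$per_size
  long <- tidyr::pivot_longer(
    df[, c("size", "r2_cv", intersect("r2_fit_nocv", names(df)))],
    -"size", names_to = "kind", values_to = "r2")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$r2,
                                     colour = .data$kind)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$size) +
    ggplot2::labs(x = "metals in predictor set", y = expression(R^2),
                  title = paste0(object$response, " (", object$method, ")")) +
    ggplot2::theme_minimal()
}

#' @rdname uritox-plots
#' @export
autoplot.utm_kde <- function(object, ...) {
  grid <- seq(min(object$samples) - 3 * object$h,
              max(object$samples) + 3 * object$h, length.out = 400)
  df <- tibble::tibble(x = grid, density = kde_eval(object, grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = tibble::tibble(x = object$samples),
                      ggplot2::aes(x = .data$x), inherit.aes = FALSE, alpha = 0.5) +
    ggplot2::labs(title = paste0(object$kernel, " kernel, h = ",
                                 signif(object$h, 3))) +
    ggplot2::theme_minimal()
}

#' @rdname uritox-plots
#' @param profile Tibble from [sensitivity_profile()].
#' @export
plot_sensitivity <- function(profile, ...) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$value, y = .data$prediction)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metal, scales = "free_x") +
    ggplot2::labs(x = "concentration (mcg/g-creatinine)",
                  y = "predicted severity") +
    ggplot2::theme_minimal()
}
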
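#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns the model's per-term table (discriminant weights, PLS
#' coefficients, PCA loadings, tradeoff grid rows, subset-search winners);
#' `glance()` a one-row model summary; `augment()` the data with fitted
#' values and residuals where that makes sense.
#'
#' @param x A fitted uritox object.
#' @param ... Unused.
#' @name uritox-tidiers
NULL

#' @rdname uritox-tidiers
#' @export
tidy.utm_discriminant <- function(x, ...) {
  if (x$kind == "linear") {
    tibble::tibble(metal = names(x$direction), weight = unname(x$direction))
  } else {
    tibble::tibble(sample = seq_along(x$alpha), alpha = unname(x$alpha))
  }
}

#' @rdname uritox-tidiers
#' @export
glance.utm_discriminant <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_train = length(x$training_scores_asd) + length(x$training_scores_nt),
    n_metals = length(x$metals),
    separation = x$separation,
    sigma = if (x$kind == "kernel") x$sigma else NA_real_,
    lambda = if (x$kind == "kernel") x$lambda else NA_real_
  )
}

#' @rdname uritox-tidiers
#' @export
tidy.utm_tradeoff <- function(x, ...) x$fixed_grid

#' @rdname uritox-tidiers
#' @export
glance.utm_tradeoff <- function(x, ...) {
  tibble::tibble(
    method = x$method %||% NA_character_,
    n = nrow(x$scores),
    n_asd = sum(x$scores$group == "ASD"),
    n_nt = sum(x$scores$group == "NT"),
    auc_like = 1 - mean(vapply(
      x$scores$score[x$scores$group == "ASD"],
      function(s) mean(x$scores$score[x$scores$group == "NT"] >= s),
      numeric(1)))
  )
}

#' @rdname uritox-tidiers
#' @export
tidy.utm_pls_model <- function(x, ...) {
  if (x$kind == "linear") {
    tibble::tibble(metal = names(x$coefficients),
                   coefficient = unname(x$coefficients))
  } else {
    tibble::tibble(sample = seq_along(x$dual), dual = unname(x$dual))
  }
}

#' @rdname uritox-tidiers
#' @export
glance.utm_pls_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_latent = x$n_latent,
                 n_metals = length(x$metals), r2_fit = x$r2_fit,
                 sigma = if (x$kind == "kernel") x$sigma else NA_real_)
}

#' @rdname uritox-tidiers
#' @param data Optional data frame to augment; defaults to the training
#'   fitted values and residuals only.
#' @export
augment.utm_pls_model <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    tibble::tibble(.fitted = x$fitted, .resid = x$residuals)
  } else {
    data <- tibble::as_tibble(data)
    data$.fitted <- predict(x, data)
    data
  }
}

#' @rdname uritox-tidiers
#' @export
tidy.utm_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "measure") |>
    tidyr::pivot_longer(-"measure", names_to = "component",
                        values_to = "loading")
}

#' @rdname uritox-tidiers
#' @export
glance.utm_pca <- function(x, ...) {
  tibble::tibble(
    n_measures = length(x$measures),
    var_pc1 = x$explained_variance_ratio[1],
    var_pc2 = x$explained_variance_ratio[2],
    var_first_two = sum(x$explained_variance_ratio[1:2])
  )
}

#' @rdname uritox-tidiers
#' @export
tidy.utm_subset_search <- function(x, ...) x$per_size

#' @rdname uritox-tidiers
#' @export
glance.utm_subset_search <- function(x, ...) {
  best <- x$global_best
  tibble::tibble(response = x$response, method = x$method,
                 n_subsets = sum(x$n_evaluated),
                 best_size = best$size, best_metals = best$metals,
                 best_r2_cv = best$r2_cv)
}
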
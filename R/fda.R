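#' Fit a linear Fisher discriminant to a standardized metal panel
#'
#' Computes the direction `w` proportional to `Sw^-1 (mu_ASD - mu_NT)`,
#' where `Sw` is the pooled within-class scatter, unit-normalizes it, and
#' fixes the sign so that the mean ASD score exceeds the mean NT score.
#' Scores are affinely normalized so the training class mean scores map to
#' +1 (ASD) and -1 (NT), making scores comparable across refits. Per-group
#' kernel density estimates of the training scores are attached for
#' score-distribution reporting.
#'
#' @param std A `utm_standardized` panel whose `z` carries a `group` column
#'   with both `"ASD"` and `"NT"` rows.
#' @param ridge Non-negative ridge added to the diagonal of `Sw` (relative
#'   to its mean diagonal) when the scatter is ill-conditioned; default 0.
#' @param densities Fit per-group score densities (default `TRUE`).
#' @return Object of class `c("utm_fda", "utm_discriminant")`.
#' @export
fit_fda <- function(std, ridge = 0, densities = TRUE) {
  z <- standardized_matrix(std)
  g <- std$z$group
  check_two_groups(g)
  x1 <- z[g == "ASD", , drop = FALSE]
  x2 <- z[g == "NT", , drop = FALSE]
  sw <- crossprod(sweep(x1, 2, colMeans(x1))) +
    crossprod(sweep(x2, 2, colMeans(x2)))
  if (ridge > 0) sw <- sw + diag(ridge * mean(diag(sw)), ncol(sw))
  dmu <- colMeans(x1) - colMeans(x2)
  w <- tryCatch(solve(sw, dmu), error = function(e) {
    abort("Within-class scatter is singular; supply `ridge` > 0.",
          class = "uritox_rank_error")
  })
  w <- w / sqrt(sum(w^2))
  raw <- drop(z %*% w)
  if (mean(raw[g == "ASD"]) < mean(raw[g == "NT"])) {
    w <- -w
    raw <- -raw
  }
  finish_discriminant(
    list(kind = "linear", direction = setNames(w, std$metals),
         metals = std$metals, center = std$center, scale = std$scale),
    raw, g, densities, class = "utm_fda")
}

#' Fit a Gaussian-kernel Fisher discriminant
#'
#' Solves the ridge-regularized kernel Fisher problem of Mika et al.: with
#' kernel `k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`, per-class mean
#' kernel vectors `M_g` and within-class kernel scatter `N`, the dual
#' coefficients are `alpha = (N + lambda * mean(diag(N)) * I)^-1 (M_ASD - M_NT)`
#' and `score(x) = sum_i alpha_i k(x, z_i)`. Scores are normalized exactly
#' as in [fit_fda()].
#'
#' @param std A `utm_standardized` panel with a two-group `group` column.
#' @param sigma Kernel width (> 0) on the z-score scale; default the median
#'   pairwise Euclidean distance among training rows.
#' @param lambda Ridge, relative to the mean diagonal of `N`; default 1e-2.
#' @param densities Fit per-group score densities.
#' @return Object of class `c("utm_kfda", "utm_discriminant")`.
#' @export
fit_kfda <- function(std, sigma = NULL, lambda = 1e-2, densities = TRUE) {
  z <- standardized_matrix(std)
  g <- std$z$group
  check_two_groups(g)
  if (is.null(sigma)) sigma <- median_pairwise_distance(z)
  if (sigma <= 0) {
    abort("`sigma` must be positive.", class = "uritox_parameter_error")
  }
  if (lambda < 0) {
    abort("`lambda` must be non-negative.", class = "uritox_parameter_error")
  }
  K <- rbf_kernel(z, z, sigma)
  alpha <- kfda_dual(K, g, lambda)
  raw <- drop(K %*% alpha)
  if (mean(raw[g == "ASD"]) < mean(raw[g == "NT"])) {
    alpha <- -alpha
    raw <- -raw
  }
  finish_discriminant(
    list(kind = "kernel", alpha = alpha, sigma = sigma, lambda = lambda,
         train_z = z, metals = std$metals, center = std$center,
         scale = std$scale),
    raw, g, densities, class = "utm_kfda")
}

check_two_groups <- function(g) {
  if (sum(g == "ASD") == 0 || sum(g == "NT") == 0) {
    abort("Both groups must be non-empty.", class = "uritox_fold_error")
  }
}

rbf_kernel <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

median_pairwise_distance <- function(z) {
  d <- stats::dist(z)
  m <- median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else m
}

kfda_dual <- function(K, g, lambda) {
  n <- nrow(K)
  N <- matrix(0, n, n)
  Ms <- list()
  for (lab in c("ASD", "NT")) {
    idx <- which(g == lab)
    Kg <- K[, idx, drop = FALSE]
    nj <- length(idx)
    Ms[[lab]] <- rowMeans(Kg)
    N <- N + tcrossprod(Kg) - nj * tcrossprod(Ms[[lab]])
  }
  solve(N + diag(lambda * mean(diag(N)) + 1e-10, n), Ms$ASD - Ms$NT)
}

finish_discriminant <- function(model, raw, g, densities, class) {
  m_asd <- mean(raw[g == "ASD"])
  m_nt <- mean(raw[g == "NT"])
  half <- (m_asd - m_nt) / 2
  if (abs(half) < 1e-12) half <- 1   # identical groups: leave scores unscaled
  model$score_center <- (m_asd + m_nt) / 2
  model$score_halfwidth <- half
  sc <- (raw - model$score_center) / half
  model$training_scores_asd <- sc[g == "ASD"]
  model$training_scores_nt <- sc[g == "NT"]
  model$separation <- mean(model$training_scores_asd) - mean(model$training_scores_nt)
  if (densities) {
    model$density_asd <- try_density(model$training_scores_asd)
    model$density_nt <- try_density(model$training_scores_nt)
  }
  structure(model, class = c(class, "utm_discriminant"))
}

try_density <- function(scores) {
  tryCatch(estimate_density(scores, "gaussian"), error = function(e) NULL)
}

#' @export
print.utm_discriminant <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$kind, " discriminant on ",
      length(x$metals), " metals; training separation = ",
      signif(x$separation, 4), "\n", sep = "")
  invisible(x)
}

#' Score observations with a fitted discriminant
#'
#' Raw concentrations are standardized with the model's stored training
#' statistics (no refitting) and projected; scores are on the normalized
#' scale where the training class means sit at +1 (ASD) and -1 (NT).
#'
#' @param model A fitted `utm_discriminant`.
#' @param x Matrix or data frame of raw concentrations with the model's
#'   metals as columns, or an already-standardized matrix when
#'   `standardized = TRUE`.
#' @param standardized Set `TRUE` when `x` is already on the z-score scale.
#' @return Numeric vector of discriminant scores.
#' @export
discriminant_score <- function(model, x, standardized = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, model$metals))
  x <- as.matrix(as.data.frame(x)[, model$metals, drop = FALSE])
  z <- if (standardized) x else {
    sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  }
  raw <- if (model$kind == "linear") {
    drop(z %*% model$direction)
  } else {
    drop(rbf_kernel(z, model$train_z, model$sigma) %*% model$alpha)
  }
  (raw - model$score_center) / model$score_halfwidth
}

#' Classify observations at a score threshold
#'
#' Labels an observation ASD iff its discriminant score strictly exceeds
#' the threshold; ties go to NT (conservative on Type I error).
#'
#' @inheritParams discriminant_score
#' @param threshold Score threshold.
#' @return Character vector of `"ASD"` / `"NT"` labels.
#' @export
classify <- function(model, x, threshold = 0, standardized = FALSE) {
  ifelse(discriminant_score(model, x, standardized) > threshold, "ASD", "NT")
}

#' Leave-one-out discriminant scores
#'
#' For each participant, refits the standardization and the discriminant on
#' all other participants and scores the held-out one, yielding a vector of
#' statistically independent scores.
#'
#' @param cohort A `utm_cohort` (substitution applied).
#' @param method `"fda"` or `"kfda"`.
#' @param metals Metal codes for the predictor panel.
#' @param sigma,lambda Kernel hyperparameters (KFDA only); `sigma = NULL`
#'   uses the per-fold median pairwise distance.
#' @return Tibble with `participant_id`, `group`, `score`.
#' @export
loo_scores <- function(cohort, method = c("fda", "kfda"),
                       metals = intersect(utm_metals_modeling, cohort_metals(cohort)),
                       sigma = NULL, lambda = 1e-2) {
  method <- match.arg(method)
  n <- nrow(cohort)
  if (min(table(cohort$group)) < 2) {
    abort("Need at least 2 participants per group for leave-one-out.",
          class = "uritox_fold_error")
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    std <- standardize_panel(cohort, metals, fit_rows = train)
    std_train <- std
    std_train$z <- std$z[train, , drop = FALSE]
    model <- if (method == "fda") {
      fit_fda(std_train, densities = FALSE)
    } else {
      fit_kfda(std_train, sigma = sigma, lambda = lambda, densities = FALSE)
    }
    z_i <- standardized_matrix(std)[i, , drop = FALSE]
    scores[i] <- discriminant_score(model, z_i, standardized = TRUE)
  }
  tibble::tibble(participant_id = cohort$participant_id,
                 group = cohort$group, score = scores)
}

#' Leave-one-out Type I / Type II error tradeoff
#'
#' Computes held-out discriminant scores via [loo_scores()], sweeps the
#' decision threshold over the pooled score range, and reports, for each
#' allowed Type I error on a fixed grid, the smallest threshold whose
#' empirical held-out NT exceedance rate does not exceed it, together with
#' the resulting Type II error (fraction of held-out ASD scores at or below
#' the threshold). Per-group kernel densities of the held-out scores are
#' attached for score-distribution plots.
#'
#' @inheritParams loo_scores
#' @param type_i_grid Allowed Type I errors (decreasing grid).
#' @return Object of class `utm_tradeoff`: list with `scores`, `points`
#'   (full threshold sweep), `fixed_grid` (tibble `type_i_allowed`,
#'   `threshold`, `type_i`, `type_ii`), `method`, and the score densities.
#' @export
error_tradeoff_loo <- function(cohort, method = c("fda", "kfda"),
                               metals = intersect(utm_metals_modeling, cohort_metals(cohort)),
                               sigma = NULL, lambda = 1e-2,
                               type_i_grid = c(0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10)) {
  method <- match.arg(method)
  scores <- loo_scores(cohort, method, metals, sigma, lambda)
  out <- tradeoff_from_scores(scores, type_i_grid)
  out$method <- method
  out$metals <- metals
  out$sigma <- sigma
  out$lambda <- if (method == "kfda") lambda else NULL
  out
}

# threshold machinery shared by LOO and training-score tradeoffs
tradeoff_from_scores <- function(scores, type_i_grid) {
  s_nt <- scores$score[scores$group == "NT"]
  s_asd <- scores$score[scores$group == "ASD"]
  thr <- sort(unique(c(-Inf, scores$score)))
  points <- tibble::tibble(
    threshold = thr,
    type_i = vapply(thr, function(t) mean(s_nt > t), numeric(1)),
    type_ii = vapply(thr, function(t) mean(s_asd <= t), numeric(1))
  )
  fixed <- purrr::map_dfr(sort(type_i_grid, decreasing = TRUE), function(a) {
    ok <- points$type_i <= a
    j <- which(ok)[1]   # smallest threshold achieving Type I <= a
    tibble::tibble(type_i_allowed = a, threshold = points$threshold[j],
                   type_i = points$type_i[j], type_ii = points$type_ii[j])
  })
  structure(list(scores = scores, points = points, fixed_grid = fixed,
                 density_asd = try_density(s_asd),
                 density_nt = try_density(s_nt)),
            class = "utm_tradeoff")
}

#' @export
print.utm_tradeoff <- function(x, ...) {
  cat("<utm_tradeoff>", if (!is.null(x$method)) paste0(" method = ", x$method), "\n", sep = "")
  print(x$fixed_grid)
  invisible(x)
}

#' Tune KFDA hyperparameters by grid search on the LOO tradeoff
#'
#' Evaluates a grid of kernel widths and ridge values, computing for each
#' the leave-one-out error tradeoff and the total error (achieved Type I +
#' Type II) at a target allowed Type I error, and returns the grid results
#' plus the winning pair. The paper-style operating point 0.15 is the
#' default target.
#'
#' @inheritParams loo_scores
#' @param sigma_grid Kernel widths; default multiples
#'   `c(0.25, 0.5, 1, 2, 4)` of the median pairwise distance of the
#'   combined standardized panel.
#' @param lambda_grid Relative ridge values.
#' @param target_type_i Allowed Type I error at which total error is scored.
#' @param type_i_grid Grid passed through to [error_tradeoff_loo()].
#' @return List with `grid` (tibble of all evaluated pairs), `best_sigma`,
#'   `best_lambda`, `best` (the winning `utm_tradeoff`).
#' @export
tune_kfda <- function(cohort,
                      metals = intersect(utm_metals_modeling, cohort_metals(cohort)),
                      sigma_grid = NULL, lambda_grid = c(1e-3, 1e-2, 1e-1),
                      target_type_i = 0.15,
                      type_i_grid = c(0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10)) {
  if (is.null(sigma_grid)) {
    std <- standardize_panel(cohort, metals)
    sigma_grid <- median_pairwise_distance(standardized_matrix(std)) *
      c(0.25, 0.5, 1, 2, 4)
  }
  grid <- tidyr::expand_grid(sigma = sigma_grid, lambda = lambda_grid)
  results <- purrr::pmap(grid, function(sigma, lambda) {
    error_tradeoff_loo(cohort, "kfda", metals, sigma = sigma, lambda = lambda,
                       type_i_grid = type_i_grid)
  })
  grid$total_error <- vapply(results, function(tr) {
    row <- tr$fixed_grid[tr$fixed_grid$type_i_allowed == target_type_i, ]
    row$type_i + row$type_ii
  }, numeric(1))
  best_i <- which.min(grid$total_error)
  list(grid = grid, best_sigma = grid$sigma[best_i],
       best_lambda = grid$lambda[best_i], best = results[[best_i]])
}
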
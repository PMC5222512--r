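#' Join metal panel and severity scores for regression
#'
#' Inner-joins the ASD rows of a cohort with a severity table by
#' `participant_id`, returning one row per ASD participant with metal
#' concentrations and severity scores side by side — the input shape for
#' [loo_r2()], [subset_search()] and friends.
#'
#' @param cohort A `utm_cohort` (substitution applied).
#' @param severity A `utm_severity` tibble.
#' @return A tibble.
#' @export
asd_regression_data <- function(cohort, severity) {
  asd <- tibble::as_tibble(cohort)[cohort$group == "ASD", ]
  out <- dplyr::inner_join(asd, tibble::as_tibble(severity), by = "participant_id")
  attr(out, "metals") <- cohort_metals(cohort)
  out
}

# NIPALS PLS1 on already centered/scaled X and centered y.
# Returns weights W, loadings P, regression scalars q, number of components
# actually extracted (may be < ncomp when rank is exhausted).
pls1_nipals <- function(X, y, ncomp) {
  p <- ncol(X)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(X %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pl <- crossprod(X, t) / tt
    q <- sum(y * t) / tt
    X <- X - tcrossprod(t, pl)
    y <- y - q * t
    a <- k
    W[, k] <- w; P[, k] <- pl; Q[k] <- q; Tm[, k] <- t
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       Q = Q[seq_len(a)], T = Tm[, seq_len(a), drop = FALSE], ncomp = a)
}

# Sequential test-set projection: predictions for every latent count 1..A.
# Znew is centered/scaled; returns matrix (nrow(Znew) x A) of centered-scale
# predictions.
pls1_predict_all <- function(fit, Znew) {
  A <- fit$ncomp
  out <- matrix(0, nrow(Znew), A)
  Xc <- Znew
  acc <- numeric(nrow(Znew))
  for (a in seq_len(A)) {
    t <- drop(Xc %*% fit$W[, a])
    Xc <- Xc - tcrossprod(t, fit$P[, a])
    acc <- acc + fit$Q[a] * t
    out[, a] <- acc
  }
  out
}

#' Fit a linear partial least squares (PLS1) regression
#'
#' Extracts `n_latent` covariance-maximizing directions by NIPALS with
#' deflation; prediction is linear in the predictors. At full latent count
#' on a well-conditioned design the fit coincides with ordinary least
#' squares. Predictors are centered and scaled, and the response centered,
#' on the supplied (training) rows.
#'
#' @param x Numeric matrix or data frame of predictors (raw scale).
#' @param y Numeric response.
#' @param n_latent Number of latent components (1..ncol(x)).
#' @param scale Scale predictors to unit variance (default `TRUE`).
#' @return Object of class `c("utm_pls", "utm_pls_model")` with weights,
#'   loadings, raw-scale coefficients, training statistics, fitted values,
#'   residuals and the in-sample `r2_fit`.
#' @export
fit_pls <- function(x, y, n_latent, scale = TRUE) {
  x <- as.matrix(as.data.frame(x))
  stopifnot(nrow(x) >= 2, length(y) == nrow(x))
  if (n_latent < 1 || n_latent > ncol(x)) {
    abort("`n_latent` must lie in 1..ncol(x).", class = "uritox_rank_error")
  }
  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, sd) else rep(1, ncol(x))
  if (any(scl == 0)) {
    abort("Constant predictor column.", class = "uritox_degenerate_error")
  }
  Z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  y_center <- mean(y)
  fit <- pls1_nipals(Z, y - y_center, n_latent)
  if (fit$ncomp < n_latent) {
    abort(paste0("Rank exhausted after ", fit$ncomp, " components; ",
                 n_latent, " requested."), class = "uritox_rank_error")
  }
  b_z <- drop(fit$W %*% solve(crossprod(fit$P, fit$W), fit$Q))
  coef_raw <- b_z / scl
  fitted <- drop(Z %*% b_z) + y_center
  res <- y - fitted
  structure(list(
    kind = "linear", metals = colnames(x), n_latent = n_latent,
    weights = fit$W, loadings = fit$P, q = fit$Q, scores = fit$T,
    coefficients = setNames(coef_raw, colnames(x)),
    intercept = y_center - sum(coef_raw * ctr),
    x_center = ctr, x_scale = scl, y_center = y_center,
    x_range = apply(x, 2, range),
    fitted = fitted, residuals = res,
    r2_fit = 1 - sum(res^2) / sum((y - y_center)^2)
  ), class = c("utm_pls", "utm_pls_model"))
}

#' @export
predict.utm_pls <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$metals, drop = FALSE])
  drop(x %*% object$coefficients) + object$intercept
}

# Kernel PLS1 on a centered kernel matrix and centered y; stores score
# vectors T and normalized response scores U for dual prediction.
kpls1_core <- function(Kc, y, ncomp) {
  n <- nrow(Kc)
  Tm <- matrix(0, n, ncomp)
  U <- matrix(0, n, ncomp)
  Kcur <- Kc
  ycur <- y
  a <- 0L
  for (k in seq_len(ncomp)) {
    ny <- sqrt(sum(ycur^2))
    if (ny < 1e-12) break
    u <- ycur / ny
    t <- drop(Kcur %*% u)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    t <- t / nt
    a <- k
    Tm[, k] <- t; U[, k] <- u
    Pm <- diag(n) - tcrossprod(t)
    Kcur <- Pm %*% Kcur %*% Pm
    ycur <- ycur - t * sum(t * ycur)
  }
  list(T = Tm[, seq_len(a), drop = FALSE], U = U[, seq_len(a), drop = FALSE],
       ncomp = a)
}

#' Fit a kernel partial least squares (KPLS1) regression
#'
#' Kernel-matrix PLS with a centered Gaussian (or linear) kernel and
#' iterative deflation. Prediction for new points uses the dual
#' coefficients `U (T' K U)^-1 T' y` with the test kernel centered against
#' the training kernel. With the linear kernel, predictions coincide with
#' [fit_pls()].
#'
#' @inheritParams fit_pls
#' @param sigma Gaussian kernel width on the scaled-predictor scale; default
#'   the median pairwise distance. Ignored for `kernel = "linear"`.
#' @param kernel `"gaussian"` or `"linear"`.
#' @param n_latent Number of components (1..n-1).
#' @return Object of class `c("utm_kpls", "utm_pls_model")`.
#' @export
fit_kpls <- function(x, y, n_latent, sigma = NULL,
                     kernel = c("gaussian", "linear"), scale = TRUE) {
  kernel <- match.arg(kernel)
  x <- as.matrix(as.data.frame(x))
  n <- nrow(x)
  stopifnot(n >= 2, length(y) == n)
  if (n_latent < 1 || n_latent > n - 1) {
    abort("`n_latent` must lie in 1..(n-1).", class = "uritox_rank_error")
  }
  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, sd) else rep(1, ncol(x))
  if (any(scl == 0)) {
    abort("Constant predictor column.", class = "uritox_degenerate_error")
  }
  Z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  if (kernel == "gaussian") {
    if (is.null(sigma)) sigma <- median_pairwise_distance(Z)
    if (sigma <= 0) abort("`sigma` must be positive.", class = "uritox_parameter_error")
    K <- rbf_kernel(Z, Z, sigma)
  } else {
    sigma <- NA_real_
    K <- tcrossprod(Z)
  }
  Jc <- diag(n) - matrix(1 / n, n, n)
  Kc <- Jc %*% K %*% Jc
  y_center <- mean(y)
  yc <- y - y_center
  fit <- kpls1_core(Kc, yc, n_latent)
  if (fit$ncomp < n_latent) {
    abort(paste0("Rank exhausted after ", fit$ncomp, " components."),
          class = "uritox_rank_error")
  }
  dual <- fit$U %*% solve(crossprod(fit$T, Kc %*% fit$U), crossprod(fit$T, yc))
  fitted <- drop(Kc %*% dual) + y_center
  res <- y - fitted
  structure(list(
    kind = "kernel", metals = colnames(x), n_latent = n_latent,
    kernel = kernel, sigma = sigma, dual = drop(dual),
    train_z = Z, K = K, x_center = ctr, x_scale = scl, y_center = y_center,
    x_range = apply(x, 2, range),
    fitted = fitted, residuals = res,
    r2_fit = 1 - sum(res^2) / sum(yc^2)
  ), class = c("utm_kpls", "utm_pls_model"))
}

#' @export
predict.utm_kpls <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$metals, drop = FALSE])
  Z <- sweep(sweep(x, 2, object$x_center), 2, object$x_scale, "/")
  n <- nrow(object$train_z)
  Kt <- if (object$kernel == "gaussian") {
    rbf_kernel(Z, object$train_z, object$sigma)
  } else {
    tcrossprod(Z, object$train_z)
  }
  ones_n <- matrix(1 / n, nrow(Z), n)
  Ktc <- (Kt - ones_n %*% object$K) %*% (diag(n) - matrix(1 / n, n, n))
  drop(Ktc %*% object$dual) + object$y_center
}

#' @export
print.utm_pls_model <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$kind, " PLS, ", x$n_latent,
      " latent component(s) on {", paste(x$metals, collapse = "/"),
      "}; fit R^2 = ", signif(x$r2_fit, 3), "\n", sep = "")
  invisible(x)
}

# One LOO pass for a fixed predictor set. Returns, for each candidate latent
# count, held-out residual sums and the fold-centered response sum of
# squares, in a small list. `scope` controls whether per-fold centering/
# scaling of X is refitted ("train_fold") or taken from the full data
# ("combined").
loo_pass <- function(X, y, method, sigma = NULL, scope = "train_fold",
                     max_latent = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  A <- max_latent %||% p
  if (method == "kernel") A <- min(A, n - 2)
  E2 <- matrix(NA_real_, n, A)   # squared held-out residuals per latent count
  ssy_i <- numeric(n)
  ctr_all <- colMeans(X)
  scl_all <- apply(X, 2, sd)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    if (scope == "train_fold") {
      ctr <- colMeans(Xtr)
      scl <- apply(Xtr, 2, sd)
    } else {
      ctr <- ctr_all
      scl <- scl_all
    }
    if (any(scl == 0)) {
      abort("Constant predictor column inside a training fold.",
            class = "uritox_degenerate_error")
    }
    Ztr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
    Zte <- matrix((X[i, ] - ctr) / scl, nrow = 1)
    ybar <- mean(ytr)
    ssy_i[i] <- (y[i] - ybar)^2
    if (method == "linear") {
      fit <- pls1_nipals(Ztr, ytr - ybar, A)
      if (fit$ncomp >= 1) {
        pred <- pls1_predict_all(fit, Zte) + ybar
        E2[i, seq_len(fit$ncomp)] <- (y[i] - pred)^2
      }
    } else {
      m <- n - 1
      K <- rbf_kernel(Ztr, Ztr, sigma)
      Jc <- diag(m) - matrix(1 / m, m, m)
      Kc <- Jc %*% K %*% Jc
      fit <- kpls1_core(Kc, ytr - ybar, A)
      if (fit$ncomp >= 1) {
        Kt <- rbf_kernel(Zte, Ztr, sigma)
        Ktc <- (Kt - matrix(1 / m, 1, m) %*% K) %*% Jc
        # predictions for each latent count via growing dual systems
        for (a in seq_len(fit$ncomp)) {
          Ta <- fit$T[, seq_len(a), drop = FALSE]
          Ua <- fit$U[, seq_len(a), drop = FALSE]
          dual <- Ua %*% solve(crossprod(Ta, Kc %*% Ua), crossprod(Ta, ytr - ybar))
          E2[i, a] <- (y[i] - (drop(Ktc %*% dual) + ybar))^2
        }
      }
    }
  }
  list(E2 = E2, ss_y = sum(ssy_i))
}

#' Leave-one-out cross-validated R-squared for one metal subset
#'
#' For each of the n folds the predictor statistics are refitted on the
#' training rows (no leakage), models with 1 up to `max_latent` components
#' are fitted, and the held-out row predicted. The number of latent
#' variables is then the one maximizing `R^2 = 1 - SS_e / SS_y` over the
#' candidates, where `SS_e` sums squared held-out residuals and `SS_y` sums
#' squared fold-centered responses. For the kernel method with `sigma =
#' NULL`, the Gaussian width is chosen from a grid of log-spaced multiples
#' of the median pairwise distance, maximizing the same criterion.
#'
#' @param data Data frame with metal columns and the response column (e.g.
#'   from [asd_regression_data()]).
#' @param response Name of the severity column.
#' @param metals Metal codes (predictor subset).
#' @param method `"linear"` or `"kernel"`.
#' @param sigma Gaussian kernel width; `NULL` selects from `sigma_mult`
#'   times the median pairwise distance (kernel method only).
#' @param sigma_mult Multiplier grid for width selection.
#' @param max_latent Cap on candidate latent counts; default the subset size.
#' @param scope `"train_fold"` (default) or `"combined"` predictor scaling.
#' @return One-row tibble: `response`, `metals` (slash-joined), `method`,
#'   `n_latent`, `sigma`, `r2_cv`, `r2_fit`, `ss_e`, `ss_y`, `n`.
#' @export
loo_r2 <- function(data, response, metals, method = c("linear", "kernel"),
                   sigma = NULL,
                   sigma_mult = exp(seq(log(0.25), log(10), length.out = 15)),
                   max_latent = NULL, scope = c("train_fold", "combined")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  X <- as.matrix(as.data.frame(data)[, metals, drop = FALSE])
  y <- data[[response]]
  if (nrow(X) < 3) abort("Need at least 3 rows.", class = "uritox_parameter_error")
  if (sd(y) == 0) {
    abort("Constant response.", class = "uritox_degenerate_error")
  }
  if (method == "kernel" && is.null(sigma)) {
    Zall <- scale(X)
    med <- median_pairwise_distance(Zall)
    cands <- purrr::map_dfr(sigma_mult * med, function(s) {
      loo_r2(data, response, metals, "kernel", sigma = s,
             max_latent = max_latent, scope = scope)
    })
    return(cands[which.max(cands$r2_cv), ])
  }
  pass <- loo_pass(X, y, method, sigma = sigma, scope = scope,
                   max_latent = max_latent)
  ss_e_by_a <- colSums(pass$E2)
  ok <- !is.na(ss_e_by_a)
  if (!any(ok)) abort("No component could be extracted in every fold.",
                      class = "uritox_rank_error")
  r2_by_a <- 1 - ss_e_by_a / pass$ss_y
  best_a <- which.max(replace(r2_by_a, !ok, -Inf))
  fit <- if (method == "linear") {
    fit_pls(X, y, n_latent = best_a)
  } else {
    fit_kpls(X, y, n_latent = best_a, sigma = sigma)
  }
  tibble::tibble(
    response = response, metals = paste(metals, collapse = "/"),
    method = method, n_latent = best_a,
    sigma = if (method == "kernel") sigma else NA_real_,
    r2_cv = r2_by_a[best_a], r2_fit = fit$r2_fit,
    ss_e = ss_e_by_a[best_a], ss_y = pass$ss_y, n = nrow(X)
  )
}

#' In-sample (no cross-validation) R-squared for one metal subset
#'
#' Fits models with 1..k latent components on all rows and reports the fit
#' R-squared at the fit-maximizing latent count. For the linear method at
#' full rank this equals the ordinary least squares R-squared.
#'
#' @inheritParams loo_r2
#' @return One-row tibble: `response`, `metals`, `method`, `n_latent`,
#'   `r2_fit`.
#' @export
fit_r2 <- function(data, response, metals, method = c("linear", "kernel"),
                   sigma = NULL) {
  method <- match.arg(method)
  X <- as.matrix(as.data.frame(data)[, metals, drop = FALSE])
  y <- data[[response]]
  A <- if (method == "linear") ncol(X) else min(ncol(X), nrow(X) - 2)
  fits <- purrr::map(seq_len(A), function(a) {
    tryCatch({
      if (method == "linear") fit_pls(X, y, a) else fit_kpls(X, y, a, sigma = sigma)
    }, error = function(e) NULL)
  })
  r2 <- vapply(fits, function(f) if (is.null(f)) -Inf else f$r2_fit, numeric(1))
  best <- which.max(r2)
  tibble::tibble(response = response, metals = paste(metals, collapse = "/"),
                 method = method, n_latent = best, r2_fit = r2[best])
}

#' Exhaustive metal-subset search under leave-one-out R-squared
#'
#' Enumerates every combination of `metals` of each requested size
#' (`sum(choose(length(metals), sizes))` models), evaluates each with
#' [loo_r2()], and keeps the best per size. Ties are broken toward the
#' lexicographically first combination (the enumeration order).
#'
#' @inheritParams loo_r2
#' @param sizes Subset sizes to enumerate (default `1:length(metals)`).
#' @param with_fit_r2 Also compute the no-cross-validation fit R-squared for
#'   each per-size winner (default `TRUE`).
#' @return Object of class `utm_subset_search`: list with `per_size` (tibble
#'   of per-size winners), `global_best` (row maximizing `r2_cv`),
#'   `n_evaluated` (per-size enumeration counts), `response`, `method`.
#' @export
subset_search <- function(data, response, metals, method = c("linear", "kernel"),
                          sizes = seq_along(metals), sigma = NULL,
                          sigma_mult = exp(seq(log(0.25), log(10), length.out = 15)),
                          scope = c("train_fold", "combined"),
                          with_fit_r2 = TRUE) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  per_size <- purrr::map_dfr(sizes, function(k) {
    combos <- combn(metals, k, simplify = FALSE)
    best <- NULL
    for (cm in combos) {
      res <- loo_r2(data, response, cm, method, sigma = sigma,
                    sigma_mult = sigma_mult, scope = scope)
      if (is.null(best) || res$r2_cv > best$r2_cv) best <- res
    }
    best$size <- k
    best$n_evaluated <- length(combos)
    if (with_fit_r2) {
      best$r2_fit_nocv <- fit_r2(data, response,
                                 strsplit(best$metals, "/")[[1]],
                                 method, sigma = best$sigma)$r2_fit
    }
    best
  })
  structure(list(
    per_size = per_size,
    global_best = per_size[which.max(per_size$r2_cv), ],
    n_evaluated = setNames(per_size$n_evaluated, per_size$size),
    response = response, method = method
  ), class = "utm_subset_search")
}

#' @export
print.utm_subset_search <- function(x, ...) {
  cat("<utm_subset_search> ", x$response, ", ", x$method, " method, ",
      sum(x$n_evaluated), " subsets evaluated\n", sep = "")
  print(x$per_size[, c("size", "metals", "n_latent", "r2_cv")])
  invisible(x)
}

#' One-at-a-time sensitivity profile of a fitted PLS/KPLS model
#'
#' Holds every predictor at its training mean and sweeps one metal at a
#' time over a grid spanning its training range, recording the model
#' prediction — a direct readout of the (non)linearity of each metal's
#' marginal response.
#'
#' @param model A fitted `utm_pls` or `utm_kpls`.
#' @param n_grid Grid points per metal.
#' @return Tibble with `metal`, `value` (raw concentration), `prediction`.
#' @export
sensitivity_profile <- function(model, n_grid = 50L) {
  base <- model$x_center
  purrr::map_dfr(model$metals, function(m) {
    grid <- seq(model$x_range[1, m], model$x_range[2, m], length.out = n_grid)
    newx <- matrix(base, n_grid, length(base), byrow = TRUE,
                   dimnames = list(NULL, model$metals))
    newx[, m] <- grid
    tibble::tibble(metal = m, value = grid,
                   prediction = predict(model, newx))
  })
}
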
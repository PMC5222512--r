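test_that("full-latent-count PLS equals ordinary least squares", {
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(20:40, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, utm_metals_all[1:p]))
    y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 0.5)
    fit <- fit_pls(X, y, n_latent = p)
    ols <- lm(y ~ X)
    expect_equal(unname(fit$coefficients), unname(coef(ols)[-1]), tolerance = 1e-8)
    expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  }
})

test_that("exact linear responses are fitted perfectly", {
  set.seed(52)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("Cs", "Sn")))
  y <- 2 * X[, 1] - X[, 2] + 5
  expect_equal(fit_pls(X, y, 2)$r2_fit, 1, tolerance = 1e-12)
})

test_that("first PLS direction matches the brute-force eigen oracle", {
  set.seed(53)
  X <- scale(matrix(rnorm(25), 5, 5))[, 1:2]
  colnames(X) <- c("Cs", "Hg")
  y <- rnorm(5); y <- y - mean(y)
  fit <- fit_pls(X, y, 1, scale = FALSE)
  M <- crossprod(X, y) %*% crossprod(y, X)   # X' y y' X
  ev <- eigen(M)$vectors[, 1]
  w <- fit$weights[, 1]
  expect_equal(abs(sum(w * ev)), 1, tolerance = 1e-8)
})

test_that("linear-kernel KPLS reproduces linear PLS for every latent count", {
  set.seed(54)
  for (rep in 1:4) {
    n <- 25; p <- 3
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, c("Cs", "Pb", "Sn")))
    y <- drop(tanh(X %*% rnorm(p))) + rnorm(n, sd = 0.2)
    Xnew <- matrix(rnorm(10 * p), 10, p, dimnames = list(NULL, colnames(X)))
    for (a in 1:p) {
      fp <- fit_pls(X, y, a)
      fk <- fit_kpls(X, y, a, kernel = "linear")
      expect_equal(fk$fitted, fp$fitted, tolerance = 1e-6)
      expect_equal(predict(fk, Xnew), predict(fp, Xnew), tolerance = 1e-6)
    }
  }
})

test_that("Gaussian KPLS captures a saturating response that linear PLS cannot", {
  set.seed(55)
  X <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "Sn"))
  y <- tanh(2.5 * X[, 1])
  expect_gt(fit_kpls(X, y, 5, sigma = 1)$r2_fit, 0.99)
  expect_lt(fit_pls(X, y, 1)$r2_fit, 0.9)
})

test_that("training residuals are orthogonal to extracted scores", {
  set.seed(56)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, utm_metals_all[1:4]))
  y <- drop(X %*% c(1, 2, 0, -1)) + rnorm(40)
  for (a in 1:3) {
    fit <- fit_pls(X, y, a)
    expect_lt(max(abs(crossprod(fit$scores, fit$residuals))), 1e-8)
  }
})

test_that("LOO harness equals an explicit brute-force refit oracle", {
  set.seed(57)
  n <- 10
  X <- matrix(exp(rnorm(n * 3)), n, 3, dimnames = list(NULL, c("Cs", "Pb", "Sn")))
  y <- drop(scale(X) %*% c(1, -1, 0.5)) + rnorm(n, sd = 0.5)
  d <- dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(ABC_total = y))

  oracle <- function(method, sigma = NULL) {
    A <- if (method == "linear") 3 else min(3, n - 2)
    E2 <- matrix(NA_real_, n, A); ssy <- 0
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      ssy <- ssy + (y[i] - mean(y[tr]))^2
      for (a in seq_len(A)) {
        f <- if (method == "linear") {
          fit_pls(X[tr, ], y[tr], a)
        } else {
          fit_kpls(X[tr, ], y[tr], a, sigma = sigma)
        }
        E2[i, a] <- (y[i] - predict(f, X[i, , drop = FALSE]))^2
      }
    }
    r2 <- 1 - colSums(E2) / ssy
    list(best = max(r2), a = which.max(r2))
  }

  lin <- loo_r2(d, "ABC_total", c("Cs", "Pb", "Sn"), "linear")
  orl <- oracle("linear")
  expect_equal(lin$r2_cv, orl$best, tolerance = 1e-10)
  expect_equal(lin$n_latent, orl$a)

  ker <- loo_r2(d, "ABC_total", c("Cs", "Pb", "Sn"), "kernel", sigma = 2)
  ork <- oracle("kernel", sigma = 2)
  expect_equal(ker$r2_cv, ork$best, tolerance = 1e-10)
  expect_equal(ker$n_latent, ork$a)
})

test_that("LOO R2 is non-positive for most independent responses", {
  r2 <- sapply(1:20, function(s) {
    set.seed(700 + s)
    X <- matrix(exp(rnorm(30 * 3)), 30, 3,
                dimnames = list(NULL, c("Cs", "Pb", "Sn")))
    d <- dplyr::bind_cols(tibble::as_tibble(X),
                          tibble::tibble(ABC_total = rnorm(30)))
    loo_r2(d, "ABC_total", c("Cs", "Pb", "Sn"), "linear")$r2_cv
  })
  expect_lte(median(r2), 0)
  expect_gte(mean(r2 <= 0), 0.7)
})

test_that("subset search enumerates completely and beats random subsets", {
  set.seed(58)
  metals <- c("Al", "Cs", "Hg", "Pb", "Sn")
  X <- matrix(exp(rnorm(25 * 5)), 25, 5, dimnames = list(NULL, metals))
  y <- drop(scale(X)[, c("Cs", "Sn")] %*% c(1, 1)) + rnorm(25, sd = 0.4)
  d <- dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(ABC_total = y))
  ss <- subset_search(d, "ABC_total", metals, "linear", sizes = 1:4,
                      with_fit_r2 = FALSE)
  expect_equal(unname(ss$n_evaluated), choose(5, 1:4))
  for (k in 2:3) {
    best_k <- ss$per_size$r2_cv[ss$per_size$size == k]
    for (rep in 1:5) {
      sub <- sort(sample(metals, k))
      expect_gte(best_k + 1e-12,
                 loo_r2(d, "ABC_total", sub, "linear")$r2_cv)
    }
  }
})

test_that("subset search recovers the driving metals in low-noise data", {
  hits <- sapply(1:10, function(s) {
    dat <- generate_cohort(small_synth_config(noise_sd = 0.1, seed = 800 + s))
    d <- asd_regression_data(dat$cohort, dat$severity)
    ss <- subset_search(d, "ABC_total", c("Cd", "Cs", "Sn"), "linear",
                        sizes = 2, with_fit_r2 = FALSE)
    ss$per_size$metals[1] == "Cs/Sn"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("noise-free linear-link data is recovered exactly by full-rank PLS", {
  dat <- generate_cohort(small_synth_config(link = "linear", noise_sd = 0))
  d <- asd_regression_data(dat$cohort, dat$severity)
  # severity is rounded to 0.1 at generation; refit tolerance reflects that
  fit <- fit_pls(d[, c("Cd", "Cs", "Sn")], d$ABC_total, 3)
  expect_gt(fit$r2_fit, 0.999)
  expect_lt(abs(fit$coefficients["Cd"]) /
              max(abs(fit$coefficients[c("Cs", "Sn")])), 0.02)
})

test_that("fit_r2 reports the no-cross-validation ceiling", {
  set.seed(59)
  X <- matrix(exp(rnorm(30 * 3)), 30, 3, dimnames = list(NULL, c("Cs", "Pb", "Sn")))
  y <- drop(scale(X) %*% c(1, 0.5, -0.5)) + rnorm(30, sd = 0.3)
  d <- dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(ABC_total = y))
  fr <- fit_r2(d, "ABC_total", c("Cs", "Pb", "Sn"), "linear")
  ols <- summary(lm(y ~ scale(X)))$r.squared
  expect_equal(fr$r2_fit, ols, tolerance = 1e-8)
  # nesting monotonicity: adding a predictor cannot reduce fit R2
  fr2 <- fit_r2(d, "ABC_total", c("Cs", "Pb"), "linear")
  expect_gte(fr$r2_fit + 1e-12, fr2$r2_fit)
})

test_that("sensitivity profiles are straight for linear fits and curved for kernel fits", {
  set.seed(60)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("Cs", "Sn")))
  y_lin <- 3 * X[, 1] + 0 * X[, 2] + 7
  fit <- fit_pls(X, y_lin, 2)
  prof <- sensitivity_profile(fit, n_grid = 20)
  cs <- prof[prof$metal == "Cs", ]
  slopes <- diff(cs$prediction) / diff(cs$value)
  expect_equal(slopes, rep(fit$coefficients[["Cs"]], 19), tolerance = 1e-8)
  # zero-coefficient metal -> flat curve
  sn <- prof[prof$metal == "Sn", ]
  expect_lt(diff(range(sn$prediction)), 1e-6)
  # kernel fit on a saturating response shows curvature
  y_nl <- tanh(2 * X[, 1])
  kfit <- fit_kpls(X, y_nl, 2, sigma = 1)
  kprof <- sensitivity_profile(kfit, n_grid = 20)
  kcs <- kprof[kprof$metal == "Cs", ]
  expect_gt(max(abs(diff(diff(kcs$prediction)))), 1e-3)
})
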
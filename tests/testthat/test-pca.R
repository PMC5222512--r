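make_severity <- function(x, names_) {
  colnames(x) <- names_
  structure(dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("a%03d", seq_len(nrow(x)))),
    tibble::as_tibble(x)),
    class = c("utm_severity", class(tibble::tibble())))
}

test_that("two perfectly correlated measures give a single component", {
  set.seed(71)
  base <- rnorm(30)
  sev <- make_severity(cbind(base, 2 * base + 3), c("ABC_total", "ATEC_total"))
  pc <- fit_pca(sev, c("ABC_total", "ATEC_total"))
  expect_equal(pc$explained_variance_ratio, c(1, 0), tolerance = 1e-12)
  expect_equal(sum(pc$explained_variance_ratio), 1)
})

test_that("the eigenvalue spectrum is invariant to orthogonal rotation of the inputs", {
  set.seed(72)
  x <- matrix(rnorm(40 * 4), 40, 4) %*% diag(c(3, 2, 1, 0.5))
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  pc1 <- fit_pca(make_severity(scale(x), utm_measures_core[1:4]),
                 utm_measures_core[1:4])
  # rotate *after* standardization so the correlation structure is conjugated
  z <- scale(x)
  pc3 <- fit_pca(make_severity(z %*% Q, utm_measures_core[1:4]),
                 utm_measures_core[1:4])
  ev1 <- eigen(stats::cor(z), only.values = TRUE)$values
  ev3 <- eigen(stats::cor(scale(z %*% Q)), only.values = TRUE)$values
  expect_equal(pc1$explained_variance_ratio, ev1 / sum(ev1), tolerance = 1e-10)
  expect_equal(pc3$explained_variance_ratio, ev3 / sum(ev3), tolerance = 1e-10)
})

test_that("loadings are orthonormal with deterministic signs and reconstruct the data", {
  dat <- generate_cohort(reference_config(seed = 14))
  pc <- fit_pca(dat$severity)
  L <- pc$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(L))) {
    expect_gt(L[which.max(abs(L[, j])), j], 0)
  }
  expect_true(all(diff(pc$explained_variance_ratio) <= 1e-12))
  expect_equal(sum(pc$explained_variance_ratio), 1, tolerance = 1e-12)
  # reconstruction from all components reproduces the standardized inputs
  x <- as.matrix(as.data.frame(dat$severity)[, pc$measures])
  z <- scale(x, center = pc$center, scale = pc$scale)
  expect_equal(pc$scores %*% t(L), z, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("planted two-factor structure is recovered by measure clustering", {
  set.seed(73)
  n <- 60
  fa <- rnorm(n); fb <- rnorm(n)
  x <- cbind(sapply(1:4, function(i) fa + rnorm(n, sd = 0.4)),
             sapply(1:4, function(i) fb + rnorm(n, sd = 0.4)))
  sev <- make_severity(x, utm_measures_core[1:8])
  cl <- cluster_measures(fit_pca(sev, utm_measures_core[1:8]))
  expect_equal(length(unique(cl$cluster[1:4])), 1)
  expect_equal(length(unique(cl$cluster[5:8])), 1)
  expect_false(cl$cluster[1] == cl$cluster[5])
  expect_false(any(cl$is_outlier))
})

test_that("cluster assignment is invariant to measure column order", {
  dat <- generate_cohort(reference_config(seed = 15))
  meas <- intersect(utm_measures_core, names(dat$severity))
  cl1 <- cluster_measures(fit_pca(dat$severity, meas))
  set.seed(74)
  perm <- sample(meas)
  cl2 <- cluster_measures(fit_pca(dat$severity, perm))
  merged <- dplyr::inner_join(cl1, cl2, by = "measure")
  expect_identical(merged$cluster.x, merged$cluster.y)
  expect_identical(merged$is_outlier.x, merged$is_outlier.y)
})

test_that("degenerate inputs raise informative errors; singletons are outliers", {
  sev <- make_severity(cbind(rep(1, 10), rnorm(10)), c("ABC_total", "SRS"))
  expect_error(fit_pca(sev, c("ABC_total", "SRS")),
               class = "uritox_degenerate_error", regexp = "ABC_total")
  # single measure: one singleton cluster
  fake <- structure(list(loadings = matrix(1, 1, 1, dimnames = list("SSP", "PC1"))),
                    class = "utm_pca")
  cl <- cluster_measures(fake)
  expect_equal(cl$cluster, 1L)
  expect_false(cl$is_outlier)
})
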
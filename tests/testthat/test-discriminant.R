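std_from_matrix <- function(x, groups, metals) {
  co <- new_cohort(dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("p%03d", seq_len(nrow(x))),
                   group = groups),
    tibble::as_tibble(`colnames<-`(x, metals))), metals = metals)
  standardize_panel(co)
}

test_that("FDA direction equals the closed form Sw^-1 dmu on random instances", {
  set.seed(41)
  for (rep in 1:12) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1); d <- sample(2:4, 1)
    metals <- utm_metals_all[seq_len(d)]
    x <- matrix(rnorm((n1 + n2) * d), n1 + n2, d)
    x[seq_len(n1), 1] <- x[seq_len(n1), 1] + 2
    g <- c(rep("ASD", n1), rep("NT", n2))
    std <- std_from_matrix(x, g, metals)
    model <- fit_fda(std)
    z <- as.matrix(std$z[, metals])
    z1 <- z[g == "ASD", , drop = FALSE]; z2 <- z[g == "NT", , drop = FALSE]
    sw <- crossprod(sweep(z1, 2, colMeans(z1))) + crossprod(sweep(z2, 2, colMeans(z2)))
    w_oracle <- solve(sw, colMeans(z1) - colMeans(z2))
    w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    if (sum(w_oracle * model$direction) < 0) w_oracle <- -w_oracle
    expect_equal(unname(model$direction), unname(w_oracle), tolerance = 1e-8)
  }
})

test_that("axis-aligned separation yields an axis-aligned direction", {
  set.seed(42)
  x <- matrix(rnorm(200 * 3, sd = 0.5), 200, 3)
  x[1:100, 1] <- x[1:100, 1] + 5
  std <- std_from_matrix(x, rep(c("ASD", "NT"), each = 100), c("Pb", "Sn", "Tl"))
  model <- fit_fda(std)
  expect_gt(abs(model$direction["Pb"]), 0.99)
  expect_gt(mean(model$training_scores_asd), mean(model$training_scores_nt))
})

test_that("identical groups give near-zero separation on the raw projection", {
  set.seed(43)
  x <- matrix(rnorm(60 * 2), 60, 2)
  std <- std_from_matrix(x, rep(c("ASD", "NT"), 30), c("Cs", "Pb"))
  model <- fit_fda(std)
  # raw (un-normalized) group mean gap is tiny relative to score spread
  gap <- abs(model$score_halfwidth)
  expect_lt(gap, 0.5 * sd(c(model$training_scores_asd * gap,
                            model$training_scores_nt * gap)))
})

test_that("KFDA solves the ring problem that defeats linear FDA", {
  co <- ring_cohort(n_per = 40)
  fda_tr <- error_tradeoff_loo(co, "fda", metals = c("Cs", "Pb"))
  kfda_tr <- error_tradeoff_loo(co, "kfda", metals = c("Cs", "Pb"),
                                sigma = 1, lambda = 1e-2)
  t2_at <- function(tr, a) {
    tr$fixed_grid$type_ii[tr$fixed_grid$type_i_allowed == a]
  }
  expect_lt(t2_at(kfda_tr, 0.20), 0.10)
  expect_gt(t2_at(fda_tr, 0.20), 0.50)
  # KFDA dominates linear FDA across the whole grid on this geometry
  expect_true(all(kfda_tr$fixed_grid$type_ii <= fda_tr$fixed_grid$type_ii))
})

test_that("large-width KFDA scores converge to linear FDA scores", {
  set.seed(44)
  x <- matrix(rnorm(50 * 2), 50, 2)
  x[1:25, ] <- x[1:25, ] + 1.5
  std <- std_from_matrix(x, rep(c("ASD", "NT"), each = 25), c("Cs", "Pb"))
  lin <- fit_fda(std)
  kf <- fit_kfda(std, sigma = 100, lambda = 1e-6)
  sc_l <- c(lin$training_scores_asd, lin$training_scores_nt)
  sc_k <- c(kf$training_scores_asd, kf$training_scores_nt)
  expect_gt(cor(sc_l, sc_k), 0.999)
})

test_that("one training sample per class puts the boundary midway", {
  co <- new_cohort(tibble::tibble(
    participant_id = c("a", "n"), group = c("ASD", "NT"),
    Cs = c(4, 2), Cs_censored = FALSE, Pb = c(4, 2), Pb_censored = FALSE))
  std <- standardize_panel(co)
  model <- fit_kfda(std, sigma = 1, lambda = 1e-3, densities = FALSE)
  # normalized scores put the class points at +1 / -1; the midpoint scores 0
  mid <- panel_matrix(co)[1, , drop = FALSE] * 0 + 3
  expect_equal(unname(discriminant_score(model, mid)), 0, tolerance = 1e-8)
})

test_that("classification respects the threshold and tie rule", {
  dat <- generate_cohort(reference_config(seed = 13))
  co <- dat$cohort
  std <- standardize_panel(co, utm_metals_modeling)
  model <- fit_fda(std, densities = FALSE)
  x_mean_asd <- matrix(colMeans(panel_matrix(co, utm_metals_modeling)[co$group == "ASD", ]),
                       nrow = 1, dimnames = list(NULL, utm_metals_modeling))
  thr_nt_median <- median(model$training_scores_nt)
  expect_equal(classify(model, x_mean_asd, thr_nt_median), "ASD")
  expect_true(all(classify(model, panel_matrix(co, utm_metals_modeling), Inf) == "NT"))
  # tie goes to NT
  s <- discriminant_score(model, x_mean_asd)
  expect_equal(classify(model, x_mean_asd, threshold = s), "NT")
})

test_that("held-out scores equal brute-force refit and reprojection", {
  cfg <- small_synth_config(n_asd = 12, n_nt = 10)
  co <- generate_cohort(cfg)$cohort
  metals <- cohort_metals(co)
  sc <- loo_scores(co, "fda", metals)
  for (i in seq_len(nrow(co))) {
    train <- setdiff(seq_len(nrow(co)), i)
    std <- standardize_panel(co, metals, fit_rows = train)
    std$z <- std$z[train, , drop = FALSE]
    m <- fit_fda(std, densities = FALSE)
    expect_equal(sc$score[i],
                 unname(discriminant_score(m, panel_matrix(co, metals)[i, , drop = FALSE])),
                 tolerance = 1e-10)
  }
})

test_that("tradeoff Type I is exactly the empirical NT exceedance rate", {
  set.seed(45)
  scores <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:40),
    group = rep(c("ASD", "NT"), each = 20),
    score = c(rnorm(20, 1), rnorm(20, -1)))
  tr <- uritox:::tradeoff_from_scores(scores, c(0.4, 0.2, 0.1))
  nt <- scores$score[scores$group == "NT"]
  for (j in seq_len(nrow(tr$points))) {
    expect_equal(tr$points$type_i[j], mean(nt > tr$points$threshold[j]))
  }
  # fixed grid: achieved Type I never exceeds the allowance, Type II
  # non-increasing as the allowance grows
  expect_true(all(tr$fixed_grid$type_i <= tr$fixed_grid$type_i_allowed + 1e-12))
  expect_true(all(diff(tr$fixed_grid$type_ii) >= -1e-12))  # grid stored decreasing
})
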
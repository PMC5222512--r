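# Shared fixtures, all generated in code.

# Tiny two-group cohort with fixed concentrations (no censoring).
tiny_cohort <- function() {
  new_cohort(tibble::tibble(
    participant_id = c("a1", "a2", "a3", "n1", "n2", "n3"),
    group = c("ASD", "ASD", "ASD", "NT", "NT", "NT"),
    Cs = c(1, 2, 3, 2, 3, 4), Cs_censored = FALSE,
    Pb = c(0.5, 0.7, 0.9, 0.2, 0.3, 0.4), Pb_censored = FALSE
  ), detection_limits = c(Cs = 0.1, Pb = 0.05))
}

# Two concentric rings (linearly inseparable classes) as a cohort.
ring_cohort <- function(n_per = 40, seed = 42) {
  set.seed(seed)
  th <- runif(2 * n_per, 0, 2 * pi)
  r <- c(rep(1, n_per), rep(3, n_per)) + rnorm(2 * n_per, sd = 0.1)
  # shifted positive so values look like concentrations
  new_cohort(tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(2 * n_per)),
    group = rep(c("ASD", "NT"), each = n_per),
    Cs = r * cos(th) + 5, Cs_censored = FALSE,
    Pb = r * sin(th) + 5, Pb_censored = FALSE
  ))
}

# Small 3-metal synthetic configuration; severity driven only by Cs and Sn.
small_synth_config <- function(link = "linear", noise_sd = 0.1,
                               group_shift = c(Cd = 1, Cs = 1.5, Sn = 2),
                               n_asd = 40, n_nt = 30, seed = 1) {
  links <- tibble::tibble(
    measure = "ABC_total", metals = list(c("Cs", "Sn")),
    coefs = list(c(1, 1)), link = link, amp = 1, gain = 2, u_load = 0,
    factor = "none", factor_load = 0, noise_sd = noise_sd,
    center = 50, scale = 10
  )
  synthetic_config(
    n_asd = n_asd, n_nt = n_nt,
    log_median = c(Cd = 0, Cs = 1, Sn = -0.5),
    log_sigma = c(Cd = 0.5, Cs = 0.5, Sn = 0.7),
    log_corr = 0.2, group_shift = group_shift,
    detection_limits = numeric(), severity_links = links, seed = seed
  )
}

# Reference configuration with the group contrast switched off.
null_config <- function(seed = 1) {
  cfg <- reference_config(seed = seed)
  cfg$group_shift[] <- 1
  cfg
}

random_panel_frame <- function(n, metals, seed) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n * length(metals))), n, length(metals),
              dimnames = list(NULL, metals))
  tibble::as_tibble(x)
}
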
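# Independent oracles and shared fixtures for the test suite.

# Matrix-exponential solution of the constant-rate, zero-supply pool system:
# state (c_sol, c_sta, c_str), rates per day, t in days.
pools_closed_form <- function(init, k3, k5m, k5, t_days) {
  A <- matrix(c(-(k3 + k5m), k5, 0,
                k5m, -k5, 0,
                k3, 0, 0), nrow = 3, byrow = TRUE)
  eg <- eigen(A)
  y <- Re(eg$vectors %*% diag(exp(eg$values * t_days)) %*%
            solve(eg$vectors) %*% init)
  stats::setNames(as.numeric(y), c("c_sol", "c_sta", "c_str"))
}

# Brute-force ANOVA by explicit orthogonal projection: builds the full-rank
# dummy model matrix term by term and measures the squared norm of each
# term's incremental projection. Independent of stats::aov.
projection_anova <- function(data, response, factors) {
  data <- as.data.frame(data)
  for (f in factors) data[[f]] <- factor(data[[f]])
  y <- data[[response]]
  term_labels <- unlist(lapply(seq_along(factors), function(k)
    combn(factors, k, FUN = paste, collapse = ":")))
  fitted_prev <- rep(mean(y), length(y))
  rank_prev <- 1L
  out <- NULL
  for (i in seq_along(term_labels)) {
    fml <- stats::as.formula(
      paste("~", paste(term_labels[seq_len(i)], collapse = "+")))
    qr_mm <- qr(stats::model.matrix(fml, data = data))
    fitted_now <- qr.fitted(qr_mm, y)
    out <- rbind(out, data.frame(term = term_labels[i],
                                 df = qr_mm$rank - rank_prev,
                                 sumsq = sum((fitted_now - fitted_prev)^2)))
    fitted_prev <- fitted_now
    rank_prev <- qr_mm$rank
  }
  resid_ss <- sum((y - fitted_prev)^2)
  resid_df <- length(y) - rank_prev
  out$meansq <- out$sumsq / out$df
  out$statistic <- out$meansq / (resid_ss / resid_df)
  out
}

# Treatment-mean carbon fractions (% of total fruit carbon) reported for the
# motivating glasshouse experiment; used only to check internal consistency
# (each row's three fractions sum to 100).
reported_fraction_means <- function() {
  tibble::tibble(
    period = c(rep("all_stages", 8), rep("maturation", 6)),
    level = c("T1", "T2", "T3", "CK", "K0", "K1", "StageII", "StageIII",
              "T1", "T2", "T3", "CK", "K0", "K1"),
    c_sta = c(5.370, 4.923, 4.979, 4.314, 4.646, 4.253, 6.841, 3.015,
              3.001, 3.336, 2.934, 2.336, 2.901, 2.757),
    c_sol = c(29.216, 30.065, 29.728, 28.175, 29.296, 31.463, 21.772, 35.544,
              35.431, 36.742, 35.738, 33.407, 35.330, 38.280),
    c_str = c(65.415, 65.012, 65.294, 67.511, 66.058, 64.284, 71.387, 61.441,
              61.568, 59.922, 61.329, 64.257, 61.769, 58.964))
}

# Small zero-supply simulation fixture shared by integrator tests.
static_growth <- function(to = 10) tibble::tibble(daa = c(0, to), dw = 0, ddw_dt = 0)
static_env <- function(to = 10, temp = 20) tibble::tibble(time_h = c(0, to * 24), temp = temp)

# Control-treatment synthetic pools for one seed (observations -> carbon).
control_pools <- function(seed, config = generator_config()) {
  truth <- generate_allocation("CK", "K0", config)
  obs <- sample_observations(truth, "CK", "K0", config, seed = seed)
  pools_from_observations(obs, config$sugar_cf, config$starch_cf)
}
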
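test_that("pools stay constant with no fluxes and no growth", {
  rates <- tibble::tibble(daa = c(0, 10), k3 = 0, k5m = 0)
  const <- sugar_constants(k5 = 1e-12) # starch conversion off
  sim <- simulate_carbon(c(c_sol = 0.2, c_sta = 0.1, c_str = 0.4),
                         static_growth(), static_env(), rates, const)
  expect_equal(max(abs(sim$c_sol - 0.2)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sim$c_sta - 0.1)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sim$c_str - 0.4)), 0, tolerance = 1e-10)
})

test_that("with only starch breakdown active, starch decays exponentially into sugar", {
  rates <- tibble::tibble(daa = c(0, 10), k3 = 0, k5m = 0)
  const <- sugar_constants()
  init <- c(c_sol = 0.05, c_sta = 0.3, c_str = 0.2)
  sim <- simulate_carbon(init, static_growth(), static_env(), rates, const,
                         step_h = 0.01)
  last <- sim[nrow(sim), ]
  expect_equal(last$c_sta, 0.3 * exp(-const$k5 * 10), tolerance = 1e-9)
  expect_equal(last$c_sol, 0.05 + 0.3 * (1 - exp(-const$k5 * 10)),
               tolerance = 1e-9)
  expect_equal(last$c_str, 0.2)
})

test_that("constant-rate zero-supply simulations match the matrix-exponential solution", {
  k3 <- 0.2; k5m <- 0.15
  const <- sugar_constants()
  init <- c(c_sol = 0.3, c_sta = 0.2, c_str = 0.5)
  rates <- tibble::tibble(daa = c(0, 10), k3 = k3, k5m = k5m)
  sim <- simulate_carbon(init, static_growth(), static_env(), rates, const,
                         step_h = 0.01)
  truth <- pools_closed_form(init, k3, k5m, const$k5, 10)
  got <- unlist(sim[nrow(sim), c("c_sol", "c_sta", "c_str")])
  expect_lt(max(abs(got - truth) / abs(truth)), 1e-6)
})

test_that("carbon is conserved: pool gain equals supply minus respiration", {
  config <- generator_config()
  growth <- generate_growth("CK", "K0", config)
  env <- generate_temperature(config)
  truth <- generate_allocation("CK", "K0", config)
  rates <- tibble::tibble(daa = truth$daa, k3 = truth$k3, k5m = truth$k5m)
  init <- c(c_sol = truth$c_sol[1], c_sta = truth$c_sta[1],
            c_str = truth$c_str[1])
  defect <- function(step_h) {
    sim <- simulate_carbon(init, growth, env, rates, from = 34, to = 73,
                           step_h = step_h)
    last <- sim[nrow(sim), ]
    abs((last$c_sol + last$c_sta + last$c_str - sum(init)) -
          (last$c_sup - last$c_rep))
  }
  d1 <- defect(1)
  d05 <- defect(0.5)
  expect_lt(d1, 1e-10)
  # halving the step does not worsen the defect beyond the roundoff floor
  expect_lt(d05, max(d1, 1e-12) * 2)
})

test_that("no pool goes negative and undershoots are clipped with a warning", {
  # with partial phloem import (k0 < 1) maintenance respiration of a heavy
  # fruit drains a near-empty soluble pool below zero within one step
  rates <- tibble::tibble(daa = c(0, 10), k3 = 0, k5m = 0)
  const <- sugar_constants(k0 = 0.5, k5 = 1e-12)
  heavy <- tibble::tibble(daa = c(0, 10), dw = 10, ddw_dt = 0)
  expect_warning(
    sim <- simulate_carbon(c(c_sol = 1e-4, c_sta = 0, c_str = 0),
                           heavy, static_env(temp = 30), rates, const,
                           step_h = 1),
    "clipped")
  expect_true(all(sim$c_sol >= 0))
  expect_true(all(sim$c_sta >= 0))
  expect_true(all(sim$c_str >= 0))

  # benign simulations emit no warning and stay non-negative
  config <- generator_config()
  truth <- generate_allocation("CK", "K0", config)
  expect_no_warning(
    sim2 <- simulate_carbon(
      c(c_sol = truth$c_sol[1], c_sta = truth$c_sta[1], c_str = truth$c_str[1]),
      generate_growth("CK", "K0", config), generate_temperature(config),
      tibble::tibble(daa = truth$daa, k3 = truth$k3, k5m = truth$k5m)))
  expect_true(all(sim2$c_sol >= 0))
})

test_that("insufficient grid coverage raises a configuration error", {
  rates <- tibble::tibble(daa = c(0, 10), k3 = 0, k5m = 0)
  short_growth <- tibble::tibble(daa = c(0, 5), dw = 0, ddw_dt = 0)
  expect_error(
    simulate_carbon(c(c_sol = 1, c_sta = 0, c_str = 0),
                    short_growth, static_env(), rates),
    "does not cover")
})

test_that("carbon fractions are percentages of the pool sum", {
  x <- tibble::tibble(c_sol = 1, c_sta = 1, c_str = 2)
  fr <- carbon_fractions(x)
  expect_equal(c(fr$frac_sol, fr$frac_sta, fr$frac_str), c(25, 25, 50))
  sim <- simulate_carbon(c(c_sol = 0.3, c_sta = 0.2, c_str = 0.5),
                         static_growth(), static_env(),
                         tibble::tibble(daa = c(0, 10), k3 = 0.1, k5m = 0.1))
  expect_equal(sim$frac_sol + sim$frac_sta + sim$frac_str,
               rep(100, nrow(sim)))
})

test_that("simulation CSV writer emits the documented column contract", {
  sim <- simulate_carbon(c(c_sol = 0.3, c_sta = 0.2, c_str = 0.5),
                         static_growth(), static_env(),
                         tibble::tibble(daa = c(0, 10), k3 = 0.1, k5m = 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim, path)
  got <- utils::read.csv(path)
  expect_identical(names(got),
                   c("time_h", "DAA", "C_sol_g", "C_sta_g", "C_str_g",
                     "C_rep_g", "C_sup_g", "frac_sol", "frac_sta", "frac_str"))
  expect_equal(nrow(got), nrow(sim))
})
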
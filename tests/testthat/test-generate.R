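test_that("the generator is deterministic in the seed and stable to added treatments", {
  a <- generate_dataset(seed = 4)
  b <- generate_dataset(seed = 4)
  expect_identical(a$observations, b$observations)
  c <- generate_dataset(seed = 5)
  expect_false(identical(a$observations$fw, c$observations$fw))

  # per-treatment streams: a treatment's draws do not depend on the others
  cfg <- generator_config()
  truth <- generate_allocation("T2", "K0", cfg)
  solo <- sample_observations(truth, "T2", "K0", cfg, seed = 4)
  joint <- dplyr::filter(a$observations, treatment == "T2")
  expect_equal(solo$fw, joint$fw)
})

test_that("growth curves respect treatment orderings and monotonicity", {
  cfg <- generator_config()
  ck <- generate_growth("CK", "K0", cfg)
  t2 <- generate_growth("T2", "K0", cfg)
  at73 <- function(g) g$fw[which.min(abs(g$daa - 73))]
  expect_gt(at73(ck), at73(t2))
  expect_true(all(diff(ck$dw) >= 0))
  expect_true(all(ck$dw >= 0 & ck$fw >= 0))
  expect_true(all(ck$fw > ck$dw))

  # neutral multipliers give identical curves
  cfg_flat <- generator_config(fw_water = c(CK = 1, T1 = 1, T2 = 1, T3 = 1),
                               dw_water = c(CK = 1, T1 = 1, T2 = 1, T3 = 1),
                               fw_k = 1, dw_k = 1)
  g1 <- generate_growth("CK", "K0", cfg_flat)
  g2 <- generate_growth("T1", "K1", cfg_flat)
  expect_identical(g1, g2)
})

test_that("allocation trajectories hit the configured fraction endpoints", {
  tr <- generate_allocation("CK", "K0")
  first <- tr[1, ]; last <- tr[nrow(tr), ]
  expect_equal(first$frac_sta, 16, tolerance = 1e-8)
  expect_equal(first$frac_str, 75, tolerance = 1e-8)
  expect_equal(last$frac_sol, 45, tolerance = 1e-8)
  expect_equal(last$frac_sta, 2, tolerance = 1e-8)
  expect_equal(tr$frac_sol + tr$frac_sta + tr$frac_str, rep(100, nrow(tr)))
  # monotone directions: soluble rises, starch falls (post-peak window),
  # structural falls
  expect_true(all(diff(tr$frac_sol) > 0))
  expect_true(all(diff(tr$frac_sta) < 0))
  expect_true(all(diff(tr$frac_str) < 0))
  # implied rates are non-negative and vanish by the last age
  expect_true(all(tr$k3 >= 0))
  expect_true(all(tr$k5m >= 0))
  expect_lt(tr$k3[nrow(tr)], 0.02 * max(tr$k3))
  expect_lt(tr$k5m[nrow(tr)], 0.05 * max(tr$k5m))
})

test_that("noiseless sampling lies exactly on the true curves", {
  cfg0 <- generator_config(noise_cv = 0)
  truth <- generate_allocation("CK", "K0", cfg0)
  obs <- sample_observations(truth, "CK", "K0", cfg0, seed = 1)
  at <- vapply(cfg0$sampling_daa, function(d) which.min(abs(truth$daa - d)), 1L)
  expect_equal(obs$fw[obs$replicate == 1], truth$fw[at], tolerance = 1e-12)
  expect_equal(obs$dw[obs$replicate == 2], truth$dw[at], tolerance = 1e-12)
})

test_that("multiplicative noise has the configured coefficient of variation", {
  cfg <- generator_config()
  truth <- generate_allocation("CK", "K0", cfg)
  cvs <- unlist(lapply(1:50, function(s) {
    obs <- sample_observations(truth, "CK", "K0", cfg, seed = s)
    stats <- dplyr::summarise(dplyr::group_by(obs, daa),
                              cv = stats::sd(fw) / mean(fw))
    stats$cv
  }))
  # per-cell sample CV (n = 3) concentrates in [1%, 15%] around the 5% target
  expect_gt(mean(cvs >= 0.01 & cvs <= 0.15), 0.9)
  expect_equal(median(cvs), 0.05, tolerance = 0.4)
})

test_that("generated effect directions reproduce the reported contrast pattern", {
  synth <- generate_dataset(seed = 1)
  obs <- pools_from_observations(synth$observations)
  by_water <- dplyr::summarise(dplyr::group_by(obs, water),
                               ssc = mean(ssc), fw = mean(fw),
                               c_str = mean(100 * c_str / c_total))
  ck <- by_water[by_water$water == "CK", ]
  deficit <- by_water[by_water$water != "CK", ]
  expect_true(all(deficit$ssc > ck$ssc))
  expect_true(all(deficit$fw < ck$fw))
  expect_true(all(deficit$c_str < ck$c_str))

  by_k <- dplyr::summarise(dplyr::group_by(obs, potassium),
                           dw = mean(dw), ssc = mean(ssc), c_sol = mean(c_sol))
  expect_gt(by_k$dw[by_k$potassium == "K1"], by_k$dw[by_k$potassium == "K0"])
  expect_gt(by_k$ssc[by_k$potassium == "K1"], by_k$ssc[by_k$potassium == "K0"])
  expect_gt(by_k$c_sol[by_k$potassium == "K1"], by_k$c_sol[by_k$potassium == "K0"])
})

test_that("the temperature series is a bounded daily sinusoid", {
  cfg <- generator_config()
  env <- generate_temperature(cfg)
  expect_true(all(env$temp >= cfg$temp_range[1] - 1e-9))
  expect_true(all(env$temp <= cfg$temp_range[2] + 1e-9))
  expect_equal(mean(env$temp[1:24]), mean(cfg$temp_range), tolerance = 1e-6)
  # 24 h period
  expect_equal(env$temp[1:24], env$temp[25:48], tolerance = 1e-9)
})
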
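#' Configuration of the synthetic experiment generator
#'
#' Parameters of the seeded generator that emulates the study design the
#' analysis assumes: a 4 water-level (CK control plus three single-stage
#' deficit treatments) by 2 potassium-level factorial, fruits sampled at
#' eight ages with three replicates, and smooth carbon-allocation
#' trajectories whose endpoints match the reported allocation pattern
#' (starch 16% of fruit carbon at the first sampled age falling to 2% at
#' harvest, structural carbon 75% falling as soluble sugar rises to 45%).
#'
#' Treatment effects enter as multipliers on the growth asymptotes (deficit
#' water lowers fresh and dry weight; potassium raises both) and as additive
#' shifts of the soluble-sugar allocation (deficit and potassium both divert
#' allocation from structural carbon to soluble sugar), reproducing the
#' direction of every reported treatment contrast without targeting exact
#' means. Measurement noise is multiplicative lognormal with a constant
#' coefficient of variation, applied independently to each measured quantity.
#'
#' @param n_reps Replicates per treatment per sampling age (default 3).
#' @param sampling_daa Sampling ages, days after anthesis.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise (default 0.05).
#' @param temp_range Site air-temperature range, degrees C.
#' @param fw_max,dw_max Control asymptotic fresh / dry weight (g).
#' @param fw_mid,fw_scale,dw_mid,dw_scale Logistic midpoint (days) and time
#'   scale (days) of the fresh- and dry-weight growth curves.
#' @param fw_water,dw_water Named multipliers of the growth asymptotes per
#'   water level.
#' @param fw_k,dw_k Potassium (K1) multipliers of the asymptotes.
#' @param sol_start,sol_end Soluble-sugar carbon fraction (%) at the first
#'   and last sampled age (control).
#' @param sta_start,sta_end Starch carbon fraction (%) at the first and last
#'   sampled age.
#' @param sol_mid,sol_scale,sta_mid,sta_scale Logistic shape parameters
#'   (days) of the rising soluble and falling starch fraction curves.
#' @param sol_shift_water Additive shift (% points) of the soluble fraction
#'   for water-deficit treatments.
#' @param sol_shift_k Additive shift (% points) for potassium-treated plants.
#' @param sugar_cf,starch_cf Carbon fractions used to back-convert pools to
#'   assay concentrations.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_reps = 3,
                             sampling_daa = c(34, 37, 48, 57, 58, 65, 66, 73),
                             noise_cv = 0.05,
                             temp_range = c(14.8, 29.1),
                             fw_max = 130, dw_max = 5.6,
                             fw_mid = 40, fw_scale = 9,
                             dw_mid = 40, dw_scale = 10,
                             fw_water = c(CK = 1, T1 = 0.78, T2 = 0.73, T3 = 0.77),
                             dw_water = c(CK = 1, T1 = 0.82, T2 = 0.96, T3 = 0.89),
                             fw_k = 1.08, dw_k = 1.17,
                             sol_start = 9, sol_end = 45,
                             sta_start = 16, sta_end = 2,
                             sol_mid = 50, sol_scale = 6,
                             sta_mid = 48, sta_scale = 7,
                             sol_shift_water = 1.2, sol_shift_k = 2.2,
                             sugar_cf = 0.40, starch_cf = 72 / 162) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_reps >= 1, length(cfg$sampling_daa) >= 4, cfg$noise_cv >= 0,
            all(names(cfg$fw_water) == names(cfg$dw_water)),
            cfg$fw_water["CK"] >= max(cfg$fw_water[names(cfg$fw_water) != "CK"]),
            cfg$fw_k >= 1, cfg$dw_k >= 1)
  structure(cfg, class = "generator_config")
}

.logistic <- function(t, mid, scale) stats::plogis((t - mid) / scale)
.dlogistic <- function(t, mid, scale) {
  p <- stats::plogis((t - mid) / scale)
  p * (1 - p) / scale
}

#' Generate a noiseless fruit growth curve for one treatment
#'
#' Logistic fresh- and dry-weight curves with treatment-scaled asymptotes;
#' the dry-weight growth rate is the analytic logistic derivative.
#'
#' @param water Water level (`"CK"`, `"T1"`, `"T2"`, `"T3"`).
#' @param potassium `"K0"` or `"K1"`.
#' @param config A [generator_config()].
#' @param daa Evaluation ages (days); default a 0.25-day grid from 0 to the
#'   last sampling age.
#' @return Tibble with `daa`, `fw`, `dw`, `ddw_dt` (g/day).
#' @export
generate_growth <- function(water, potassium, config = generator_config(),
                            daa = seq(0, max(config$sampling_daa), by = 0.25)) {
  stopifnot(water %in% names(config$fw_water), potassium %in% c("K0", "K1"))
  kf <- if (potassium == "K1") config$fw_k else 1
  kd <- if (potassium == "K1") config$dw_k else 1
  fw_asym <- config$fw_max * config$fw_water[[water]] * kf
  dw_asym <- config$dw_max * config$dw_water[[water]] * kd
  tibble::tibble(
    daa = daa,
    fw = fw_asym * .logistic(daa, config$fw_mid, config$fw_scale),
    dw = dw_asym * .logistic(daa, config$dw_mid, config$dw_scale),
    ddw_dt = dw_asym * .dlogistic(daa, config$dw_mid, config$dw_scale))
}

# Fraction curves: a rising normalised logistic for the soluble share, a
# falling one for starch, structural as the remainder. Anchored exactly at
# the first and last sampling age so the configured endpoints are hit.
.fraction_curves <- function(water, potassium, config) {
  t0 <- min(config$sampling_daa); t1 <- max(config$sampling_daa)
  shift <- (water != "CK") * config$sol_shift_water +
    (potassium == "K1") * config$sol_shift_k
  a <- config$sol_start + shift; b <- config$sol_end + shift
  s0 <- .logistic(t0, config$sol_mid, config$sol_scale)
  s1 <- .logistic(t1, config$sol_mid, config$sol_scale)
  r0 <- .logistic(-t0, -config$sta_mid, config$sta_scale)
  r1 <- .logistic(-t1, -config$sta_mid, config$sta_scale)
  list(
    sol = function(t) a + (b - a) * (.logistic(t, config$sol_mid, config$sol_scale) - s0) / (s1 - s0),
    dsol = function(t) (b - a) * .dlogistic(t, config$sol_mid, config$sol_scale) / (s1 - s0),
    sta = function(t) config$sta_end + (config$sta_start - config$sta_end) *
      (.logistic(-t, -config$sta_mid, config$sta_scale) - r1) / (r0 - r1),
    dsta = function(t) -(config$sta_start - config$sta_end) *
      .dlogistic(-t, -config$sta_mid, config$sta_scale) / (r0 - r1))
}

#' Generate the noiseless true trajectory for one treatment
#'
#' Smooth monotone carbon-fraction curves hitting the configured endpoints,
#' converted to pool carbon via the growth curve, together with the implied
#' time-varying conversion rates obtained by applying the pool-balance
#' identities to the noiseless curves (analytic derivatives throughout).
#' These implied rates are the ground truth the inversion stage is tested
#' against.
#'
#' @inheritParams generate_growth
#' @param const A [sugar_constants()] object (supplies `c_DW` and `k5`).
#' @return A tibble with `daa`, `fw`, `dw`, `ddw_dt`, fractions `frac_sol`,
#'   `frac_sta`, `frac_str` (%), pools `c_sol`, `c_sta`, `c_str` (g C) and
#'   implied `k3`, `k5m` (per day, floored at 0).
#' @export
generate_allocation <- function(water, potassium, config = generator_config(),
                                const = sugar_constants(),
                                daa = seq(min(config$sampling_daa),
                                          max(config$sampling_daa), by = 0.25)) {
  growth <- generate_growth(water, potassium, config, daa)
  fc <- .fraction_curves(water, potassium, config)
  sol <- fc$sol(daa); sta <- fc$sta(daa); str <- 100 - sol - sta
  pools <- tibble::tibble(
    daa = daa, fw = growth$fw, dw = growth$dw, ddw_dt = growth$ddw_dt,
    frac_sol = sol, frac_sta = sta, frac_str = str,
    c_sol = sol / 100 * const$c_DW * growth$dw,
    c_sta = sta / 100 * const$c_DW * growth$dw,
    c_str = str / 100 * const$c_DW * growth$dw)
  # analytic pool derivatives, g/day
  dsol <- fc$dsol(daa); dsta <- fc$dsta(daa); dstr <- -dsol - dsta
  dc_str <- const$c_DW * (dstr / 100 * growth$dw + str / 100 * growth$ddw_dt)
  dc_sta <- const$c_DW * (dsta / 100 * growth$dw + sta / 100 * growth$ddw_dt)
  pools$k3 <- pmax(dc_str / pools$c_sol, 0)
  pools$k5m <- pmax((const$k5 * pools$c_sta + dc_sta) / pools$c_sol, 0)
  pools
}

#' Daily sinusoidal temperature series
#'
#' Hourly air temperature oscillating between the configured minimum and
#' maximum with a 24-hour period (warmest mid-afternoon).
#'
#' @param config A [generator_config()].
#' @param from,to Window in days after anthesis.
#' @return Tibble with `time_h` and `temp` (degrees C).
#' @export
generate_temperature <- function(config = generator_config(), from = 0,
                                 to = max(config$sampling_daa)) {
  time_h <- seq(from * 24, to * 24, by = 1)
  mid <- mean(config$temp_range)
  amp <- diff(config$temp_range) / 2
  tibble::tibble(time_h = time_h,
                 temp = mid + amp * sin(2 * pi * (time_h %% 24 - 9) / 24))
}

# Independent, order-stable RNG stream per treatment: the substream seed is
# a deterministic function of the global seed and the treatment label, so
# adding treatments never reshuffles existing draws.
.treatment_seed <- function(seed, label) {
  (as.integer(seed) %% 100000L) * 20011L +
    sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 20011L
}

#' Sample noisy fruit observations from a true trajectory
#'
#' Evaluates the noiseless curves at the sampling ages, back-converts pools
#' to assay concentrations, and applies seeded multiplicative lognormal
#' noise (unit mean, configured CV) independently to fresh weight, dry
#' weight and both concentrations for each replicate fruit.
#'
#' @param truth A [generate_allocation()] trajectory.
#' @param water,potassium Treatment labels recorded in the output.
#' @param config A [generator_config()].
#' @param seed Global seed; the treatment's substream is derived from it.
#' @return An observation tibble with columns `treatment`, `water`,
#'   `potassium`, `truss`, `replicate`, `daa`, `fw`, `dw`, `ssc`, `stc`.
#' @export
sample_observations <- function(truth, water, potassium,
                                config = generator_config(), seed = 1) {
  label <- paste0(water, ifelse(potassium == "K1", "K", ""))
  at <- vapply(config$sampling_daa, function(d) which.min(abs(truth$daa - d)), 1L)
  base <- truth[at, ]
  base <- concentrations_from_pools(base, config$sugar_cf, config$starch_cf)
  truss <- findInterval(config$sampling_daa, c(-Inf, 36, 57.5, 65.5)) # 34 | 37-57 | 58-65 | 66-73
  cv <- config$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(.treatment_seed(seed, label))
  rows <- purrr::map(seq_len(config$n_reps), function(rep) {
    noise <- function(n) stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    n <- nrow(base)
    tibble::tibble(
      treatment = label, water = water, potassium = potassium,
      truss = truss, replicate = rep, daa = config$sampling_daa,
      fw = base$fw * noise(n), dw = base$dw * noise(n),
      ssc = base$ssc * noise(n), stc = base$stc * noise(n))
  })
  dplyr::bind_rows(rows)
}

#' Generate a complete synthetic experiment
#'
#' Runs the generator for every treatment of the water-by-potassium
#' factorial and stacks the noisy observation tables; the noiseless truth
#' (curves plus implied rates) is returned alongside for use as a test
#' oracle.
#'
#' @param seed Global seed driving every treatment's noise stream.
#' @param config A [generator_config()].
#' @param const A [sugar_constants()] object.
#' @return A list of class `sugar_synthesis` with elements `observations`
#'   (one row per sampled fruit), `truth` (noiseless trajectories per
#'   treatment with implied rates), `temperature`, `config` and `seed`.
#' @examples
#' synth <- generate_dataset(seed = 1)
#' dplyr::count(synth$observations, treatment)
#' @export
generate_dataset <- function(seed = 1, config = generator_config(),
                             const = sugar_constants()) {
  grid <- tidyr::expand_grid(water = names(config$fw_water),
                             potassium = c("K0", "K1"))
  parts <- purrr::pmap(grid, function(water, potassium) {
    truth <- generate_allocation(water, potassium, config, const)
    obs <- sample_observations(truth, water, potassium, config, seed)
    label <- paste0(water, ifelse(potassium == "K1", "K", ""))
    truth <- dplyr::mutate(truth, treatment = label, water = water,
                           potassium = potassium, .before = 1)
    list(obs = obs, truth = truth)
  })
  structure(list(
    observations = dplyr::bind_rows(purrr::map(parts, "obs")),
    truth = dplyr::bind_rows(purrr::map(parts, "truth")),
    temperature = generate_temperature(config),
    config = config, seed = seed), class = "sugar_synthesis")
}

#' @export
print.sugar_synthesis <- function(x, ...) {
  cat(sprintf("Synthetic fruit carbon experiment (seed %s)\n", format(x$seed)))
  cat(sprintf("  %d observations, %d treatments, ages %s DAA\n",
              nrow(x$observations),
              length(unique(x$observations$treatment)),
              paste(range(x$config$sampling_daa), collapse = "-")))
  invisible(x)
}
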
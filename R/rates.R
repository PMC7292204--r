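#' Conversion rate soluble sugar to structural carbon, k3(t)
#'
#' From the structural-pool balance `dC_str/dt = k3(t) C_sol`, the rate is
#' recovered pointwise as `k3(t) = (dC_str/dt) / C_sol`. Points where the
#' smoothed soluble pool is at or below the floor are flagged and withheld
#' (`NA`); negative estimates (smoothing artifacts) are floored at 0 but the
#' raw value is preserved for diagnostics.
#'
#' @param smoothed A [smooth_pools()] result carrying `c_sol`, `c_str` and
#'   `dc_str_dt`.
#' @param c_sol_floor Smallest soluble-pool carbon (g) accepted in the
#'   denominator (default 1e-6).
#' @return Tibble with `daa`, `k3` (per day, floored at 0), `k3_raw`, and a
#'   logical `flag` marking withheld or floored points.
#' @export
estimate_k3 <- function(smoothed, c_sol_floor = 1e-6) {
  stopifnot(all(c("daa", "c_sol", "dc_str_dt") %in% names(smoothed)))
  raw <- smoothed$dc_str_dt / smoothed$c_sol
  withheld <- smoothed$c_sol <= c_sol_floor
  raw[withheld] <- NA_real_
  k3 <- pmax(raw, 0)
  tibble::tibble(daa = smoothed$daa, k3 = k3, k3_raw = raw,
                 flag = withheld | (!is.na(raw) & raw < 0))
}

#' Conversion rate soluble sugar to starch, k5m(t)
#'
#' From the starch-pool balance `dC_sta/dt = k5m(t) C_sol - k5 C_sta`:
#' `k5m(t) = k5 C_sta / C_sol + (dC_sta/dt) / C_sol`, with `k5` the constant
#' starch-breakdown rate. Flagging and flooring as in [estimate_k3()].
#'
#' @inheritParams estimate_k3
#' @param k5 Constant starch-to-sugar conversion rate (per day).
#' @return Tibble with `daa`, `k5m` (per day), `k5m_raw`, `flag`.
#' @export
estimate_k5m <- function(smoothed, k5 = sugar_constants()$k5, c_sol_floor = 1e-6) {
  stopifnot(all(c("daa", "c_sol", "c_sta", "dc_sta_dt") %in% names(smoothed)))
  raw <- (k5 * smoothed$c_sta + smoothed$dc_sta_dt) / smoothed$c_sol
  withheld <- smoothed$c_sol <= c_sol_floor
  raw[withheld] <- NA_real_
  tibble::tibble(daa = smoothed$daa, k5m = pmax(raw, 0), k5m_raw = raw,
                 flag = withheld | (!is.na(raw) & raw < 0))
}

#' Phloem supply flux implied by a growth curve
#'
#' Evaluates `dC_sup/dt = c_DW dDW/dt + respiration` along a growth curve
#' and temperature series: by mass conservation the phloem must deliver the
#' carbon laid down in dry matter plus the carbon respired.
#'
#' @param growth Data frame with `daa`, `dw` (g) and `ddw_dt` (g/day).
#' @param env Data frame with `time_h` and `temp` (degrees C); temperature is
#'   interpolated at each age.
#' @param const A [sugar_constants()] object.
#' @return Tibble with `daa`, `dcsup_dt` and `dcrep_dt` (g C/day).
#' @export
estimate_supply_flux <- function(growth, env, const = sugar_constants()) {
  stopifnot(all(c("daa", "dw", "ddw_dt") %in% names(growth)),
            all(c("time_h", "temp") %in% names(env)))
  temp <- stats::approx(env$time_h / 24, env$temp, xout = growth$daa, rule = 2)$y
  # smoothing can leave a marginally negative growth-rate estimate near the
  # plateau; fruits do not shrink in dry weight, so floor at 0
  ddw_h <- per_day_to_per_hour(pmax(growth$ddw_dt, 0))
  rep_h <- respiration_rate(growth$dw, ddw_h, temp, const)
  tibble::tibble(daa = growth$daa,
                 dcsup_dt = per_hour_to_per_day(const$c_DW * ddw_h + rep_h),
                 dcrep_dt = per_hour_to_per_day(rep_h))
}

#' Recover the full time-varying rate series from smoothed trajectories
#'
#' The inversion stage: given smoothed pool trajectories (and, if the dry
#' weight was smoothed alongside, a temperature series), assembles k3(t),
#' k5m(t), the respiration coefficient k6(t) and the supply flux on the
#' evaluation grid. Local-polynomial derivatives are unreliable at window
#' boundaries, so by default the series is reported only on the interior
#' `edge_fraction` of the observed age span.
#'
#' @param smoothed A [smooth_pools()] result (pools; optionally `dw` and
#'   `ddw_dt`).
#' @param env Optional temperature series (`time_h`, `temp`); required for
#'   k6 and the supply flux.
#' @param const A [sugar_constants()] object.
#' @param k5 Constant starch-breakdown rate (per day); defaults to
#'   `const$k5`.
#' @param c_sol_floor Denominator floor, g (default 1e-6).
#' @param edge_fraction Fraction of the observed age span kept, centred
#'   (default 0.8); use 1 to keep the full grid.
#' @return A tibble of class `rate_series`: `daa`, `k3`, `k5m`, `k6`,
#'   `dcsup_dt` (all per day), diagnostic columns `k3_raw`, `k5m_raw`, and
#'   logical `flag`.
#' @export
estimate_rates <- function(smoothed, env = NULL, const = sugar_constants(),
                           k5 = const$k5, c_sol_floor = 1e-6,
                           edge_fraction = 0.8) {
  stopifnot(edge_fraction > 0, edge_fraction <= 1)
  est3 <- estimate_k3(smoothed, c_sol_floor)
  est5m <- estimate_k5m(smoothed, k5, c_sol_floor)
  out <- tibble::tibble(daa = smoothed$daa,
                        k3 = est3$k3, k5m = est5m$k5m,
                        k6 = NA_real_, dcsup_dt = NA_real_,
                        k3_raw = est3$k3_raw, k5m_raw = est5m$k5m_raw,
                        flag = est3$flag | est5m$flag)
  if (!is.null(env) && all(c("dw", "ddw_dt") %in% names(smoothed))) {
    growth <- tibble::tibble(daa = smoothed$daa, dw = smoothed$dw,
                             ddw_dt = smoothed$ddw_dt)
    flux <- estimate_supply_flux(growth, env, const)
    out$dcsup_dt <- flux$dcsup_dt
    csol <- smoothed$c_sol
    k6 <- flux$dcrep_dt / csol
    k6[csol <= c_sol_floor] <- NA_real_
    out$k6 <- k6
  }
  rng <- attr(smoothed, "daa_range") %||% range(smoothed$daa)
  trim <- (1 - edge_fraction) / 2 * diff(rng)
  out <- out[out$daa >= rng[1] + trim - 1e-9 & out$daa <= rng[2] - trim + 1e-9, ]
  class(out) <- c("rate_series", class(out))
  out
}

#' Invert observation tables to rate series, per treatment
#'
#' End-to-end inversion: converts assay observations to carbon pools,
#' smooths each treatment's pooled replicates, and recovers the rate series.
#'
#' @param obs Observation table (see [read_observations()] for the column
#'   contract); must carry a `treatment` column.
#' @param env Optional temperature series for k6/supply.
#' @param bandwidth,grid_step Passed to [smooth_pools()].
#' @param ... Passed to [estimate_rates()].
#' @inheritParams pools_from_observations
#' @return Tibble: one [estimate_rates()] block per treatment, stacked, with
#'   the `treatment` column first.
#' @export
invert_observations <- function(obs, env = NULL, const = sugar_constants(),
                                sugar_cf = 0.40, starch_cf = 72 / 162,
                                bandwidth = 0.6, grid_step = 1, ...) {
  stopifnot("treatment" %in% names(obs))
  pools <- pools_from_observations(obs, sugar_cf, starch_cf, const)
  pools |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(function(df, key) {
      sm <- smooth_pools(df, bandwidth = bandwidth, grid_step = grid_step)
      estimate_rates(sm, env = env, const = const, ...)
    }) |>
    dplyr::ungroup()
}

#' @export
autoplot.rate_series <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::any_of(c("k3", "k5m", "k6")),
                              names_to = "rate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$daa, .data$value, colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Days after anthesis", y = "Relative rate (1/day)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
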
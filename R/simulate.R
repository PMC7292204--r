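# Linear interpolation helpers; rule = 2 would mask coverage errors, so
# coverage is validated explicitly before any interpolant is built.
.check_cover <- function(grid, from, to, what) {
  if (min(grid) > from + 1e-9 || max(grid) < to - 1e-9) {
    rlang::abort(sprintf(
      "%s grid [%g, %g] does not cover the simulation interval [%g, %g].",
      what, min(grid), max(grid), from, to))
  }
}

#' Forward simulation of the three-pool fruit carbon balance
#'
#' Integrates the coupled balance equations for soluble-sugar, starch and
#' structural carbon,
#' \deqn{dC_{sol}/dt = k_0\,dC_{sup}/dt + k_5 C_{sta} - (k_3 + k_{5m} + k_6) C_{sol}}
#' \deqn{dC_{sta}/dt = k_{5m} C_{sol} - k_5 C_{sta}}
#' \deqn{dC_{str}/dt = k_3 C_{sol}}
#' with a fixed-step fourth-order Runge-Kutta scheme on an hourly internal
#' clock, accumulating cumulative respiration and supply. The supply flux is
#' implied by growth and respiration through mass conservation. Conversion
#' rates and growth rates are supplied per day and converted internally;
#' schedules are linearly interpolated between grid points.
#'
#' If the integrator transiently undershoots zero, pools are clipped at 0 and
#' a warning reports the largest excursion.
#'
#' @param init Named numeric vector or list with initial pools `c_sol`,
#'   `c_sta`, `c_str` (g C), all non-negative.
#' @param growth Data frame with columns `daa`, `dw` (g) and `ddw_dt`
#'   (g/day): the fruit growth curve.
#' @param env Data frame with columns `time_h` (hours since anthesis) and
#'   `temp` (degrees C).
#' @param rates Data frame with columns `daa`, `k3`, `k5m` (per day).
#' @param const A [sugar_constants()] object; `k5` (per day) is taken from it.
#' @param from,to Simulation window in days after anthesis; defaults to the
#'   span of `rates$daa`.
#' @param step_h Integrator step in hours (default 1).
#' @return A tibble of class `sugar_simulation` with columns `time_h`, `daa`,
#'   `c_sol`, `c_sta`, `c_str`, `c_rep` (cumulative respiration, g),
#'   `c_sup` (cumulative supply, g), and fraction columns `frac_sol`,
#'   `frac_sta`, `frac_str` (% of total pool carbon).
#' @examples
#' growth <- tibble::tibble(daa = c(0, 10), dw = c(1, 1), ddw_dt = c(0, 0))
#' env <- tibble::tibble(time_h = c(0, 240), temp = 20)
#' rates <- tibble::tibble(daa = c(0, 10), k3 = 0, k5m = 0)
#' sim <- simulate_carbon(c(c_sol = 0.1, c_sta = 0.05, c_str = 0.3),
#'                        growth, env, rates)
#' @export
simulate_carbon <- function(init, growth, env, rates,
                            const = sugar_constants(),
                            from = min(rates$daa), to = max(rates$daa),
                            step_h = 1) {
  init <- unlist(init)[c("c_sol", "c_sta", "c_str")]
  if (anyNA(init)) rlang::abort("`init` must name c_sol, c_sta and c_str.")
  if (any(init < 0)) rlang::abort("Initial pools must be non-negative.")
  stopifnot(all(c("daa", "dw", "ddw_dt") %in% names(growth)),
            all(c("time_h", "temp") %in% names(env)),
            all(c("daa", "k3", "k5m") %in% names(rates)),
            to > from, step_h > 0)
  .check_cover(growth$daa, from, to, "Growth")
  .check_cover(env$time_h / 24, from, to, "Environment")
  .check_cover(rates$daa, from, to, "Rate-schedule")

  dw_f   <- stats::approxfun(growth$daa, growth$dw)
  ddw_f  <- stats::approxfun(growth$daa, growth$ddw_dt)     # g/day
  temp_f <- stats::approxfun(env$time_h, env$temp)
  k3_f   <- stats::approxfun(rates$daa, rates$k3)           # /day
  k5m_f  <- stats::approxfun(rates$daa, rates$k5m)          # /day
  k5_h   <- per_day_to_per_hour(const$k5)

  deriv <- function(t_h, y) {
    daa <- t_h / 24
    dw <- dw_f(daa)
    ddw_h <- per_day_to_per_hour(ddw_f(daa))
    temp <- temp_f(t_h)
    rep_r <- respiration_rate(dw, ddw_h, temp, const)
    sup_r <- const$c_DW * ddw_h + rep_r
    k3h <- per_day_to_per_hour(k3_f(daa))
    k5mh <- per_day_to_per_hour(k5m_f(daa))
    c(const$k0 * sup_r + k5_h * y[2] - (k3h + k5mh) * y[1] - rep_r,
      k5mh * y[1] - k5_h * y[2],
      k3h * y[1],
      rep_r,
      sup_r)
  }

  times <- seq(from * 24, to * 24, by = step_h)
  if (times[length(times)] < to * 24 - 1e-9) times <- c(times, to * 24)
  n <- length(times)
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("c_sol", "c_sta", "c_str", "c_rep", "c_sup")))
  y <- c(init, c_rep = 0, c_sup = 0)
  out[1, ] <- y
  undershoot <- 0
  for (i in seq_len(n - 1)) {
    h <- times[i + 1] - times[i]
    k1 <- deriv(times[i], y)
    k2 <- deriv(times[i] + h / 2, y + h / 2 * k1)
    k3v <- deriv(times[i] + h / 2, y + h / 2 * k2)
    k4 <- deriv(times[i] + h, y + h * k3v)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3v + k4)
    if (any(y[1:3] < 0)) {
      undershoot <- max(undershoot, -min(y[1:3]))
      y[1:3] <- pmax(y[1:3], 0)
    }
    out[i + 1, ] <- y
  }
  if (undershoot > 0) {
    rlang::warn(sprintf(
      "Integrator undershot zero; pools clipped at 0 (largest excursion %.3g g).",
      undershoot))
  }
  res <- tibble::as_tibble(out)
  res <- dplyr::mutate(res, time_h = times, daa = times / 24, .before = 1)
  res <- carbon_fractions(res)
  class(res) <- c("sugar_simulation", class(res))
  res
}

#' Per-step carbon fractions of the three pools
#'
#' Adds `frac_sol`, `frac_sta`, `frac_str`: each pool as a percentage of the
#' pool sum at that row (summing to 100). Works on any data frame carrying
#' `c_sol`, `c_sta`, `c_str` columns (simulations, converted observations,
#' smoothed trajectories).
#'
#' @param x Data frame with columns `c_sol`, `c_sta`, `c_str`.
#' @return `x` as a tibble with the three `frac_*` columns added (replaced if
#'   already present).
#' @export
carbon_fractions <- function(x) {
  stopifnot(all(c("c_sol", "c_sta", "c_str") %in% names(x)))
  tot <- x$c_sol + x$c_sta + x$c_str
  dplyr::mutate(tibble::as_tibble(x),
                frac_sol = 100 * c_sol / tot,
                frac_sta = 100 * c_sta / tot,
                frac_str = 100 * c_str / tot)
}

#' Write a simulation result to CSV
#'
#' Columns: `time_h, DAA, C_sol_g, C_sta_g, C_str_g, C_rep_g, C_sup_g,
#' frac_sol, frac_sta, frac_str`.
#'
#' @param sim A `sugar_simulation` tibble from [simulate_carbon()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  out <- data.frame(time_h = sim$time_h, DAA = sim$daa,
                    C_sol_g = sim$c_sol, C_sta_g = sim$c_sta,
                    C_str_g = sim$c_str, C_rep_g = sim$c_rep,
                    C_sup_g = sim$c_sup, frac_sol = sim$frac_sol,
                    frac_sta = sim$frac_sta, frac_str = sim$frac_str)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
autoplot.sugar_simulation <- function(object, fractions = FALSE, ...) {
  if (fractions) {
    long <- tidyr::pivot_longer(object, dplyr::all_of(c("frac_sol", "frac_sta", "frac_str")),
                                names_to = "pool", values_to = "value")
    ylab <- "Carbon fraction (% of total)"
  } else {
    long <- tidyr::pivot_longer(object, dplyr::all_of(c("c_sol", "c_sta", "c_str")),
                                names_to = "pool", values_to = "value")
    ylab <- "Carbon (g)"
  }
  long$pool <- factor(long$pool, labels = c("soluble sugar", "starch", "structural"))
  ggplot2::ggplot(long, ggplot2::aes(.data$daa, .data$value, colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Days after anthesis", y = ylab, colour = "Pool") +
    ggplot2::theme_minimal()
}
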
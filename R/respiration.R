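#' Maintenance respiration rate
#'
#' Carbon lost to maintenance respiration of standing biomass, with a Q10
#' temperature response referenced to 20 degrees C:
#' `q_m * DW * Q10^((T - 20)/10)`.
#'
#' @param dw Fruit dry weight (g); non-negative.
#' @param temp Temperature (degrees C).
#' @param const A [sugar_constants()] object.
#' @return Respiration rate in g C per hour (vectorised over inputs).
#' @examples
#' maintenance_respiration(1, 20)            # q_m itself
#' maintenance_respiration(1, 30) / maintenance_respiration(1, 20)  # Q10
#' @export
maintenance_respiration <- function(dw, temp, const = sugar_constants()) {
  if (any(dw < 0, na.rm = TRUE)) rlang::abort("Dry weight must be non-negative.")
  const$q_m * dw * const$Q10^((temp - 20) / 10)
}

#' Total fruit respiration rate
#'
#' Growth plus maintenance respiration: `q_g * dDW/dt + q_m * DW *
#' Q10^((T-20)/10)`. Growth respiration is proportional to the dry-weight
#' growth rate, maintenance to standing dry weight.
#'
#' @param dw Dry weight (g); non-negative.
#' @param ddw_dt Dry-weight growth rate (g/h); non-negative (fruits do not
#'   shrink in dry weight).
#' @param temp Temperature (degrees C).
#' @inheritParams maintenance_respiration
#' @return Respiration rate in g C per hour.
#' @export
respiration_rate <- function(dw, ddw_dt, temp, const = sugar_constants()) {
  if (any(ddw_dt < 0, na.rm = TRUE)) {
    rlang::abort("Dry-weight growth rate must be non-negative.")
  }
  const$q_g * ddw_dt + maintenance_respiration(dw, temp, const)
}

#' Total fruit carbon from dry weight
#'
#' `c_DW * DW`: the carbon held in the fruit, all pools together.
#'
#' @inheritParams maintenance_respiration
#' @return Carbon (g).
#' @export
carbon_total <- function(dw, const = sugar_constants()) {
  const$c_DW * dw
}

#' Phloem carbon supply rate implied by growth
#'
#' By mass conservation, carbon import must cover both the accumulation of
#' fruit carbon (`c_DW * dDW/dt`) and respiration losses, so
#' `dC_sup/dt = c_DW * dDW/dt + respiration_rate(...)`.
#'
#' @inheritParams respiration_rate
#' @return Supply flux in g C per hour.
#' @export
supply_rate <- function(ddw_dt, dw, temp, const = sugar_constants()) {
  const$c_DW * ddw_dt + respiration_rate(dw, ddw_dt, temp, const)
}

#' Respiration coefficient k6(t)
#'
#' The relative rate at which the soluble-sugar pool is respired:
#' total respiration divided by soluble-sugar carbon. Directly computable,
#' not a fitted parameter. Where `c_sol` is at or below zero the coefficient
#' is undefined and `NA` is returned.
#'
#' @inheritParams respiration_rate
#' @param c_sol Soluble-sugar carbon (g).
#' @return k6 in 1/h; `NA_real_` where `c_sol <= 0`.
#' @export
k6_rate <- function(dw, ddw_dt, temp, c_sol, const = sugar_constants()) {
  r <- respiration_rate(dw, ddw_dt, temp, const)
  out <- r / c_sol
  out[!is.na(c_sol) & c_sol <= 0] <- NA_real_
  out
}
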
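#' Irrigation amount from soil-water deficit
#'
#' `W = (theta_t1 - theta_t2) * V`: the water volume needed to raise the pot
#' soil from its measured pre-irrigation water content to the refill target.
#'
#' @param theta_upper Refill target, volumetric soil water content
#'   (cm^3/cm^3).
#' @param theta_measured Measured pre-irrigation soil water content
#'   (cm^3/cm^3); must not exceed `theta_upper`.
#' @param volume Pot soil volume (cm^3).
#' @return Irrigation amount in cm^3 (vectorised).
#' @examples
#' irrigation_amount(0.95 * 0.25, 0.70 * 0.25, 13077)
#' @export
irrigation_amount <- function(theta_upper, theta_measured, volume) {
  if (any(theta_measured < 0)) rlang::abort("Soil water content cannot be negative.")
  if (any(theta_measured > theta_upper + 1e-12)) {
    rlang::abort("Measured soil water exceeds the refill target: no irrigation needed.")
  }
  (theta_upper - theta_measured) * volume
}

#' Default pot soil volume
#'
#' Soil volume used in the irrigation equation, taken as soil mass over bulk
#' density rather than pot geometry (the gravel drainage layer makes the
#' geometric volume an overestimate).
#'
#' @param soil_kg Air-dried soil mass per pot (kg); default 17.
#' @param bulk_density Soil bulk density (g/cm^3); default 1.3.
#' @return Volume in cm^3.
#' @export
pot_soil_volume <- function(soil_kg = 17, bulk_density = 1.3) {
  soil_kg * 1000 / bulk_density
}

#' Build the water-by-potassium treatment design table
#'
#' Constructs the eight treatments of a 4 water-level by 2 potassium-level
#' factorial: a well-watered control (CK) and three deficit treatments (T1,
#' T2, T3), each receiving half the control irrigation amount during exactly
#' one growth stage (stage I, II, III respectively) and the full amount
#' otherwise; half of the plants additionally receive potassium as two equal
#' K2O applications at `k_rate` g per kg of pot soil each.
#'
#' @param control_stage_mm Irrigation amounts of the well-watered control in
#'   the three stages (mm). Default `c(60.66, 114.92, 91.64)`.
#' @param deficit_stage Named integer vector mapping each deficit treatment
#'   to its halved stage. Default `c(T1 = 1, T2 = 2, T3 = 3)`.
#' @param k_rate K2O dose rate per application (g per kg soil); default 0.46.
#' @param soil_kg Pot soil mass (kg); default 17.
#' @param n_applications Number of potassium applications; default 2.
#' @return A tibble with 8 rows and columns `treatment`, `water`,
#'   `potassium`, `stage1_mm`, `stage2_mm`, `stage3_mm`, `k_per_application_g`,
#'   `k_total_g`.
#' @examples
#' build_design()
#' @export
build_design <- function(control_stage_mm = c(60.66, 114.92, 91.64),
                         deficit_stage = c(T1 = 1, T2 = 2, T3 = 3),
                         k_rate = 0.46, soil_kg = 17, n_applications = 2) {
  stopifnot(length(control_stage_mm) == 3, all(control_stage_mm > 0),
            k_rate > 0, soil_kg > 0)
  water_levels <- c(names(deficit_stage), "CK")
  dose <- k_rate * soil_kg
  grid <- tidyr::expand_grid(water = water_levels, potassium = c("K0", "K1"))
  rows <- purrr::pmap(grid, function(water, potassium) {
    stages <- control_stage_mm
    if (water %in% names(deficit_stage)) {
      s <- deficit_stage[[water]]
      stages[s] <- stages[s] / 2
    }
    tibble::tibble(
      treatment = paste0(water, ifelse(potassium == "K1", "K", "")),
      water = water, potassium = potassium,
      stage1_mm = stages[1], stage2_mm = stages[2], stage3_mm = stages[3],
      k_per_application_g = ifelse(potassium == "K1", dose, 0),
      k_total_g = ifelse(potassium == "K1", n_applications * dose, 0))
  })
  dplyr::bind_rows(rows)
}
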
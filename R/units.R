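#' Convert fruit observations to carbon pools
#'
#' Bridges assay measurements to the model's state. Soluble-sugar and starch
#' carbon are computed from their concentrations (g per 100 g fresh weight)
#' and the carbon fraction of each compound class; structural carbon is the
#' remainder of total fruit carbon (`c_DW * DW`):
#' \deqn{C_{sol} = SSC/100 \times FW \times f_{sugar}, \quad
#'       C_{sta} = STC/100 \times FW \times f_{starch}, \quad
#'       C_{str} = c_{DW} DW - C_{sol} - C_{sta}.}
#'
#' Records whose implied structural carbon is negative are internally
#' inconsistent (assay error): they are dropped with a warning naming the
#' rows, not clipped, since clipping would bias downstream rate estimates.
#'
#' @param obs Data frame of fruit observations with columns `daa`, `fw` (g),
#'   `dw` (g), `ssc` and `stc` (g/100 g FW); additional columns (treatment
#'   labels, replicate, truss) are carried through.
#' @param sugar_cf Carbon fraction of soluble sugar (g C/g). Default 0.40,
#'   the hexose stoichiometry 72/180 (tomato soluble sugar is predominantly
#'   glucose + fructose).
#' @param starch_cf Carbon fraction of starch (g C/g). Default 72/162
#'   (about 0.444), the anhydroglucose stoichiometry.
#' @param const A [sugar_constants()] object.
#' @return The input as a tibble with `c_sol`, `c_sta`, `c_str` (g C) and
#'   `c_total` (g C) columns appended; inconsistent rows removed.
#' @export
pools_from_observations <- function(obs,
                                    sugar_cf = 0.40,
                                    starch_cf = 72 / 162,
                                    const = sugar_constants()) {
  stopifnot(all(c("fw", "dw", "ssc", "stc") %in% names(obs)))
  if (sugar_cf <= 0 || sugar_cf >= 1 || starch_cf <= 0 || starch_cf >= 1) {
    rlang::abort("Carbon conversion factors must lie in (0, 1).")
  }
  out <- dplyr::mutate(tibble::as_tibble(obs),
                       c_sol = .data$ssc / 100 * .data$fw * sugar_cf,
                       c_sta = .data$stc / 100 * .data$fw * starch_cf,
                       c_total = carbon_total(.data$dw, const),
                       c_str = .data$c_total - .data$c_sol - .data$c_sta)
  bad <- which(out$c_str < 0)
  if (length(bad) > 0) {
    rlang::warn(sprintf(
      "Dropped %d observation(s) with negative implied structural carbon (rows %s).",
      length(bad), paste(utils::head(bad, 10), collapse = ", ")))
    out <- out[-bad, ]
  }
  out
}

#' Recover assay concentrations from carbon pools
#'
#' Inverse of [pools_from_observations()]: back-computes soluble sugar and
#' starch concentrations (g/100 g FW) from pool carbon, fresh weight and the
#' compound carbon fractions. Used by the synthetic-data generator and for
#' round-trip validation.
#'
#' @param pools Data frame with columns `c_sol`, `c_sta` (g C) and `fw` (g).
#' @inheritParams pools_from_observations
#' @return Tibble with `ssc` and `stc` columns added/replaced.
#' @export
concentrations_from_pools <- function(pools, sugar_cf = 0.40, starch_cf = 72 / 162) {
  stopifnot(all(c("c_sol", "c_sta", "fw") %in% names(pools)))
  dplyr::mutate(tibble::as_tibble(pools),
                ssc = .data$c_sol / sugar_cf / .data$fw * 100,
                stc = .data$c_sta / starch_cf / .data$fw * 100)
}

#' Carbon fractions of total fruit carbon per record
#'
#' Expresses each pool as a percentage of the pool sum, as allocation tables
#' in fruit carbon-balance studies report them; the three fractions sum to
#' 100 by construction.
#'
#' @param pools Data frame with `c_sol`, `c_sta`, `c_str` columns.
#' @return Tibble with `frac_sol`, `frac_sta`, `frac_str` appended.
#' @seealso [carbon_fractions()], which this wraps.
#' @export
fractions_from_pools <- function(pools) carbon_fractions(pools)

#' Read a fruit-observation CSV
#'
#' Header-validated reader for the observation-table contract: columns
#' `treatment`, `water`, `potassium`, `truss`, `replicate`, `daa`, `fw`,
#' `dw`, `ssc`, `stc` (extra columns allowed, missing required ones an
#' error). Decimal separator is `.`; the file must carry a header row.
#'
#' @param path CSV path.
#' @return A tibble of observations.
#' @export
read_observations <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("treatment", "water", "potassium", "truss", "replicate",
                "daa", "fw", "dw", "ssc", "stc")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("Observation file ", path, " lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) rlang::abort(paste0("Observation file ", path, " is empty."))
  tibble::as_tibble(df)
}

#' Write a table to CSV under the package's tabular contract
#'
#' Plain CSV, header row, `.` decimal separator, no quoting of numerics.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
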
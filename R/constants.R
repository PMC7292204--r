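#' Model constants for the simplified fruit carbon-balance model
#'
#' Bundles the fixed parameters of the three-pool carbon-balance model of a
#' growing tomato fruit. All respiration constants are expressed per hour;
#' relative conversion rates (`k5` and the time-varying schedules used
#' elsewhere) are expressed per day in all user-facing interfaces and
#' converted internally (see [per_day_to_per_hour()]).
#'
#' @param c_DW Carbon content per gram dry weight (g C / g DW). Default 0.44.
#' @param q_g Growth respiration coefficient (g C respired per g DW gained).
#'   Default 0.088.
#' @param q_m Maintenance respiration coefficient at 20 degrees C
#'   (g C / g DW / h). Default 0.000168.
#' @param Q10 Temperature ratio of maintenance respiration over a 10 degree C
#'   step (dimensionless). Default 1.4.
#' @param k0 Phloem import fraction (dimensionless); the share of supplied
#'   carbon entering the soluble-sugar pool. Fixed at 1 for tomato.
#' @param k5 Relative conversion rate starch to soluble sugar (1/day),
#'   treated as constant through fruit development. Default 0.296517337.
#'
#' @return An object of class `sugar_constants`: a named list with the six
#'   parameters.
#' @examples
#' const <- sugar_constants()
#' const$c_DW
#' @export
sugar_constants <- function(c_DW = 0.44,
                            q_g = 0.088,
                            q_m = 0.000168,
                            Q10 = 1.4,
                            k0 = 1,
                            k5 = 0.296517337) {
  vals <- list(c_DW = c_DW, q_g = q_g, q_m = q_m, Q10 = Q10, k0 = k0, k5 = k5)
  bad <- names(vals)[!vapply(vals, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    rlang::abort(paste0("All model constants must be single positive numbers; offending: ",
                        paste(bad, collapse = ", ")))
  }
  structure(vals, class = "sugar_constants")
}

#' @export
print.sugar_constants <- function(x, ...) {
  cat("Simplified fruit carbon-balance model constants\n")
  cat(sprintf("  c_DW = %g g C/g DW   q_g = %g g C/g DW   q_m = %g g C/g DW/h\n",
              x$c_DW, x$q_g, x$q_m))
  cat(sprintf("  Q10  = %g            k0  = %g            k5  = %g /day\n",
              x$Q10, x$k0, x$k5))
  invisible(x)
}

#' Read model constants from a configuration file
#'
#' Accepts a YAML or JSON file of `name: value` pairs overriding any subset of
#' the defaults of [sugar_constants()]. Unknown keys are an error so that
#' typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML or JSON file.
#' @return A `sugar_constants` object.
#' @export
read_constants <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt) else yaml::yaml.load(txt)
  allowed <- names(formals(sugar_constants))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown constant(s) in ", path, ": ", paste(unknown, collapse = ", ")))
  }
  do.call(sugar_constants, lapply(vals, as.numeric))
}

# The per-day <-> per-hour conversion lives here and nowhere else: rate
# schedules (k3, k5m, k5, supply flux, growth rates) are per day at the user
# surface, while respiration constants and the integrator clock are hourly.

#' Convert a per-day rate to a per-hour rate
#'
#' The single place where the day/hour conversion factor is applied.
#'
#' @param x Numeric vector of per-day rates.
#' @return Per-hour rates (`x / 24`).
#' @seealso [per_hour_to_per_day()]
#' @export
per_day_to_per_hour <- function(x) x / 24

#' Convert a per-hour rate to a per-day rate
#' @param x Numeric vector of per-hour rates.
#' @return Per-day rates (`x * 24`).
#' @export
per_hour_to_per_day <- function(x) x * 24
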
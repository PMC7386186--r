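#' Inverse square factor at the midplane prescription point
#'
#' Output falls with the square of distance from the source. The monitor
#' unit calibration references `cal_distance` (100 cm by default); the
#' prescription point sits at the treatment SSD plus half the patient
#' separation (midplane), so
#' `ISF = (cal_distance / (treatment_ssd + separation / 2))^2`.
#'
#' @param geometry A [machine_geometry()].
#' @param separation Patient separation, cm (>= 0).
#' @return Dimensionless inverse-square factor.
#' @examples
#' inverse_square_factor(machine_geometry(), 0)   # (100/500)^2 = 0.04
#' @export
inverse_square_factor <- function(geometry, separation) {
  if (!is.numeric(separation) || !is.finite(separation) || separation < 0) {
    tbi_abort("separation must be a non-negative number", "tbi_domain_error")
  }
  geometry$cal_distance^2 / (geometry$treatment_ssd + separation / 2)^2
}

#' Assemble the dose-per-MU factor breakdown
#'
#' The hand calculation expresses the dose per monitor unit at the
#' midplane prescription point as the product of six factors: the
#' inverse-square factor, collimator factor Sc, phantom scatter factor Sp,
#' tissue maximum ratio at midplane depth, the beam-spoiler factor, and
#' the dose-to-water to dose-to-muscle conversion. Energy is selected from
#' the patient separation; table factors are interpolated from the beam
#' data.
#'
#' Which equivalent-square side Sc and Sp are read at is configurable
#' (`sc_side`, `sp_side`): by default both use the collimator setting at
#' treatment (40 cm). Clinics that prefer a patient-limited equivalent
#' square for Sp can pass one explicitly.
#'
#' @param data A `beam_data_set`.
#' @param rx A [prescription()].
#' @param sc_side,sp_side Equivalent-square side (cm) at which to read Sc
#'   and Sp; default the geometry's `treatment_field`.
#' @return A `factor_breakdown` object: the six factors, their product
#'   `dose_per_mu` (cGy/MU), plus the selected energy, midplane depth and
#'   source-to-point distance.
#' @export
dose_per_mu <- function(data, rx, sc_side = NULL, sp_side = NULL) {
  geom <- data$geometry
  sc_side <- sc_side %||% geom$treatment_field
  sp_side <- sp_side %||% geom$treatment_field
  energy <- select_energy(data, rx$separation)
  depth <- rx$separation / 2
  fb <- list(
    energy = energy,
    depth = depth,
    distance_to_point = geom$treatment_ssd + depth,
    isf = inverse_square_factor(geom, rx$separation),
    sc = interpolate_factor(data, energy, "Sc", sc_side),
    sp = interpolate_factor(data, energy, "Sp", sp_side),
    tmr = interpolate_factor(data, energy, "TMR", depth),
    spoiler = spoiler_factor(data, energy),
    muscle = geom$water_to_muscle
  )
  fb$dose_per_mu <- fb$isf * fb$sc * fb$sp * fb$tmr * fb$spoiler * fb$muscle
  structure(fb, class = "factor_breakdown")
}

#' @export
print.factor_breakdown <- function(x, ...) {
  cat("<factor_breakdown>", x$energy, "@ depth", x$depth, "cm\n")
  for (f in c("isf", "sc", "sp", "tmr", "spoiler", "muscle")) {
    cat(sprintf("  %-8s %.6f\n", f, x[[f]]))
  }
  cat(sprintf("  %-8s %.6g cGy/MU\n", "dose/MU", x$dose_per_mu))
  invisible(x)
}

#' Choose the machine dose-rate setting under the prescription limit
#'
#' Instantaneous dose rate at the prescription point is limited by
#' protocol (typically 10 cGy/min for whole-body delivery). The linac
#' offers a discrete ladder of repetition rates; this picks the largest
#' deliverable rate R (MU/min) with `R * dose_per_mu <= max_dose_rate`
#' (inclusive), minimizing beam-on time without breaching the limit, and
#' reports the dose rate achieved at the prescription point.
#'
#' @param data A `beam_data_set` (supplies the dose-rate ladder).
#' @param rx A [prescription()] (supplies `max_dose_rate`, cGy/min).
#' @param factors A `factor_breakdown` from [dose_per_mu()].
#' @return List with `machine_dose_rate` (MU/min, a ladder member) and
#'   `achieved_dose_rate` (cGy/min).
#' @export
compute_dose_rate <- function(data, rx, factors) {
  ladder <- data$dose_rates
  feasible <- ladder[ladder * factors$dose_per_mu <= rx$max_dose_rate]
  if (length(feasible) == 0) {
    tbi_abort(
      glue::glue(
        "no deliverable dose rate: even {min(ladder)} MU/min gives ",
        "{signif(min(ladder) * factors$dose_per_mu, 4)} cGy/min ",
        "> limit {rx$max_dose_rate} cGy/min"),
      "tbi_no_feasible_rate_error"
    )
  }
  rate <- max(feasible)
  list(machine_dose_rate = rate,
       achieved_dose_rate = rate * factors$dose_per_mu)
}

#' Compute monitor units and dose-rate setting for one field
#'
#' The full hand calculation: assemble the factor breakdown, divide the
#' prescribed dose per field by dose-per-MU, round half-up to whole
#' monitor units, and select the maximal feasible machine dose rate. The
#' result carries the complete factor breakdown and the beam-data version
#' and checksum as its audit trail.
#'
#' A configurable sanity cap refuses absurd outputs (a tiny dose-per-MU
#' from a bad lookup would otherwise propagate silently): if the rounded
#' MU exceeds `mu_cap`, the calculation errors instead of returning.
#'
#' @param data A `beam_data_set`.
#' @param rx A [prescription()].
#' @param mu_cap Refuse results above this many MU per field.
#' @param sc_side,sp_side Passed to [dose_per_mu()].
#' @return A `calc_result` object.
#' @export
compute_mu <- function(data, rx, mu_cap = 25000, sc_side = NULL, sp_side = NULL) {
  fb <- dose_per_mu(data, rx, sc_side = sc_side, sp_side = sp_side)
  mu <- round_half_up(rx$dose_per_field / fb$dose_per_mu)
  if (mu < 1) {
    tbi_abort("calculated MU below 1; check prescription dose", "tbi_domain_error")
  }
  if (mu > mu_cap) {
    tbi_abort(
      glue::glue("calculated {mu} MU exceeds the sanity cap of {mu_cap} MU; ",
                 "refusing (check separation, tables and prescription)"),
      "tbi_sanity_cap_error"
    )
  }
  dr <- compute_dose_rate(data, rx, fb)
  structure(
    list(
      energy = fb$energy, depth = fb$depth,
      distance_to_point = fb$distance_to_point,
      factors = fb, mu_per_field = mu,
      machine_dose_rate = dr$machine_dose_rate,
      achieved_dose_rate = dr$achieved_dose_rate,
      beam_data_version = data$version,
      beam_data_checksum = data$checksum
    ),
    class = "calc_result"
  )
}

#' @export
print.calc_result <- function(x, ...) {
  cat("<calc_result>\n")
  cat(sprintf("  energy %s, depth %g cm (midplane), SPD %g cm\n",
              x$energy, x$depth, x$distance_to_point))
  cat(sprintf("  %d MU/field @ %g MU/min (%.3f cGy/min at point)\n",
              x$mu_per_field, x$machine_dose_rate, x$achieved_dose_rate))
  cat("  beam data:", x$beam_data_version, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a factor breakdown into a long tibble
#'
#' @param x A `factor_breakdown`.
#' @param ... Unused.
#' @return Tibble with one row per factor plus the `dose_per_mu` product.
#' @export
tidy.factor_breakdown <- function(x, ...) {
  tibble::tibble(
    factor = c("isf", "sc", "sp", "tmr", "spoiler", "muscle", "dose_per_mu"),
    value = c(x$isf, x$sc, x$sp, x$tmr, x$spoiler, x$muscle, x$dose_per_mu)
  )
}

#' @rdname tidy.factor_breakdown
#' @export
tidy.calc_result <- function(x, ...) tidy(x$factors)

#' One-row summary of a calculation result
#'
#' @param x A `calc_result`.
#' @param ... Unused.
#' @return One-row tibble: energy, depth, MU per field, machine dose rate,
#'   achieved dose rate, dose per MU, beam-data version.
#' @export
glance.calc_result <- function(x, ...) {
  tibble::tibble(
    energy = x$energy, depth = x$depth,
    mu_per_field = x$mu_per_field,
    machine_dose_rate = x$machine_dose_rate,
    achieved_dose_rate = x$achieved_dose_rate,
    dose_per_mu = x$factors$dose_per_mu,
    beam_data_version = x$beam_data_version
  )
}

#' Serialize / restore a calculation result
#'
#' JSON round-trip preserving every numeric field bit-exactly (full
#' precision, no rounding on write).
#'
#' @param calc A `calc_result`.
#' @param path Output path (`.json`).
#' @return `path` invisibly; `read_calc_result()` returns the restored
#'   `calc_result`.
#' @export
write_calc_result <- function(calc, path) {
  payload <- unclass(calc)
  payload$factors <- unclass(payload$factors)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_calc_result
#' @export
read_calc_result <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$factors <- structure(payload$factors, class = "factor_breakdown")
  payload$mu_per_field <- as.numeric(payload$mu_per_field)
  structure(payload, class = "calc_result")
}
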
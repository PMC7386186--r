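#' Default TBI protocol registry
#'
#' Per-protocol bounds used by [validate_prescription()]: the dose-rate
#' ceiling at the prescription point (10 cGy/min for the standard
#' protocols, following the classic whole-body dose-rate limit; 15 cGy/min
#' for the high-dose-rate adult protocol), plausible dose-per-field and
#' separation ranges, and the age class the protocol is written for. The
#' separation split at 28 cm is what operationally distinguishes an adult
#' from a pediatric habitus, so a prescription whose separation falls in
#' the other protocol's range is flagged as a probable wrong-worksheet
#' error.
#'
#' @return A tibble, one row per protocol.
#' @export
default_protocols <- function() {
  tibble::tribble(
    ~protocol,              ~age_class,  ~dose_rate_ceiling, ~dose_min, ~dose_max, ~sep_min, ~sep_max, ~fx_min, ~fx_max,
    "standard_adult",       "adult",     10,                 50,        400,       28,       60,       1,       12,
    "high_dose_rate_adult", "adult",     15,                 50,        400,       28,       60,       1,       12,
    "standard_pediatric",   "pediatric", 10,                 50,        300,       10,       28,       1,       12
  )
}

tbi_arrangements <- list(
  "AP/PA" = c("AP", "PA"),
  "RLat/LLat" = c("RLat", "LLat")
)

#' Construct a TBI prescription
#'
#' The physician's order as entered at planning time: protocol, dose per
#' field, fractionation, patient separation, the maximum instantaneous
#' dose rate allowed at the prescription point, and the field arrangement.
#' Structural invariants (positivity, known arrangement) are enforced
#' here; clinical consistency against the protocol registry is the job of
#' [validate_prescription()], which returns findings rather than throwing.
#'
#' @param protocol Protocol label, a row of the registry
#'   (see [default_protocols()]).
#' @param dose_per_field Prescribed dose per field, cGy.
#' @param num_fractions Number of fractions, >= 1.
#' @param separation Patient separation along the beam axis, cm.
#' @param max_dose_rate Maximum allowed dose rate at the prescription
#'   point, cGy/min.
#' @param arrangement `"AP/PA"` or `"RLat/LLat"`.
#' @param patient_id Medical record number.
#' @param patient_name Patient name.
#' @return A `prescription` object.
#' @export
prescription <- function(protocol, dose_per_field, num_fractions, separation,
                         max_dose_rate, arrangement = "AP/PA",
                         patient_id = "", patient_name = "") {
  if (!is.numeric(dose_per_field) || dose_per_field <= 0) {
    tbi_abort("dose_per_field must be positive", "tbi_validation_error")
  }
  if (!is.numeric(num_fractions) || num_fractions < 1 ||
      num_fractions != round(num_fractions)) {
    tbi_abort("num_fractions must be a whole number >= 1", "tbi_validation_error")
  }
  if (!is.numeric(separation) || separation <= 0) {
    tbi_abort("separation must be positive", "tbi_validation_error")
  }
  if (!is.numeric(max_dose_rate) || max_dose_rate <= 0) {
    tbi_abort("max_dose_rate must be positive", "tbi_validation_error")
  }
  if (!arrangement %in% names(tbi_arrangements)) {
    tbi_abort(paste0("unknown arrangement: ", arrangement), "tbi_validation_error")
  }
  structure(
    list(
      protocol = protocol, dose_per_field = dose_per_field,
      num_fractions = as.integer(num_fractions), separation = separation,
      max_dose_rate = max_dose_rate, arrangement = arrangement,
      patient_id = patient_id, patient_name = patient_name
    ),
    class = "prescription"
  )
}

#' @export
print.prescription <- function(x, ...) {
  cat("<prescription>", x$protocol, "\n")
  cat(sprintf("  %g cGy/field x %d fx, separation %g cm, %s, limit %g cGy/min\n",
              x$dose_per_field, x$num_fractions, x$separation,
              x$arrangement, x$max_dose_rate))
  invisible(x)
}

#' Read a prescription from YAML or JSON
#'
#' @param path Path to a YAML or JSON document whose keys mirror the
#'   [prescription()] arguments.
#' @return A `prescription` object.
#' @export
read_prescription <- function(path) {
  if (!file.exists(path)) {
    tbi_abort(paste0("prescription file not found: ", path), "tbi_load_error")
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(prescription, doc)
}

finding <- function(check_id, severity, field, message, evidence = list()) {
  tibble::tibble(
    check_id = check_id,
    severity = severity, field = field, message = message,
    evidence = list(evidence)
  )
}

no_findings <- function() {
  tibble::tibble(
    check_id = character(), severity = character(), field = character(),
    message = character(), evidence = list()
  )
}

#' Validate a prescription against its protocol registry
#'
#' Cross-checks the order against the registry row for its protocol and
#' returns machine-readable findings. The blocking checks target the
#' wrong-worksheet class of error: a dose rate above the protocol ceiling,
#' or parameters (separation, dose per field) sitting in another age
#' class's range, e.g. an adult patient calculated on a pediatric
#' worksheet.
#'
#' @param rx A [prescription()].
#' @param registry Protocol registry tibble (default [default_protocols()]).
#' @return A tibble of findings (columns `check_id`, `severity`, `field`,
#'   `message`, `evidence`); zero rows when fully conformant.
#' @export
validate_prescription <- function(rx, registry = default_protocols()) {
  row <- registry[registry$protocol == rx$protocol, ]
  if (nrow(row) != 1) {
    tbi_abort(paste0("unknown protocol: ", rx$protocol), "tbi_validation_error")
  }
  out <- no_findings()
  if (rx$max_dose_rate > row$dose_rate_ceiling) {
    out <- dplyr::bind_rows(out, finding(
      "rx_dose_rate_ceiling", "block", "max_dose_rate",
      glue::glue("max dose rate {rx$max_dose_rate} cGy/min exceeds the ",
                 "{rx$protocol} ceiling of {row$dose_rate_ceiling} cGy/min"),
      list(value = rx$max_dose_rate, ceiling = row$dose_rate_ceiling)
    ))
  }
  if (rx$separation < row$sep_min || rx$separation >= row$sep_max) {
    other <- registry[registry$age_class != row$age_class &
                        rx$separation >= registry$sep_min &
                        rx$separation < registry$sep_max, ]
    msg <- if (nrow(other) > 0) {
      glue::glue("separation {rx$separation} cm is in the ",
                 "{other$age_class[1]} range: likely wrong worksheet ",
                 "({rx$protocol} used for a {other$age_class[1]} patient)")
    } else {
      glue::glue("separation {rx$separation} cm outside the {rx$protocol} ",
                 "range [{row$sep_min}, {row$sep_max})")
    }
    out <- dplyr::bind_rows(out, finding(
      "rx_separation_range", "block", "separation", msg,
      list(value = rx$separation, range = c(row$sep_min, row$sep_max))
    ))
  }
  if (rx$dose_per_field < row$dose_min || rx$dose_per_field > row$dose_max) {
    out <- dplyr::bind_rows(out, finding(
      "rx_dose_range", "block", "dose_per_field",
      glue::glue("dose per field {rx$dose_per_field} cGy outside the ",
                 "{rx$protocol} range [{row$dose_min}, {row$dose_max}] cGy"),
      list(value = rx$dose_per_field, range = c(row$dose_min, row$dose_max))
    ))
  }
  if (rx$num_fractions < row$fx_min || rx$num_fractions > row$fx_max) {
    out <- dplyr::bind_rows(out, finding(
      "rx_fractions_range", "warn", "num_fractions",
      glue::glue("{rx$num_fractions} fractions outside the usual ",
                 "{rx$protocol} range [{row$fx_min}, {row$fx_max}]"),
      list(value = rx$num_fractions)
    ))
  }
  out
}
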
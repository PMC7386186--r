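#' Date-based plan name with collision suffixes
#'
#' Plans are named `TBI_MM-YYYY` after the month the builder runs; if that
#' name is taken, the smallest positive numeric suffix not already in use
#' is appended (`TBI_07-2019-1`, `TBI_07-2019-2`, ...), so repeated
#' same-day runs never collide.
#'
#' @param today A `Date`.
#' @param existing_names Character vector (or set) of names already in the
#'   course.
#' @return The chosen plan name.
#' @examples
#' make_plan_name(as.Date("2019-07-15"), character())  # "TBI_07-2019"
#' @export
make_plan_name <- function(today, existing_names = character()) {
  base <- format(as.Date(today), "TBI_%m-%Y")
  if (!base %in% existing_names) {
    return(base)
  }
  k <- 1
  while (paste0(base, "-", k) %in% existing_names) {
    k <- k + 1
  }
  paste0(base, "-", k)
}

#' Default field-geometry presets
#'
#' Gantry angles, SSD, field size and machine name applied to each
#' arrangement's fields. These are configuration, not constants: a clinic
#' supplies its own presets and they are validated at build time.
#'
#' @param ssd Treatment SSD per field, cm.
#' @param field_size Collimator setting, cm (x, y).
#' @param machine Treatment machine name stamped into exports.
#' @return A presets list.
#' @export
default_presets <- function(ssd = 500, field_size = c(40, 40),
                            machine = "TrueBeam") {
  list(
    arrangements = list(
      "AP/PA" = tibble::tibble(name = c("AP", "PA"), gantry = c(270, 90)),
      "RLat/LLat" = tibble::tibble(name = c("RLat", "LLat"), gantry = c(270, 90))
    ),
    ssd = ssd, field_size = field_size, machine = machine,
    phantom = list(side = 40, body_contour = TRUE)
  )
}

#' Mock dose state for MU setting
#'
#' Stand-in for the planning system's placeholder dose calculation (whose
#' distribution is irrelevant for treatment): each field has a base MU
#' response at the reference point, and the delivered MU obey
#' `delivered_i = base_i * weight_i * (100 / normalization)`.
#'
#' @param base_mu Positive numeric vector, one base MU per field.
#' @return A `mock_dose_state` object.
#' @export
mock_dose_state <- function(base_mu) {
  if (any(!is.finite(base_mu)) || any(base_mu <= 0)) {
    tbi_abort("base MU must be positive", "tbi_validation_error")
  }
  structure(list(base_mu = as.numeric(base_mu)), class = "mock_dose_state")
}

#' Set per-field MU via plan normalization and field weights
#'
#' Inverts the mock dose model so every field delivers its target MU:
#' weights are scaled so the hottest field has weight 1 and the plan
#' normalization absorbs the remaining global factor. The forward model
#' `base_i * weight_i * 100 / normalization` then reproduces every target
#' exactly (to rounding of delivered MU at whole units).
#'
#' @param state A [mock_dose_state()].
#' @param targets Target MU per field (all >= 1).
#' @param weight_min Smallest admissible field weight.
#' @param norm_range Admissible plan-normalization range, percent.
#' @return List with `normalization` (percent), `weights`, and
#'   `delivered_mu` (forward-model check, rounded to whole MU).
#' @export
set_field_mu <- function(state, targets, weight_min = 0.001,
                         norm_range = c(0.5, 2000)) {
  base <- state$base_mu
  if (length(targets) != length(base)) {
    tbi_abort("one target MU required per field", "tbi_validation_error")
  }
  if (any(targets < 1)) {
    tbi_abort("target MU must be >= 1", "tbi_validation_error")
  }
  normalization <- 100 * min(base / targets)
  if (normalization < norm_range[1] || normalization > norm_range[2]) {
    tbi_abort(
      glue::glue("required normalization {signif(normalization, 4)}% outside ",
                 "admissible range [{norm_range[1]}, {norm_range[2]}]"),
      "tbi_unattainable_error"
    )
  }
  weights <- targets * normalization / (100 * base)
  if (any(weights < weight_min)) {
    tbi_abort("target spread needs a field weight below the admissible minimum",
              "tbi_unattainable_error")
  }
  delivered <- base * weights * (100 / normalization)
  list(normalization = normalization, weights = weights,
       delivered_mu = round_half_up(delivered))
}

#' Build a complete TBI plan from a prescription and calculation
#'
#' Pure construction of the plan object the automated workflow would push
#' into the planning system: a cubic water phantom with a body contour,
#' date-based course/plan names with collision suffixes, reference points
#' whose limits derive from the prescription, one static `TOTAL`-technique
#' field per arrangement member at the preset gantry/SSD/field size, and
#' per-field MU and dose rate from the calculation, applied through the
#' normalization/field-weight inversion. Deterministic given its inputs;
#' never mutates the prescription or calculation.
#'
#' @param rx A [prescription()].
#' @param calc A `calc_result` from [compute_mu()].
#' @param presets Field-geometry presets ([default_presets()]).
#' @param today Build date (injected for reproducibility).
#' @param existing_names Plan names already present in the course.
#' @return A `tbi_plan` object.
#' @export
build_plan <- function(rx, calc, presets = default_presets(),
                       today = Sys.Date(), existing_names = character()) {
  arr <- presets$arrangements[[rx$arrangement]]
  if (is.null(arr)) {
    tbi_abort(paste0("no geometry preset for arrangement ", rx$arrangement),
              "tbi_config_error")
  }
  n <- nrow(arr)
  targets <- rep(calc$mu_per_field, n)  # equally weighted opposed fields
  state <- mock_dose_state(rep(100, n))
  mu_set <- set_field_mu(state, targets)
  fields <- tibble::tibble(
    name = arr$name,
    technique = "TOTAL",
    gantry = arr$gantry,
    field_size_x = presets$field_size[1],
    field_size_y = presets$field_size[2],
    ssd = presets$ssd,
    energy = calc$energy,
    mu = targets,
    dose_rate = calc$machine_dose_rate,
    weight = mu_set$weights
  )
  daily <- rx$dose_per_field * n
  ref_points <- tibble::tibble(
    name = "TBI midplane",
    session_limit = daily,
    daily_limit = daily,
    total_limit = daily * rx$num_fractions
  )
  plan_name <- make_plan_name(today, existing_names)
  plan <- structure(
    list(
      course_name = format(as.Date(today), "TBI_%m-%Y"),
      plan_name = plan_name,
      patient_id = rx$patient_id,
      patient_name = rx$patient_name,
      phantom = presets$phantom,
      machine = presets$machine,
      reference_points = ref_points,
      fields = fields,
      normalization = mu_set$normalization,
      num_fractions = rx$num_fractions,
      created = as.Date(today)
    ),
    class = "tbi_plan"
  )
  validate_plan(plan)
  plan
}

validate_plan <- function(plan) {
  if (!inherits(plan, "tbi_plan")) {
    tbi_abort("not a tbi_plan", "tbi_validation_error")
  }
  f <- plan$fields
  if (is.null(f) || nrow(f) == 0) {
    tbi_abort("plan must contain at least one field", "tbi_validation_error")
  }
  if (any(f$technique != "TOTAL")) {
    tbi_abort("every field must carry the TOTAL technique", "tbi_validation_error")
  }
  if (any(f$mu < 1)) {
    tbi_abort("field MU must be >= 1", "tbi_validation_error")
  }
  rp <- plan$reference_points
  if (any(rp$session_limit > rp$daily_limit) ||
      any(rp$daily_limit > rp$total_limit)) {
    tbi_abort("reference point limits must satisfy session <= daily <= total",
              "tbi_validation_error")
  }
  invisible(plan)
}

#' @export
print.tbi_plan <- function(x, ...) {
  cat("<tbi_plan>", x$course_name, "/", x$plan_name, "\n")
  cat("  patient:", x$patient_name, paste0("(", x$patient_id, ")"), "\n")
  cat(sprintf("  %d field(s), normalization %.4g%%\n",
              nrow(x$fields), x$normalization))
  print(x$fields[, c("name", "gantry", "energy", "mu", "dose_rate", "weight")])
  invisible(x)
}

#' Tidy the fields of a plan
#'
#' @param x A `tbi_plan`.
#' @param ... Unused.
#' @return The plan's field table as a tibble.
#' @export
tidy.tbi_plan <- function(x, ...) x$fields

#' @export
glance.tbi_plan <- function(x, ...) {
  tibble::tibble(
    course_name = x$course_name, plan_name = x$plan_name,
    n_fields = nrow(x$fields), total_mu = sum(x$fields$mu),
    normalization = x$normalization, created = x$created
  )
}

#' Export / import a plan
#'
#' JSON export round-trips losslessly through [read_plan_json()]. DICOM
#' export writes a minimal RT Plan object (see [dicom_write_rtplan()]).
#'
#' @param plan A `tbi_plan`.
#' @param path Output path.
#' @param format `"json"` or `"dicom"`.
#' @return `path`, invisibly.
#' @export
export_plan <- function(plan, path, format = c("json", "dicom")) {
  format <- match.arg(format)
  validate_plan(plan)
  if (format == "json") {
    payload <- unclass(plan)
    payload$created <- format(plan$created, "%Y-%m-%d")
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "rows")
  } else {
    dicom_write_rtplan(plan, path)
  }
  invisible(path)
}

#' @rdname export_plan
#' @export
read_plan_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$created <- as.Date(payload$created)
  payload$fields <- tibble::as_tibble(payload$fields)
  for (col in c("gantry", "field_size_x", "field_size_y", "ssd", "mu",
                "dose_rate", "weight")) {
    payload$fields[[col]] <- as.numeric(payload$fields[[col]])
  }
  payload$normalization <- as.numeric(payload$normalization)
  payload$reference_points <- tibble::as_tibble(payload$reference_points)
  payload$field_size <- NULL
  plan <- structure(payload, class = "tbi_plan")
  validate_plan(plan)
  plan
}
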
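#' Pre-treatment check battery
#'
#' Mechanizes the error modes that manual TBI planning historically
#' produced and that human physics/therapist checks had to catch:
#'
#' * `ids_match` — patient name/MRN agree across plan, prescription and
#'   worksheet (catches a wrong patient name in the plan document);
#' * `field_labels` — field names unique and exactly the arrangement's
#'   members (catches every field labelled "LLat");
#' * prescription/protocol consistency via [validate_prescription()]
#'   (catches an adult calculated on a pediatric worksheet);
#' * `mu_independent` — monitor units and every factor re-derived by the
#'   independent naive oracle ([recompute_naive()]), never by the engine
#'   that produced them (catches 531 MU entered instead of 231, a wrong
#'   separation transcribed, or a spoiler factor taken from the wrong
#'   energy's table);
#' * `dose_rate` — the per-field rate is a deliverable ladder member,
#'   uniform across fields, within the prescription limit at the
#'   prescription point, and maximal-feasible (catches a stale dose rate
#'   after a replan for a backup machine, or one field of two set wrong);
#' * `energy_lookup` — field energy equals the separation-table selection
#'   (catches an energy set incorrectly in the TPS);
#' * `geometry` — gantry angles and field size match the validated presets
#'   (catches 270 degrees set instead of 90, or a wrong field size);
#' * `worksheet_present` — the calculation document exists and its numbers
#'   match the plan (catches a missing calculation document).
#'
#' Findings are returned, never thrown; severity `"block"` marks anything
#' with mistreatment potential. In strict mode the CLI refuses to export
#' while blockers exist.
#'
#' @param plan A `tbi_plan`.
#' @param rx The [prescription()] the plan claims to implement.
#' @param calc The `calc_result` the plan was built from.
#' @param beam_data The `beam_data_set` in force.
#' @param worksheet Path to the rendered markdown worksheet, or `NULL` if
#'   none was attached.
#' @param presets Geometry presets the plan should follow.
#' @param registry Protocol registry for prescription validation.
#' @return Tibble of findings (`check_id`, `severity`, `field`, `message`,
#'   `evidence`); zero rows when everything is consistent.
#' @export
run_checks <- function(plan, rx, calc, beam_data, worksheet = NULL,
                       presets = default_presets(),
                       registry = default_protocols()) {
  out <- no_findings()
  add <- function(...) {
    out <<- dplyr::bind_rows(out, finding(...))
  }
  oracle <- recompute_naive(beam_data, rx)

  # (a) identifiers
  if (!identical(plan$patient_id, rx$patient_id)) {
    add("ids_match", "block", "patient_id",
        glue::glue("plan MRN '{plan$patient_id}' != prescription MRN '{rx$patient_id}'"),
        list(plan = plan$patient_id, rx = rx$patient_id))
  }
  if (!identical(plan$patient_name, rx$patient_name)) {
    add("ids_match", "block", "patient_name",
        glue::glue("plan patient '{plan$patient_name}' != prescription patient '{rx$patient_name}'"),
        list(plan = plan$patient_name, rx = rx$patient_name))
  }

  # (b) field labels
  expected_names <- tbi_arrangements[[rx$arrangement]]
  if (anyDuplicated(plan$fields$name) > 0) {
    add("field_labels", "block", "fields",
        paste0("duplicate field labels: ",
               paste(plan$fields$name, collapse = ", ")),
        list(names = plan$fields$name))
  } else if (!setequal(plan$fields$name, expected_names)) {
    add("field_labels", "block", "fields",
        glue::glue("field labels ({paste(plan$fields$name, collapse = ', ')}) ",
                   "do not match arrangement {rx$arrangement}"),
        list(names = plan$fields$name, expected = expected_names))
  }

  # (c) prescription vs protocol registry
  out <- dplyr::bind_rows(out, validate_prescription(rx, registry))

  # (d) independent MU recomputation
  for (fct in c("isf", "sc", "sp", "tmr", "spoiler", "muscle")) {
    got <- calc$factors[[fct]]
    want <- oracle$factors[[fct]]
    if (abs(got - want) > 1e-9 * max(abs(want), 1)) {
      add("mu_independent", "block", fct,
          glue::glue("factor {fct} = {signif(got, 6)} disagrees with the ",
                     "independent lookup {signif(want, 6)}"),
          list(calc = got, oracle = want))
    }
  }
  for (i in seq_len(nrow(plan$fields))) {
    if (plan$fields$mu[i] != oracle$mu_per_field) {
      add("mu_independent", "block", paste0("fields[", plan$fields$name[i], "].mu"),
          glue::glue("field '{plan$fields$name[i]}' has {plan$fields$mu[i]} MU; ",
                     "independent recomputation gives {oracle$mu_per_field} MU"),
          list(plan = plan$fields$mu[i], oracle = oracle$mu_per_field))
    }
  }

  # (e) dose rate: deliverable, uniform, feasible, maximal
  rates <- plan$fields$dose_rate
  if (length(unique(rates)) > 1) {
    add("dose_rate", "block", "fields",
        paste0("dose rate differs between fields: ",
               paste(rates, collapse = ", ")),
        list(rates = rates))
  }
  for (i in seq_along(rates)) {
    fld <- plan$fields$name[i]
    if (!rates[i] %in% beam_data$dose_rates) {
      add("dose_rate", "block", paste0("fields[", fld, "].dose_rate"),
          glue::glue("dose rate {rates[i]} MU/min is not deliverable on this ",
                     "machine (ladder: {paste(beam_data$dose_rates, collapse = ', ')})"),
          list(rate = rates[i], ladder = beam_data$dose_rates))
    } else if (rates[i] * oracle$dose_per_mu > rx$max_dose_rate) {
      add("dose_rate", "block", paste0("fields[", fld, "].dose_rate"),
          glue::glue("dose rate {rates[i]} MU/min gives ",
                     "{signif(rates[i] * oracle$dose_per_mu, 4)} cGy/min at the ",
                     "prescription point, above the limit {rx$max_dose_rate} cGy/min"),
          list(rate = rates[i], achieved = rates[i] * oracle$dose_per_mu,
               limit = rx$max_dose_rate))
    } else if (!is.na(oracle$machine_dose_rate) &&
               rates[i] < oracle$machine_dose_rate) {
      add("dose_rate", "warn", paste0("fields[", fld, "].dose_rate"),
          glue::glue("dose rate {rates[i]} MU/min is feasible but below the ",
                     "maximal feasible {oracle$machine_dose_rate} MU/min ",
                     "(longer beam-on time than necessary)"),
          list(rate = rates[i], maximal = oracle$machine_dose_rate))
    }
  }

  # (f) energy vs separation lookup
  for (i in seq_len(nrow(plan$fields))) {
    if (plan$fields$energy[i] != oracle$energy) {
      add("energy_lookup", "block",
          paste0("fields[", plan$fields$name[i], "].energy"),
          glue::glue("field '{plan$fields$name[i]}' uses {plan$fields$energy[i]}; ",
                     "separation {rx$separation} cm selects {oracle$energy}"),
          list(plan = plan$fields$energy[i], oracle = oracle$energy))
    }
  }

  # (g) geometry vs presets
  preset_arr <- presets$arrangements[[rx$arrangement]]
  for (i in seq_len(nrow(plan$fields))) {
    fld <- plan$fields$name[i]
    want_gantry <- preset_arr$gantry[match(fld, preset_arr$name)]
    if (!is.na(want_gantry) && plan$fields$gantry[i] != want_gantry) {
      add("geometry", "block", paste0("fields[", fld, "].gantry"),
          glue::glue("field '{fld}' gantry {plan$fields$gantry[i]} deg; ",
                     "preset requires {want_gantry} deg"),
          list(plan = plan$fields$gantry[i], preset = want_gantry))
    }
    sizes <- c(plan$fields$field_size_x[i], plan$fields$field_size_y[i])
    if (!all(sizes == presets$field_size)) {
      add("geometry", "block", paste0("fields[", fld, "].field_size"),
          glue::glue("field '{fld}' size {sizes[1]} x {sizes[2]} cm; preset ",
                     "requires {presets$field_size[1]} x {presets$field_size[2]} cm"),
          list(plan = sizes, preset = presets$field_size))
    }
  }

  # (h) worksheet attached and consistent
  if (is.null(worksheet) || !file.exists(worksheet %||% "")) {
    add("worksheet_present", "block", "worksheet",
        "calculation worksheet missing from the record", list())
  } else {
    ws <- parse_worksheet(worksheet)
    if (!identical(ws$patient_name, plan$patient_name) ||
        !identical(ws$patient_id, plan$patient_id)) {
      add("ids_match", "block", "worksheet",
          glue::glue("worksheet is for '{ws$patient_name}' ({ws$patient_id}); ",
                     "plan is for '{plan$patient_name}' ({plan$patient_id})"),
          list(worksheet = ws[c("patient_name", "patient_id")],
               plan = list(patient_name = plan$patient_name,
                           patient_id = plan$patient_id)))
    }
    if (!is.null(ws$mu_per_field) &&
        any(plan$fields$mu != ws$mu_per_field)) {
      add("worksheet_present", "block", "worksheet",
          glue::glue("worksheet documents {ws$mu_per_field} MU/field; plan ",
                     "fields carry {paste(unique(plan$fields$mu), collapse = ', ')}"),
          list(worksheet = ws$mu_per_field, plan = plan$fields$mu))
    }
  }

  out
}

#' Does a findings table contain blockers?
#'
#' @param findings Tibble from [run_checks()] / [validate_prescription()].
#' @return `TRUE` if any finding has severity `"block"`.
#' @export
has_blockers <- function(findings) {
  nrow(findings) > 0 && any(findings$severity == "block")
}
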
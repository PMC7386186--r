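worksheet_numeric_fields <- c(
  "dose_per_field_cGy", "num_fractions", "separation_cm",
  "max_dose_rate_cGy_min", "depth_cm", "distance_to_point_cm",
  "isf", "sc", "sp", "tmr", "spoiler", "muscle", "dose_per_mu_cGy",
  "mu_per_field", "machine_dose_rate_mu_min", "achieved_dose_rate_cGy_min"
)

worksheet_fields <- function(rx, calc, operator, generated) {
  fb <- calc$factors
  list(
    patient_name = rx$patient_name,
    patient_id = rx$patient_id,
    protocol = rx$protocol,
    dose_per_field_cGy = rx$dose_per_field,
    num_fractions = rx$num_fractions,
    separation_cm = rx$separation,
    max_dose_rate_cGy_min = rx$max_dose_rate,
    arrangement = rx$arrangement,
    energy = calc$energy,
    depth_cm = calc$depth,
    distance_to_point_cm = calc$distance_to_point,
    isf = fb$isf, sc = fb$sc, sp = fb$sp, tmr = fb$tmr,
    spoiler = fb$spoiler, muscle = fb$muscle,
    dose_per_mu_cGy = fb$dose_per_mu,
    mu_per_field = calc$mu_per_field,
    machine_dose_rate_mu_min = calc$machine_dose_rate,
    achieved_dose_rate_cGy_min = calc$achieved_dose_rate,
    beam_data_version = calc$beam_data_version,
    beam_data_checksum = calc$beam_data_checksum,
    generated = format(as.Date(generated), "%Y-%m-%d"),
    operator = operator
  )
}

ws_num <- function(x) {
  if (is.numeric(x)) formatC(x, format = "g", digits = 17) else as.character(x)
}

#' Render the patient calculation worksheet
#'
#' Writes the hand-calculation worksheet that accompanies the plan into
#' the record: patient identifiers, the prescription echo, the complete
#' factor breakdown, MU and dose rate per field, and the beam-data
#' version/checksum audit trail. Every number is serialized directly from
#' the calculation result at full precision — nothing is retyped or
#' reformatted by hand, which is precisely the transcription step the
#' automated workflow exists to remove. Markdown renders are exactly
#' invertible via [parse_worksheet()]; the PDF render typesets the same
#' lines.
#'
#' @param rx A [prescription()]; must carry non-empty `patient_id` and
#'   `patient_name`.
#' @param calc The `calc_result` produced from this prescription.
#' @param path Output path.
#' @param format `"markdown"` or `"pdf"`.
#' @param operator Operator identifier recorded on the sheet.
#' @param generated Generation date (injected for reproducibility).
#' @return `path`, invisibly.
#' @export
render_worksheet <- function(rx, calc, path, format = c("markdown", "pdf"),
                             operator = "autoplan", generated = Sys.Date()) {
  format <- match.arg(format)
  if (!nzchar(rx$patient_id) || !nzchar(rx$patient_name)) {
    tbi_abort("patient_id and patient_name are required on the worksheet",
              "tbi_validation_error")
  }
  fields <- worksheet_fields(rx, calc, operator, generated)
  lines <- c(
    "# TBI Monitor-Unit Calculation Worksheet",
    "",
    purrr::imap_chr(fields, function(v, k) paste0("- ", k, ": ", ws_num(v)))
  )
  if (format == "markdown") {
    writeLines(lines, path)
  } else {
    grDevices::pdf(path, width = 8.5, height = 11)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(1, 1, 1, 1))
    graphics::plot.new()
    graphics::text(0, seq(1, 0, length.out = length(lines)), lines,
                   adj = c(0, 1), family = "mono", cex = 0.8)
  }
  invisible(path)
}

#' Parse a markdown worksheet back into its fields
#'
#' Inverse of the markdown render: recovers every field with numeric
#' fields restored as numbers (full-precision round trip).
#'
#' @param path Path to a markdown worksheet.
#' @return Named list of worksheet fields.
#' @export
parse_worksheet <- function(path) {
  lines <- readLines(path)
  entries <- stringr::str_match(lines, "^- ([a-zA-Z0-9_]+): (.*)$")
  entries <- entries[!is.na(entries[, 1]), , drop = FALSE]
  out <- as.list(entries[, 3])
  names(out) <- entries[, 2]
  for (k in intersect(names(out), worksheet_numeric_fields)) {
    out[[k]] <- as.numeric(out[[k]])
  }
  out
}
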
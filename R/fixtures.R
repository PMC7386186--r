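#' Write the bundled demo inputs
#'
#' Materializes a complete demo input set into a directory: a synthetic
#' beam-data master (YAML + CSV tables, via [generate_beam_fixture()]), a
#' demo prescription, and the reference incident CSV (35 TBI reports whose
#' category/classification marginals match the bundled audit counts, see
#' [ils_reference_counts()]). Deterministic for a fixed seed.
#'
#' @param dir Output directory.
#' @param seed Seed for the synthetic beam data.
#' @param n_energies Energies in the synthetic machine.
#' @return Named character vector of the paths written.
#' @export
write_demo_inputs <- function(dir, seed = 2019, n_energies = 3) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bd_dir <- file.path(dir, "beamdata")
  if (!dir.exists(bd_dir)) dir.create(bd_dir)
  bd_path <- file.path(bd_dir, "machine.yaml")
  save_beam_data(generate_beam_fixture(seed, n_energies), bd_path)

  rx_path <- file.path(dir, "demo_rx.yaml")
  yaml::write_yaml(list(
    protocol = "standard_adult", dose_per_field = 75, num_fractions = 8,
    separation = 36, max_dose_rate = 10, arrangement = "AP/PA",
    patient_id = "MRN0001", patient_name = "DEMO^PATIENT"
  ), rx_path)

  ils_path <- file.path(dir, "ils_tbi_reports.csv")
  utils::write.csv(reference_incident_reports(), ils_path, row.names = FALSE)
  c(beam_data = bd_path, prescription = rx_path, incidents = ils_path)
}

#' The 35-report reference incident table
#'
#' One row per TBI report of the bundled audit: 11 treatment, 12
#' documentation and 12 field-issue reports; 17 operational/workflow, 11
#' unsafe-condition and 7 near-miss classifications; the 24
#' planning-related reports are the documentation and field-issue rows.
#' Dates cycle deterministically through the 25 pre-automation quarters
#' (2013Q1-2019Q1).
#'
#' @return Tibble of 35 incident reports.
#' @export
reference_incident_reports <- function() {
  counts <- ils_reference_counts()
  # joint category x classification assignment consistent with the marginals
  cells <- tibble::tribble(
    ~category,       ~classification,        ~n,
    "treatment",     "operational_workflow",  6,
    "treatment",     "unsafe_condition",      3,
    "treatment",     "near_miss",             2,
    "documentation", "operational_workflow",  6,
    "documentation", "unsafe_condition",      4,
    "documentation", "near_miss",             2,
    "field_issue",   "operational_workflow",  5,
    "field_issue",   "unsafe_condition",      4,
    "field_issue",   "near_miss",             3
  )
  stopifnot(sum(cells$n) == counts$reports_tbi)
  reports <- tidyr::uncount(cells, .data$n)
  quarters <- seq(as.Date("2013-01-01"), as.Date("2019-01-01"),
                  by = "3 months")
  idx <- (seq_len(nrow(reports)) - 1) %% length(quarters) + 1
  reports$report_date <- quarters[idx] + 40
  reports$treatment_type <- "TBI"
  reports$planning_related <- reports$category %in%
    c("documentation", "field_issue")
  tibble::as_tibble(
    reports[c("report_date", "treatment_type", "category", "classification",
              "planning_related")]
  )
}
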
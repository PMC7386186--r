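# Shared fixtures: everything is generated in code at test time.

demo_beam_data <- function(seed = 7, n_energies = 3) {
  generate_beam_fixture(seed, n_energies)
}

demo_rx <- function(separation = 36, dose = 75, max_dr = 10,
                    protocol = "standard_adult", arrangement = "AP/PA",
                    id = "MRN0001", name = "DOE^JANE") {
  prescription(protocol, dose, 8, separation, max_dr, arrangement,
               patient_id = id, patient_name = name)
}

# A fully consistent pipeline context: beam data, prescription,
# calculation, plan and rendered worksheet.
clean_context <- function(seed = 7) {
  bd <- demo_beam_data(seed)
  rx <- demo_rx()
  calc <- compute_mu(bd, rx)
  plan <- build_plan(rx, calc, today = as.Date("2019-07-01"))
  ws <- tempfile(fileext = ".md")
  render_worksheet(rx, calc, ws, "markdown", generated = as.Date("2019-07-01"))
  list(bd = bd, rx = rx, calc = calc, plan = plan, ws = ws)
}

# Seeded random prescriptions within the fixture's tabulated ranges.
random_cases <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    separation = stats::runif(n, 4, 56),
    dose = stats::runif(n, 50, 250),
    max_dr = sample(c(5, 8, 10, 15), n, replace = TRUE),
    arrangement = sample(c("AP/PA", "RLat/LLat"), n, replace = TRUE)
  ))
}

case_rx <- function(case) {
  prescription("standard_adult", case$dose, 8, case$separation, case$max_dr,
               case$arrangement, patient_id = "MRN-X", patient_name = "X^Y")
}
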
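# Thirteen manual-planning error scenarios, one per historically reported
# root error. Each scenario perturbs a clean pipeline context and states
# which check must fire (with blocking severity). Used by the safety-report
# tests and the acceptance suite.
#
# Each entry is a function(ctx) returning list(args = <run_checks args>,
# expect = <check_id>).
table1_scenarios <- function() {
  list(
    wrong_patient_name_in_document = function(ctx) {
      rx_bad <- ctx$rx
      rx_bad$patient_name <- "WRONG^PATIENT"
      ws_bad <- tempfile(fileext = ".md")
      render_worksheet(rx_bad, ctx$calc, ws_bad, "markdown",
                       generated = as.Date("2019-07-01"))
      list(args = list(ctx$plan, ctx$rx, ctx$calc, ctx$bd, worksheet = ws_bad),
           expect = "ids_match")
    },
    all_fields_labelled_llat = function(ctx) {
      plan <- ctx$plan
      plan$fields$name <- rep("LLat", nrow(plan$fields))
      list(args = list(plan, ctx$rx, ctx$calc, ctx$bd, worksheet = ctx$ws),
           expect = "field_labels")
    },
    missing_calculation_document = function(ctx) {
      list(args = list(ctx$plan, ctx$rx, ctx$calc, ctx$bd, worksheet = NULL),
           expect = "worksheet_present")
    },
    adult_on_pediatric_worksheet = function(ctx) {
      # adult-sized separation ordered under the pediatric protocol
      rx_bad <- demo_rx(protocol = "standard_pediatric")
      calc <- compute_mu(ctx$bd, rx_bad)
      plan <- build_plan(rx_bad, calc, today = as.Date("2019-07-01"))
      ws <- tempfile(fileext = ".md")
      render_worksheet(rx_bad, calc, ws, "markdown",
                       generated = as.Date("2019-07-01"))
      list(args = list(plan, rx_bad, calc, ctx$bd, worksheet = ws),
           expect = "rx_separation_range")
    },
    pediatric_low_dose_rate_ignored = function(ctx) {
      # pediatric order limited to 2 cGy/min; fields left at a high rate
      rx_ped <- demo_rx(separation = 20, dose = 60, max_dr = 5,
                        protocol = "standard_pediatric")
      calc <- compute_mu(ctx$bd, rx_ped)
      plan <- build_plan(rx_ped, calc, today = as.Date("2019-07-01"))
      ws <- tempfile(fileext = ".md")
      render_worksheet(rx_ped, calc, ws, "markdown",
                       generated = as.Date("2019-07-01"))
      plan$fields$dose_rate <- 600
      list(args = list(plan, rx_ped, calc, ctx$bd, worksheet = ws),
           expect = "dose_rate")
    },
    gantry_270_instead_of_90 = function(ctx) {
      plan <- ctx$plan
      plan$fields$gantry[2] <- 270
      list(args = list(plan, ctx$rx, ctx$calc, ctx$bd, worksheet = ctx$ws),
           expect = "geometry")
    },
    wrong_field_size = function(ctx) {
      plan <- ctx$plan
      plan$fields$field_size_x[1] <- 30
      list(args = list(plan, ctx$rx, ctx$calc, ctx$bd, worksheet = ctx$ws),
           expect = "geometry")
    },
    separation_transcribed_incorrectly = function(ctx) {
      # calculation ran on 30 cm; the order says 36 cm
      rx_typo <- demo_rx(separation = 30)
      calc_bad <- compute_mu(ctx$bd, rx_typo)
      plan <- build_plan(ctx$rx, calc_bad, today = as.Date("2019-07-01"))
      list(args = list(plan, ctx$rx, calc_bad, ctx$bd, worksheet = ctx$ws),
           expect = "mu_independent")
    },
    mu_entered_incorrectly = function(ctx) {
      plan <- ctx$plan
      plan$fields$mu <- plan$fields$mu + 300  # e.g. 531 typed instead of 231
      list(args = list(plan, ctx$rx, ctx$calc, ctx$bd, worksheet = ctx$ws),
           expect = "mu_independent")
    },
    spoiler_factor_from_wrong_energy = function(ctx) {
      calc_bad <- ctx$calc
      wrong_energy <- setdiff(unique(ctx$bd$energy_selection$energy),
                              ctx$calc$energy)[1]
      calc_bad$factors$spoiler <- spoiler_factor(ctx$bd, wrong_energy)
      list(args = list(ctx$plan, ctx$rx, calc_bad, ctx$bd, worksheet = ctx$ws),
           expect = "mu_independent")
    },
    dose_rate_stale_after_backup_replan = function(ctx) {
      # replanned onto a backup machine with a different rate ladder;
      # the copied fields still carry the old machine's rate
      bd_backup <- beam_data_set(ctx$bd$geometry, ctx$bd$tables,
                                 ctx$bd$energy_selection,
                                 dose_rates = c(50, 150, 250, 350),
                                 version = "backup-machine")
      list(args = list(ctx$plan, ctx$rx, ctx$calc, bd_backup,
                       worksheet = ctx$ws),
           expect = "dose_rate")
    },
    dose_rate_wrong_for_one_field = function(ctx) {
      plan <- ctx$plan
      plan$fields$dose_rate[2] <- ctx$bd$dose_rates[1]
      list(args = list(plan, ctx$rx, ctx$calc, ctx$bd, worksheet = ctx$ws),
           expect = "dose_rate")
    },
    energy_set_incorrectly_in_tps = function(ctx) {
      plan <- ctx$plan
      wrong_energy <- setdiff(unique(ctx$bd$energy_selection$energy),
                              ctx$calc$energy)[1]
      plan$fields$energy <- wrong_energy
      list(args = list(plan, ctx$rx, ctx$calc, ctx$bd, worksheet = ctx$ws),
           expect = "energy_lookup")
    }
  )
}

# Run every scenario; returns tibble(scenario, expected_fired (as block),
# n_block_or_warn).
run_table1_battery <- function(ctx = clean_context()) {
  purrr::imap_dfr(table1_scenarios(), function(scenario, nm) {
    sc <- scenario(ctx)
    findings <- do.call(run_checks, sc$args)
    hit <- findings[findings$check_id == sc$expect, ]
    tibble::tibble(
      scenario = nm,
      expected_fired = nrow(hit) > 0 && any(hit$severity == "block"),
      n_block_or_warn = sum(findings$severity %in% c("block", "warn"))
    )
  })
}
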
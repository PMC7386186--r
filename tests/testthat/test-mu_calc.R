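test_that("inverse square factor has its closed form and monotonicity", {
  geom <- machine_geometry()
  expect_identical(inverse_square_factor(geom, 0), 0.04)
  expect_equal(inverse_square_factor(geom, 40), (100 / 520)^2, tolerance = 1e-15)
  isf <- vapply(seq(0, 60, by = 1), function(s) inverse_square_factor(geom, s),
                numeric(1))
  expect_true(all(diff(isf) < 0))
  expect_error(inverse_square_factor(geom, -1), class = "tbi_domain_error")
})

unit_tables_bd <- function(spoiler = 1) {
  beam_data_set(
    machine_geometry(),
    dplyr::bind_rows(
      tibble::tibble(energy = "6X", kind = "TMR", abscissa = c(0.5, 40),
                     value = c(1, 1)),
      tibble::tibble(energy = "6X", kind = "Sc", abscissa = c(4, 45),
                     value = c(1, 1)),
      tibble::tibble(energy = "6X", kind = "Sp", abscissa = c(4, 45),
                     value = c(1, 1)),
      tibble::tibble(energy = "6X", kind = "spoiler", abscissa = 0,
                     value = spoiler)
    ),
    tibble::tibble(sep_min = 0, sep_max = 60, energy = "6X"),
    dose_rates = c(100, 200, 300, 400, 500, 600)
  )
}

test_that("dose per MU collapses to ISF x muscle when tables are unity", {
  rx <- demo_rx(separation = 2)
  fb <- dose_per_mu(unit_tables_bd(), rx)
  expect_identical(fb$dose_per_mu,
                   inverse_square_factor(machine_geometry(), 2) * 0.99)
  # multiplicative separability in the spoiler factor
  fb95 <- dose_per_mu(unit_tables_bd(spoiler = 0.95), rx)
  expect_identical(fb95$dose_per_mu, fb$dose_per_mu * 0.95)
  # product identity holds for a realistic fixture too
  fb2 <- dose_per_mu(demo_beam_data(), demo_rx())
  expect_equal(fb2$dose_per_mu,
               fb2$isf * fb2$sc * fb2$sp * fb2$tmr * fb2$spoiler * fb2$muscle,
               tolerance = 1e-15)
})

test_that("monitor units follow the half-up rounding contract", {
  expect_identical(round_half_up(200 / 1), 200)
  expect_identical(round_half_up(200 / 0.0396), 5051)  # 5050.50505...
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(1.5), 2)

  bd <- demo_beam_data()
  rx <- demo_rx()
  calc <- compute_mu(bd, rx)
  dpm <- calc$factors$dose_per_mu
  expect_identical(calc$mu_per_field, round_half_up(rx$dose_per_field / dpm))
  # MU x dose-per-MU reproduces the prescription within half an MU of dose
  expect_lte(abs(calc$mu_per_field * dpm - rx$dose_per_field), dpm / 2)
  expect_gte(calc$mu_per_field, 1)
})

test_that("an absurd MU result is refused by the sanity cap", {
  expect_error(compute_mu(demo_beam_data(), demo_rx(), mu_cap = 100),
               class = "tbi_sanity_cap_error")
})

test_that("engine output equals the independent naive recomputation", {
  bd <- demo_beam_data()
  dir <- withr::local_tempdir()
  master <- file.path(dir, "machine.yaml")
  save_beam_data(bd, master)
  cases <- random_cases(1000, seed = 101)
  for (i in seq_len(nrow(cases))) {
    rx <- case_rx(cases[i, ])
    calc <- compute_mu(bd, rx)
    oracle <- recompute_naive(bd, rx)
    expect_identical(calc$mu_per_field, oracle$mu_per_field)
    expect_lt(abs(calc$factors$dose_per_mu - oracle$dose_per_mu) /
                oracle$dose_per_mu, 1e-12)
    expect_identical(calc$energy, oracle$energy)
    expect_identical(calc$machine_dose_rate, oracle$machine_dose_rate)
  }
  # spot-check the file-reading oracle path against the in-memory one
  rx <- case_rx(cases[1, ])
  from_file <- recompute_naive(master, rx)
  expect_equal(recompute_naive(bd, rx)$dose_per_mu, from_file$dose_per_mu,
               tolerance = 1e-15)
})

test_that("dose-rate selection is feasible, maximal and inclusive", {
  bd <- unit_tables_bd()
  fb <- structure(list(dose_per_mu = 0.05), class = "factor_breakdown")
  bd$dose_rates <- c(100, 200, 300)
  rx <- demo_rx(max_dr = 10)
  dr <- compute_dose_rate(bd, rx, fb)
  expect_identical(dr$machine_dose_rate, 200)   # 300 x 0.05 = 15 > 10
  expect_identical(dr$achieved_dose_rate, 10)   # boundary is inclusive
  bd$dose_rates <- 400
  expect_error(compute_dose_rate(bd, rx, fb),
               class = "tbi_no_feasible_rate_error")
})

test_that("selected rate is maximal-feasible across 1000 seeded cases", {
  bd <- demo_beam_data()
  cases <- random_cases(1000, seed = 202)
  for (i in seq_len(nrow(cases))) {
    rx <- case_rx(cases[i, ])
    calc <- compute_mu(bd, rx)
    rate <- calc$machine_dose_rate
    dpm <- calc$factors$dose_per_mu
    expect_lte(rate * dpm, rx$max_dose_rate)
    higher <- bd$dose_rates[bd$dose_rates > rate]
    if (length(higher) > 0) {
      expect_gt(min(higher) * dpm, rx$max_dose_rate)
    }
  }
})

test_that("MU per field is non-decreasing in separation at fixed energy", {
  bd <- generate_beam_fixture(5, 1)  # one energy covers the whole range
  mus <- vapply(seq(4, 56, by = 2), function(s) {
    compute_mu(bd, demo_rx(separation = s))$mu_per_field
  }, numeric(1))
  expect_true(all(diff(mus) >= 0))
})

test_that("prescription validation catches protocol mismatches", {
  # adult-sized separation ordered on the pediatric protocol
  f <- validate_prescription(demo_rx(protocol = "standard_pediatric"))
  expect_true(any(f$check_id == "rx_separation_range" & f$severity == "block"))
  # dose rate above the protocol ceiling
  f <- validate_prescription(demo_rx(max_dr = 15))
  expect_true(any(f$check_id == "rx_dose_rate_ceiling" & f$severity == "block"))
  # same rate is fine under the high-dose-rate protocol
  f <- validate_prescription(demo_rx(max_dr = 15, protocol = "high_dose_rate_adult"))
  expect_identical(nrow(f), 0L)
  # fully conformant order
  expect_identical(nrow(validate_prescription(demo_rx())), 0L)
  expect_error(validate_prescription(demo_rx(protocol = "nonesuch")),
               class = "tbi_validation_error")
})

test_that("calculation results serialize to JSON and back bit-exactly", {
  calc <- compute_mu(demo_beam_data(), demo_rx())
  path <- file.path(withr::local_tempdir(), "calc.json")
  write_calc_result(calc, path)
  back <- read_calc_result(path)
  expect_identical(back$mu_per_field, calc$mu_per_field)
  expect_identical(back$factors$dose_per_mu, calc$factors$dose_per_mu)
  expect_identical(back$factors$tmr, calc$factors$tmr)
  expect_identical(back$beam_data_checksum, calc$beam_data_checksum)
})
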
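test_that("a minimal single-energy data set saves, loads and validates", {
  tmr <- tibble::tibble(energy = "6X", kind = "TMR",
                        abscissa = c(2, 5, 10, 20, 30),
                        value = c(1.0, 0.9, 0.75, 0.5, 0.33))
  extras <- dplyr::bind_rows(
    tibble::tibble(energy = "6X", kind = "Sc", abscissa = c(10, 40),
                   value = c(1.0, 1.03)),
    tibble::tibble(energy = "6X", kind = "Sp", abscissa = c(10, 40),
                   value = c(1.0, 1.05)),
    tibble::tibble(energy = "6X", kind = "spoiler", abscissa = 0, value = 0.98)
  )
  bd <- beam_data_set(
    machine_geometry(), dplyr::bind_rows(tmr, extras),
    tibble::tibble(sep_min = 0, sep_max = 60, energy = "6X"),
    dose_rates = c(100, 300), version = "mini-1"
  )
  expect_length(unique(bd$energy_selection$energy), 1)
  path <- file.path(withr::local_tempdir(), "machine.yaml")
  save_beam_data(bd, path)
  expect_s3_class(load_beam_data(path), "beam_data_set")
})

test_that("non-monotone table knots are rejected at load and construction", {
  expect_error(
    beam_data_set(
      machine_geometry(),
      tibble::tibble(energy = "6X", kind = "TMR",
                     abscissa = c(10, 5, 20), value = c(0.7, 0.9, 0.5)),
      tibble::tibble(sep_min = 0, sep_max = 60, energy = "6X"),
      dose_rates = 100
    ),
    class = "tbi_validation_error"
  )
  # same failure surfaced through the file loader
  dir <- withr::local_tempdir()
  path <- file.path(dir, "machine.yaml")
  save_beam_data(generate_beam_fixture(1, 1), path)
  csv <- file.path(dir, "6X_TMR.csv")
  rows <- readLines(csv)
  writeLines(c(rows[1], rows[c(4, 2, 3)], rows[-(1:4)]), csv)
  expect_error(load_beam_data(path), class = "tbi_validation_error")
})

test_that("save/load round trip reproduces the data set bit-exactly", {
  bd <- generate_beam_fixture(1, 2)
  path <- file.path(withr::local_tempdir(), "machine.yaml")
  save_beam_data(bd, path)
  bd2 <- load_beam_data(path)
  expect_identical(as.data.frame(bd2$tables), as.data.frame(bd$tables))
  expect_identical(unclass(bd2$geometry), unclass(bd$geometry))
  expect_identical(bd2$dose_rates, bd$dose_rates)
  expect_identical(bd2$checksum, bd$checksum)
})

test_that("a checksum mismatch is a hard integrity error", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "machine.yaml")
  save_beam_data(generate_beam_fixture(3, 2), path)
  master <- yaml::read_yaml(path)
  master$checksum <- paste0(rev(strsplit(master$checksum, "")[[1]]),
                            collapse = "")
  yaml::write_yaml(master, path)
  expect_error(load_beam_data(path), class = "tbi_integrity_error")
})

test_that("interpolation is linear between knots and exact on them", {
  bd <- beam_data_set(
    machine_geometry(),
    dplyr::bind_rows(
      tibble::tibble(energy = "6X", kind = "TMR", abscissa = c(10, 20),
                     value = c(0.80, 0.60)),
      tibble::tibble(energy = "6X", kind = "Sc", abscissa = c(10, 40),
                     value = c(1, 1.02)),
      tibble::tibble(energy = "6X", kind = "Sp", abscissa = c(10, 40),
                     value = c(1, 1.04)),
      tibble::tibble(energy = "6X", kind = "spoiler", abscissa = 0, value = 1)
    ),
    tibble::tibble(sep_min = 0, sep_max = 60, energy = "6X"),
    dose_rates = 100
  )
  expect_identical(interpolate_factor(bd, "6X", "TMR", 15), 0.70)
  expect_identical(interpolate_factor(bd, "6X", "TMR", 10), 0.80)
  expect_identical(interpolate_factor(bd, "6X", "TMR", 20), 0.60)
  expect_error(interpolate_factor(bd, "6X", "TMR", 41), class = "tbi_range_error")
  expect_error(interpolate_factor(bd, "6X", "TMR", 9.99), class = "tbi_range_error")
})

test_that("interpolation matches an independent piecewise-linear oracle", {
  bd <- generate_beam_fixture(11, 2)
  for (kind in c("TMR", "Sc", "Sp")) {
    tab <- bd$tables[bd$tables$energy == "10X" & bd$tables$kind == kind, ]
    xs <- withr::with_seed(42, stats::runif(1000, min(tab$abscissa),
                                            max(tab$abscissa)))
    got <- vapply(xs, function(x) interpolate_factor(bd, "10X", kind, x),
                  numeric(1))
    want <- stats::approx(tab$abscissa, tab$value, xout = xs,
                          ties = "ordered")$y
    expect_lt(max(abs(got - want) / abs(want)), 1e-12)
    # never overshoots the bracketing knots
    lo <- tab$value[findInterval(xs, tab$abscissa, rightmost.closed = TRUE)]
    hi <- tab$value[findInterval(xs, tab$abscissa, rightmost.closed = TRUE) + 1]
    expect_true(all(got >= pmin(lo, hi, na.rm = TRUE) - 1e-12 &
                      got <= pmax(lo, hi, na.rm = TRUE) + 1e-12))
  }
})

test_that("energy selection is half-open, total and a partition", {
  bd <- beam_data_set(
    machine_geometry(),
    dplyr::bind_rows(purrr::map_dfr(c("E1", "E2"), function(e) dplyr::bind_rows(
      tibble::tibble(energy = e, kind = "TMR", abscissa = c(1, 40),
                     value = c(1, 0.3)),
      tibble::tibble(energy = e, kind = "Sc", abscissa = c(4, 45), value = c(1, 1)),
      tibble::tibble(energy = e, kind = "Sp", abscissa = c(4, 45), value = c(1, 1)),
      tibble::tibble(energy = e, kind = "spoiler", abscissa = 0, value = 1)
    ))),
    tibble::tibble(sep_min = c(0, 30), sep_max = c(30, 60),
                   energy = c("E1", "E2")),
    dose_rates = 100
  )
  expect_identical(select_energy(bd, 30), "E2")     # boundary -> upper interval
  expect_identical(select_energy(bd, 29.999), "E1")
  expect_error(select_energy(bd, 60), class = "tbi_range_error")
  expect_error(select_energy(bd, -1), class = "tbi_range_error")
  # exhaustive sweep: every covered separation maps to exactly one energy
  grid <- seq(0, 59.9, by = 0.1)
  hits <- vapply(grid, function(s) {
    sum(s >= bd$energy_selection$sep_min & s < bd$energy_selection$sep_max)
  }, numeric(1))
  expect_true(all(hits == 1))
  labels <- vapply(grid, function(s) select_energy(bd, s), character(1))
  expect_identical(unique(labels), c("E1", "E2"))
})

test_that("fixture generation is reproducible, physical and self-valid", {
  a <- generate_beam_fixture(7, 3)
  b <- generate_beam_fixture(7, 3)
  expect_identical(a, b)
  expect_false(identical(a$checksum, generate_beam_fixture(8, 3)$checksum))
  for (e in unique(a$energy_selection$energy)) {
    tmr25 <- interpolate_factor(a, e, "TMR", 25)
    tmr10 <- interpolate_factor(a, e, "TMR", 10)
    expect_lt(tmr25, tmr10)
    # strictly decreasing beyond build-up
    tab <- a$tables[a$tables$energy == e & a$tables$kind == "TMR", ]
    beyond <- tab$value[tab$abscissa >= 4]
    expect_true(all(diff(beyond) < 0))
    expect_gt(spoiler_factor(a, e), 0.9)
    expect_lte(spoiler_factor(a, e), 1.1)
  }
  expect_s3_class(validate_beam_data(a), "beam_data_set")
})
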
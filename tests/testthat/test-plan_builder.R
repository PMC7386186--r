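test_that("plan names follow the date convention with collision suffixes", {
  d <- as.Date("2019-07-15")
  expect_identical(make_plan_name(d, character()), "TBI_07-2019")
  expect_identical(make_plan_name(d, "TBI_07-2019"), "TBI_07-2019-1")
  expect_identical(
    make_plan_name(d, c("TBI_07-2019", "TBI_07-2019-1", "TBI_07-2019-3")),
    "TBI_07-2019-2"   # smallest free suffix
  )
  expect_identical(make_plan_name(as.Date("2020-01-02"), character()),
                   "TBI_01-2020")
  # repeated same-day runs never collide
  names <- character()
  for (i in 1:10) names <- c(names, make_plan_name(d, names))
  expect_identical(anyDuplicated(names), 0L)
})

test_that("a built plan carries the arrangement's fields with equal MU", {
  ctx <- clean_context()
  plan <- ctx$plan
  expect_identical(plan$fields$name, c("AP", "PA"))
  expect_identical(plan$fields$mu[1], plan$fields$mu[2])
  expect_true(all(plan$fields$technique == "TOTAL"))
  expect_true(all(plan$fields$dose_rate %in% ctx$bd$dose_rates))
  expect_identical(plan$plan_name, "TBI_07-2019")
  expect_identical(plan$phantom$side, 40)
  rp <- plan$reference_points
  expect_true(all(rp$session_limit <= rp$daily_limit &
                    rp$daily_limit <= rp$total_limit))
  expect_identical(rp$total_limit, rp$daily_limit * ctx$rx$num_fractions)

  lat <- build_plan(demo_rx(arrangement = "RLat/LLat"), ctx$calc,
                    today = as.Date("2019-07-01"))
  expect_identical(lat$fields$name, c("RLat", "LLat"))
  expect_error(
    build_plan(ctx$rx, ctx$calc, presets = list(arrangements = list())),
    class = "tbi_config_error"
  )
})

test_that("plan construction is deterministic and pure", {
  bd <- demo_beam_data()
  rx <- demo_rx()
  calc <- compute_mu(bd, rx)
  rx_snapshot <- unserialize(serialize(rx, NULL))
  calc_snapshot <- unserialize(serialize(calc, NULL))
  p1 <- build_plan(rx, calc, today = as.Date("2019-07-01"))
  p2 <- build_plan(rx, calc, today = as.Date("2019-07-01"))
  f1 <- file.path(withr::local_tempdir(), "a.json")
  f2 <- file.path(withr::local_tempdir(), "b.json")
  export_plan(p1, f1)
  export_plan(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(rx, rx_snapshot)
  expect_identical(calc, calc_snapshot)
})

test_that("MU setting inverts the mock normalization/weight model", {
  # single field closed form
  sol <- set_field_mu(mock_dose_state(100), 200)
  expect_identical(sol$weights, 1)
  expect_identical(sol$normalization, 50)
  # equal targets get equal weights
  sol <- set_field_mu(mock_dose_state(c(100, 100)), c(3301, 3301))
  expect_identical(sol$weights[1], sol$weights[2])
  # 200 seeded trials round-trip exactly through the forward model
  trials <- withr::with_seed(303, purrr::map(1:200, function(i) {
    n <- sample(1:4, 1)
    list(base = stats::runif(n, 50, 150),
         targets = round(stats::runif(n, 50, 6000)))
  }))
  for (tr in trials) {
    sol <- set_field_mu(mock_dose_state(tr$base), tr$targets)
    delivered <- tr$base * sol$weights * (100 / sol$normalization)
    expect_identical(round_half_up(delivered), tr$targets)
    expect_identical(sol$delivered_mu, tr$targets)
    expect_true(all(sol$weights <= 1 + 1e-12))
  }
  # unattainable under tightened bounds
  expect_error(
    set_field_mu(mock_dose_state(100), 200, norm_range = c(60, 100)),
    class = "tbi_unattainable_error"
  )
  expect_error(
    set_field_mu(mock_dose_state(c(100, 100)), c(1, 5000), weight_min = 0.5),
    class = "tbi_unattainable_error"
  )
})

test_that("JSON export round-trips the plan losslessly", {
  ctx <- clean_context()
  path <- file.path(withr::local_tempdir(), "plan.json")
  export_plan(ctx$plan, path, "json")
  back <- read_plan_json(path)
  expect_equal(back$fields, ctx$plan$fields)
  expect_equal(back$reference_points, ctx$plan$reference_points)
  expect_identical(back$plan_name, ctx$plan$plan_name)
  expect_identical(back$created, ctx$plan$created)
  expect_identical(back$normalization, ctx$plan$normalization)
  # a fieldless plan must be refused
  empty <- ctx$plan
  empty$fields <- empty$fields[0, ]
  expect_error(export_plan(empty, path), class = "tbi_validation_error")
})

test_that("DICOM export preserves beams, MU and geometry on read-back", {
  ctx <- clean_context()
  path <- file.path(withr::local_tempdir(), "plan.dcm")
  export_plan(ctx$plan, path, "dicom")
  back <- dicom_read_rtplan(path)
  expect_identical(nrow(back$beams), nrow(ctx$plan$fields))
  expect_identical(back$beams$mu, ctx$plan$fields$mu)
  expect_identical(back$beams$name, ctx$plan$fields$name)
  expect_identical(back$beams$gantry, ctx$plan$fields$gantry)
  expect_identical(back$beams$dose_rate, ctx$plan$fields$dose_rate)
  expect_identical(back$beams$technique, rep("TOTAL", 2))
  expect_identical(back$patient_id, ctx$plan$patient_id)
  expect_identical(back$plan_name, ctx$plan$plan_name)
  expect_identical(back$num_fractions, as.numeric(ctx$plan$num_fractions))
})

test_that("an independent DICOM implementation reads the export identically", {
  ctx <- clean_context()
  path <- file.path(withr::local_tempdir(), "plan.dcm")
  export_plan(ctx$plan, path, "dicom")
  script <- paste0(
    "import pydicom, json; ds = pydicom.dcmread('", path, "'); ",
    "print(json.dumps({",
    "'n': len(ds.BeamSequence), ",
    "'mu': [float(b.BeamMeterset) for b in ",
    "ds.FractionGroupSequence[0].ReferencedBeamSequence], ",
    "'names': [str(b.BeamName) for b in ds.BeamSequence], ",
    "'pid': str(ds.PatientID)}))"
  )
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parsed <- jsonlite::fromJSON(out)
  expect_identical(parsed$n, nrow(ctx$plan$fields))
  expect_identical(parsed$mu, ctx$plan$fields$mu)
  expect_identical(parsed$names, ctx$plan$fields$name)
  expect_identical(parsed$pid, ctx$plan$patient_id)
})
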
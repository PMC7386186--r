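# tbiplanr

Automated treatment planning, documentation and safety checks for
extended-SSD total body irradiation (TBI), plus incident-learning-system
(ILS) analytics.

TBI monitor units are classically obtained by a *hand calculation*: at the
midplane prescription point (depth = separation/2, distance =
SSD + separation/2),

```
D/MU = ISF · Sc · Sp · TMR(d) · f_spoiler · f_muscle
ISF  = (d_cal / (SSD + separation/2))²
MU/field = round_half_up(D_field / (D/MU))
```

with the machine dose rate set to the largest deliverable repetition rate
keeping the instantaneous dose rate at the prescription point within the
protocol limit (typically 10 cGy/min). The calculation itself is easy; the
errors live in the manual bridging around it — transcribing prescriptions
into worksheets, retyping MU into the planning system, mislabelled fields,
stale dose rates after a replan. tbiplanr makes the whole chain one data
flow:

* **beam data** — versioned, checksummed machine tables (TMR, Sc, Sp,
  spoiler, dose-rate ladder, energy-by-separation selection) with strict
  validation, linear interpolation and no extrapolation
  (`load_beam_data()`, `generate_beam_fixture()`);
* **hand-calculation engine** — `compute_mu()` returns MU, dose-rate
  setting and the complete factor breakdown as an audit trail;
* **plan builder** — `build_plan()` constructs the phantom, date-based
  names, reference points and `TOTAL`-technique fields, setting per-field
  MU by inverting a normalization/field-weight model; exports to JSON and
  a minimal DICOM-RT Plan (`export_plan()`);
* **worksheet + checks** — `render_worksheet()` serializes the calculation
  document straight from the data model; `run_checks()` re-derives
  everything with an independent brute-force oracle and returns blocking
  findings for every historically observed error mode;
* **ILS analytics** — quarterly report series, percentage breakdowns,
  overrepresentation factors, pre/post-intervention rates
  (`quarterly_series()`, `proportion()`, `pre_post_summary()`);
* **workflow** — `run_autoplan()` / `run_ils()` and the
  `inst/scripts/tbi-autoplan.R` front end tie it together with strict-mode
  blocking and deterministic artifacts.

Intended for medical physicists and planners who want the algebra of an
automated TBI workflow — and its safety interlocks — in an open, testable
form. It computes no volumetric dose and talks to no vendor system.

## Worked example

```r
library(tbiplanr)

bd <- generate_beam_fixture(seed = 7, n_energies = 3)
rx <- prescription("standard_adult", dose_per_field = 75, num_fractions = 8,
                   separation = 36, max_dose_rate = 10, arrangement = "AP/PA",
                   patient_id = "MRN0001", patient_name = "DOE^JANE")
(calc <- compute_mu(bd, rx))
#> <calc_result>
#>   energy 10X, depth 18 cm (midplane), SPD 518 cm
#>   3301 MU/field @ 400 MU/min (9.087 cGy/min at point)
#>   beam data: fixture-s7-e3
```

Separation 36 cm selects the 10X beam; the factor product gives
0.0227 cGy/MU, so 75 cGy/field needs 3301 MU, and 400 MU/min is the
fastest setting keeping the point dose rate (9.09 cGy/min) under the
10 cGy/min limit. Build, document and check the plan:

```r
plan <- build_plan(rx, calc, today = as.Date("2019-07-01"))
render_worksheet(rx, calc, "worksheet.md", generated = as.Date("2019-07-01"))
run_checks(plan, rx, calc, bd, worksheet = "worksheet.md")
#> # A tibble: 0 × 5      (no findings on the clean plan)
```

Perturb the plan the way a manual typo would and the independent
recomputation blocks it:

```r
plan$fields$mu <- plan$fields$mu + 300
run_checks(plan, rx, calc, bd, worksheet = "worksheet.md")$message[1]
#> "field 'AP' has 3601 MU; independent recomputation gives 3301 MU"
```

The end-to-end demo (bundled synthetic beam data and prescription):

```r
run_autoplan(system.file("extdata", "beamdata", "machine.yaml", package = "tbiplanr"),
             system.file("extdata", "demo_rx.yaml", package = "tbiplanr"),
             "out", date = as.Date("2019-07-01"))
```

writes `plan.json`, `plan.dcm`, `worksheet.md`, `findings.json` and
`audit.log`, exits 0, and is byte-identical across reruns.

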
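---
title: "Automated TBI planning: models, checks and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated TBI planning: models, checks and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbiplanr)
```

## The problem

Total body irradiation (TBI) is delivered at extended SSD (500 cm here)
with a fully open 40 × 40 cm field, usually without volumetric imaging.
Monitor units are therefore obtained by a hand calculation from tabulated
machine factors rather than from a volumetric dose engine. The procedure
itself is simple and well validated; the risk concentrates in the manual
*bridging* steps — transcribing the prescription into the worksheet,
copying worksheet outputs into the planning system, re-entering identifiers
into documents. tbiplanr automates the full chain (calculation → plan
construction → worksheet → checks) so that every number flows from one data
model and transcription never happens.

## The hand-calculation model

Dose per monitor unit at the midplane prescription point is the product of
six factors:

$$\frac{D}{\mathrm{MU}} = \mathrm{ISF} \cdot S_c \cdot S_p \cdot
\mathrm{TMR}(d) \cdot f_{\mathrm{spoiler}} \cdot f_{\mathrm{muscle}}$$

with depth $d = \mathrm{separation}/2$ and

$$\mathrm{ISF} = \left(\frac{d_{\mathrm{cal}}}
{\mathrm{SSD} + \mathrm{separation}/2}\right)^2 .$$

Monitor units per field are the prescribed dose per field divided by this
product, rounded half-up to whole MU; the machine dose-rate setting is the
largest deliverable repetition rate whose dose rate at the prescription
point stays within the prescription limit (10 cGy/min for the standard
protocols, 15 cGy/min for the high-dose-rate adult protocol).

Design choices where the convention was genuinely open:

* **Midplane prescription point.** Depth is separation/2 and the
  source-to-point distance is SSD + separation/2, consistent with
  whole-body midplane dose specification.
* **Interpolation is piecewise linear** in one variable (depth for TMR,
  equivalent-square side for `Sc`/`Sp`), matching spreadsheet practice and
  exactly testable. Values are exact at knots and bounded by bracketing
  knots (no overshoot).
* **No extrapolation.** A lookup outside the tabulated range is a hard
  error, never a silent guess — a silently extrapolated factor is exactly
  the kind of hidden defect the check battery exists to catch.
* **TMR is one-dimensional.** The collimator is fixed at 40 × 40 cm at
  500 cm, so TMR is tabulated versus depth at a protocol-level effective
  field size rather than as a 2-D grid.
* **Sc/Sp equivalent square.** Whether `Sc` and `Sp` should be read at the
  collimator setting or at a projected/patient-limited equivalent square is
  a clinic convention; both default to the collimator setting (40 cm) and
  both are arguments (`sc_side`, `sp_side`) of `dose_per_mu()`.
* **MU rounding** is half-up to integer MU (`round_half_up()`), matching
  deliverable monitor units; the rounding contract is
  $|\mathrm{MU} \cdot D/\mathrm{MU} - D_{\mathrm{field}}| \le
  \tfrac{1}{2} D/\mathrm{MU}$.
* **Dose-rate quantization** picks the *maximal* feasible ladder member
  (boundary inclusive), minimizing beam-on time without breaching the
  limit.
* **Sanity cap.** `compute_mu()` refuses results above `mu_cap`
  (default 25 000 MU, several times the largest plausible extended-SSD
  case) instead of emitting them — a forcing function against absurd
  inputs propagating downstream.
* **Energy intervals are half-open** `[sep_min, sep_max)`, so a separation
  on a boundary deterministically selects the upper interval.

```{r}
bd <- generate_beam_fixture(seed = 7, n_energies = 3)
rx <- prescription("standard_adult", dose_per_field = 75, num_fractions = 8,
                   separation = 36, max_dose_rate = 10, arrangement = "AP/PA",
                   patient_id = "MRN0001", patient_name = "DOE^JANE")
calc <- compute_mu(bd, rx)
tidy(calc)
glance(calc)
```

## Plan construction and the mock dose model

`build_plan()` reproduces the automated plan-construction sequence against
a neutral data model: a 40 cm cubic water phantom with a body contour,
date-based course/plan names with collision suffixes (`TBI_07-2019`,
`TBI_07-2019-1`, ...), reference points whose limits derive from the
prescription (session = daily = dose per field × fields per fraction;
total = daily × fractions), and one static `TOTAL`-technique field per
arrangement member with preset gantry/SSD/field size. Gantry presets
(270°/90° for both arrangements) are configuration, validated at build
time, not constants.

A real planning system requires a placeholder dose distribution before MU
can be set; that distribution is irrelevant for treatment. The package
replaces it with an explicit mock model
$\mathrm{MU}_i^{\mathrm{delivered}} = \mathrm{MU}_i^{\mathrm{base}} \cdot
w_i \cdot 100 / N$, and `set_field_mu()` inverts it: weights are scaled so
the hottest field has $w = 1$ and the plan normalization $N$ absorbs the
global factor. The inversion composed with the forward model is the
identity on targets (to whole-MU rounding) — that algebra, not the dose
engine, is the tested content. Admissible bounds default to
$w \ge 0.001$ and $N \in [0.5, 2000]\,\%$ so that target spreads of two
orders of magnitude (50–6000 MU) remain attainable; narrower clinic
bounds can be passed and violations are hard errors.

Dates are injected (`today =`), never read from the wall clock inside
logic, so identical inputs give byte-identical artifacts.

## Worksheet and check battery

`render_worksheet()` serializes the patient identifiers, prescription
echo, full factor breakdown, MU/dose-rate and beam-data version directly
from the data model at full floating precision; `parse_worksheet()`
inverts the markdown render exactly. The PDF render typesets the same
lines via the `pdf()` graphics device.

`run_checks()` re-derives everything with `recompute_naive()`, a
deliberately independent code path (energy by linear scan,
`stats::approx()` interpolation, its own product and rounding) — a check
that shared code with the engine could not catch the engine's bugs. The
battery covers identifier consistency, field-label/arrangement agreement,
protocol-registry conformance, independent MU and per-factor
recomputation, dose-rate deliverability/uniformity/feasibility/maximality,
energy-versus-separation lookup, gantry/field-size presets, and worksheet
presence/consistency. Thirteen fixture scenarios — one per historically
reported root error (wrong patient name, all fields labelled "LLat",
missing calculation document, adult on pediatric worksheet, ignored
pediatric dose-rate limit, wrong gantry, wrong field size, mistranscribed
separation, mistyped MU, spoiler from the wrong energy, stale dose rate
after a backup-machine replan, one field's rate wrong, wrong energy) —
each trigger a blocking finding, and a clean auto-built plan triggers
none. In strict mode the workflow refuses to succeed while blockers exist.

## Incident-learning analytics

`quarterly_series()`, `proportion()`, `overrepresentation_factor()` and
`pre_post_summary()` reproduce standard ILS reporting: zero-filled
per-quarter counts, percentages rounded half-up to one decimal (the
precision such audits print), and pre/post-intervention rate summaries
where the intervention quarter belongs to the *pre* period (an
intervention rolled out at the end of that quarter). The bundled reference
counts (`ils_reference_counts()`) and the 35-row report table
(`reference_incident_reports()`, also shipped as
`extdata/ils_tbi_reports.csv`) encode a published six-and-a-half-year
single-institution audit: 9108 patients (411 TBI), 1566 reports (470
planning-related, 24 of them TBI), and 35 TBI reports whose marginals are
17/11/7 by classification and 11/12/12 by category. The joint assignment
of planning-relatedness (all documentation and field-issue rows) is not
constrained by the published marginals and was fixed once. The 25
pre-automation quarters give a mean of exactly 1.4 reports/quarter; the
published ±1.7 SD depends on the unpublished per-quarter breakdown and is
therefore not asserted.

```{r}
reports <- reference_incident_reports()
ils_summary(reports)$by_classification
pre_post_summary(reports, as.Date("2019-03-31"),
                 as.Date("2013-01-01"), as.Date("2019-06-30"))
```

## What the synthetic beam data emulates — and what it does not

`generate_beam_fixture()` produces physically plausible commissioned-style
tables: TMR rising through build-up (deeper build-up for higher energies)
then falling exponentially with an energy-dependent effective attenuation
coefficient of roughly 0.03–0.05 cm⁻¹; `Sc`/`Sp` near unity, increasing
logarithmically with equivalent-square side; spoiler factors in
(0.9, 1.1]; a 100–600 MU/min repetition-rate ladder; and energies
partitioning the 0–60 cm separation range equally. It is bit-reproducible
under a fixed seed.

It does **not** emulate measured-data noise, off-axis or oblique-incidence
effects, compensator or lung-block transmission, or machine-to-machine
output drift. Passing tests therefore demonstrate the *algebra* of the
workflow — factor assembly, interpolation, inversion, checks — on data
with the right shape, not the dosimetric accuracy of any clinical beam
model. Commissioned clinical tables are loaded through the same
`load_beam_data()` schema (versioned and checksummed; a content/checksum
mismatch is a hard integrity error echoed into every audit log).

## Problem sizes and determinism

The test and acceptance workloads use a three-energy synthetic machine;
property suites run 1000 seeded random prescriptions for engine/oracle
agreement and dose-rate maximality, 200 seeded target vectors for the
MU-setting inversion, and 500 seeded replicates for Poisson rate recovery
— sizes at which every property is exercised across the full tabulated
range while the whole suite runs in well under a minute. All randomness is
seeded through `withr::with_seed()`; nothing in the pipeline reads the
wall clock, so artifacts are reproducible byte for byte.

## Known limitations

* The dose model behind plan construction is the explicit mock above;
  no volumetric dose is computed anywhere.
* DICOM-RT export writes a documented minimal tag subset (identity,
  beams, metersets, one control point each) in explicit-VR little-endian;
  it is not a general DICOM toolkit.
* TLD-based in-vivo boost calculation, compensator design, lung-block
  transmission and record-and-verify transactions are out of scope.
* Protocol-registry bounds (age-class separation split at 28 cm, dose and
  fraction ranges) are package defaults a clinic should replace with its
  own registry.
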
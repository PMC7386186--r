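#' Naive independent recomputation of the hand calculation
#'
#' A deliberately separate code path used by the pre-treatment check
#' battery (and the test suite) to re-derive every factor from the raw
#' table knots: energy by a linear scan of the selection intervals,
#' table factors via [stats::approx()], the inverse-square factor from
#' first principles, and monitor units by truncation-based half-up
#' rounding. It shares no arithmetic with [compute_mu()], so a defect in
#' the engine cannot hide from a check built on this function.
#'
#' @param data A `beam_data_set`, or the path of a master YAML file (the
#'   tables are then re-read from the raw CSVs on disk).
#' @param rx A [prescription()].
#' @param sc_side,sp_side Equivalent-square sides for Sc/Sp; default the
#'   treatment collimator setting, as in the engine.
#' @return List with `energy`, `dose_per_mu`, `mu_per_field`,
#'   `machine_dose_rate`, `achieved_dose_rate` and the individual factors.
#' @export
recompute_naive <- function(data, rx, sc_side = NULL, sp_side = NULL) {
  if (is.character(data)) {
    data <- naive_read_tables(data)
  }
  geom <- data$geometry
  sc_side <- sc_side %||% geom$treatment_field
  sp_side <- sp_side %||% geom$treatment_field

  # energy: first interval whose [min, max) contains the separation
  energy <- NA_character_
  es <- data$energy_selection
  for (i in seq_len(nrow(es))) {
    if (rx$separation >= es$sep_min[i] && rx$separation < es$sep_max[i]) {
      energy <- es$energy[i]
      break
    }
  }
  if (is.na(energy)) {
    tbi_abort("naive recomputation: separation not covered", "tbi_range_error")
  }

  lookup <- function(kind, x) {
    tab <- data$tables[data$tables$energy == energy & data$tables$kind == kind, ]
    if (kind == "spoiler") return(tab$value[1])
    if (x < min(tab$abscissa) || x > max(tab$abscissa)) {
      tbi_abort(paste0("naive recomputation: ", kind, " abscissa out of range"),
                "tbi_range_error")
    }
    stats::approx(tab$abscissa, tab$value, xout = x, method = "linear",
                  ties = "ordered")$y
  }

  depth <- rx$separation / 2
  isf <- (geom$cal_distance^2) / (geom$treatment_ssd + depth)^2
  factors <- c(
    isf = isf,
    sc = lookup("Sc", sc_side),
    sp = lookup("Sp", sp_side),
    tmr = lookup("TMR", depth),
    spoiler = lookup("spoiler", 0),
    muscle = geom$water_to_muscle
  )
  dpm <- prod(factors)
  mu <- trunc(rx$dose_per_field / dpm + 0.5)

  rate <- NA_real_
  for (r in sort(data$dose_rates, decreasing = TRUE)) {
    if (r * dpm <= rx$max_dose_rate) {
      rate <- r
      break
    }
  }
  list(
    energy = energy, dose_per_mu = dpm, mu_per_field = mu,
    machine_dose_rate = rate,
    achieved_dose_rate = if (is.na(rate)) NA_real_ else rate * dpm,
    factors = as.list(factors)
  )
}

# Re-read the raw CSV knots referenced by a master YAML, without going
# through load_beam_data's constructors (keeps the oracle path separate).
naive_read_tables <- function(path) {
  master <- yaml::read_yaml(path)
  dir <- dirname(path)
  rows <- lapply(master$tables, function(entry) {
    csv <- utils::read.csv(file.path(dir, entry$file))
    data.frame(energy = entry$energy, kind = entry$kind,
               abscissa = csv$abscissa, value = csv$value)
  })
  es <- do.call(rbind, lapply(master$energy_selection, as.data.frame))
  g <- master$geometry
  list(
    geometry = g,
    tables = do.call(rbind, rows),
    energy_selection = es,
    dose_rates = as.numeric(master$dose_rates)
  )
}
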
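ils_categories <- c("treatment", "documentation", "field_issue", "other")
ils_classifications <- c("operational_workflow", "unsafe_condition",
                         "near_miss", "other")

#' Read incident reports from CSV
#'
#' Expected header: `report_date` (ISO date), `treatment_type`
#' (`TBI`/`other`), `category` (treatment, documentation, field_issue,
#' other), `classification` (operational_workflow, unsafe_condition,
#' near_miss, other), `planning_related` (TRUE/FALSE). Malformed rows
#' (bad date, unknown label) are dropped with a message, or raise an
#' error in strict mode.
#'
#' @param path CSV path.
#' @param strict Error on malformed rows instead of dropping them.
#' @return Tibble of incident reports.
#' @export
read_incident_reports <- function(path, strict = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("report_date", "treatment_type", "category", "classification",
              "planning_related")
  if (nrow(raw) == 0 && !all(needed %in% names(raw))) {
    return(tibble::tibble(
      report_date = as.Date(character()), treatment_type = character(),
      category = character(), classification = character(),
      planning_related = logical()
    ))
  }
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    tbi_abort(paste0("incident CSV missing column(s): ",
                     paste(missing, collapse = ", ")), "tbi_load_error")
  }
  reports <- tibble::as_tibble(raw[needed])
  dates <- as.Date(reports$report_date, format = "%Y-%m-%d")
  bad <- is.na(dates) |
    !reports$category %in% ils_categories |
    !reports$classification %in% ils_classifications
  if (any(bad)) {
    msg <- paste0(sum(bad), " malformed incident row(s) at line(s) ",
                  paste(which(bad) + 1, collapse = ", "))
    if (strict) tbi_abort(msg, "tbi_load_error")
    message(msg, " - dropped")
  }
  reports$report_date <- dates
  reports$planning_related <- as.logical(reports$planning_related)
  reports[!bad, ]
}

quarter_label <- function(dates) {
  paste0(lubridate::year(dates), "Q", lubridate::quarter(dates))
}

#' Per-quarter incident counts
#'
#' Zero-filled counts of reports per calendar quarter over a window.
#' Reports outside the window are excluded with a logged notice.
#'
#' @param reports Tibble with a `report_date` column.
#' @param window_start,window_end Dates bounding the window (their
#'   quarters are included).
#' @return A `quarterly_series` tibble: `quarter` (start date), `label`
#'   (`"2013Q1"`), `n`.
#' @export
quarterly_series <- function(reports, window_start, window_end) {
  window_start <- lubridate::floor_date(as.Date(window_start), "quarter")
  window_end <- lubridate::floor_date(as.Date(window_end), "quarter")
  if (window_end < window_start) {
    tbi_abort("window_end precedes window_start", "tbi_validation_error")
  }
  quarters <- seq(window_start, window_end, by = "3 months")
  window_stop <- seq(window_end, by = "3 months", length.out = 2)[2]
  outside <- reports$report_date < window_start |
    reports$report_date >= window_stop
  if (any(outside, na.rm = TRUE)) {
    message(sum(outside, na.rm = TRUE),
            " report(s) outside the analysis window - excluded")
    reports <- reports[!outside, ]
  }
  counts <- table(factor(quarter_label(reports$report_date),
                         levels = quarter_label(quarters)))
  out <- tibble::tibble(
    quarter = quarters,
    label = quarter_label(quarters),
    n = as.integer(counts)
  )
  class(out) <- c("quarterly_series", class(out))
  out
}

#' Percentage with worksheet-style rounding
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal — the
#' precision incident summaries are reported at.
#'
#' @param numerator,denominator Counts; `denominator > 0`.
#' @return Percentage, one decimal.
#' @examples
#' proportion(7, 35)  # 20.0
#' @export
proportion <- function(numerator, denominator) {
  if (!is.numeric(denominator) || any(denominator <= 0)) {
    tbi_abort("denominator must be positive", "tbi_domain_error")
  }
  round_half_up(100 * numerator / denominator, 1)
}

#' Overrepresentation factor between two shares
#'
#' Ratio of two percentage shares (e.g. a treatment type's share of
#' planning-related reports over its share of treated patients), rounded
#' half-up to one decimal.
#'
#' @param share_a,share_b Percentage shares; `share_b > 0`.
#' @return The factor, one decimal.
#' @export
overrepresentation_factor <- function(share_a, share_b) {
  if (!is.numeric(share_b) || any(share_b <= 0)) {
    tbi_abort("share_b must be positive", "tbi_domain_error")
  }
  round_half_up(share_a / share_b, 1)
}

#' Summarise incident reports
#'
#' Counts and percentage breakdowns by category and classification.
#'
#' @param reports Tibble of incident reports.
#' @return List with `n`, and tibbles `by_category`, `by_classification`
#'   (columns `level`, `n`, `pct`).
#' @export
ils_summary <- function(reports) {
  breakdown <- function(col, levels) {
    counts <- table(factor(reports[[col]], levels = levels))
    tibble::tibble(
      level = levels, n = as.integer(counts),
      pct = if (nrow(reports) > 0) proportion(as.integer(counts), nrow(reports))
            else rep(NA_real_, length(levels))
    )
  }
  list(
    n = nrow(reports),
    by_category = breakdown("category", ils_categories),
    by_classification = breakdown("classification", ils_classifications)
  )
}

#' Quarterly rates before and after an intervention
#'
#' Splits the per-quarter series at an intervention date (the quarter
#' containing the intervention belongs to the "pre" period, matching an
#' intervention rolled out at the end of that quarter) and reports count,
#' mean and SD of reports per quarter on each side.
#'
#' @param reports Tibble of incident reports.
#' @param intervention_date Date of the intervention.
#' @param window_start,window_end Analysis window passed to
#'   [quarterly_series()].
#' @return Tibble with one row per period (`pre`, `post`): `n_quarters`,
#'   `total`, `mean_per_quarter`, `sd_per_quarter`.
#' @export
pre_post_summary <- function(reports, intervention_date,
                             window_start, window_end) {
  series <- quarterly_series(reports, window_start, window_end)
  cutoff <- lubridate::floor_date(as.Date(intervention_date), "quarter")
  series$period <- ifelse(series$quarter <= cutoff, "pre", "post")
  series |>
    dplyr::group_by(period = factor(.data$period, levels = c("pre", "post"))) |>
    dplyr::summarise(
      n_quarters = dplyr::n(),
      total = sum(.data$n),
      mean_per_quarter = mean(.data$n),
      sd_per_quarter = stats::sd(.data$n),
      .groups = "drop"
    ) |>
    tidyr::complete(period,
                    fill = list(n_quarters = 0L, total = 0L,
                                mean_per_quarter = 0, sd_per_quarter = NA_real_))
}

#' Generate synthetic incident reports
#'
#' Seeded stand-in for a confidential ILS export: per-quarter report
#' counts drawn from a Poisson process at a configurable rate, with
#' report dates uniform within each quarter and labels drawn from the
#' closed vocabularies.
#'
#' @param seed Integer seed (deterministic output).
#' @param rate Mean reports per quarter.
#' @param window_start,window_end Window of quarters to populate.
#' @return Tibble of incident reports.
#' @export
generate_incident_reports <- function(seed = 1, rate = 1.4,
                                      window_start = as.Date("2013-01-01"),
                                      window_end = as.Date("2019-03-31")) {
  quarters <- seq(lubridate::floor_date(as.Date(window_start), "quarter"),
                  lubridate::floor_date(as.Date(window_end), "quarter"),
                  by = "3 months")
  withr::with_seed(seed, {
    counts <- stats::rpois(length(quarters), rate)
    purrr::map2_dfr(quarters, counts, function(q, k) {
      if (k == 0) return(NULL)
      span <- as.integer(seq(q, by = "3 months", length.out = 2)[2] - q)
      tibble::tibble(
        report_date = q + sample.int(span, k, replace = TRUE) - 1,
        treatment_type = "TBI",
        category = sample(ils_categories[1:3], k, replace = TRUE),
        classification = sample(ils_classifications[1:3], k, replace = TRUE),
        planning_related = sample(c(TRUE, FALSE), k, replace = TRUE,
                                  prob = c(0.7, 0.3))
      )
    })
  })
}

#' Bar chart of the quarterly incident series
#'
#' @param object A `quarterly_series` from [quarterly_series()].
#' @param intervention_date Optional date; drawn as a dashed vertical
#'   line at the end of its quarter.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quarterly_series <- function(object, intervention_date = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$quarter, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30", width = 80) +
    ggplot2::scale_y_continuous(breaks = scales_integer_breaks(object$n)) +
    ggplot2::labs(x = "Quarter", y = "Reports submitted",
                  title = "TBI planning-related incident reports per quarter") +
    ggplot2::theme_minimal()
  if (!is.null(intervention_date)) {
    cutoff <- lubridate::ceiling_date(as.Date(intervention_date), "quarter")
    p <- p + ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed")
  }
  p
}

scales_integer_breaks <- function(n) {
  seq(0, max(c(n, 1)), by = max(1, ceiling(max(c(n, 1)) / 6)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Reference audit counts for the bundled ILS example
#'
#' Aggregate counts from a published six-and-a-half-year single-institution
#' incident-learning audit of TBI planning (January 2013 - June 2019),
#' bundled so the analytics can be exercised against real reported
#' numbers: patients treated overall and with TBI, reports submitted
#' overall, planning-related reports, TBI reports with their category and
#' classification splits, and the 25 pre-automation quarters.
#'
#' @return Named list of counts.
#' @export
ils_reference_counts <- function() {
  list(
    patients_total = 9108L,
    patients_tbi = 411L,
    reports_total = 1566L,
    reports_planning = 470L,
    reports_tbi = 35L,
    reports_tbi_planning = 24L,
    classification = c(operational_workflow = 17L, unsafe_condition = 11L,
                       near_miss = 7L),
    category = c(treatment = 11L, documentation = 12L, field_issue = 12L),
    pre_automation_quarters = 25L
  )
}
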
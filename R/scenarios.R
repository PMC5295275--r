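#' Read a community scenario file
#'
#' A scenario file (YAML) defines named communities with the four dose
#' parameters: soil/dust or air concentration `concentration`, intake rate
#' `intake_rate`, exposure factor (either `exposure_factor` directly or
#' `exposed_hours_per_day`, converted via [compute_exposure_factor()]), and
#' `body_weight`. A shared `unit_conversion` applies to all scenarios.
#'
#' Scenarios may also carry multiplicative derivation factors
#' (`body_weight_factor`, `intake_rate_factor`) on a shared `base`; when
#' both a value and a factor are present they are checked for mutual
#' consistency, which guards the packaged fixture against silent drift.
#'
#' The packaged default, `scenarios_lead_soil.yaml`, is the four-community
#' lead soil-ingestion spectrum from wealthiest (C = 5 mg/kg, IR = 50
#' mg/day, EF = 3/24, BW = 80 kg) to EJ community (C = 5e3 mg/kg, IR = 85
#' mg/day, EF = 1, BW = 84 kg).
#'
#' @param path YAML path; defaults to the packaged lead scenarios.
#' @return tibble with columns `name`, `concentration`, `intake_rate`,
#'   `exposure_factor`, `body_weight`, `unit_conversion`, `narrative_tags`
#'   (list column).
#' @export
read_scenarios <- function(path = ejadd_example("scenarios_lead_soil.yaml")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios)) {
    abort_validation("scenario file must define at least one scenario.")
  }
  conv <- cfg$unit_conversion %||% 1e-3
  base <- cfg$base
  rows <- purrr::map(cfg$scenarios, function(s) {
    if (is.null(s$name)) abort_validation("every scenario needs a `name`.")
    ef <- if (!is.null(s$exposure_factor)) {
      s$exposure_factor
    } else if (!is.null(s$exposed_hours_per_day)) {
      compute_exposure_factor(s$exposed_hours_per_day)
    } else {
      abort_validation(sprintf(
        "scenario '%s' needs `exposure_factor` or `exposed_hours_per_day`.",
        s$name
      ))
    }
    check_factor <- function(value, factor, base_value, field) {
      if (!is.null(factor) && !is.null(base_value) &&
          abs(value - base_value * factor) > 1e-9 * max(1, abs(value))) {
        abort_validation(sprintf(
          "scenario '%s': %s %g disagrees with base %g x factor %g.",
          s$name, field, value, base_value, factor
        ))
      }
    }
    check_factor(s$body_weight, s$body_weight_factor, base$body_weight,
                 "body_weight")
    check_factor(s$intake_rate, s$intake_rate_factor, base$intake_rate,
                 "intake_rate")
    tibble(
      name = s$name,
      concentration = s$concentration,
      intake_rate = s$intake_rate,
      exposure_factor = ef,
      body_weight = s$body_weight,
      unit_conversion = conv,
      narrative_tags = list(unlist(s$narrative_tags) %||% character())
    )
  })
  bind_rows(rows)
}

#' Derive scenario dose parameters by multiplicative adjustment
#'
#' Community scenarios are often constructed from a baseline community by
#' proportional adjustments, e.g. a 5% higher body weight (80 kg x 1.05 =
#' 84 kg) or a 70% higher soil ingestion rate (50 mg/day x 1.7 = 85
#' mg/day).
#'
#' @param base data frame (or one-row tibble) with columns `concentration`,
#'   `intake_rate`, `exposure_factor`, `body_weight`.
#' @param concentration_factor,intake_rate_factor,exposure_factor_factor,body_weight_factor
#'   multiplicative adjustments (default 1 = unchanged).
#' @return tibble of adjusted parameters.
#' @export
derive_scenario_parameters <- function(base,
                                       concentration_factor = 1,
                                       intake_rate_factor = 1,
                                       exposure_factor_factor = 1,
                                       body_weight_factor = 1) {
  base <- as_tibble(base)
  mutate(base,
    concentration = .data$concentration * concentration_factor,
    intake_rate = .data$intake_rate * intake_rate_factor,
    exposure_factor = .data$exposure_factor * exposure_factor_factor,
    body_weight = .data$body_weight * body_weight_factor
  )
}

#' Run a set of community dose scenarios
#'
#' Applies [compute_add()] to each scenario and builds a pairwise dose-ratio
#' table. Each dose is reported at full precision and display-rounded
#' (see [dose_display()]); each ratio is reported both from full-precision
#' doses and from the display-rounded doses, the convention under which
#' ratios are usually quoted from published tables.
#'
#' @param scenarios tibble as returned by [read_scenarios()].
#' @return object of class `scenario_report`: a list with tibbles
#'   `scenarios` (`name`, parameters, `add`, `add_display`) and `ratios`
#'   (`numerator`, `denominator`, `ratio`, `ratio_display_inputs`).
#' @examples
#' report <- run_scenarios(read_scenarios())
#' report
#' tidy(report)
#' @export
run_scenarios <- function(scenarios) {
  stopifnot(nrow(scenarios) >= 1)
  sc <- mutate(scenarios,
    add = compute_add(
      .data$concentration, .data$intake_rate, .data$exposure_factor,
      .data$body_weight, .data$unit_conversion
    ),
    add_display = dose_display(.data$add)
  )
  pairs <- tidyr::expand_grid(
    numerator = sc$name, denominator = sc$name
  )
  pairs <- pairs[pairs$numerator != pairs$denominator, ]
  ratios <- if (nrow(pairs)) {
    num <- sc[match(pairs$numerator, sc$name), ]
    den <- sc[match(pairs$denominator, sc$name), ]
    mutate(pairs,
      ratio = scenario_dose_ratio(num$add, den$add),
      ratio_display_inputs = num$add_display / den$add_display
    )
  } else {
    tibble(
      numerator = character(), denominator = character(),
      ratio = numeric(), ratio_display_inputs = numeric()
    )
  }
  structure(
    list(scenarios = sc, ratios = ratios),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Community dose scenarios (ADD, mg/kg-day)\n\n")
  sc <- x$scenarios
  tab <- data.frame(
    Community = sc$name,
    C = sc$concentration,
    IR = sc$intake_rate,
    EF = sc$exposure_factor,
    BW = sc$body_weight,
    ADD = format(sc$add_display, digits = 3, scientific = NA)
  )
  print(tab, row.names = FALSE)
  if (nrow(x$ratios)) {
    top <- x$ratios[which.max(x$ratios$ratio_display_inputs), ]
    cat(sprintf(
      "\nLargest dose ratio: %s / %s = %s (from displayed doses; %s at full precision)\n",
      top$numerator, top$denominator,
      format(round(top$ratio_display_inputs), big.mark = ","),
      format(round(top$ratio), big.mark = ",")
    ))
  }
  invisible(x)
}

#' Tidy a scenario report
#'
#' @param x a `scenario_report`.
#' @param ... unused.
#' @return tibble of per-scenario parameters and doses.
#' @export
tidy.scenario_report <- function(x, ...) {
  select(
    x$scenarios, "name", "concentration", "intake_rate",
    "exposure_factor", "body_weight", "unit_conversion",
    "add", "add_display"
  )
}

#' One-row summary of a scenario report
#'
#' @param x a `scenario_report`.
#' @param ... unused.
#' @return tibble with scenario count, dose extremes and the maximum
#'   pairwise ratio (displayed-dose convention).
#' @export
glance.scenario_report <- function(x, ...) {
  tibble(
    n_scenarios = nrow(x$scenarios),
    min_add = min(x$scenarios$add),
    max_add = max(x$scenarios$add),
    max_ratio_display_inputs = if (nrow(x$ratios)) {
      max(x$ratios$ratio_display_inputs)
    } else {
      NA_real_
    }
  )
}

#' Write a scenario report to disk
#'
#' Emits `scenarios.csv` and `ratios.csv` (full precision) plus a
#' human-readable `report.txt` (display-rounded).
#'
#' @param report a `scenario_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_scenario_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    scenarios = file.path(dir, "scenarios.csv"),
    ratios = file.path(dir, "ratios.csv"),
    text = file.path(dir, "report.txt")
  )
  readr::write_csv(
    select(report$scenarios, -"narrative_tags"), paths[["scenarios"]]
  )
  readr::write_csv(report$ratios, paths[["ratios"]])
  writeLines(utils::capture.output(print(report)), paths[["text"]])
  invisible(paths)
}
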
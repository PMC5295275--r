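#' Default pollutant set for the synthetic generator
#'
#' Six air toxics representative of vehicular and industrial emissions,
#' with generative parameters on the log-concentration scale: baseline
#' `log_mean` (log ug/m^3), additive effects of the non-white and poverty
#' fractions (`effect_race`, `effect_poverty`, per unit fraction) and a
#' lognormal noise scale `log_sd`.
#'
#' @return tibble with columns `name`, `log_mean`, `effect_race`,
#'   `effect_poverty`, `log_sd`.
#' @export
default_chemicals <- function() {
  tibble(
    name = c("acetaldehyde", "benzene", "cyanide", "toluene",
             "butadiene_13", "diesel_pm"),
    log_mean = log(c(1.5, 1.3, 0.05, 2.5, 0.08, 1.0)),
    effect_race = c(0.9, 1.0, 1.0, 1.0, 1.1, 1.3),
    effect_poverty = c(0.5, 0.6, 0.7, 0.6, 0.6, 0.7),
    log_sd = 0.25
  )
}

#' Default national grouped-age template
#'
#' Population shares per sex for the four age groups (0,10), (10,20),
#' (20,60) and 60+, close to the U.S. national distribution.
#'
#' @return tibble with columns `sex`, `lower`, `upper` (`NA` = open-ended),
#'   `percent`.
#' @export
default_age_template <- function() {
  tibble(
    sex = rep(c("male", "female"), each = 4),
    lower = rep(c(0, 10, 20, 60), 2),
    upper = rep(c(10, 20, 60, NA), 2),
    percent = c(
      0.13, 0.14, 0.55, 0.18,
      0.12, 0.13, 0.54, 0.21
    )
  )
}

#' Simulate a synthetic census-tract dataset
#'
#' Generates tract-level records with the statistical structure the
#' nationwide dose analysis assumes: a non-white fraction drawn from a Beta
#' distribution; a poverty fraction coupled to it through a logit-linear
#' link with Gaussian noise; per-chemical ambient concentrations that are
#' lognormal with a log-mean depending (optionally) on both demographic
#' fractions; and grouped age distributions jittered around a national
#' template and renormalized. Output uses the flat tract CSV schema (see
#' [read_tracts()]), so synthetic and real data are interchangeable
#' downstream.
#'
#' The generation is fully deterministic given `seed`. Fractions are
#' clipped to \[0, 1\] where the link could leave the unit interval; the
#' number of clipped values is recorded in attribute `n_clipped`.
#'
#' @param n_tracts number of tracts (>= 1).
#' @param seed integer RNG seed.
#' @param race_shape length-2 Beta shape parameters for the non-white
#'   fraction.
#' @param poverty_link list with `intercept`, `slope` and `sd` of the
#'   logit-linear poverty link: `logit(poverty) = intercept +
#'   slope * logit(nonwhite) + N(0, sd)`.
#' @param chemicals tibble as in [default_chemicals()].
#' @param age_template tibble as in [default_age_template()].
#' @param age_jitter_sd standard deviation of the additive jitter applied
#'   to the age-template shares before renormalization.
#' @return tibble of tract records: `tract_id`, `nonwhite_fraction`,
#'   `poverty_fraction`, `age_<sex>_<lower>_<upper|open>` columns and
#'   `conc_<chemical>` columns (ug/m^3).
#' @examples
#' tracts <- simulate_tracts(50, seed = 1)
#' @export
simulate_tracts <- function(n_tracts = 1000,
                            seed = 1,
                            race_shape = c(2, 3.5),
                            poverty_link = list(
                              intercept = -0.8, slope = 0.9, sd = 0.6
                            ),
                            chemicals = default_chemicals(),
                            age_template = default_age_template(),
                            age_jitter_sd = 0.02) {
  if (n_tracts < 1) abort_validation("`n_tracts` must be >= 1.")
  if (length(race_shape) != 2 || any(race_shape <= 0)) {
    abort_validation("`race_shape` must be two positive Beta parameters.")
  }
  needed <- c("intercept", "slope", "sd")
  if (!all(needed %in% names(poverty_link)) || poverty_link$sd < 0) {
    abort_validation(
      "`poverty_link` needs `intercept`, `slope` and non-negative `sd`."
    )
  }
  chem_cols <- c("name", "log_mean", "effect_race", "effect_poverty",
                 "log_sd")
  if (!all(chem_cols %in% names(chemicals)) ||
      any(chemicals$log_sd < 0)) {
    abort_validation(paste0(
      "`chemicals` needs columns ", paste(chem_cols, collapse = ", "),
      " with non-negative `log_sd`."
    ))
  }
  for (s in unique(age_template$sex)) {
    tot <- sum(age_template$percent[age_template$sex == s])
    if (abs(tot - 1) > 1e-6) {
      abort_validation(sprintf(
        "age-template percents for sex '%s' must sum to 1.", s
      ))
    }
  }
  if (age_jitter_sd < 0) abort_validation("`age_jitter_sd` must be >= 0.")

  withr::with_seed(seed, {
    r <- rbeta(n_tracts, race_shape[1], race_shape[2])
    p_lin <- poverty_link$intercept + poverty_link$slope * qlogis(r) +
      rnorm(n_tracts, 0, poverty_link$sd)
    p <- plogis(p_lin)
    n_clipped <- sum(r < 0 | r > 1 | p < 0 | p > 1)
    r <- pmin(pmax(r, 0), 1)
    p <- pmin(pmax(p, 0), 1)

    out <- tibble(
      tract_id = sprintf("T%05d", seq_len(n_tracts)),
      nonwhite_fraction = r,
      poverty_fraction = p
    )

    # age distributions: jitter the template, clamp at zero, renormalize
    for (s in unique(age_template$sex)) {
      tpl <- age_template[age_template$sex == s, ]
      shares <- matrix(
        rep(tpl$percent, each = n_tracts), nrow = n_tracts
      )
      if (age_jitter_sd > 0) {
        shares <- shares + matrix(
          rnorm(n_tracts * nrow(tpl), 0, age_jitter_sd),
          nrow = n_tracts
        )
        shares[shares < 0] <- 0
        shares <- shares / rowSums(shares)
      }
      cols <- sprintf(
        "age_%s_%g_%s", s, tpl$lower,
        ifelse(is.na(tpl$upper), "open", sprintf("%g", tpl$upper))
      )
      for (j in seq_along(cols)) out[[cols[j]]] <- shares[, j]
    }

    for (i in seq_len(nrow(chemicals))) {
      ch <- chemicals[i, ]
      log_c <- ch$log_mean + ch$effect_race * r + ch$effect_poverty * p +
        rnorm(n_tracts, 0, ch$log_sd)
      out[[paste0("conc_", ch$name)]] <- exp(log_c)
    }

    attr(out, "n_clipped") <- n_clipped
    out
  })
}

#' Summary moments of a tract dataset
#'
#' @param tracts tibble of tract records ([simulate_tracts()] or
#'   [read_tracts()]).
#' @return list of tibbles: `chemicals` (per-chemical mean/sd of log
#'   concentration), `fractions` (mean demographic fractions) and
#'   `score_counts` (tract counts per poverty-score x race-score
#'   combination, all 100 cells).
#' @export
summarize_tracts <- function(tracts) {
  conc_cols <- grep("^conc_", names(tracts), value = TRUE)
  chem <- purrr::map_dfr(conc_cols, function(cl) {
    x <- log(tracts[[cl]])
    tibble(
      chemical = sub("^conc_", "", cl),
      mean_log_conc = mean(x),
      sd_log_conc = stats::sd(x)
    )
  })
  fractions <- tibble(
    mean_nonwhite = mean(tracts$nonwhite_fraction),
    mean_poverty = mean(tracts$poverty_fraction)
  )
  counts <- tracts |>
    mutate(
      poverty_score = assign_score(.data$poverty_fraction),
      race_score = assign_score(.data$nonwhite_fraction)
    ) |>
    count(.data$poverty_score, .data$race_score, name = "n_tracts") |>
    tidyr::complete(
      poverty_score = 1:10, race_score = 1:10,
      fill = list(n_tracts = 0L)
    )
  list(chemicals = chem, fractions = fractions, score_counts = counts)
}
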
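#' Assign an EJ score to a population fraction
#'
#' The range \[0, 1\] is binned evenly into ten intervals, each associated
#' with an integer score from 1 to 10: a fraction in
#' \[(k-1)/10, k/10) receives score k, and the top bin is closed so that a
#' fraction of exactly 1 scores 10. Applied to the fraction of non-white
#' residents this yields the race/ethnicity score; applied to the fraction
#' of residents below 1.5 times the poverty level it yields the poverty
#' score.
#'
#' @param fraction population proportion(s) in \[0, 1\].
#' @return integer score(s) in 1..10.
#' @examples
#' assign_score(c(0.05, 0.10, 1.0)) # 1 2 10
#' @export
assign_score <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    abort_domain("`fraction` must lie in [0, 1].")
  }
  pmin(as.integer(floor(fraction * 10)) + 1L, 10L)
}

#' Fraction of residents below the poverty threshold
#'
#' The poverty indicator is the share of residents whose ratio of income to
#' the poverty level is strictly below 1.5 (income less than one-and-a-half
#' times the poverty level).
#'
#' @param income_to_poverty_ratios non-empty numeric vector of per-person
#'   ratios, all >= 0.
#' @param threshold ratio cutoff (default 1.5); the comparison is strict.
#' @return fraction in \[0, 1\].
#' @examples
#' poverty_fraction(c(0.5, 1.0, 2.0, 3.0)) # 0.5
#' @export
poverty_fraction <- function(income_to_poverty_ratios, threshold = 1.5) {
  if (length(income_to_poverty_ratios) == 0) {
    abort_domain("`income_to_poverty_ratios` must be non-empty.")
  }
  if (any(income_to_poverty_ratios < 0)) {
    abort_domain("income-to-poverty ratios must be non-negative.")
  }
  mean(income_to_poverty_ratios < threshold)
}

#' Weighted average age from a grouped age distribution
#'
#' Census age data come as population percentages per age interval. The
#' weighted average age is the sum over groups of the interval midpoint
#' times the group's population share; an open-ended top interval (e.g.
#' 60+) uses a predefined representative age instead of a midpoint.
#'
#' @param groups data frame with columns `lower` (years, inclusive),
#'   `upper` (years, or `NA` for an open-ended group) and `percent`
#'   (population share in \[0, 1\]; shares must sum to 1 within 1e-6).
#' @param open_ended_value representative age for open-ended groups
#'   (default 90 years).
#' @return weighted average age in years.
#' @examples
#' groups <- tibble::tibble(
#'   lower = c(0, 10, 20, 60), upper = c(10, 20, 60, NA),
#'   percent = c(0.10, 0.20, 0.40, 0.30)
#' )
#' weighted_average_age(groups) # 46.5
#' @export
weighted_average_age <- function(groups, open_ended_value = 90) {
  stopifnot(all(c("lower", "upper", "percent") %in% names(groups)))
  if (any(groups$lower < 0) || any(groups$percent < 0)) {
    abort_validation("age-group bounds and percents must be non-negative.")
  }
  if (any(!is.na(groups$upper) & groups$upper <= groups$lower)) {
    abort_validation("bounded age groups must have upper > lower.")
  }
  if (abs(sum(groups$percent) - 1) > 1e-6) {
    abort_validation(sprintf(
      "age-group percents must sum to 1 (got %.8f).", sum(groups$percent)
    ))
  }
  mid <- ifelse(is.na(groups$upper),
    open_ended_value,
    (groups$lower + groups$upper) / 2
  )
  sum(mid * groups$percent)
}

#' Pooled average age across tracts and sexes
#'
#' First averages the per-tract weighted ages within each sex, then averages
#' the per-sex means. The two steps matter: with unequal tract counts per
#' sex this differs from the grand mean over all (tract, sex) rows.
#'
#' @param per_tract_sex_ages data frame with columns `sex` and
#'   `weighted_age` (one row per tract and sex); at least two sexes must be
#'   present, each with at least one tract.
#' @return pooled average age in years.
#' @export
pooled_average_age <- function(per_tract_sex_ages) {
  stopifnot(all(c("sex", "weighted_age") %in% names(per_tract_sex_ages)))
  x <- per_tract_sex_ages[!is.na(per_tract_sex_ages$weighted_age), ]
  sexes <- unique(x$sex)
  if (length(sexes) < 2) {
    abort_domain("both sexes must be present with at least one tract each.")
  }
  per_sex <- vapply(
    sexes,
    function(s) mean(x$weighted_age[x$sex == s]),
    numeric(1)
  )
  mean(per_sex)
}
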
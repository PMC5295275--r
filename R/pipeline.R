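#' Long-format age distributions from a tract table
#'
#' Parses the flat `age_<sex>_<lower>_<upper|open>` columns into a tidy
#' table of grouped age shares.
#'
#' @param tracts tract tibble (see [read_tracts()]).
#' @return tibble with columns `tract_id`, `sex`, `lower`, `upper`
#'   (`NA` = open-ended), `percent`.
#' @export
tract_ages_long <- function(tracts) {
  age_cols <- grep("^age_[a-z]+_[0-9]+_([0-9]+|open)$",
                   names(tracts), value = TRUE)
  if (!length(age_cols)) {
    abort_validation("no `age_<sex>_<lower>_<upper|open>` columns found.")
  }
  long <- tidyr::pivot_longer(
    tracts[c("tract_id", age_cols)],
    cols = dplyr::all_of(age_cols),
    names_to = c("sex", "lower", "upper"),
    names_pattern = "^age_([a-z]+)_([0-9]+)_([0-9]+|open)$",
    values_to = "percent"
  )
  mutate(long,
    lower = as.numeric(.data$lower),
    upper = ifelse(.data$upper == "open", NA_real_,
                   suppressWarnings(as.numeric(.data$upper)))
  )
}

#' Long-format concentrations from a tract table
#'
#' @param tracts tract tibble.
#' @return tibble with columns `tract_id`, `chemical`, `concentration`.
#' @export
tract_concentrations_long <- function(tracts) {
  conc_cols <- grep("^conc_", names(tracts), value = TRUE)
  if (!length(conc_cols)) {
    abort_validation("no `conc_<chemical>` columns found.")
  }
  long <- tidyr::pivot_longer(
    tracts[c("tract_id", conc_cols)],
    cols = dplyr::all_of(conc_cols),
    names_to = "chemical", names_prefix = "conc_",
    values_to = "concentration"
  )
  long
}

#' Per-tract, per-sex weighted average ages
#'
#' @param tracts tract tibble.
#' @param open_ended_value representative age for open-ended groups.
#' @return tibble with columns `tract_id`, `sex`, `weighted_age`
#'   (`NA` where a tract's age shares are missing or do not sum to 1).
#' @export
tract_weighted_ages <- function(tracts, open_ended_value = 90) {
  ages <- tract_ages_long(tracts)
  wage_or_na <- function(lower, upper, percent) {
    if (anyNA(percent) || abs(sum(percent) - 1) > 1e-6) {
      return(NA_real_)
    }
    weighted_average_age(
      tibble(lower = lower, upper = upper, percent = percent),
      open_ended_value
    )
  }
  ages |>
    group_by(.data$tract_id, .data$sex) |>
    summarise(
      weighted_age = wage_or_na(.data$lower, .data$upper, .data$percent),
      .groups = "drop"
    )
}

#' Per-tract average daily doses
#'
#' Computes the ADD of every chemical in every tract from its ambient
#' concentration, an age-appropriate body weight and intake rate, and a
#' common exposure factor (default 1: residents constantly exposed to
#' ambient levels).
#'
#' Two age modes are available. In `"pooled"` mode (default) one national
#' average age — the pooled mean of per-tract, per-sex weighted ages, see
#' [pooled_average_age()] — selects a single body weight/intake rate pair
#' applied to every tract. In `"per_tract"` mode each tract's own weighted
#' age (mean of its per-sex weighted ages) drives the lookup; tracts whose
#' age data are missing or invalid are dropped with a warning and the
#' pipeline continues.
#'
#' @param tracts tract tibble.
#' @param ef_table exposure-factor lookup table ([read_ef_table()]).
#' @param exposure_factor common exposure factor in \[0, 1\].
#' @param age_mode `"pooled"` or `"per_tract"`.
#' @param unit_conversion multiplier on the C x IR product (default `1e-3`,
#'   ug to mg for inhalation).
#' @param open_ended_value representative age for open-ended age groups.
#' @return tibble with one row per (tract, chemical): `tract_id`,
#'   `chemical`, `concentration`, `age`, `body_weight`, `intake_rate`,
#'   `add` (mg/kg-day).
#' @examples
#' tracts <- simulate_tracts(20, seed = 1)
#' doses <- per_tract_add(tracts)
#' @export
per_tract_add <- function(tracts,
                          ef_table = default_ef_table(),
                          exposure_factor = 1,
                          age_mode = c("pooled", "per_tract"),
                          unit_conversion = 1e-3,
                          open_ended_value = 90) {
  age_mode <- match.arg(age_mode)
  wages <- tract_weighted_ages(tracts, open_ended_value)

  if (age_mode == "pooled") {
    pooled_age <- pooled_average_age(wages)
    by_tract <- tibble(
      tract_id = tracts$tract_id,
      age = pooled_age
    )
  } else {
    by_tract <- wages |>
      group_by(.data$tract_id) |>
      summarise(age = mean(.data$weighted_age), .groups = "drop")
    bad <- by_tract$tract_id[is.na(by_tract$age)]
    if (length(bad)) {
      warn(sprintf(
        "dropping %d tract(s) with missing/invalid age data: %s",
        length(bad), paste(head(bad, 5), collapse = ", ")
      ))
      by_tract <- by_tract[!is.na(by_tract$age), ]
    }
  }
  bwir <- ef_lookup(by_tract$age, ef_table)
  by_tract$body_weight <- bwir$body_weight
  by_tract$intake_rate <- bwir$intake_rate

  conc <- tract_concentrations_long(tracts)
  doses <- inner_join(conc, by_tract, by = "tract_id")
  mutate(doses,
    add = compute_add(
      .data$concentration, .data$intake_rate, exposure_factor,
      .data$body_weight, unit_conversion
    )
  )
}

tract_scores <- function(tracts) {
  tibble(
    tract_id = tracts$tract_id,
    poverty_score = assign_score(tracts$poverty_fraction),
    race_score = assign_score(tracts$nonwhite_fraction)
  )
}

#' Mean dose per EJ score stratum
#'
#' Groups tracts by EJ score — poverty, race, or every (poverty, race)
#' combination — and returns the unweighted arithmetic mean dose per
#' stratum and chemical. All scores 1..10 (or all 100 score pairs) are
#' present in the output; empty strata carry `n_tracts = 0` and a missing
#' mean (never zero — zero is a valid dose).
#'
#' @param doses per-tract dose table from [per_tract_add()] (columns
#'   `tract_id`, `chemical`, `add`).
#' @param tracts tract tibble providing the demographic fractions.
#' @param by `"poverty"`, `"race"`, or `"both"`.
#' @return for a single indicator, a tibble with columns `indicator`,
#'   `score`, `chemical`, `n_tracts`, `mean_add`; for `"both"`, columns
#'   `poverty_score`, `race_score`, `chemical`, `n_tracts`, `mean_add`.
#' @export
group_mean_by_score <- function(doses, tracts,
                                by = c("poverty", "race", "both")) {
  by <- match.arg(by)
  scores <- tract_scores(tracts)
  x <- inner_join(doses, scores, by = "tract_id")
  if (by == "both") {
    out <- x |>
      group_by(.data$poverty_score, .data$race_score, .data$chemical) |>
      summarise(
        n_tracts = dplyr::n_distinct(.data$tract_id),
        mean_add = mean(.data$add),
        .groups = "drop"
      ) |>
      tidyr::complete(
        poverty_score = 1:10, race_score = 1:10,
        chemical = unique(x$chemical),
        fill = list(n_tracts = 0L)
      )
    return(out)
  }
  score_col <- if (by == "poverty") "poverty_score" else "race_score"
  x$score <- x[[score_col]]
  x |>
    group_by(.data$score, .data$chemical) |>
    summarise(
      n_tracts = dplyr::n_distinct(.data$tract_id),
      mean_add = mean(.data$add),
      .groups = "drop"
    ) |>
    tidyr::complete(
      score = 1:10, chemical = unique(x$chemical),
      fill = list(n_tracts = 0L)
    ) |>
    mutate(indicator = by, .before = 1)
}

#' Normalize stratum means to percent of the per-chemical maximum
#'
#' Divides each value by the maximum across score categories within each
#' chemical and expresses the result as a percentage, so the maximum maps
#' to exactly 100 and chemicals on very different dose scales become
#' comparable on one plot.
#'
#' @param summaries score-stratified summary tibble (must contain
#'   `chemical` and the value column).
#' @param col column to normalize (default `mean_add`).
#' @return `summaries` with an added/overwritten `percent` column.
#' @export
normalize_to_percent <- function(summaries, col = mean_add) {
  col <- enquo(col)
  out <- summaries |>
    group_by(.data$chemical) |>
    mutate(percent = {
      v <- !!col
      m <- suppressWarnings(max(v, na.rm = TRUE))
      if (!is.finite(m) || m <= 0) {
        abort_domain(
          "normalization needs at least one positive stratum mean per chemical."
        )
      }
      v / m * 100
    }) |>
    ungroup()
  out
}

#' Exclude sparsely populated strata from reporting
#'
#' Score strata backed by very few tracts are unstable and are excluded
#' from reporting output (by default: poverty scores above 7, and empty
#' strata). Excluded rows are retained in the `"excluded"` attribute for
#' audit.
#'
#' @param summaries output of [group_mean_by_score()].
#' @param max_poverty_score highest poverty score kept (default 7).
#' @param min_n minimum tract count per stratum (default 1).
#' @return filtered tibble with attribute `excluded` holding the dropped
#'   rows.
#' @export
apply_exclusion <- function(summaries, max_poverty_score = 7, min_n = 1) {
  pov <- if ("poverty_score" %in% names(summaries)) {
    summaries$poverty_score
  } else if ("indicator" %in% names(summaries)) {
    ifelse(summaries$indicator == "poverty", summaries$score, NA_real_)
  } else {
    NA_real_
  }
  drop <- summaries$n_tracts < min_n |
    (!is.na(pov) & pov > max_poverty_score)
  kept <- summaries[!drop, ]
  attr(kept, "excluded") <- summaries[drop, ]
  kept
}

#' Build a 10 x 10 score surface
#'
#' Arranges the mean doses for every (poverty score, race score)
#' combination of one chemical (or mixture layer) into a 10 x 10 matrix,
#' with a parallel matrix of tract counts. Cells with no tracts are `NA` in
#' the dose grid; the count grid is always fully populated.
#'
#' @param pair_summaries output of `group_mean_by_score(..., by = "both")`.
#' @param chemical chemical (or layer label) to extract.
#' @return object of class `score_surface`: list with `grid` and `counts`
#'   (10 x 10 matrices, rows = poverty score, columns = race score) and
#'   `label`.
#' @export
build_surface <- function(pair_summaries, chemical) {
  need <- c("poverty_score", "race_score", "chemical", "n_tracts",
            "mean_add")
  stopifnot(all(need %in% names(pair_summaries)))
  x <- pair_summaries[pair_summaries$chemical == chemical, ]
  if (!nrow(x)) {
    abort_validation(sprintf("no rows for chemical '%s'.", chemical))
  }
  grid <- matrix(NA_real_, 10, 10,
    dimnames = list(poverty_score = 1:10, race_score = 1:10))
  counts <- matrix(0L, 10, 10,
    dimnames = list(poverty_score = 1:10, race_score = 1:10))
  idx <- cbind(x$poverty_score, x$race_score)
  counts[idx] <- x$n_tracts
  filled <- x$n_tracts > 0
  grid[idx[filled, , drop = FALSE]] <- x$mean_add[filled]
  structure(
    list(grid = grid, counts = counts, label = chemical),
    class = "score_surface"
  )
}

#' @export
print.score_surface <- function(x, ...) {
  cat(sprintf(
    "<score_surface> %s: %d of 100 cells populated, %d tracts\n",
    x$label, sum(!is.na(x$grid)), sum(x$counts)
  ))
  invisible(x)
}

#' @describeIn build_surface tidy a surface back into one row per cell.
#' @param x a `score_surface`.
#' @param ... unused.
#' @export
as_tibble.score_surface <- function(x, ...) {
  tibble(
    poverty_score = rep(1:10, times = 10),
    race_score = rep(1:10, each = 10),
    n_tracts = as.integer(x$counts),
    mean_add = as.numeric(x$grid),
    label = x$label
  )
}

#' Write a score surface as JSON
#'
#' Serializes the dose grid (missing cells as `null`), the count grid and
#' the label as nested 10 x 10 arrays.
#'
#' @param surface a `score_surface`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_surface_json <- function(surface, path) {
  obj <- list(
    label = surface$label,
    poverty_scores = 1:10,
    race_scores = 1:10,
    mean_add = lapply(1:10, function(i) unname(as.list(surface$grid[i, ]))),
    counts = lapply(1:10, function(i) unname(as.list(surface$counts[i, ])))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Cumulative mixture dose layers
#'
#' Builds the per-tract cumulative RPF-weighted dose layers used to stack
#' mixture surfaces: layer k is the sum over the first k chemicals of
#' `rpf * dose`, so layer 1 is the raw index-chemical dose and successive
#' layers are pointwise non-decreasing.
#'
#' @param doses per-tract dose table ([per_tract_add()]).
#' @param rpfs an [rpf_set()].
#' @param layer_order chemicals in stacking order; must start with the
#'   index chemical. Default: index chemical first, then the remaining
#'   `rpfs` chemicals present in `doses`.
#' @return tibble with columns `tract_id`, `layer`, `layer_label`, `add`.
#' @export
mixture_layers <- function(doses, rpfs, layer_order = NULL) {
  index <- attr(rpfs, "index_chemical")
  if (is.null(layer_order)) {
    layer_order <- c(
      index,
      setdiff(intersect(rpfs$chemical, unique(doses$chemical)), index)
    )
  }
  if (layer_order[1] != index) {
    abort(
      sprintf("`layer_order` must start with the index chemical '%s'.",
              index),
      class = "ejadd_config_error"
    )
  }
  missing_rpf <- setdiff(layer_order, rpfs$chemical)
  if (length(missing_rpf)) {
    abort_validation(sprintf(
      "no RPF available for: %s", paste(missing_rpf, collapse = ", ")
    ))
  }
  w <- setNames(rpfs$rpf, rpfs$chemical)
  x <- doses[doses$chemical %in% layer_order,
             c("tract_id", "chemical", "add")]
  wide <- tidyr::pivot_wider(
    x, names_from = "chemical", values_from = "add"
  )
  if (anyNA(wide[layer_order])) {
    abort_validation("every tract needs a dose for every layer chemical.")
  }
  purrr::map_dfr(seq_along(layer_order), function(k) {
    chems <- layer_order[seq_len(k)]
    cum <- Reduce(`+`, lapply(chems, function(ch) w[[ch]] * wide[[ch]]))
    tibble(
      tract_id = wide$tract_id,
      layer = k,
      layer_label = paste(chems, collapse = " + "),
      add = as.numeric(cum)
    )
  })
}
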
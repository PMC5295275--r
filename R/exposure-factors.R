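#' Path to a packaged example/asset file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return full path to the file.
#' @export
ejadd_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ejadd")))
  }
  path <- system.file("extdata", file, package = "ejadd")
  if (!nzchar(path)) {
    abort_validation(sprintf("no packaged file '%s'.", file))
  }
  path
}

#' Read an age-indexed exposure-factor lookup table
#'
#' The table maps age intervals to a recommended body weight and daily
#' intake rate, in the style of the EPA Exposure Factors Handbook. Columns:
#' `age_lower` (years, inclusive), `age_upper` (years, exclusive; blank for
#' the final open-ended interval), `body_weight_kg`, `intake_rate`,
#' `intake_units`. Intervals must tile the age axis from 0 upward with no
#' gaps or overlaps.
#'
#' The packaged default (`exposure_factors_default.csv`) is an illustrative
#' synthetic table — plausible values for inhalation, not a reproduction of
#' any handbook — so that all examples run without external documents.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return a validated tibble of class `ef_table`.
#' @export
read_ef_table <- function(path = ejadd_example("exposure_factors_default.csv")) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("age_lower", "age_upper", "body_weight_kg", "intake_rate")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort_validation(sprintf(
      "exposure-factor table lacks column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  tab <- dplyr::arrange(tab, .data$age_lower)
  viol <- validate_ef_table(tab)
  if (nrow(viol)) {
    abort_validation(paste0(
      "invalid exposure-factor table:\n",
      paste(sprintf("- %s", viol$message), collapse = "\n")
    ))
  }
  structure(tab, class = c("ef_table", class(tab)))
}

#' Default exposure-factor table
#'
#' Convenience wrapper around [read_ef_table()] for the packaged
#' illustrative table (inhalation; adult body weight 80 kg).
#'
#' @return an `ef_table` tibble.
#' @export
default_ef_table <- function() {
  read_ef_table()
}

#' Validate an exposure-factor table
#'
#' Checks that the age intervals start at 0, tile the age axis without gaps
#' or overlaps, end with one open-ended interval, and that body weights and
#' intake rates are positive.
#'
#' @param table data frame with the [read_ef_table()] columns.
#' @return tibble of violations (`type`, `age_lower`, `age_upper`,
#'   `message`); zero rows means the table is valid.
#' @export
validate_ef_table <- function(table) {
  v <- list()
  add <- function(type, lo, hi, msg) {
    v[[length(v) + 1]] <<- tibble(
      type = type, age_lower = lo, age_upper = hi, message = msg
    )
  }
  tab <- table[order(table$age_lower), ]
  n <- nrow(tab)
  if (n == 0) {
    add("empty", NA_real_, NA_real_, "table has no entries")
    return(bind_rows(v))
  }
  if (tab$age_lower[1] != 0) {
    add("gap", 0, tab$age_lower[1], sprintf(
      "ages [0, %g) are not covered", tab$age_lower[1]
    ))
  }
  if (!is.na(tab$age_upper[n])) {
    add("gap", tab$age_upper[n], Inf, sprintf(
      "ages beyond %g are not covered (last interval must be open-ended)",
      tab$age_upper[n]
    ))
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      hi <- tab$age_upper[i]
      lo_next <- tab$age_lower[i + 1]
      if (is.na(hi)) {
        add("overlap", tab$age_lower[i], NA_real_,
          sprintf("open-ended interval at age %g is not last",
                  tab$age_lower[i]))
      } else if (hi < lo_next) {
        add("gap", hi, lo_next,
          sprintf("gap at ages [%g, %g)", hi, lo_next))
      } else if (hi > lo_next) {
        add("overlap", lo_next, hi,
          sprintf("overlap at ages [%g, %g)", lo_next, hi))
      }
    }
  }
  bad_bw <- which(!is.finite(tab$body_weight_kg) | tab$body_weight_kg <= 0)
  for (i in bad_bw) {
    add("nonpositive", tab$age_lower[i], tab$age_upper[i],
      sprintf("body weight must be positive in interval starting %g",
              tab$age_lower[i]))
  }
  bad_ir <- which(!is.finite(tab$intake_rate) | tab$intake_rate <= 0)
  for (i in bad_ir) {
    add("nonpositive", tab$age_lower[i], tab$age_upper[i],
      sprintf("intake rate must be positive in interval starting %g",
              tab$age_lower[i]))
  }
  if (length(v)) bind_rows(v) else tibble(
    type = character(), age_lower = numeric(), age_upper = numeric(),
    message = character()
  )
}

#' Look up body weight and intake rate for an age
#'
#' Returns, for each age, the body weight and intake rate of the unique
#' table interval containing it (intervals are half-open `[lower, upper)`;
#' the final interval is open-ended).
#'
#' @param age numeric vector of ages in years (>= 0).
#' @param table an exposure-factor table (default: packaged table).
#' @return tibble with columns `age`, `body_weight`, `intake_rate`.
#' @export
ef_lookup <- function(age, table = default_ef_table()) {
  if (any(!is.finite(age)) || any(age < 0)) {
    abort_domain("`age` must be non-negative and finite.")
  }
  viol <- validate_ef_table(table)
  if (nrow(viol)) {
    abort_validation("exposure-factor table is invalid; see validate_ef_table().")
  }
  tab <- table[order(table$age_lower), ]
  idx <- findInterval(age, tab$age_lower)
  tibble(
    age = age,
    body_weight = tab$body_weight_kg[idx],
    intake_rate = tab$intake_rate[idx]
  )
}
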
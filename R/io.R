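#' Read a tract CSV
#'
#' The tract schema is flat and spreadsheet-safe: one row per tract with
#' columns `tract_id`, `nonwhite_fraction`, `poverty_fraction`, grouped age
#' shares encoded as `age_<sex>_<lower>_<upper|open>`, and one
#' `conc_<chemical>` column per pollutant. [simulate_tracts()] writes the
#' same schema, so synthetic and real data are interchangeable.
#'
#' Structural problems (missing required columns, no concentration columns)
#' are errors. Row-level problems — a fraction outside \[0, 1\], a negative
#' concentration, age shares not summing to 1, a duplicated tract id — are
#' rejected per row with a warning naming the offending file line numbers,
#' and reading continues with the valid rows.
#'
#' @param path CSV path.
#' @return tibble of validated tract records.
#' @export
read_tracts <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("tract_id", "nonwhite_fraction", "poverty_fraction")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort_validation(sprintf(
      "tract file lacks required column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  conc_cols <- grep("^conc_", names(tab), value = TRUE)
  if (!length(conc_cols)) {
    abort_validation("tract file has no `conc_<chemical>` columns.")
  }
  age_cols <- grep("^age_[a-z]+_[0-9]+_([0-9]+|open)$",
                   names(tab), value = TRUE)
  if (!length(age_cols)) {
    abort_validation(
      "tract file has no `age_<sex>_<lower>_<upper|open>` columns."
    )
  }

  bad <- rep(FALSE, nrow(tab))
  reason <- rep(NA_character_, nrow(tab))
  flag <- function(cond, why) {
    cond <- cond & !bad
    reason[cond] <<- why
    bad[cond] <<- TRUE
  }
  in01 <- function(x) is.finite(x) & x >= 0 & x <= 1
  flag(!in01(tab$nonwhite_fraction) | !in01(tab$poverty_fraction),
       "demographic fraction outside [0, 1]")
  for (cl in conc_cols) {
    flag(!is.finite(tab[[cl]]) | tab[[cl]] < 0,
         sprintf("negative or missing %s", cl))
  }
  sexes <- unique(sub("^age_([a-z]+)_.*$", "\\1", age_cols))
  for (s in sexes) {
    cols <- grep(sprintf("^age_%s_", s), age_cols, value = TRUE)
    shares <- as.matrix(tab[cols])
    flag(apply(shares, 1, function(r) {
      anyNA(r) || any(r < 0) || abs(sum(r) - 1) > 1e-6
    }), sprintf("age shares for sex '%s' invalid or not summing to 1", s))
  }
  flag(duplicated(tab$tract_id), "duplicated tract_id")

  if (any(bad)) {
    lines <- which(bad) + 1L # header is line 1
    warn(sprintf(
      "rejected %d row(s) of %s:\n%s",
      sum(bad), basename(path),
      paste(sprintf("- line %d: %s", head(lines, 10),
                    head(reason[bad], 10)),
            collapse = "\n")
    ))
  }
  tab[!bad, ]
}

#' Write a tract CSV
#'
#' Full-precision CSV in the [read_tracts()] schema; writing is
#' deterministic, so the same data always produce byte-identical files.
#'
#' @param tracts tract tibble.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tracts <- function(tracts, path) {
  readr::write_csv(tracts, path, progress = FALSE)
  invisible(path)
}
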
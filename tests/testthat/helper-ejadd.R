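# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately share no code with the package implementation.

# A small hand-built tract table in the flat CSV schema: identical national
# age template for every tract (so pooled and per-tract modes coincide
# unless perturbed), caller-chosen fractions and concentrations.
make_tracts <- function(nonwhite, poverty,
                        conc = list(benzene = rep(2, length(nonwhite)))) {
  n <- length(nonwhite)
  stopifnot(length(poverty) == n)
  out <- tibble::tibble(
    tract_id = sprintf("X%03d", seq_len(n)),
    nonwhite_fraction = nonwhite,
    poverty_fraction = poverty,
    age_male_0_10 = rep(0.10, n),
    age_male_10_20 = rep(0.20, n),
    age_male_20_60 = rep(0.40, n),
    age_male_60_open = rep(0.30, n),
    age_female_0_10 = rep(0.10, n),
    age_female_10_20 = rep(0.20, n),
    age_female_20_60 = rep(0.40, n),
    age_female_60_open = rep(0.30, n)
  )
  for (ch in names(conc)) out[[paste0("conc_", ch)]] <- conc[[ch]]
  out
}

# independent score binning: explicit scan over the ten intervals
oracle_score <- function(f) {
  for (k in 1:9) {
    if (f >= (k - 1) / 10 && f < k / 10) return(k)
  }
  10L
}

# independent per-stratum accumulation with plain lists and loops
oracle_group_means <- function(doses, tracts, by) {
  sc <- list()
  for (i in seq_len(nrow(tracts))) {
    sc[[tracts$tract_id[i]]] <- c(
      poverty = oracle_score(tracts$poverty_fraction[i]),
      race = oracle_score(tracts$nonwhite_fraction[i])
    )
  }
  acc <- list()
  tracts_seen <- list()
  for (i in seq_len(nrow(doses))) {
    s <- sc[[doses$tract_id[i]]]
    key <- switch(by,
      poverty = paste(s[["poverty"]], doses$chemical[i]),
      race = paste(s[["race"]], doses$chemical[i]),
      both = paste(s[["poverty"]], s[["race"]], doses$chemical[i])
    )
    acc[[key]] <- c(acc[[key]], doses$add[i])
    tracts_seen[[key]] <- union(tracts_seen[[key]], doses$tract_id[i])
  }
  list(
    mean = vapply(acc, mean, numeric(1)),
    n = vapply(tracts_seen, length, integer(1))
  )
}

# reference exposure-factor table known to tile the age axis
make_ef_table <- function() {
  tab <- tibble::tibble(
    age_lower = c(0, 1, 10, 20, 60),
    age_upper = c(1, 10, 20, 60, NA),
    body_weight_kg = c(8, 25, 58, 80, 78),
    intake_rate = c(7, 14, 21, 19, 16),
    intake_units = "m3/day"
  )
  tab
}
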
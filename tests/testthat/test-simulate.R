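test_that("generation is deterministic given the seed", {
  a <- simulate_tracts(60, seed = 4)
  b <- simulate_tracts(60, seed = 4)
  expect_identical(a, b)
  c <- simulate_tracts(60, seed = 5)
  expect_false(identical(a$nonwhite_fraction, c$nonwhite_fraction))
})

test_that("generated records satisfy the schema invariants", {
  tracts <- simulate_tracts(300, seed = 8)
  expect_true(all(tracts$nonwhite_fraction >= 0 &
                  tracts$nonwhite_fraction <= 1))
  expect_true(all(tracts$poverty_fraction >= 0 &
                  tracts$poverty_fraction <= 1))
  conc <- as.matrix(tracts[grep("^conc_", names(tracts))])
  expect_true(all(conc > 0))
  for (s in c("male", "female")) {
    shares <- as.matrix(tracts[grep(sprintf("^age_%s_", s), names(tracts))])
    expect_true(all(shares >= 0))
    expect_equal(unname(rowSums(shares)), rep(1, nrow(tracts)))
  }
  expect_false(anyNA(tracts))
  expect_identical(anyDuplicated(tracts$tract_id), 0L)
})

test_that("zero effects and zero noise give exactly the baseline level", {
  chems <- default_chemicals()
  chems$effect_race <- 0
  chems$effect_poverty <- 0
  chems$log_sd <- 0
  tracts <- simulate_tracts(25, seed = 3, chemicals = chems)
  for (i in seq_len(nrow(chems))) {
    expect_equal(
      tracts[[paste0("conc_", chems$name[i])]],
      rep(exp(chems$log_mean[i]), 25)
    )
  }
})

test_that("race effect induces the analytically implied log-concentration correlation", {
  # one chemical, no poverty effect: log C = m + b*R + e with R ~ Beta(a1,a2)
  # and e ~ N(0, s^2), so cor(R, log C) = b*sd(R) / sqrt(b^2 var(R) + s^2),
  # derived here from the generative model before sampling
  a1 <- 2; a2 <- 3.5; b <- 1.0; s <- 0.25
  var_r <- (a1 * a2) / ((a1 + a2)^2 * (a1 + a2 + 1))
  rho <- b * sqrt(var_r) / sqrt(b^2 * var_r + s^2)
  chems <- tibble::tibble(
    name = "benzene", log_mean = 0.3, effect_race = b,
    effect_poverty = 0, log_sd = s
  )
  tracts <- simulate_tracts(5000, seed = 21, race_shape = c(a1, a2),
                            chemicals = chems)
  got <- cor(tracts$nonwhite_fraction, log(tracts$conc_benzene))
  expect_lt(abs(got - rho), 0.05)
})

test_that("invalid generator configurations are rejected with field names", {
  expect_error(simulate_tracts(0, seed = 1),
               class = "ejadd_validation_error")
  expect_error(simulate_tracts(10, seed = 1, race_shape = c(-1, 2)),
               "race_shape", class = "ejadd_validation_error")
  expect_error(
    simulate_tracts(10, seed = 1,
                    poverty_link = list(intercept = 0, slope = 1)),
    "poverty_link", class = "ejadd_validation_error"
  )
  bad_tpl <- default_age_template()
  bad_tpl$percent[1] <- 0.5
  expect_error(simulate_tracts(10, seed = 1, age_template = bad_tpl),
               class = "ejadd_validation_error")
})

test_that("summaries report moments and a complete score-count table", {
  tracts <- simulate_tracts(120, seed = 13)
  sm <- summarize_tracts(tracts)
  expect_identical(nrow(sm$chemicals), 6L)
  expect_identical(nrow(sm$score_counts), 100L)
  expect_equal(sum(sm$score_counts$n_tracts), 120)
  one <- summarize_tracts(tracts[1, ])
  expect_equal(one$chemicals$mean_log_conc,
               log(as.numeric(tracts[1, paste0("conc_",
                 sm$chemicals$chemical)])))
  expect_equal(one$fractions$mean_nonwhite, tracts$nonwhite_fraction[1])
})
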
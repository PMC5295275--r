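test_that("compute_add evaluates C x IR x EF x conv / BW", {
  # wealthiest and EJ community parameter sets; display at 3 sig figs
  expect_equal(compute_add(5, 50, 0.125, 80, 1e-3), 3.90625e-4)
  expect_equal(signif_half_up(compute_add(5, 50, 0.125, 80, 1e-3), 3),
               3.91e-4)
  ej <- compute_add(5e3, 85, 1, 84, 1e-3)
  expect_equal(ej, 5000 * 85 * 1e-3 / 84)
  expect_equal(dose_display(ej), 5.06)
  expect_identical(compute_add(0, 50, 1, 80), 0)
  expect_identical(compute_add(3, 0, 1, 80), 0)
  expect_identical(compute_add(3, 50, 0, 80), 0)
})

test_that("compute_add rejects out-of-domain parameters", {
  expect_error(compute_add(5, 50, 1, 0), class = "ejadd_domain_error")
  expect_error(compute_add(5, 50, 1, -10), class = "ejadd_domain_error")
  expect_error(compute_add(-1, 50, 1, 80), class = "ejadd_domain_error")
  expect_error(compute_add(5, -1, 1, 80), class = "ejadd_domain_error")
  expect_error(compute_add(5, 50, 1.2, 80), class = "ejadd_domain_error")
  expect_error(compute_add(5, 50, 1, 80, 0), class = "ejadd_domain_error")
})

test_that("compute_add is linear in C, IR, EF and inverse in BW", {
  withr::with_seed(101, {
    for (i in 1:25) {
      C <- runif(1, 0.1, 100); IR <- runif(1, 1, 100)
      EF <- runif(1, 0, 1); BW <- runif(1, 10, 120)
      k <- runif(1, 0.5, 3)
      base <- compute_add(C, IR, EF, BW)
      expect_equal(compute_add(k * C, IR, EF, BW), k * base)
      expect_equal(compute_add(C, k * IR, EF, BW), k * base)
      expect_equal(compute_add(C, IR, EF, k * BW), base / k)
      if (k * EF <= 1) {
        expect_equal(compute_add(C, IR, k * EF, BW), k * base)
      }
    }
  })
})

test_that("exposure factor is contact hours over averaging time", {
  expect_equal(compute_exposure_factor(3), 0.125)
  expect_equal(compute_exposure_factor(24), 1)
  expect_equal(compute_exposure_factor(0), 0)
  expect_equal(compute_exposure_factor(6, 12), 0.5)
  expect_error(compute_exposure_factor(25), class = "ejadd_domain_error")
  expect_error(compute_exposure_factor(-1), class = "ejadd_domain_error")
  expect_error(compute_exposure_factor(1, 0), class = "ejadd_domain_error")
})

test_that("unit-risk ranges collapse to their midpoint", {
  expect_equal(unit_risk_point_value(c(2.2e-6, 7.8e-6)), 5e-6)
  expect_equal(unit_risk_point_value(3e-5), 3e-5)
  expect_equal(unit_risk_point_value(c(4e-6, 4e-6)), 4e-6)
  expect_error(unit_risk_point_value(c(7.8e-6, 2.2e-6)),
               class = "ejadd_domain_error")
  expect_error(unit_risk_point_value(-1e-6), class = "ejadd_domain_error")
  expect_error(unit_risk_point_value(c(1e-6, 2e-6, 3e-6)),
               class = "ejadd_domain_error")
})

test_that("RPFs are unit-risk ratios with reciprocal symmetry", {
  expect_equal(compute_rpf(3e-5, 5e-6), 6)
  expect_equal(compute_rpf(2.2e-6, 5e-6), 0.44)
  expect_equal(compute_rpf(5e-6, 5e-6), 1)
  expect_error(compute_rpf(0, 5e-6), class = "ejadd_domain_error")
  withr::with_seed(77, {
    for (i in 1:20) {
      a <- runif(1, 1e-7, 1e-4); b <- runif(1, 1e-7, 1e-4)
      expect_equal(compute_rpf(a, b) * compute_rpf(b, a), 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("rpf_set gives the index chemical RPF exactly 1", {
  rpfs <- rpf_set("benzene", list(
    benzene = c(2.2e-6, 7.8e-6), butadiene_13 = 3e-5, acetaldehyde = 2.2e-6
  ))
  expect_identical(rpfs$rpf[rpfs$chemical == "benzene"], 1)
  expect_equal(rpfs$rpf[rpfs$chemical == "butadiene_13"], 6)
  expect_equal(rpfs$rpf[rpfs$chemical == "acetaldehyde"], 0.44)
  expect_identical(attr(rpfs, "index_chemical"), "benzene")
  expect_error(rpf_set("toluene", list(benzene = 5e-6)),
               class = "ejadd_validation_error")
})

test_that("ICED mixture dose is the RPF-weighted sum", {
  rpfs <- rpf_set("benzene", list(
    benzene = 5e-6, butadiene_13 = 3e-5, acetaldehyde = 2.2e-6
  ))
  expect_equal(iced_mixture_dose(c(benzene = 2e-4), rpfs), 2e-4)
  expect_equal(
    iced_mixture_dose(c(benzene = 2e-4, butadiene_13 = 1e-5), rpfs),
    2.6e-4
  )
  # independently coded term-by-term summation over the three chemicals
  b <- 3e-4; d <- 2e-5; a <- 5e-4
  manual <- 1 * b + 6 * d + 0.44 * a
  expect_equal(
    iced_mixture_dose(
      c(benzene = b, butadiene_13 = d, acetaldehyde = a), rpfs
    ),
    manual
  )
  expect_error(
    iced_mixture_dose(c(benzene = 1e-4, toluene = 1e-4), rpfs),
    class = "ejadd_validation_error"
  )
})

test_that("ICED is permutation-invariant and additive over subsets", {
  rpfs <- rpf_set("benzene", list(
    benzene = 5e-6, butadiene_13 = 3e-5, acetaldehyde = 2.2e-6
  ))
  withr::with_seed(5, {
    for (i in 1:10) {
      doses <- setNames(runif(3, 0, 1e-3),
                        c("benzene", "butadiene_13", "acetaldehyde"))
      perm <- sample(doses)
      expect_equal(iced_mixture_dose(perm, rpfs),
                   iced_mixture_dose(doses, rpfs))
      expect_equal(
        iced_mixture_dose(doses, rpfs),
        iced_mixture_dose(doses[1], rpfs) +
          iced_mixture_dose(doses[2:3], rpfs)
      )
      expect_gte(iced_mixture_dose(doses, rpfs),
                 max(c(1, 6, 0.44)[match(names(doses),
                   c("benzene", "butadiene_13", "acetaldehyde"))] * doses))
    }
  })
})

test_that("scenario dose ratios support rounded-input and full precision", {
  # quoted convention: ratio of display-rounded doses
  expect_equal(scenario_dose_ratio(5.06, 3.91e-4), 5.06 / 3.91e-4)
  ej <- 5000 * 85 * 1e-3 / 84
  w <- 5 * 50 * 0.125 * 1e-3 / 80
  # full-precision division, computed independently here
  expect_equal(scenario_dose_ratio(ej, w), (425 / 84) / 3.90625e-4)
  expect_equal(scenario_dose_ratio(ej, w, round_inputs_to_sig_figs = 3),
               5.06 / 3.91e-4)
  expect_equal(scenario_dose_ratio(0.37, 0.37), 1)
  expect_error(scenario_dose_ratio(1, 0), class = "ejadd_domain_error")
})

test_that("display rounding follows the dose-table convention", {
  expect_equal(dose_display(3.90625e-4), 3.91e-4)
  expect_equal(dose_display(9.101941747e-3), 9.10e-3)
  expect_equal(dose_display(0.2253605769), 0.23)
  expect_equal(dose_display(5.059523810), 5.06)
  expect_equal(signif_half_up(0.0025, 2), 0.0025)
  expect_equal(signif_half_up(1.25, 2), 1.3) # half away from zero
  expect_equal(round_half_up(-1.25, 1), -1.3)
})
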
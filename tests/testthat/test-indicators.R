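test_that("score binning splits [0,1] into ten even half-open intervals", {
  expect_identical(assign_score(0.05), 1L)
  expect_identical(assign_score(0.10), 2L)
  expect_identical(assign_score(0), 1L)
  expect_identical(assign_score(1.0), 10L)
  expect_identical(assign_score(0.95), 10L)
  expect_error(assign_score(-0.01), class = "ejadd_domain_error")
  expect_error(assign_score(1.01), class = "ejadd_domain_error")
})

test_that("score binning is a monotone step function covering 1..10", {
  f <- (0:1000) / 1000
  s <- assign_score(f)
  expect_true(all(s %in% 1:10))
  expect_true(all(diff(s) >= 0))
  expect_identical(sort(unique(s)), 1:10)
  counts <- table(s)
  # ten bins of width ~0.1 over a grid of 1001 points
  expect_true(all(counts >= 99 & counts <= 102))
  # agreement with an interval-scan oracle on the same stored doubles
  expect_identical(s, vapply(f, oracle_score, integer(1)))
})

test_that("poverty fraction counts ratios strictly below the threshold", {
  expect_equal(poverty_fraction(c(0.5, 1.0, 2.0, 3.0)), 0.5)
  expect_equal(poverty_fraction(c(1.5, 2, 10)), 0)
  expect_equal(poverty_fraction(1.5), 0) # boundary: strict inequality
  expect_equal(poverty_fraction(1.4999), 1)
  expect_error(poverty_fraction(numeric()), class = "ejadd_domain_error")
  expect_error(poverty_fraction(c(1, -0.2)), class = "ejadd_domain_error")
  withr::with_seed(31, {
    for (i in 1:15) {
      r <- runif(sample(1:20, 1), 0, 4)
      brute <- sum(vapply(r, function(x) x < 1.5, logical(1))) / length(r)
      expect_equal(poverty_fraction(r), brute)
    }
  })
})

test_that("weighted average age evaluates midpoint-weighted sums", {
  groups <- tibble::tibble(
    lower = c(0, 10, 20, 60), upper = c(10, 20, 60, NA),
    percent = c(0.10, 0.20, 0.40, 0.30)
  )
  # evaluated independently: 5*0.10 + 15*0.20 + 40*0.40 + 90*0.30
  expect_equal(weighted_average_age(groups),
               5 * 0.10 + 15 * 0.20 + 40 * 0.40 + 90 * 0.30)
  expect_equal(weighted_average_age(groups), 46.5)
  one <- tibble::tibble(lower = 0, upper = 10, percent = 1)
  expect_equal(weighted_average_age(one), 5)
  sym <- tibble::tibble(lower = c(10, 30), upper = c(30, 50),
                        percent = c(0.5, 0.5))
  expect_equal(weighted_average_age(sym), 30)
})

test_that("weighted average age is order-invariant and linear in percents", {
  groups <- tibble::tibble(
    lower = c(0, 10, 20, 60), upper = c(10, 20, 60, NA),
    percent = c(0.10, 0.20, 0.40, 0.30)
  )
  shuffled <- groups[c(3, 1, 4, 2), ]
  expect_equal(weighted_average_age(shuffled), weighted_average_age(groups))
  # linearity: mixing two percent vectors mixes the results
  p2 <- c(0.25, 0.25, 0.25, 0.25)
  g2 <- groups; g2$percent <- p2
  lambda <- 0.3
  mix <- groups; mix$percent <- lambda * groups$percent + (1 - lambda) * p2
  expect_equal(
    weighted_average_age(mix),
    lambda * weighted_average_age(groups) +
      (1 - lambda) * weighted_average_age(g2)
  )
  bad <- groups; bad$percent <- bad$percent * 0.9
  expect_error(weighted_average_age(bad),
               class = "ejadd_validation_error")
})

test_that("pooled average age nests tract means within sex means", {
  x <- tibble::tibble(
    sex = c("male", "male", "female", "female"),
    weighted_age = c(40, 44, 46, 50)
  )
  expect_equal(pooled_average_age(x), 45)
  same <- tibble::tibble(sex = c("male", "female"), weighted_age = c(37, 37))
  expect_equal(pooled_average_age(same), 37)
  # unequal tract counts: sex-then-tract order matters
  asym <- tibble::tibble(
    sex = c("male", "female", "female"),
    weighted_age = c(40, 50, 50)
  )
  expect_equal(pooled_average_age(asym), mean(c(mean(40), mean(c(50, 50)))))
  expect_equal(pooled_average_age(asym), 45)
  expect_false(isTRUE(all.equal(pooled_average_age(asym),
                                mean(asym$weighted_age))))
  onesex <- tibble::tibble(sex = "male", weighted_age = 40)
  expect_error(pooled_average_age(onesex), class = "ejadd_domain_error")
})
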
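toy_series <- function() {
  phase_series(seq(0, 90, by = 10), c(10, 8, 6, 5, 6, 8, 9, 10, 10, 9))
}

test_that("ejection fraction reads the volume curve extremes", {
  f <- ejection_fraction(toy_series())
  expect_identical(f$ef, 0.5)
  expect_identical(f$diastolic_index, 1L)   # first occurrence of the maximum
  expect_identical(f$systolic_index, 4L)
  expect_identical(f$diastolic_volume, 10)
  expect_identical(f$systolic_volume, 5)
  expect_gte(f$diastolic_volume, f$systolic_volume)
  g <- glance(f)
  expect_equal(g$ef_percent, 50)
  td <- tidy(f)
  expect_true(td$is_diastole[1] && td$is_systole[4])

  const <- phase_series(c(0, 50), c(7, 7))
  expect_identical(ejection_fraction(const)$ef, 0)
  expect_error(ejection_fraction(phase_series(0, 5)), "at least 2")
  expect_error(phase_series(c(0, 10), c(5, -1)), "positive")
  expect_error(phase_series(c(0, 100), c(5, 5)), "\\[0, 100\\)")
})

test_that("ejection fraction is invariant under cyclic rotation of the phases", {
  s <- toy_series()
  for (k in c(2, 5, 8)) {
    rot <- phase_series(s$phase_percent, s$volume_cm3[c(k:10, 1:(k - 1))])
    expect_identical(ejection_fraction(rot)$ef, 0.5)
  }
})

test_that("Mosteller BSA and normalization follow the closed form", {
  b <- body_metrics(180, 80)
  expect_equal(b$bsa, 2)
  expect_equal(normalize_by_bsa(10, b), 5)
  ident <- body_metrics(60, 60)             # bsa exactly 1
  expect_equal(ident$bsa, 1)
  expect_equal(normalize_by_bsa(3.7, ident), 3.7)
  expect_error(body_metrics(-1, 70), "positive")
})

test_that("coefficient of variation matches the hand computation", {
  tb <- agreement_table(m1 = c(10, 10), m2 = c(12, 12))
  expect_equal(coefficient_of_variation(tb)$cov_percent, 100 * sqrt(2) / 11,
               tolerance = 1e-12)
  expect_equal(coefficient_of_variation(agreement_table(c(4, 5, 6), c(4, 5, 6)))$cov_percent, 0)
  # scale invariance
  tb2 <- agreement_table(m1 = c(10, 11, 14, 9), m2 = c(11, 10, 13, 10))
  expect_equal(coefficient_of_variation(tb2)$cov_percent,
               coefficient_of_variation(agreement_table(tb2$m1 * 3.7, tb2$m2 * 3.7))$cov_percent)
  expect_error(agreement_table(10, 12), "at least 2")
  expect_error(coefficient_of_variation(agreement_table(c(1, -1), c(-1, 1))),
               "grand mean")
})

test_that("Bland-Altman bias and limits match the hand computation", {
  tb <- agreement_table(m1 = c(1, 0, 1, 0), m2 = c(0, 1, 0, 1))  # d = 1,-1,1,-1
  ba <- bland_altman(tb)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_upper, 1.96 * sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_lower, -ba$loa_upper)
  expect_match(ba$interval, "^\\]-2.26; 2.26\\[$")
  # translation shifts the bias, not the width
  ba2 <- bland_altman(agreement_table(tb$m1 + 5, tb$m2))
  expect_equal(ba2$bias, 5)
  expect_equal(ba2$loa_upper - ba2$loa_lower, ba$loa_upper - ba$loa_lower)
  # identical raters collapse everything
  ba0 <- bland_altman(agreement_table(c(2, 3), c(2, 3)))
  expect_equal(c(ba0$bias, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))
})

test_that("paired t-test matches the t-distribution oracle and stats::t.test", {
  tb <- agreement_table(m1 = c(5, 7, 9), m2 = c(4, 5, 6))   # d = 1,2,3
  tt <- paired_t_test(tb)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  # numerical CDF oracle: integrate the t density
  dens <- function(x, df) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  p_num <- 2 * integrate(dens, lower = 2 * sqrt(3), upper = Inf, df = 2)$value
  expect_equal(tt$p_value, p_num, tolerance = 1e-8)

  set.seed(9)
  m1 <- rnorm(12, 10); m2 <- rnorm(12, 10)
  ours <- paired_t_test(agreement_table(m1, m2))
  ref <- stats::t.test(m1, m2, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # symmetry under swapping the raters
  swapped <- paired_t_test(agreement_table(m2, m1))
  expect_equal(swapped$p_value, ours$p_value)
  expect_equal(swapped$t, -ours$t)
  # all-zero differences use the defined convention
  z <- paired_t_test(agreement_table(c(1, 2, 3), c(1, 2, 3)))
  expect_identical(c(z$t, z$p_value), c(0, 1))
})

test_that("CoV, bias and limits collapse together on identical raters", {
  tb <- agreement_table(c(4.2, 5.5, 6.1), c(4.2, 5.5, 6.1))
  expect_equal(coefficient_of_variation(tb)$cov_percent, 0)
  ba <- bland_altman(tb)
  expect_true(ba$bias == 0 && ba$loa_lower == 0 && ba$loa_upper == 0)
  expect_equal(paired_t_test(tb)$p_value, 1)
})

test_that("result objects plot without error", {
  p1 <- autoplot(ejection_fraction(toy_series()))
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(bland_altman(agreement_table(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4))))
  expect_s3_class(p2, "ggplot")
})
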
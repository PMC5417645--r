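test_that("angle summaries use the sample standard deviation", {
  s <- angle_sample("anterior", c(29, 29, 29))
  expect_equal(summarize_angles(s)$mean_deg, 29)
  expect_equal(summarize_angles(s)$sd_deg, 0)
  s2 <- angle_sample("anterior", c(27, 31))
  expect_equal(summarize_angles(s2)$mean_deg, 29)
  expect_equal(summarize_angles(s2)$sd_deg, sqrt(8), tolerance = 1e-12)
  expect_error(summarize_angles(angle_sample("x", 30)), "two")
  # brute-force two-pass computation agrees
  x <- c(21.5, 33.2, 28.9, 30.1, 26.4)
  sm <- summarize_angles(angle_sample("x", x))
  expect_equal(sm$mean_deg, sum(x) / length(x))
  expect_equal(sm$sd_deg,
               sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1)))
})

test_that("large synthetic samples reproduce the generating moments", {
  s <- generate_angles(29, 3.9, n = 1e4, seed = 19)
  sm <- summarize_angles(s)
  expect_lt(abs(sm$mean_deg - 29), 0.15)
  expect_lt(abs(sm$sd_deg - 3.9), 0.15)
})

test_that("two-SD coverage matches direct enumeration", {
  # skewed sample with one extreme value, coverage by hand
  x <- c(1, 1, 1, 1, 89)
  s <- angle_sample("x", x)
  m <- mean(x); sdev <- sd(x)
  expected <- sum(x >= m - 2 * sdev & x <= m + 2 * sdev) / length(x)
  expect_equal(two_sd_coverage(s), expected)
  # the extreme point lies inside 2 SD here (Chebyshev-style sample)
  expect_equal(expected, 1)
  # constant sample: coverage 1 by the zero-SD rule
  expect_equal(two_sd_coverage(angle_sample("x", rep(29, 5))), 1)
  expect_error(two_sd_coverage(angle_sample("x", c(29, 30))), "three")
})

test_that("coverage is invariant to shifts and positive rescaling", {
  x <- generate_angles(20, 4, n = 200, seed = 4)$angles_deg
  base <- two_sd_coverage(angle_sample("x", x))
  expect_equal(two_sd_coverage(angle_sample("x", x + 10)), base)
  expect_equal(two_sd_coverage(angle_sample("x", x * 1.5)), base)
})

test_that("near-normal samples reach the 95 percent two-SD criterion", {
  s <- generate_angles(29, 3.9, n = 5000, seed = 1)
  expect_gte(two_sd_coverage(s), 0.95)
})

test_that("the K2 omnibus statistic matches an independent implementation", {
  # expected values computed with an independent skewness-kurtosis omnibus
  # implementation (scipy.stats.normaltest) on these exact literals
  x20 <- c(34.35, 26.80, 30.42, 31.47, 30.58, 28.59, 34.89, 28.63, 36.87,
           28.76, 34.09, 37.92, 23.58, 27.91, 28.48, 31.48, 27.89, 18.64,
           19.48, 34.15)
  res <- normality_check(angle_sample("x", x20))
  expect_equal(res$statistic, 1.866054249870, tolerance = 1e-9)
  expect_equal(res$p_value, 0.393361152918, tolerance = 1e-9)
  expect_identical(res$verdict, "pass")

  u60 <- seq(1.5, 88.5, length.out = 60)
  res_u <- normality_check(angle_sample("x", u60))
  expect_equal(res_u$statistic, 15.581399740211, tolerance = 1e-9)
  expect_equal(res_u$p_value, 0.000413563342, tolerance = 1e-7)
  expect_identical(res_u$verdict, "fail")
})

test_that("the normality check has reasonable size and power", {
  verdicts_norm <- vapply(1:30, function(s)
    normality_check(generate_angles(29, 3.9, n = 300, seed = 400 + s))$verdict,
    character(1))
  expect_gte(sum(verdicts_norm == "pass"), 25)

  verdicts_unif <- vapply(1:30, function(s) {
    set.seed(500 + s)
    normality_check(angle_sample("x", runif(300, 0.01, 89.99)))$verdict
  }, character(1))
  # uniform data fail the omnibus essentially always at this sample size
  expect_gte(sum(verdicts_unif == "fail"), 29)
})

test_that("degenerate samples are inconclusive rather than errors", {
  expect_identical(normality_check(angle_sample("x", rep(29, 10)))$verdict,
                   "inconclusive")
  expect_identical(normality_check(angle_sample("x", c(28, 29, 31)))$verdict,
                   "inconclusive")
})

test_that("angle CSV input and JSON report output work end to end", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    region = rep(c("anterior", "posterior"), each = 30),
    angle_deg = c(generate_angles(29, 3.9, 30, seed = 1)$angles_deg,
                  generate_angles(28, 4.1, 30, seed = 2)$angles_deg))
  write.csv(df, path, row.names = FALSE)
  samples <- read_angles_csv(path)
  expect_setequal(names(samples), c("anterior", "posterior"))
  expect_equal(length(samples$anterior$angles_deg), 30)
  out <- withr::local_tempfile(fileext = ".json")
  rep1 <- angle_report(samples, path = out)
  expect_true(file.exists(out))
  back <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(back$anterior$mean_deg, rep1$anterior$mean_deg)
  expect_true(all(c("two_sd_coverage", "normality") %in% names(back$anterior)))
})

test_that("out-of-range measurements are rejected", {
  expect_error(angle_sample("x", c(30, 91)), "between 0 and 90")
  expect_error(angle_sample("x", c(0, 30)), "between 0 and 90")
})
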
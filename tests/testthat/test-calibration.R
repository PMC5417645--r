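make_curve <- function(strain, stress, mode = "compression")
  stress_strain_curve(strain, stress, mode = mode)

test_that("mse is the mean squared stress residual on a shared strain grid", {
  a <- make_curve(c(0.1, 0.2), c(0.5, 0.7))
  expect_equal(mse(a, a), 0)
  b <- make_curve(c(0.1, 0.2), c(0.6, 0.6))  # residuals +0.1, -0.1
  expect_equal(mse(a, b), 0.01)
  # depends only on the multiset of residuals, not on which strain they sit at
  a2 <- make_curve(c(0.1, 0.2), c(0.5, 0.7))
  b2 <- make_curve(c(0.1, 0.2), c(0.4, 0.8))  # residuals -0.1, +0.1
  expect_equal(mse(a2, b2), mse(a, b))
  expect_error(mse(a, make_curve(c(0.1, 0.3), c(1, 1))), "strain grids")
})

test_that("r_squared follows the 1 - SSres/SStot definition", {
  obs <- make_curve(c(0.1, 0.2, 0.3), c(0.1, 0.3, 0.8))
  expect_equal(r_squared(obs, obs), 1)
  mean_pred <- make_curve(c(0.1, 0.2, 0.3), rep(mean(obs$stress), 3))
  expect_equal(r_squared(obs, mean_pred), 0)
  bad <- make_curve(c(0.1, 0.2, 0.3), c(0.8, 0.3, 0.1))
  expect_lt(r_squared(obs, bad), 0)
  flat <- make_curve(c(0.1, 0.2), c(0.5, 0.5))
  expect_error(r_squared(flat, flat), "variance")
})

test_that("noise-free on-grid parameters are recovered exactly (ground)", {
  e_grid <- seq(0.2, 0.5, by = 0.05)
  for (E in c(0.3, 0.45)) {
    target <- simulate_compression(elastic_to_ground(E, nu = 0.49))
    fit <- fit_ground(target, e_grid = e_grid)
    expect_equal(fit$best$E, E)
    expect_lt(fit$objective, 1e-20)
    expect_false(fit$boundary)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("noise-free on-grid parameters are recovered exactly (fibers)", {
  gp <- ref_mats$lateral$ground
  k1_grid <- c(1, 3, 5, 9, 15)
  k2_grid <- c(100, 400, 940, 1500)
  set.seed(21)
  draws <- cbind(sample(k1_grid, 3), sample(k2_grid, 3))
  for (i in seq_len(nrow(draws))) {
    truth <- fiber_params(draws[i, 1], draws[i, 2], 0.01, 30)
    target <- simulate_tension(gp, fibers = truth)
    fit <- fit_fibers(target, gp, theta_deg = 30,
                      k1_grid = k1_grid, k2_grid = k2_grid)
    expect_equal(fit$best$k1, draws[i, 1])
    expect_equal(fit$best$k2, draws[i, 2])
    expect_lt(fit$objective, 1e-18)
  }
})

test_that("the grid scan is exhaustive and the reported minimum is the trace minimum", {
  gp <- ref_mats$posterior$ground
  target <- simulate_tension(ref_mats$posterior)
  k1_grid <- c(1, 2, 4); k2_grid <- c(50, 150, 500, 1000)
  fit <- fit_fibers(target, gp, theta_deg = 28,
                    k1_grid = k1_grid, k2_grid = k2_grid)
  expect_equal(nrow(fit$trace), length(k1_grid) * length(k2_grid))
  # independent re-scan of the trace
  i_best <- order(fit$trace$objective, fit$trace$k1, fit$trace$k2)[1]
  expect_equal(fit$objective, min(fit$trace$objective))
  expect_equal(fit$best$k1, fit$trace$k1[i_best])
  expect_equal(fit$best$k2, fit$trace$k2[i_best])
  # every combination appears exactly once
  expect_equal(nrow(unique(fit$trace[, c("k1", "k2")])), nrow(fit$trace))
})

test_that("single-value grids return that value with the boundary flag", {
  target <- simulate_compression(elastic_to_ground(0.3, nu = 0.49))
  fit <- fit_ground(target, e_grid = 0.25)
  expect_equal(fit$best$E, 0.25)
  expect_true(fit$boundary)
  # degenerate fiber grid k1 = {0}: ground-only fit
  tens <- simulate_tension(ref_mats$posterior)
  ffit <- fit_fibers(tens, ref_mats$posterior$ground, theta_deg = 28,
                     k1_grid = 0, k2_grid = 50)
  expect_equal(ffit$best$k1, 0)
  expect_true(ffit$boundary)
})

test_that("ties break toward the smaller parameter values", {
  # a target that no candidate can alter: all candidates give identical
  # predictions when k1 = 0 is forced through equal fiber grids
  gp <- ref_mats$posterior$ground
  tens <- simulate_tension(gp, fibers = NULL)
  fit <- fit_fibers(tens, gp, theta_deg = 28,
                    k1_grid = c(0, 0.001), k2_grid = c(50, 100))
  # k1 = 0 rows tie exactly (k2 irrelevant); smallest (k1, k2) wins
  expect_equal(fit$best$k1, 0)
  expect_equal(fit$best$k2, 50)
})

test_that("refining the grid never increases the best objective", {
  target <- generate_curve(ref_mats$posterior, "compression",
                           noise = noise_model("multiplicative_gaussian",
                                               0.05, seed = 5))
  coarse <- fit_ground(target, e_grid = seq(0.3, 0.6, by = 0.1))
  fine <- fit_ground(target, e_grid = seq(0.3, 0.6, by = 0.05))
  expect_lte(fine$objective, coarse$objective)
})

test_that("repeated fits on identical input give identical traces", {
  target <- simulate_tension(ref_mats$lateral)
  gp <- ref_mats$lateral$ground
  f1 <- fit_fibers(target, gp, 30, k1_grid = c(1, 5), k2_grid = c(500, 940))
  f2 <- fit_fibers(target, gp, 30, k1_grid = c(1, 5), k2_grid = c(500, 940))
  expect_identical(f1$trace, f2$trace)
})

test_that("noisy compression curves recover E within one grid step", {
  truth_E <- 0.46
  truth <- simulate_compression(elastic_to_ground(truth_E, nu = 0.49))
  e_grid <- seq(0.3, 0.6, by = 0.02)
  hits <- 0
  for (s in 1:5) {
    noisy <- generate_curve(ref_mats$posterior, "compression",
                            noise = noise_model("multiplicative_gaussian",
                                                0.05, seed = 100 + s))
    # the posterior reference ground has E = 0.46 up to printed rounding
    fit <- fit_ground(noisy, e_grid = e_grid)
    if (abs(fit$best$E - truth_E) <= 0.02 + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("a cached tension grid reproduces the direct fit", {
  gp <- ref_mats$lateral$ground
  target <- simulate_tension(ref_mats$lateral)
  k1g <- c(1, 5, 9); k2g <- c(500, 940, 1400)
  cache <- tension_grid(gp, 30, k1g, k2g)
  direct <- fit_fibers(target, gp, 30, k1_grid = k1g, k2_grid = k2g)
  cached <- fit_fibers(target, gp, 30, grid_curves = cache)
  expect_equal(cached$best, direct$best)
  expect_equal(cached$objective, direct$objective)
  # mismatched strain grids are refused
  short <- simulate_tension(ref_mats$lateral, strain_levels = c(0.1, 0.2))
  expect_error(fit_fibers(short, gp, 30, grid_curves = cache), "strain")
})

test_that("mode mismatches are rejected", {
  tens <- simulate_tension(ref_mats$posterior)
  comp <- simulate_compression(ref_mats$posterior$ground)
  expect_error(fit_ground(tens), "compression")
  expect_error(fit_fibers(comp, ref_mats$posterior$ground, 28), "tension")
})
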
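test_that("the reference state is an equilibrium with zero stress", {
  gp <- ground_params(0.077, 0.261)
  st <- solve_uniaxial_state(gp, NULL, 1)
  expect_equal(st$stress, 0, tolerance = 1e-9)
  expect_equal(st$state$lambda_t1, 1, tolerance = 1e-8)
  expect_equal(st$state$lambda_t2, 1, tolerance = 1e-8)
})

test_that("axial stress matches the finite-difference derivative of relaxed energy", {
  # spot checks here; the full lambda sweep over all reference materials
  # runs in the acceptance suite
  gp <- elastic_to_ground(0.46, nu = 0.49)
  lat <- ref_mats$lateral
  cases <- list(list(gp, NULL, 0.8, "free"),
                list(gp, NULL, 1.3, "free"),
                list(lat$ground, lat$fibers, 1.4, "free"),
                list(lat$ground, lat$fibers, 1.4, "coupled"))
  for (cs in cases) {
    st <- solve_uniaxial_state(cs[[1]], cs[[2]], cs[[3]], lateral = cs[[4]])
    fd <- fd_axial_stress(cs[[1]], cs[[2]], cs[[3]], lateral = cs[[4]])
    expect_lt(abs(st$stress / fd - 1), 1e-5)
    expect_lt(st$transverse_residual, 1e-9)
  }
})

test_that("near-incompressible response approaches the incompressible closed form", {
  gp <- elastic_to_ground(0.46, nu = 0.49)
  mu0 <- 2 * gp$C10
  st <- solve_uniaxial_state(gp, NULL, 1.1)
  expect_lt(abs(st$stress / (mu0 * (1.1 - 1.1^-2)) - 1), 0.03)
})

test_that("isotropic materials deform with equal transverse stretches", {
  gp <- ground_params(0.05, 0.4)
  for (l3 in c(0.75, 0.9, 1.2, 1.5)) {
    st <- solve_uniaxial_state(gp, NULL, l3)
    expect_lt(abs(st$state$lambda_t1 - st$state$lambda_t2), 1e-10)
  }
})

test_that("compression curves behave physically", {
  soft <- simulate_compression(elastic_to_ground(0.2, nu = 0.49))
  stiff <- simulate_compression(elastic_to_ground(0.5, nu = 0.49))
  expect_identical(attr(soft, "mode"), "compression")
  expect_equal(soft$strain, c(0.10, 0.15, 0.20, 0.25, 0.30))
  # monotone increasing stress, pointwise stiffer material above softer
  expect_true(all(diff(soft$stress) > 0))
  expect_true(all(stiff$stress > soft$stress))
  # convex: increasing increments
  expect_true(all(diff(diff(stiff$stress) / diff(stiff$strain)) > 0))
  # empty strain list gives an empty curve
  expect_equal(nrow(simulate_compression(soft_gp <- elastic_to_ground(0.2, nu = 0.49),
                                         strain_levels = numeric(0))), 0L)
  expect_error(simulate_compression(soft_gp, strain_levels = 1.2), "strain")
})

test_that("fiber activation in compression is evaluated and reported", {
  ant <- ref_mats$anterior
  # shallow-angle fibers are stretched by the transverse expansion
  shallow <- simulate_compression(ant$ground, fibers = ant$fibers)
  expect_true(attr(shallow, "metadata")$fibers_active)
  # axial fibers are slack under axial compression: curve equals ground-only
  axial <- simulate_compression(ant$ground,
                                fibers = fiber_params(24, 1700, 0.01, 90))
  expect_false(attr(axial, "metadata")$fibers_active)
  ground_only <- simulate_compression(ant$ground)
  expect_equal(axial$stress, ground_only$stress, tolerance = 1e-9)
})

test_that("tension curves reduce to the ground substance when fibers are off", {
  gp <- elastic_to_ground(0.46, nu = 0.49)
  base <- simulate_tension(gp, fibers = NULL)
  zero_k1 <- simulate_tension(gp, fibers = fiber_params(0, 100, 0.01, 30))
  expect_equal(zero_k1$stress, base$stress, tolerance = 1e-12)
})

test_that("tensile stress is pointwise non-decreasing in k1", {
  gp <- elastic_to_ground(0.3, nu = 0.49)
  prev <- NULL
  for (k1 in c(1, 5, 15, 30, 45)) {
    cur <- simulate_tension(gp, fibers = fiber_params(k1, 500, 0.01, 29))
    if (!is.null(prev)) expect_true(all(cur$stress >= prev$stress - 1e-10))
    prev <- cur
  }
})

test_that("grip-constrained tension stiffens exponentially, free tension does not", {
  ant <- ref_mats$anterior
  coupled <- simulate_tension(ant, lateral = "coupled")
  free <- simulate_tension(ant, lateral = "free")
  # chord stiffness of the last segment vastly exceeds the first segment
  chord <- function(cv) diff(cv$stress) / diff(cv$strain)
  expect_gt(tail(chord(coupled), 1) / chord(coupled)[1], 10)
  # with free lateral faces the in-plane stretch contracts and the fibers
  # stay near their activation threshold: response close to ground-only
  free_ground <- simulate_tension(ant$ground, lateral = "free")
  expect_lt(max(abs(free$stress - free_ground$stress)) / max(free$stress),
            0.25)
  expect_gt(max(coupled$stress), 5 * max(free$stress))
})

test_that("tangent modulus is the final-chord slope", {
  lin <- stress_strain_curve(c(0.1, 0.2, 0.3), 2 * c(0.1, 0.2, 0.3),
                             mode = "tension")
  expect_equal(tangent_modulus(lin), 2)
  two <- stress_strain_curve(c(0.1, 0.2), c(0.1, 0.3), mode = "tension")
  expect_equal(tangent_modulus(two), 2.0)
  one <- stress_strain_curve(0.1, 0.1, mode = "tension")
  expect_error(tangent_modulus(one), "two")
  # convex stiffening: tangent modulus >= secant modulus from the origin
  cv <- simulate_tension(ref_mats$lateral)
  expect_gte(tangent_modulus(cv), max(cv$stress) / max(cv$strain))
})

test_that("curves survive a CSV round trip with their metadata line", {
  cv <- simulate_tension(ref_mats$posterior, strain_levels = c(0.1, 0.3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  expect_identical(readLines(path, n = 1L), "# mode=tension region=posterior")
  back <- read_curve_csv(path)
  expect_identical(attr(back, "mode"), "tension")
  expect_identical(attr(back, "region"), "posterior")
  expect_equal(back$strain, cv$strain)
  expect_equal(back$stress, cv$stress)
})

test_that("curve invariants are enforced", {
  expect_error(stress_strain_curve(c(0.2, 0.1), c(1, 2), "tension"),
               "increasing")
  expect_error(stress_strain_curve(c(0.1, 0.2), c(1, -2), "tension"),
               "non-negative")
  expect_error(stress_strain_curve(c(0, 0.2), c(0.5, 1), "tension"),
               "zero strain")
  expect_error(stress_strain_curve(0.1, c(1, 2), "tension"), "length")
})
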
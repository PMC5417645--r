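## Full-factorial grid-search calibration: MSE objective, R-squared
## reporting, exhaustive trace.

#' Mean squared error between two curves
#'
#' Mean over points of the squared stress residual at matched strains.  The
#' two curves must share the same strain grid; no resampling is performed,
#' mirroring a displacement-controlled test protocol.
#'
#' @param observed,predicted [stress_strain_curve()] objects on identical
#'   strain grids.
#' @return MSE, MPa^2.
#' @export
mse <- function(observed, predicted) {
  stopifnot(inherits(observed, "stress_strain_curve"),
            inherits(predicted, "stress_strain_curve"))
  if (nrow(observed) != nrow(predicted) ||
      (nrow(observed) && max(abs(observed$strain - predicted$strain)) > 1e-9))
    stop("curves are on different strain grids")
  mean((observed$stress - predicted$stress)^2)
}

#' Coefficient of determination between two curves
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the observed stresses.  Can be negative for predictions worse than the
#' observed mean.
#'
#' @inheritParams mse
#' @return R-squared, dimensionless.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(inherits(observed, "stress_strain_curve"),
            inherits(predicted, "stress_strain_curve"))
  if (nrow(observed) < 2L) stop("r_squared needs at least two points")
  if (nrow(observed) != nrow(predicted) ||
      max(abs(observed$strain - predicted$strain)) > 1e-9)
    stop("curves are on different strain grids")
  ss_tot <- sum((observed$stress - mean(observed$stress))^2)
  if (ss_tot == 0) stop("observed stresses have zero variance; R^2 undefined")
  1 - sum((observed$stress - predicted$stress)^2) / ss_tot
}

.check_grid <- function(values, name) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty grid for ", name)
  if (length(values) > 1L && any(diff(values) <= 0))
    stop("grid for ", name, " must be strictly increasing")
  values
}

.grid_fit <- function(stage, params, objective, extra = list()) {
  best_i <- which.min(objective)  # first minimum = smallest parameters
  structure(c(list(
    stage = stage,
    best = as.list(params[best_i, , drop = FALSE]),
    objective = objective[best_i],
    trace = cbind(params, objective = objective),
    boundary = any(vapply(names(params), function(nm) {
      v <- sort(unique(params[[nm]]))
      length(v) == 1L || params[[nm]][best_i] %in% v[c(1L, length(v))]
    }, logical(1L)))), extra),
    class = "hgo_grid_fit")
}

#' @export
print.hgo_grid_fit <- function(x, ...) {
  cat(sprintf("Grid-search fit (%s stage): %d combinations evaluated\n",
              x$stage, nrow(x$trace)))
  cat("  best: ",
      paste(sprintf("%s = %g", names(x$best), unlist(x$best)), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  objective (MSE) = %.6g MPa^2", x$objective))
  if (!is.null(x$r_squared)) cat(sprintf(", R^2 = %.4f", x$r_squared))
  cat("\n")
  if (isTRUE(x$boundary))
    cat("  note: optimum lies on a grid boundary\n")
  invisible(x)
}

#' Fit the ground substance to a compression curve
#'
#' Full-factorial search over the Young modulus at fixed Poisson ratio: each
#' candidate `E` is converted to Neo-Hookean parameters via
#' [elastic_to_ground()], the uniaxial compression test is simulated at the
#' target's strain levels, and the mean squared stress error is scored.  The
#' argmin is returned with the full trace; ties break toward the smaller
#' (softer) `E`.
#'
#' @param target a compression-mode [stress_strain_curve()].
#' @param e_grid candidate Young moduli, MPa, strictly increasing.  Default
#'   0.1 to 3 MPa in steps of 0.01.
#' @param nu fixed Poisson ratio (default 0.49, nearly incompressible).
#' @param settings a [solver_settings()] list.
#' @return An object of class `"hgo_grid_fit"` with fields `best`
#'   (`E`, `nu`, `C10`, `D`), `objective` (MPa^2), `r_squared`, `trace`
#'   (every evaluated combination), and `boundary` (TRUE when the optimum
#'   touches a grid edge).  Grid points whose simulation fails score an
#'   infinite objective rather than aborting the scan.
#' @examples
#' target <- simulate_compression(elastic_to_ground(0.3, nu = 0.49))
#' fit_ground(target, e_grid = seq(0.2, 0.4, by = 0.05))$best$E
#' @export
fit_ground <- function(target, e_grid = seq(0.1, 3, by = 0.01), nu = 0.49,
                       settings = solver_settings()) {
  stopifnot(inherits(target, "stress_strain_curve"))
  if (attr(target, "mode") != "compression")
    stop("fit_ground expects a compression curve")
  e_grid <- .check_grid(e_grid, "E")
  obj <- numeric(length(e_grid))
  pred_best <- NULL
  for (i in seq_along(e_grid)) {
    obj[i] <- tryCatch({
      pred <- simulate_compression(elastic_to_ground(e_grid[i], nu),
                                   strain_levels = target$strain,
                                   settings = settings)
      mse(target, pred)
    }, error = function(e) Inf)
  }
  fit <- .grid_fit("ground", data.frame(E = e_grid), obj)
  gp <- elastic_to_ground(fit$best$E, nu)
  fit$best$nu <- nu
  fit$best$C10 <- gp$C10
  fit$best$D <- gp$D
  pred <- simulate_compression(gp, strain_levels = target$strain,
                               settings = settings)
  fit$fitted <- pred
  fit$r_squared <- if (nrow(target) >= 2L && var(target$stress) > 0)
    r_squared(target, pred) else NA_real_
  fit
}

#' Precompute tension curves over a fiber-parameter grid
#'
#' Simulates the uniaxial tension test for every `(k1, k2)` combination at
#' fixed ground substance, angle and dispersion.  The result can be passed
#' to [fit_fibers()] to score many target curves (e.g. noisy replicates)
#' without re-running the solver.
#'
#' @inheritParams fit_fibers
#' @param strain_levels tensile strain levels of the virtual test.
#' @param lateral lateral boundary condition of the virtual tension test;
#'   see [simulate_tension()].
#' @return An object of class `"tension_grid"`: combinations in
#'   lexicographic `(k1, k2)` order with a stress matrix (one row per
#'   combination, one column per strain level).  Failed combinations carry
#'   `NA` stresses.
#' @export
tension_grid <- function(ground, theta_deg,
                         k1_grid = seq(1, 45, by = 1),
                         k2_grid = seq(50, 2000, by = 30),
                         kappa = 0.01,
                         strain_levels = c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60),
                         settings = solver_settings(),
                         lateral = c("coupled", "free")) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(ground, "ground_params"))
  k1_grid <- .check_grid(k1_grid, "k1")
  k2_grid <- .check_grid(k2_grid, "k2")
  combos <- expand.grid(k2 = k2_grid, k1 = k1_grid,
                        KEEP.OUT.ATTRS = FALSE)[, c("k1", "k2")]
  strain_levels <- sort(strain_levels)
  S <- matrix(NA_real_, nrow(combos), length(strain_levels))
  for (i in seq_len(nrow(combos))) {
    fp <- if (combos$k1[i] == 0)
      NULL
    else fiber_params(combos$k1[i], combos$k2[i], kappa, theta_deg)
    S[i, ] <- tryCatch(
      .simulate_levels(ground, fp, 1 + strain_levels, settings,
                       coupled = lateral == "coupled")$stress,
      error = function(e) rep(NA_real_, length(strain_levels)))
  }
  structure(list(combos = combos, stress = S, strain_levels = strain_levels,
                 ground = ground, theta_deg = theta_deg, kappa = kappa,
                 lateral = lateral),
            class = "tension_grid")
}

#' Fit the fiber parameters to a tension curve
#'
#' Exhaustive full-factorial evaluation of the `k1 x k2` grid at fixed
#' ground substance (from the prior compression fit), fiber angle and
#' dispersion.  The argmin of the mean squared stress error is returned;
#' ties break lexicographically toward smaller `(k1, k2)`.  The boundary
#' flag is set when the best point touches any grid edge, which matters in
#' practice because fitted `k1` values can sit on the lower bound of the
#' published search range.
#'
#' @param target a tension-mode [stress_strain_curve()].
#' @param ground a [ground_params()] object (held fixed).
#' @param theta_deg fiber angle from the transverse plane, degrees.
#' @param k1_grid,k2_grid candidate values, strictly increasing.  Defaults:
#'   `k1` 1-45 MPa step 1, `k2` 50-2000 step 30.
#' @param kappa fixed dispersion (default 0.01).
#' @param settings a [solver_settings()] list.
#' @param lateral lateral boundary condition of the virtual tension test;
#'   see [simulate_tension()].
#' @param grid_curves optional precomputed [tension_grid()] for the same
#'   ground/angle/dispersion and the target's strain levels.
#' @return An `"hgo_grid_fit"` object (see [fit_ground()]) whose `best`
#'   holds `k1` and `k2`.
#' @examples
#' gp <- elastic_to_ground(0.46, nu = 0.49)
#' target <- simulate_tension(gp, fibers = fiber_params(5, 500, 0.01, 30),
#'                            strain_levels = c(0.2, 0.4, 0.6))
#' fit_fibers(target, gp, theta_deg = 30,
#'            k1_grid = c(1, 5, 10), k2_grid = c(100, 500, 900))$best
#' @export
fit_fibers <- function(target, ground, theta_deg,
                       k1_grid = seq(1, 45, by = 1),
                       k2_grid = seq(50, 2000, by = 30),
                       kappa = 0.01,
                       settings = solver_settings(),
                       lateral = c("coupled", "free"),
                       grid_curves = NULL) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(target, "stress_strain_curve"))
  if (attr(target, "mode") != "tension")
    stop("fit_fibers expects a tension curve")
  if (is.null(grid_curves)) {
    grid_curves <- tension_grid(ground, theta_deg, k1_grid, k2_grid, kappa,
                                strain_levels = target$strain,
                                settings = settings, lateral = lateral)
  } else {
    stopifnot(inherits(grid_curves, "tension_grid"))
    if (length(grid_curves$strain_levels) != nrow(target) ||
        max(abs(grid_curves$strain_levels - target$strain)) > 1e-9)
      stop("grid_curves were computed on different strain levels")
  }
  resid2 <- sweep(grid_curves$stress, 2, target$stress)^2
  obj <- rowMeans(resid2)
  obj[!is.finite(obj)] <- Inf
  fit <- .grid_fit("fibers", grid_curves$combos, obj)
  best_i <- which.min(obj)
  pred <- stress_strain_curve(grid_curves$strain_levels,
                              grid_curves$stress[best_i, ],
                              mode = "tension")
  fit$fitted <- pred
  fit$r_squared <- if (nrow(target) >= 2L && var(target$stress) > 0)
    r_squared(target, pred) else NA_real_
  fit$theta_deg <- theta_deg
  fit$kappa <- kappa
  fit
}
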
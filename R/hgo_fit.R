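## The two-stage characterization as a classed model fit.

#' Fit the HGO annulus model to uniaxial specimen curves
#'
#' Runs the two-stage regional characterization: (1) the Neo-Hookean ground
#' substance is identified from the uniaxial compression curve by a
#' full-factorial search over the Young modulus at fixed Poisson ratio
#' ([fit_ground()]); (2) holding the ground substance fixed, the fiber
#' stiffness and non-linearity are identified from the uniaxial tension
#' curve by an exhaustive `k1 x k2` scan ([fit_fibers()]).  The fiber angle
#' comes from orientation measurements and is not fitted.
#'
#' If `tension` is missing the result is a ground-only material with the
#' fibers switched off (`k1 = 0`), with a warning.
#'
#' @param compression a compression-mode [stress_strain_curve()].
#' @param tension a tension-mode [stress_strain_curve()], or `NULL`.
#' @param theta_deg fiber angle from the transverse plane, degrees.
#' @param region optional region label (`"anterior"`, `"lateral"`,
#'   `"posterior"`).
#' @param e_grid,nu ground-stage grid and fixed Poisson ratio; see
#'   [fit_ground()].
#' @param k1_grid,k2_grid,kappa fiber-stage grids and fixed dispersion; see
#'   [fit_fibers()].
#' @param settings a [solver_settings()] list.
#' @param lateral lateral boundary condition of the virtual tension test;
#'   see [simulate_tension()].
#' @param grid_curves optional precomputed [tension_grid()] for the fiber
#'   stage.
#' @return An object of class `"hgo_fit"`: a list with `material` (a
#'   [material_region()]), `stages` (the two `"hgo_grid_fit"` objects),
#'   `curves` (the observed inputs), `r_squared` (per stage), and `call`.
#'   Supported methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' truth <- material_region("posterior", elastic_to_ground(0.46, nu = 0.49),
#'                          fiber_params(1, 50, 0.01, 28))
#' comp <- simulate_compression(truth$ground)
#' tens <- simulate_tension(truth)
#' fit <- hgo_fit(comp, tens, theta_deg = 28, region = "posterior",
#'                e_grid = seq(0.40, 0.50, by = 0.02),
#'                k1_grid = c(1, 2, 5), k2_grid = c(50, 500))
#' coef(fit)
#' @export
hgo_fit <- function(compression, tension = NULL, theta_deg,
                    region = NULL,
                    e_grid = seq(0.1, 3, by = 0.01), nu = 0.49,
                    k1_grid = seq(1, 45, by = 1),
                    k2_grid = seq(50, 2000, by = 30),
                    kappa = 0.01,
                    settings = solver_settings(),
                    lateral = c("coupled", "free"),
                    grid_curves = NULL) {
  cl <- match.call()
  lateral <- match.arg(lateral)
  ground_fit <- fit_ground(compression, e_grid = e_grid, nu = nu,
                           settings = settings)
  gp <- ground_params(ground_fit$best$C10, ground_fit$best$D)
  if (is.null(tension)) {
    warning("no tension curve supplied: returning a ground-only material (k1 = 0)")
    fiber_fit <- NULL
    fp <- NULL
  } else {
    fiber_fit <- fit_fibers(tension, gp, theta_deg = theta_deg,
                            k1_grid = k1_grid, k2_grid = k2_grid,
                            kappa = kappa, settings = settings,
                            lateral = lateral, grid_curves = grid_curves)
    fp <- fiber_params(fiber_fit$best$k1, fiber_fit$best$k2, kappa, theta_deg)
  }
  material <- material_region(
    region = if (is.null(region)) "unlabelled" else region,
    ground = gp, fibers = fp)
  structure(
    list(material = material,
         theta_deg = theta_deg, nu = nu, kappa = kappa, lateral = lateral,
         stages = list(ground = ground_fit, fibers = fiber_fit),
         curves = list(compression = compression, tension = tension),
         r_squared = c(compression = ground_fit$r_squared,
                       tension = if (is.null(fiber_fit)) NA_real_
                                 else fiber_fit$r_squared),
         settings = settings,
         call = cl),
    class = "hgo_fit")
}

#' @export
print.hgo_fit <- function(x, ...) {
  cat("HGO annulus characterization\n")
  cat("Region:", x$material$region, "\n")
  cat(sprintf("Ground substance: C10 = %.4g MPa, D = %.4g 1/MPa (E = %.4g MPa, nu = %.3g)\n",
              x$material$ground$C10, x$material$ground$D,
              x$stages$ground$best$E, x$nu))
  if (!is.null(x$material$fibers)) {
    cat(sprintf("Fibers: k1 = %.4g MPa, k2 = %.4g, kappa = %.3g, theta = %.3g deg\n",
                x$material$fibers$k1, x$material$fibers$k2,
                x$kappa, x$theta_deg))
  } else cat("Fibers: none (ground-only fit)\n")
  cat(sprintf("R^2: compression %.4f", x$r_squared[["compression"]]))
  if (!is.na(x$r_squared[["tension"]]))
    cat(sprintf(", tension %.4f", x$r_squared[["tension"]]))
  cat("\n")
  invisible(x)
}

#' @export
summary.hgo_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.hgo_fit")
}

#' @export
print.summary.hgo_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nGround stage:\n"); print(f$stages$ground)
  if (!is.null(f$stages$fibers)) {
    cat("\nFiber stage:\n"); print(f$stages$fibers)
  }
  invisible(x)
}

#' @export
coef.hgo_fit <- function(object, ...) {
  fb <- object$material$fibers
  c(C10 = object$material$ground$C10,
    D = object$material$ground$D,
    k1 = if (is.null(fb)) 0 else fb$k1,
    k2 = if (is.null(fb)) NA_real_ else fb$k2,
    kappa = object$kappa,
    theta_deg = object$theta_deg)
}

#' Predict nominal stresses from a fitted HGO model
#'
#' Re-runs the virtual specimen test at the requested strains using the
#' fitted material.
#'
#' @param object an [hgo_fit()] object.
#' @param strain engineering strain magnitudes; defaults to the observed
#'   strain levels of the requested mode.
#' @param mode `"tension"` or `"compression"`.
#' @param ... unused.
#' @return A numeric vector of nominal stress magnitudes, MPa.
#' @export
predict.hgo_fit <- function(object, strain = NULL,
                            mode = c("tension", "compression"), ...) {
  mode <- match.arg(mode)
  if (is.null(strain)) {
    obs <- object$curves[[mode]]
    if (is.null(obs)) stop("no observed ", mode, " curve to take strains from")
    strain <- obs$strain
  }
  curve <- if (mode == "tension")
    simulate_tension(object$material, strain_levels = strain,
                     settings = object$settings, lateral = object$lateral)
  else
    simulate_compression(object$material$ground, strain_levels = strain,
                         settings = object$settings)
  setNames(curve$stress, format(curve$strain))
}

#' @export
fitted.hgo_fit <- function(object, ...) {
  out <- list(compression = object$stages$ground$fitted)
  if (!is.null(object$stages$fibers))
    out$tension <- object$stages$fibers$fitted
  out
}

#' @export
residuals.hgo_fit <- function(object, ...) {
  fit <- fitted(object)
  res <- lapply(names(fit), function(mode) {
    obs <- object$curves[[mode]]
    data.frame(mode = mode, strain = obs$strain,
               residual = obs$stress - fit[[mode]]$stress)
  })
  do.call(rbind, res)
}

#' @export
plot.hgo_fit <- function(x, ...) {
  modes <- names(fitted(x))
  op <- par(mfrow = c(1, length(modes)), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (mode in modes) {
    obs <- x$curves[[mode]]
    pred <- fitted(x)[[mode]]
    plot(obs$strain, obs$stress, pch = 16,
         xlab = "engineering strain", ylab = "nominal stress (MPa)",
         main = sprintf("%s (%s)", mode, x$material$region), ...)
    lines(pred$strain, pred$stress, col = 2)
    legend("topleft", bty = "n", pch = c(16, NA), lty = c(NA, 1),
           col = c(1, 2), legend = c("observed", "fitted"))
  }
  invisible(x)
}

#' Simulate replicate noisy curves from a fitted HGO model
#'
#' Draws `nsim` replicate curves from the fitted material under the
#' multiplicative Gaussian noise model of [generate_curve()].
#'
#' @param object an [hgo_fit()] object.
#' @param nsim number of replicates.
#' @param seed integer seed for reproducibility.
#' @param mode `"tension"` or `"compression"`.
#' @param sigma relative noise standard deviation.
#' @param ... unused.
#' @return A list of [stress_strain_curve()] objects.
#' @export
simulate.hgo_fit <- function(object, nsim = 1, seed = NULL,
                             mode = c("tension", "compression"),
                             sigma = 0.05, ...) {
  mode <- match.arg(mode)
  strain <- object$curves[[mode]]$strain
  if (is.null(strain))
    strain <- if (mode == "tension") seq(0.1, 0.6, by = 0.1)
              else seq(0.10, 0.30, by = 0.05)
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  lapply(seeds, function(s)
    generate_curve(object$material, mode = mode, strain_levels = strain,
                   noise = noise_model("multiplicative_gaussian", sigma, s),
                   settings = object$settings, lateral = object$lateral))
}
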
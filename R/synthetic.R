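## Synthetic-data generation: forward-simulated curves with multiplicative
## Gaussian noise, fiber-angle draws, and the bundled reference values.

#' Noise model for synthetic stress-strain curves
#'
#' @param kind `"none"` or `"multiplicative_gaussian"` (each stress is
#'   scaled by `1 + eps` with `eps ~ Normal(0, sigma^2)`, clipped at -0.9 so
#'   stresses stay positive).
#' @param sigma relative standard deviation, dimensionless, >= 0.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(kind = c("none", "multiplicative_gaussian"),
                        sigma = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0)
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_model")
}

## run expr with a locally seeded RNG, leaving the caller's stream intact
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic stress-strain curve
#'
#' Forward-simulates the virtual specimen test for a material and applies
#' the noise model.  With `noise = noise_model("none")` the exact forward
#' curve is returned, so a subsequent fit on a grid containing the true
#' parameters recovers them exactly.
#'
#' @param mr a [material_region()] object.
#' @param mode `"tension"` or `"compression"`.
#' @param strain_levels engineering strain levels; defaults to the standard
#'   protocol of the requested mode.
#' @param noise a [noise_model()].
#' @param settings a [solver_settings()] list.
#' @param lateral lateral boundary condition of the virtual tension test;
#'   see [simulate_tension()].
#' @return A [stress_strain_curve()].
#' @examples
#' post <- af_reference()$materials$posterior
#' generate_curve(post, "tension",
#'                noise = noise_model("multiplicative_gaussian", 0.05, seed = 1))
#' @export
generate_curve <- function(mr, mode = c("tension", "compression"),
                           strain_levels = NULL,
                           noise = noise_model("none"),
                           settings = solver_settings(),
                           lateral = c("coupled", "free")) {
  mode <- match.arg(mode)
  lateral <- match.arg(lateral)
  stopifnot(inherits(mr, "material_region"), inherits(noise, "noise_model"))
  if (is.null(strain_levels))
    strain_levels <- if (mode == "tension") seq(0.1, 0.6, by = 0.1)
                     else seq(0.10, 0.30, by = 0.05)
  curve <- if (mode == "tension")
    simulate_tension(mr, strain_levels = strain_levels, settings = settings,
                     lateral = lateral)
  else
    simulate_compression(mr$ground, strain_levels = strain_levels,
                         fibers = NULL, region = mr$region,
                         settings = settings)
  if (noise$kind == "multiplicative_gaussian" && noise$sigma > 0) {
    eps <- .with_seed(noise$seed, rnorm(nrow(curve), 0, noise$sigma))
    eps <- pmax(eps, -0.9)
    curve <- stress_strain_curve(curve$strain, curve$stress * (1 + eps),
                                 mode = mode, region = mr$region,
                                 metadata = attr(curve, "metadata"))
  }
  curve
}

#' Generate synthetic fiber-angle measurements
#'
#' Draws `n` angles from `Normal(mean_deg, sd_deg)`, redrawing any value
#' outside the open interval (0, 90) degrees.
#'
#' @param mean_deg mean angle, degrees, in (0, 90).
#' @param sd_deg standard deviation, degrees, >= 0.
#' @param n number of measurements.
#' @param seed integer seed, or `NULL`.
#' @param region region label for the resulting sample.
#' @return An [angle_sample()] object.
#' @examples
#' generate_angles(29, 3.9, n = 50, seed = 1)
#' @export
generate_angles <- function(mean_deg, sd_deg, n, seed = NULL,
                            region = "unlabelled") {
  stopifnot(n >= 1, mean_deg > 0, mean_deg < 90, sd_deg >= 0)
  draws <- .with_seed(seed, {
    x <- rnorm(n, mean_deg, sd_deg)
    bad <- which(x <= 0 | x >= 90)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mean_deg, sd_deg)
      bad <- bad[x[bad] <= 0 | x[bad] >= 90]
    }
    x
  })
  angle_sample(region, draws)
}

#' Bundled reference characterization values
#'
#' The regional material parameters, median yield points, and fiber-angle
#' statistics of the published ovine lumbar annulus characterization that
#' this package re-implements, for use as test fixtures and worked
#' examples.  Each block carries a `source` tag naming what it is.
#'
#' @return A list:
#' \describe{
#'   \item{materials}{named list of [material_region()] objects for the
#'     anterior, lateral and posterior annulus, plus `nucleus` (ground-only
#'     Neo-Hookean).}
#'   \item{yield_points}{data frame of median yield stress (MPa, with SD)
#'     and the strain it occurs at, per region: single-point tension
#'     anchors.}
#'   \item{fiber_angles}{data frame of mean and SD of the measured fiber
#'     angles, degrees, per region.}
#'   \item{tangent_moduli}{data frame of reported specimen tangent moduli
#'     (MPa, with SD) per region.}
#' }
#' @examples
#' af_reference()$materials$posterior
#' @export
af_reference <- function() {
  mat <- function(region, C10, D, k1, k2, theta)
    material_region(region, ground_params(C10, D),
                    fiber_params(k1, k2, 0.01, theta))
  materials <- list(
    anterior  = mat("anterior",  0.061, 0.311, 24, 1700, 29),
    lateral   = mat("lateral",   0.033, 0.615,  5,  940, 30),
    posterior = mat("posterior", 0.077, 0.261,  1,   50, 28),
    nucleus   = structure(
      list(region = "nucleus", ground = ground_params(0.168, 0.12),
           fibers = NULL),
      class = "material_region"))
  attr(materials, "source") <- "reference regional material table (ovine lumbar disc model)"
  yp <- data.frame(
    region = c("anterior", "lateral", "posterior"),
    strain = c(0.5, 0.6, 0.6),
    stress_mpa = c(2.85, 1.95, 2.06),
    stress_sd_mpa = c(0.79, 0.86, 0.26))
  attr(yp, "source") <- "reported median yield points of the tensile specimen tests"
  fa <- data.frame(
    region = c("anterior", "lateral", "posterior"),
    mean_deg = c(29, 30, 28),
    sd_deg = c(3.9, 4.0, 4.1))
  attr(fa, "source") <- "reported fiber-angle means/SDs from MR measurements"
  tm <- data.frame(
    region = c("anterior", "lateral", "posterior"),
    modulus_mpa = c(5.6, 2.6, 2.7),
    modulus_sd_mpa = c(1.4, 1.2, 0.6))
  attr(tm, "source") <- "reported specimen tangent moduli (axial tangent stiffness)"
  list(materials = materials, yield_points = yp, fiber_angles = fa,
       tangent_moduli = tm)
}

#' Import curve sheets exported from the supplementary workbook
#'
#' Reads per-sheet CSV exports of the experimental workbook that accompanies
#' the reference characterization.  Expected layout: the first column is the
#' engineering strain; every further column is a nominal stress series in
#' MPa named for its region (`anterior`, `lateral`, `posterior`) or an
#' arbitrary series label.  The `'Little data'` sheet (ground-substance
#' compression) and the `'Anterior'`/`'Lateral'`/`'Posterior'` sheets
#' (tension medians) both follow this shape once exported to CSV.
#'
#' @param path CSV file path (one sheet per file).
#' @param mode loading mode of the series in this sheet.
#' @return A named list of [stress_strain_curve()] objects, one per stress
#'   column.  Rows with any missing value are dropped; a leading zero-strain
#'   row is retained only when its stress is zero.
#' @export
import_curve_sheet <- function(path, mode = c("compression", "tension")) {
  mode <- match.arg(mode)
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) < 2L)
    stop("sheet must have a strain column and at least one stress column: ",
         path)
  strain <- as.numeric(df[[1]])
  out <- list()
  for (nm in names(df)[-1]) {
    stress <- as.numeric(df[[nm]])
    keep <- is.finite(strain) & is.finite(stress)
    s <- strain[keep]; y <- stress[keep]
    o <- order(s); s <- s[o]; y <- y[o]
    if (length(s) && s[1] == 0 && y[1] != 0) { s <- s[-1]; y <- y[-1] }
    region <- if (tolower(nm) %in% c("anterior", "lateral", "posterior"))
      tolower(nm) else NULL
    out[[nm]] <- stress_strain_curve(s, y, mode = mode, region = region)
  }
  out
}
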
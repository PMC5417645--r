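## Material parameter containers and Neo-Hookean <-> elastic conversions.

#' Elastic constants of the ground substance
#'
#' Bundles the equivalent Young modulus and Poisson ratio of the isotropic
#' ground substance together with the derived shear and bulk moduli
#' `mu0 = E / (2 (1 + nu))` and `K0 = E / (3 (1 - 2 nu))`.
#'
#' @param E Young modulus, MPa; must be positive.
#' @param nu Poisson ratio, dimensionless; must lie in (0, 0.5).  The
#'   incompressible limit `nu = 0.5` is rejected because the compressibility
#'   parameter `D` of the Neo-Hookean form would vanish.
#' @return An object of class `"elastic_constants"`: a list with fields
#'   `E`, `nu`, `mu0`, `K0`.
#' @seealso [elastic_to_ground()], [ground_to_elastic()]
#' @examples
#' elastic_constants(E = 0.46, nu = 0.49)
#' @export
elastic_constants <- function(E, nu) {
  stopifnot(is.numeric(E), length(E) == 1L, is.numeric(nu), length(nu) == 1L)
  if (!is.finite(E) || E <= 0)
    stop("invalid elastic constants: E must be positive, got ", E)
  if (!is.finite(nu) || nu <= 0 || nu >= 0.5)
    stop("invalid elastic constants: nu must lie in (0, 0.5), got ", nu)
  structure(
    list(E = E, nu = nu,
         mu0 = E / (2 * (1 + nu)),
         K0  = E / (3 * (1 - 2 * nu))),
    class = "elastic_constants")
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat(sprintf("Elastic constants: E = %g MPa, nu = %g (mu0 = %g MPa, K0 = %g MPa)\n",
              x$E, x$nu, x$mu0, x$K0))
  invisible(x)
}

#' Neo-Hookean ground-substance parameters
#'
#' `C10` (MPa) sets the deviatoric stiffness of the matrix and `D`
#' (1/MPa) its compressibility; both must be positive.
#'
#' @param C10 deviatoric stiffness, MPa.
#' @param D compressibility parameter, 1/MPa.
#' @return An object of class `"ground_params"`.
#' @examples
#' ground_params(C10 = 0.077, D = 0.261)
#' @export
ground_params <- function(C10, D) {
  stopifnot(is.numeric(C10), length(C10) == 1L, is.numeric(D), length(D) == 1L)
  if (!is.finite(C10) || C10 <= 0)
    stop("invalid ground parameters: C10 must be positive, got ", C10)
  if (!is.finite(D) || D <= 0)
    stop("invalid ground parameters: D must be positive, got ", D)
  structure(list(C10 = C10, D = D), class = "ground_params")
}

#' @export
print.ground_params <- function(x, ...) {
  cat(sprintf("Neo-Hookean ground substance: C10 = %g MPa, D = %g 1/MPa\n",
              x$C10, x$D))
  invisible(x)
}

#' Collagen fiber parameters of the HGO model
#'
#' Two symmetric fiber families lie in the plane spanned by the first
#' transverse axis and the load (spine) axis, at `+theta_deg` and
#' `-theta_deg` from the transverse plane.
#'
#' @param k1 fiber stiffness, MPa; non-negative (`k1 = 0` switches the
#'   fibers off and recovers the Neo-Hookean matrix).
#' @param k2 fiber non-linearity, dimensionless; positive.
#' @param kappa dispersion, in `[0, 1/3]`: 0 means perfectly aligned fibers,
#'   1/3 the isotropic limit.  Default 0.01 (minimal dispersion).
#' @param theta_deg fiber angle from the transverse plane, degrees, in
#'   `[0, 90]`.
#' @param n_families number of fiber families; fixed at 2.
#' @return An object of class `"fiber_params"`.
#' @examples
#' fiber_params(k1 = 1, k2 = 50, theta_deg = 28)
#' @export
fiber_params <- function(k1, k2, kappa = 0.01, theta_deg, n_families = 2L) {
  stopifnot(length(k1) == 1L, length(k2) == 1L, length(kappa) == 1L,
            length(theta_deg) == 1L)
  if (!is.finite(k1) || k1 < 0)
    stop("invalid fiber parameters: k1 must be >= 0, got ", k1)
  if (!is.finite(k2) || k2 <= 0)
    stop("invalid fiber parameters: k2 must be > 0, got ", k2)
  if (!is.finite(kappa) || kappa < 0 || kappa > 1 / 3 + 1e-12)
    stop("invalid fiber parameters: kappa must lie in [0, 1/3], got ", kappa)
  if (!is.finite(theta_deg) || theta_deg < 0 || theta_deg > 90)
    stop("invalid fiber parameters: theta_deg must lie in [0, 90], got ",
         theta_deg)
  if (n_families != 2L)
    stop("only two symmetric fiber families (+theta, -theta) are supported")
  structure(
    list(k1 = k1, k2 = k2, kappa = min(kappa, 1 / 3),
         theta_deg = theta_deg, n_families = 2L),
    class = "fiber_params")
}

#' @export
print.fiber_params <- function(x, ...) {
  cat(sprintf(
    "HGO fibers: k1 = %g MPa, k2 = %g, kappa = %g, two families at +/-%g deg\n",
    x$k1, x$k2, x$kappa, x$theta_deg))
  invisible(x)
}

#' Regional annulus material definition
#'
#' @param region region label; the standard annulus regions are
#'   `"anterior"`, `"lateral"`, `"posterior"`, but any label is accepted so
#'   that non-annulus tissues can reuse the container.
#' @param ground a [ground_params()] object.
#' @param fibers a [fiber_params()] object, or `NULL` for a fiber-free
#'   (pure Neo-Hookean) material.
#' @return An object of class `"material_region"`.
#' @examples
#' material_region("posterior", ground_params(0.077, 0.261),
#'                 fiber_params(1, 50, 0.01, 28))
#' @export
material_region <- function(region, ground, fibers = NULL) {
  stopifnot(is.character(region), length(region) == 1L, nzchar(region))
  if (!inherits(ground, "ground_params"))
    stop("'ground' must be a ground_params object")
  if (!is.null(fibers) && !inherits(fibers, "fiber_params"))
    stop("'fibers' must be a fiber_params object or NULL")
  structure(list(region = region, ground = ground, fibers = fibers),
            class = "material_region")
}

#' @export
print.material_region <- function(x, ...) {
  cat(sprintf("Material region '%s'\n", x$region))
  print(x$ground)
  if (is.null(x$fibers)) cat("  (no fibers)\n") else print(x$fibers)
  invisible(x)
}

#' Convert elastic constants to Neo-Hookean parameters
#'
#' `C10 = mu0 / 2 = E / (4 (1 + nu))` and `D = 2 / K0 = 6 (1 - 2 nu) / E`.
#' Exact inverse of [ground_to_elastic()] to machine precision.
#'
#' @param ec an [elastic_constants()] object, or a Young modulus in MPa if
#'   `nu` is supplied.
#' @param nu Poisson ratio, used only when `ec` is numeric.
#' @return A [ground_params()] object.
#' @examples
#' elastic_to_ground(0.46, nu = 0.49)   # C10 ~ 0.077, D ~ 0.261
#' @export
elastic_to_ground <- function(ec, nu = NULL) {
  if (is.numeric(ec)) ec <- elastic_constants(ec, nu)
  stopifnot(inherits(ec, "elastic_constants"))
  ground_params(C10 = ec$mu0 / 2, D = 2 / ec$K0)
}

#' Convert Neo-Hookean parameters to elastic constants
#'
#' Inverts [elastic_to_ground()]: `mu0 = 2 C10`, `K0 = 2 / D`, then
#' `E = 9 K0 mu0 / (3 K0 + mu0)` and `nu = (3 K0 - 2 mu0) / (2 (3 K0 + mu0))`.
#' The resulting `nu` is always strictly below 0.5.
#'
#' @param gp a [ground_params()] object.
#' @return An [elastic_constants()] object.
#' @examples
#' ground_to_elastic(ground_params(0.077, 0.261))  # E ~ 0.46 MPa
#' @export
ground_to_elastic <- function(gp) {
  stopifnot(inherits(gp, "ground_params"))
  mu0 <- 2 * gp$C10
  K0  <- 2 / gp$D
  E   <- 9 * K0 * mu0 / (3 * K0 + mu0)
  nu  <- (3 * K0 - 2 * mu0) / (2 * (3 * K0 + mu0))
  elastic_constants(E = E, nu = nu)
}

#' Read or write a regional material as JSON
#'
#' The on-disk schema uses explicit-unit keys:
#' `{region, C10_MPa, D_per_MPa, k1_MPa, k2, kappa, theta_deg}`.  A
#' fiber-free material omits the fiber keys.
#'
#' @param mr a [material_region()] object.
#' @param path file path.
#' @return `read_material()` returns a [material_region()];
#'   `write_material()` returns `path` invisibly.
#' @export
write_material <- function(mr, path) {
  stopifnot(inherits(mr, "material_region"))
  x <- list(region = mr$region,
            C10_MPa = mr$ground$C10, D_per_MPa = mr$ground$D)
  if (!is.null(mr$fibers))
    x <- c(x, list(k1_MPa = mr$fibers$k1, k2 = mr$fibers$k2,
                   kappa = mr$fibers$kappa, theta_deg = mr$fibers$theta_deg))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_material
#' @export
read_material <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$region) && length(x) >= 1L && !is.null(x[[1]]$region))
    stop("file holds a material set; use read_material_set(): ", path)
  .material_from_list(x)
}

#' @rdname write_material
#' @export
read_material_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$region)) x <- list(x)
  out <- lapply(x, .material_from_list)
  names(out) <- vapply(out, function(m) m$region, character(1))
  out
}

.material_from_list <- function(x) {
  fibers <- NULL
  if (!is.null(x$k1_MPa))
    fibers <- fiber_params(k1 = x$k1_MPa, k2 = x$k2,
                           kappa = if (is.null(x$kappa)) 0.01 else x$kappa,
                           theta_deg = x$theta_deg)
  material_region(region = x$region,
                  ground = ground_params(C10 = x$C10_MPa, D = x$D_per_MPa),
                  fibers = fibers)
}
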
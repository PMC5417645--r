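## HGO strain energy and kinematics of homogeneous triaxial stretch.
##
## Convention: axis 3 is the specimen load axis (the spine axis); the two
## fiber families lie in the (axis-1, axis-3) plane at +theta and -theta
## measured from axis 1, i.e. from the transverse plane.  Under a diagonal
## stretch the two families see the same pseudo-invariant, but both are
## carried explicitly so that sign conventions stay auditable.

## fast numeric core: everything the solver loops over lives here, with no
## S3 containers in the hot path.  c2 = cos^2(theta), s2 = sin^2(theta).
.hgo_energy <- function(l1, l2, l3, C10, D, k1, k2, kappa, c2, s2) {
  J <- l1 * l2 * l3
  Jm23 <- J^(-2 / 3)
  I1b <- Jm23 * (l1 * l1 + l2 * l2 + l3 * l3)
  U <- C10 * (I1b - 3) + (1 / D) * ((J * J - 1) / 2 - log(J))
  if (k1 > 0) {
    I4b <- Jm23 * (l1 * l1 * c2 + l3 * l3 * s2)
    Eb <- kappa * (I1b - 3) + (1 - 3 * kappa) * (I4b - 1)
    if (Eb > 0)
      U <- U + (k1 / k2) * (exp(k2 * Eb * Eb) - 1)  # two identical families
  }
  U
}

## nominal (first Piola-Kirchhoff) stresses conjugate to the stretches:
## P_i = dU/dlambda_i.  Returns c(P1, P2, P3).
.hgo_gradient <- function(l1, l2, l3, C10, D, k1, k2, kappa, c2, s2) {
  J <- l1 * l2 * l3
  Jm23 <- J^(-2 / 3)
  I1b <- Jm23 * (l1 * l1 + l2 * l2 + l3 * l3)
  dI1 <- c(2 * Jm23 * l1 - (2 / 3) * I1b / l1,
           2 * Jm23 * l2 - (2 / 3) * I1b / l2,
           2 * Jm23 * l3 - (2 / 3) * I1b / l3)
  pvol <- (1 / D) * (J - 1 / J)
  P <- C10 * dI1 + pvol * c(J / l1, J / l2, J / l3)
  if (k1 > 0) {
    I4b <- Jm23 * (l1 * l1 * c2 + l3 * l3 * s2)
    Eb <- kappa * (I1b - 3) + (1 - 3 * kappa) * (I4b - 1)
    if (Eb > 0) {
      dI4 <- c(2 * Jm23 * l1 * c2 - (2 / 3) * I4b / l1,
               -(2 / 3) * I4b / l2,
               2 * Jm23 * l3 * s2 - (2 / 3) * I4b / l3)
      ## dU/dEb per family = k1 * Eb * exp(k2 Eb^2); two families
      P <- P + 2 * k1 * Eb * exp(k2 * Eb * Eb) *
        (kappa * dI1 + (1 - 3 * kappa) * dI4)
    }
  }
  P
}

.fiber_trig <- function(fibers) {
  if (is.null(fibers)) return(c(c2 = 0, s2 = 0, k1 = 0, k2 = 1, kappa = 0))
  th <- fibers$theta_deg * pi / 180
  c(c2 = cos(th)^2, s2 = sin(th)^2,
    k1 = fibers$k1, k2 = fibers$k2, kappa = fibers$kappa)
}

#' Kinematic state of a homogeneous triaxial stretch
#'
#' Computes the volume ratio, the deviatoric first invariant, and (when
#' fibers are supplied) the deviatoric fiber pseudo-invariants and the
#' strain-like fiber quantities
#' `E_bar = kappa (I1_bar - 3) + (1 - 3 kappa) (I4_bar - 1)`
#' for the two families at `+theta` and `-theta`.
#'
#' @param lambda_axial stretch along the load axis (axis 3); positive.
#' @param lambda_t1,lambda_t2 transverse stretches (axes 1 and 2); positive.
#'   Axis 1 is the in-plane axis of the fiber families.
#' @param fibers a [fiber_params()] object or `NULL`.
#' @return An object of class `"kinematic_state"`: a list with
#'   `lambda_axial`, `lambda_t1`, `lambda_t2`, `J`, `I1_bar`, and, with
#'   fibers, `I4_bar` and `E_bar` (length-2 vectors, families a = +theta,
#'   b = -theta).
#' @examples
#' uniaxial_kinematics(1.1, 0.95, 0.95, fiber_params(1, 50, 0.01, 28))
#' @export
uniaxial_kinematics <- function(lambda_axial, lambda_t1, lambda_t2,
                                fibers = NULL) {
  stopifnot(lambda_axial > 0, lambda_t1 > 0, lambda_t2 > 0)
  l1 <- lambda_t1; l2 <- lambda_t2; l3 <- lambda_axial
  J <- l1 * l2 * l3
  Jm23 <- J^(-2 / 3)
  I1b <- Jm23 * (l1^2 + l2^2 + l3^2)
  out <- list(lambda_axial = l3, lambda_t1 = l1, lambda_t2 = l2,
              J = J, I1_bar = I1b)
  if (!is.null(fibers)) {
    stopifnot(inherits(fibers, "fiber_params"))
    th <- fibers$theta_deg * pi / 180
    ## family a: (cos t, 0, sin t); family b: (cos t, 0, -sin t).  Under a
    ## diagonal stretch both give the same I4_bar; kept separate anyway.
    I4a <- Jm23 * (l1^2 * cos(th)^2 + l3^2 * sin(th)^2)
    I4b <- Jm23 * (l1^2 * cos(th)^2 + l3^2 * (-sin(th))^2)
    k <- fibers$kappa
    out$I4_bar <- c(a = I4a, b = I4b)
    out$E_bar <- c(a = k * (I1b - 3) + (1 - 3 * k) * (I4a - 1),
                   b = k * (I1b - 3) + (1 - 3 * k) * (I4b - 1))
  }
  structure(out, class = "kinematic_state")
}

#' @export
print.kinematic_state <- function(x, ...) {
  cat(sprintf("Stretches (t1, t2, axial) = (%.6g, %.6g, %.6g), J = %.6g, I1_bar = %.6g\n",
              x$lambda_t1, x$lambda_t2, x$lambda_axial, x$J, x$I1_bar))
  if (!is.null(x$E_bar))
    cat(sprintf("  I4_bar = (%.6g, %.6g), E_bar = (%.6g, %.6g)\n",
                x$I4_bar[1], x$I4_bar[2], x$E_bar[1], x$E_bar[2]))
  invisible(x)
}

#' HGO strain-energy density
#'
#' Evaluates
#' `U = C10 (I1_bar - 3) + (1/D) ((J^2 - 1)/2 - ln J)
#'    + k1/(2 k2) * sum_a (exp(k2 <E_bar_a>^2) - 1)`
#' where `<x> = max(x, 0)` is the Macaulay bracket: fibers contribute only
#' in tension (`E_bar > 0`).  With `fibers = NULL` or `k1 = 0` this is the
#' compressible Neo-Hookean energy of the ground substance.
#'
#' @param gp a [ground_params()] object.
#' @param fp a [fiber_params()] object or `NULL`.
#' @param ks a [uniaxial_kinematics()] state (its stretches are used).
#' @return Energy density, MPa.  Zero exactly at the undeformed state.
#' @examples
#' gp <- ground_params(0.077, 0.261)
#' strain_energy(gp, NULL, uniaxial_kinematics(1.1, 0.97, 0.97))
#' @export
strain_energy <- function(gp, fp, ks) {
  stopifnot(inherits(gp, "ground_params"), inherits(ks, "kinematic_state"))
  ft <- .fiber_trig(fp)
  U <- .hgo_energy(ks$lambda_t1, ks$lambda_t2, ks$lambda_axial,
                   gp$C10, gp$D, ft["k1"], ft["k2"], ft["kappa"],
                   ft["c2"], ft["s2"])
  if (!is.finite(U))
    stop("numeric overflow in strain energy (large k2 with large fiber strain)")
  unname(U)
}
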
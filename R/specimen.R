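## Virtual uniaxial specimen tests: homogeneous deformation with
## traction-free lateral faces.  The axial stretch is prescribed and the two
## transverse stretches are solved so that both transverse nominal stresses
## vanish; the axial nominal stress is then dU/dlambda_axial per unit
## reference area.

#' Transverse-equilibrium solver settings
#'
#' @param tol residual tolerance on the transverse nominal stresses, MPa.
#' @param max_iter maximum damped-Newton iterations per load step.
#' @param max_bisect maximum recursive bisections of a load step when the
#'   solver fails to converge from the previous solution (continuation).
#' @return A list of class `"solver_settings"`.
#' @export
solver_settings <- function(tol = 1e-9, max_iter = 100L, max_bisect = 12L) {
  stopifnot(tol > 0, max_iter >= 1, max_bisect >= 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 max_bisect = as.integer(max_bisect)),
            class = "solver_settings")
}

## Damped Newton on x = (lambda_t1, lambda_t2) with a forward-difference
## 2x2 Jacobian.  `p` is the flat parameter vector c(C10, D, k1, k2, kappa,
## c2, s2).  Returns list(x, P, residual, iterations, converged).
.newton_transverse <- function(l3, p, guess, tol, max_iter) {
  res <- function(x) {
    g <- .hgo_gradient(x[1], x[2], l3, p[1], p[2], p[3], p[4], p[5], p[6], p[7])
    g[1:2]
  }
  x <- guess
  r <- res(x)
  if (any(!is.finite(r))) { x <- c(1, 1); r <- res(x) }
  nr <- max(abs(r))
  for (it in seq_len(max_iter)) {
    if (is.finite(nr) && nr < tol) {
      P <- .hgo_gradient(x[1], x[2], l3, p[1], p[2], p[3], p[4], p[5], p[6], p[7])
      return(list(x = x, P = P, residual = nr, iterations = it - 1L,
                  converged = TRUE))
    }
    h1 <- 1e-7 * max(abs(x[1]), 1)
    h2 <- 1e-7 * max(abs(x[2]), 1)
    r1 <- res(c(x[1] + h1, x[2]))
    r2 <- res(c(x[1], x[2] + h2))
    Jm <- cbind((r1 - r) / h1, (r2 - r) / h2)
    step <- tryCatch(solve(Jm, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    t <- 1
    accepted <- FALSE
    for (k in 1:40) {
      xn <- x + t * step
      if (all(xn > 1e-4)) {
        rn <- res(xn)
        nn <- max(abs(rn))
        if (is.finite(nn) && (nn < nr || nn < tol)) {
          x <- xn; r <- rn; nr <- nn; accepted <- TRUE
          break
        }
      }
      t <- t / 2
    }
    if (!accepted) break
  }
  list(x = x, P = rep(NA_real_, 3), residual = nr, iterations = max_iter,
       converged = FALSE)
}

## Grip-constrained variant: the transverse stretches are tied
## (lambda_t1 = lambda_t2 = lt) and the NET transverse nominal stress
## P1 + P2 vanishes.  Scalar damped Newton.
.newton_coupled <- function(l3, p, guess, tol, max_iter) {
  res <- function(lt) {
    g <- .hgo_gradient(lt, lt, l3, p[1], p[2], p[3], p[4], p[5], p[6], p[7])
    g[1] + g[2]
  }
  x <- guess[1]
  r <- res(x)
  if (!is.finite(r)) { x <- 1; r <- res(x) }
  nr <- abs(r)
  for (it in seq_len(max_iter)) {
    if (is.finite(nr) && nr < tol) {
      P <- .hgo_gradient(x, x, l3, p[1], p[2], p[3], p[4], p[5], p[6], p[7])
      return(list(x = c(x, x), P = P, residual = nr, iterations = it - 1L,
                  converged = TRUE))
    }
    h <- 1e-7 * max(abs(x), 1)
    d <- (res(x + h) - r) / h
    if (!is.finite(d) || d == 0) break
    step <- -r / d
    t <- 1
    accepted <- FALSE
    for (k in 1:40) {
      xn <- x + t * step
      if (xn > 1e-4) {
        rn <- res(xn)
        nn <- abs(rn)
        if (is.finite(nn) && (nn < nr || nn < tol)) {
          x <- xn; r <- rn; nr <- nn; accepted <- TRUE
          break
        }
      }
      t <- t / 2
    }
    if (!accepted) break
  }
  list(x = c(x, x), P = rep(NA_real_, 3), residual = nr,
       iterations = max_iter, converged = FALSE)
}

## Continuation wrapper: try the target stretch directly from `guess`
## (solution at l3_from); on failure bisect the load step.
.solve_transverse <- function(l3, p, guess, l3_from, settings, depth = 0L,
                              coupled = FALSE) {
  sol <- if (coupled)
    .newton_coupled(l3, p, guess, settings$tol, settings$max_iter)
  else
    .newton_transverse(l3, p, guess, settings$tol, settings$max_iter)
  if (sol$converged) return(sol)
  if (depth >= settings$max_bisect)
    stop(sprintf(
      "transverse equilibrium failed at lambda_axial = %g (last residual %g MPa)",
      l3, sol$residual))
  mid <- (l3_from + l3) / 2
  half <- .solve_transverse(mid, p, guess, l3_from, settings, depth + 1L,
                            coupled = coupled)
  .solve_transverse(l3, p, half$x, mid, settings, depth + 1L,
                    coupled = coupled)
}

.flat_params <- function(gp, fp) {
  ft <- .fiber_trig(fp)
  c(gp$C10, gp$D, ft[["k1"]], ft[["k2"]], ft[["kappa"]], ft[["c2"]], ft[["s2"]])
}

#' Solve a uniaxial specimen state
#'
#' Prescribes the axial stretch and solves the two transverse stretches so
#' that both transverse nominal stresses vanish (traction-free lateral
#' faces), then returns the axial nominal stress `dU/dlambda_axial` at the
#' solved state.  For an isotropic (fiber-free) material the two transverse
#' stretches coincide.
#'
#' @param gp a [ground_params()] object.
#' @param fp a [fiber_params()] object or `NULL` for ground substance only.
#' @param lambda_axial axial stretch, positive (`> 1` tension, `< 1`
#'   compression).
#' @param settings a [solver_settings()] list.
#' @param guess optional starting value `c(lambda_t1, lambda_t2)`; by
#'   default the identity, with automatic load-step bisection from the
#'   undeformed state if the direct solve fails.
#' @param lateral lateral boundary condition.  `"free"` (default): the two
#'   transverse stretches are independent and each transverse nominal
#'   stress vanishes (traction-free lateral faces).  `"coupled"`: the
#'   transverse stretches are tied (`lambda_t1 = lambda_t2`) and the net
#'   transverse nominal stress `P1 + P2` vanishes — the package's
#'   homogeneous surrogate for a wide specimen whose large faces are held
#'   by the grips, which suppress preferential in-plane contraction along
#'   the fiber direction.
#' @return A list of class `"uniaxial_state"`: `state` (a
#'   [uniaxial_kinematics()] object), `stress` (axial nominal stress, MPa,
#'   signed), `transverse_residual` (MPa; for `"coupled"` the net
#'   residual), `iterations`.
#' @examples
#' gp <- elastic_to_ground(0.46, nu = 0.49)
#' solve_uniaxial_state(gp, NULL, 1.1)$stress
#' @export
solve_uniaxial_state <- function(gp, fp = NULL, lambda_axial,
                                 settings = solver_settings(), guess = NULL,
                                 lateral = c("free", "coupled")) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(gp, "ground_params"), lambda_axial > 0)
  p <- .flat_params(gp, fp)
  if (is.null(guess)) guess <- c(1, 1)
  sol <- .solve_transverse(lambda_axial, p, guess, 1, settings,
                           coupled = lateral == "coupled")
  structure(
    list(state = uniaxial_kinematics(lambda_axial, sol$x[1], sol$x[2], fp),
         stress = sol$P[3],
         transverse_residual = sol$residual,
         iterations = sol$iterations),
    class = "uniaxial_state")
}

#' @export
print.uniaxial_state <- function(x, ...) {
  cat(sprintf("Uniaxial state: axial nominal stress %.6g MPa (transverse residual %.2g MPa)\n",
              x$stress, x$transverse_residual))
  print(x$state)
  invisible(x)
}

## shared driver: solve a sequence of strain levels with continuation
.simulate_levels <- function(gp, fp, lambdas, settings, coupled = FALSE) {
  p <- .flat_params(gp, fp)
  n <- length(lambdas)
  stress <- numeric(n)
  ebar_max <- -Inf
  guess <- c(1, 1); l_prev <- 1
  for (i in seq_len(n)) {
    sol <- .solve_transverse(lambdas[i], p, guess, l_prev, settings,
                             coupled = coupled)
    stress[i] <- sol$P[3]
    if (p[3] > 0) {
      l1 <- sol$x[1]; l2 <- sol$x[2]; l3 <- lambdas[i]
      Jm23 <- (l1 * l2 * l3)^(-2 / 3)
      I1b <- Jm23 * (l1^2 + l2^2 + l3^2)
      I4b <- Jm23 * (l1^2 * p[6] + l3^2 * p[7])
      ebar_max <- max(ebar_max,
                      p[5] * (I1b - 3) + (1 - 3 * p[5]) * (I4b - 1))
    }
    guess <- sol$x; l_prev <- lambdas[i]
  }
  list(stress = stress, fibers_active = is.finite(ebar_max) && ebar_max > 0,
       ebar_max = ebar_max)
}

#' Simulate a uniaxial compression test
#'
#' Imposes compressive engineering strains (default 10, 15, 20, 25, 30 % of
#' specimen height, i.e. `lambda = 1 - strain`) and records the magnitude of
#' the axial nominal stress.  By default the test characterizes the ground
#' substance alone (`fibers = NULL`).  If fibers are supplied they are
#' evaluated, not assumed inactive: with shallow fiber angles the
#' near-incompressible transverse expansion can stretch the fiber
#' directions, in which case the returned curve flags `fibers_active` in its
#' metadata.
#'
#' @param gp a [ground_params()] object.
#' @param strain_levels compressive engineering strains in (0, 1).
#' @param fibers optional [fiber_params()].
#' @param region optional region label carried into the curve.
#' @param settings a [solver_settings()] list.
#' @return A [stress_strain_curve()] with `mode = "compression"`.
#' @examples
#' simulate_compression(elastic_to_ground(0.46, nu = 0.49))
#' @export
simulate_compression <- function(gp,
                                 strain_levels = c(0.10, 0.15, 0.20, 0.25, 0.30),
                                 fibers = NULL, region = NULL,
                                 settings = solver_settings()) {
  if (length(strain_levels) == 0L)
    return(stress_strain_curve(numeric(0), numeric(0), mode = "compression",
                               region = region))
  if (any(strain_levels <= 0 | strain_levels >= 1))
    stop("compressive strain levels must lie in (0, 1)")
  strain_levels <- sort(strain_levels)
  sim <- .simulate_levels(gp, fibers, 1 - strain_levels, settings)
  stress_strain_curve(strain_levels, abs(sim$stress), mode = "compression",
                      region = region,
                      metadata = list(fibers_active = sim$fibers_active))
}

#' Simulate a uniaxial tension test
#'
#' Imposes tensile engineering strains (default 10-60 % of specimen height,
#' `lambda = 1 + strain`) on a regional material; the fiber families
#' contribute wherever their strain-like quantity `E_bar` is positive.
#'
#' The default lateral condition is `"coupled"`: the tensile annulus
#' specimen this test emulates is a wide slab stretched across its height
#' with the large faces held by the grips, so the two transverse stretches
#' are tied and only their net traction vanishes.  This is what engages the
#' fiber families and produces the characteristic exponential stiffening.
#' With `lateral = "free"` (both faces individually traction-free) the
#' in-plane stretch contracts until the fibers sit at their activation
#' threshold, and the response stays close to the ground substance alone —
#' uniaxial tension with fully free lateral faces cannot load
#' shallow-angle fibers.
#'
#' @param mr a [material_region()] object, or a [ground_params()] object
#'   combined with the `fibers` argument.
#' @param strain_levels tensile engineering strains in (0, 1].
#' @param fibers optional [fiber_params()] when `mr` is a plain
#'   [ground_params()] object.
#' @param settings a [solver_settings()] list.
#' @param lateral lateral boundary condition, see [solve_uniaxial_state()].
#' @return A [stress_strain_curve()] with `mode = "tension"`.
#' @examples
#' post <- af_reference()$materials$posterior
#' simulate_tension(post, strain_levels = c(0.1, 0.2))
#' @export
simulate_tension <- function(mr,
                             strain_levels = c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60),
                             fibers = NULL,
                             settings = solver_settings(),
                             lateral = c("coupled", "free")) {
  lateral <- match.arg(lateral)
  if (inherits(mr, "material_region")) {
    gp <- mr$ground; fp <- mr$fibers; region <- mr$region
  } else {
    gp <- mr; fp <- fibers; region <- NULL
  }
  stopifnot(inherits(gp, "ground_params"))
  if (length(strain_levels) == 0L)
    return(stress_strain_curve(numeric(0), numeric(0), mode = "tension",
                               region = region))
  if (any(strain_levels <= 0 | strain_levels > 1))
    stop("tensile strain levels must lie in (0, 1]")
  strain_levels <- sort(strain_levels)
  sim <- .simulate_levels(gp, fp, 1 + strain_levels, settings,
                          coupled = lateral == "coupled")
  stress_strain_curve(strain_levels, sim$stress, mode = "tension",
                      region = region,
                      metadata = list(fibers_active = sim$fibers_active))
}

#' Tangent modulus of a stress-strain curve
#'
#' The specimen Young modulus is taken as the tangent stiffness in the axial
#' direction, computed as the slope of the final chord (the last two points)
#' of the curve.  For the exponentially stiffening tension curves this is
#' the stiffness at the largest applied strain.
#'
#' @param curve a [stress_strain_curve()] with at least two points.
#' @return Tangent modulus, MPa.
#' @examples
#' tangent_modulus(stress_strain_curve(c(0.1, 0.2), c(0.1, 0.3), "tension"))
#' @export
tangent_modulus <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  n <- nrow(curve)
  if (n < 2L) stop("tangent modulus needs at least two curve points")
  (curve$stress[n] - curve$stress[n - 1L]) /
    (curve$strain[n] - curve$strain[n - 1L])
}
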
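# shared fixtures: reference materials and finite-difference oracles

ref_mats <- af_reference()$materials

# relaxed strain energy along the axial stretch (lateral equilibrium
# re-solved), for finite-difference checks of the nominal stress
relaxed_energy <- function(gp, fp, l3, lateral = "free",
                           settings = solver_settings()) {
  st <- solve_uniaxial_state(gp, fp, l3, settings = settings,
                             lateral = lateral)
  strain_energy(gp, fp, st$state)
}

fd_axial_stress <- function(gp, fp, l3, lateral = "free", h = 2e-5) {
  (relaxed_energy(gp, fp, l3 + h, lateral) -
     relaxed_energy(gp, fp, l3 - h, lateral)) / (2 * h)
}

# independent transcription of the strain-energy formula using explicit
# tensor algebra (no shared code with the implementation)
oracle_energy <- function(C10, D, k1, k2, kappa, theta_deg, l1, l2, l3) {
  F <- diag(c(l1, l2, l3))
  J <- det(F)
  Cbar <- J^(-2 / 3) * (t(F) %*% F)
  I1b <- sum(diag(Cbar))
  th <- theta_deg * pi / 180
  dirs <- list(c(cos(th), 0, sin(th)), c(cos(th), 0, -sin(th)))
  U <- C10 * (I1b - 3) + (1 / D) * ((J^2 - 1) / 2 - log(J))
  for (a in dirs) {
    I4 <- drop(t(a) %*% Cbar %*% a)
    Eb <- kappa * (I1b - 3) + (1 - 3 * kappa) * (I4 - 1)
    U <- U + k1 / (2 * k2) * (exp(k2 * max(Eb, 0)^2) - 1)
  }
  U
}
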
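## Full-factorial sensitivity sweep over (E, k1, k2) with specimen-level
## outputs: tensile stresses at the standard strain levels, the final-chord
## tangent modulus, and the ground-substance compressive stress at 0.30
## strain.

#' Full-factorial sensitivity design
#'
#' Four levels per parameter by default, spanning the published search
#' ranges: `E` in 0.1-1 MPa and `k1` in 1-45 MPa on linear spacing, `k2` in
#' 1-2000 on geometric spacing (the range spans three orders of magnitude),
#' giving 4 x 4 x 4 = 64 combinations.
#'
#' @param e_levels Young-modulus levels, MPa.
#' @param k1_levels fiber-stiffness levels, MPa.
#' @param k2_levels fiber non-linearity levels.
#' @return A list of class `"sensitivity_design"` with the levels and
#'   `n_combinations`.
#' @examples
#' sensitivity_design()$n_combinations  # 64
#' @export
sensitivity_design <- function(e_levels = seq(0.1, 1, length.out = 4),
                               k1_levels = seq(1, 45, length.out = 4),
                               k2_levels = exp(seq(log(1), log(2000),
                                                   length.out = 4))) {
  e_levels <- sort(as.numeric(e_levels))
  k1_levels <- sort(as.numeric(k1_levels))
  k2_levels <- sort(as.numeric(k2_levels))
  stopifnot(length(e_levels) >= 1, length(k1_levels) >= 1,
            length(k2_levels) >= 1,
            all(e_levels > 0), all(k1_levels >= 0), all(k2_levels > 0))
  structure(list(e_levels = e_levels, k1_levels = k1_levels,
                 k2_levels = k2_levels,
                 n_combinations = length(e_levels) * length(k1_levels) *
                   length(k2_levels)),
            class = "sensitivity_design")
}

#' @export
print.sensitivity_design <- function(x, ...) {
  cat(sprintf("Sensitivity design: %d combinations\n", x$n_combinations))
  cat("  E (MPa): ", paste(signif(x$e_levels, 4), collapse = ", "), "\n")
  cat("  k1 (MPa):", paste(signif(x$k1_levels, 4), collapse = ", "), "\n")
  cat("  k2:      ", paste(signif(x$k2_levels, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Run the material-parameter sensitivity sweep
#'
#' Exhaustively evaluates every `(E, k1, k2)` combination of the design:
#' for each, the ground substance is derived from `E` at fixed `nu`, the
#' uniaxial tension test is simulated at the standard strain levels, and
#' the ground-substance compression stress at 0.30 strain is computed.
#' Records are ordered lexicographically by `(E, k1, k2)` and the sweep is
#' fully deterministic.  A combination whose solve fails is recorded with
#' `NA` outputs and `ok = FALSE`; the sweep continues.
#'
#' @param design a [sensitivity_design()].
#' @param theta_deg fiber angle from the transverse plane, degrees.
#' @param nu fixed Poisson ratio (default 0.49).
#' @param kappa fixed dispersion (default 0.01).
#' @param strain_levels tensile strain levels.
#' @param settings a [solver_settings()] list.
#' @param lateral lateral boundary condition of the virtual tension test;
#'   see [simulate_tension()].
#' @return A data frame of class `"hgo_sensitivity"`: columns `E`, `k1`,
#'   `k2`, one tensile stress column per strain level
#'   (`tension_<percent>`), `tangent_modulus` (final-chord, MPa),
#'   `compression_30` (MPa), and `ok`.
#' @examples
#' d <- sensitivity_design(e_levels = 0.5, k1_levels = c(1, 10),
#'                         k2_levels = 100)
#' run_sensitivity(d, theta_deg = 29)
#' @export
run_sensitivity <- function(design, theta_deg, nu = 0.49, kappa = 0.01,
                            strain_levels = c(0.10, 0.20, 0.30, 0.40,
                                              0.50, 0.60),
                            settings = solver_settings(),
                            lateral = c("coupled", "free")) {
  lateral <- match.arg(lateral)
  stopifnot(inherits(design, "sensitivity_design"))
  strain_levels <- sort(strain_levels)
  combos <- expand.grid(k2 = design$k2_levels, k1 = design$k1_levels,
                        E = design$e_levels,
                        KEEP.OUT.ATTRS = FALSE)[, c("E", "k1", "k2")]
  tcols <- sprintf("tension_%g", round(100 * strain_levels))
  out <- matrix(NA_real_, nrow(combos), length(strain_levels) + 2L)
  ok <- logical(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    res <- tryCatch({
      gp <- elastic_to_ground(combos$E[i], nu)
      fp <- if (combos$k1[i] == 0) NULL
            else fiber_params(combos$k1[i], combos$k2[i], kappa, theta_deg)
      tens <- .simulate_levels(gp, fp, 1 + strain_levels, settings,
                               coupled = lateral == "coupled")$stress
      comp <- abs(.simulate_levels(gp, NULL, 1 - 0.30, settings)$stress)
      nlev <- length(strain_levels)
      tan_mod <- if (nlev >= 2L)
        (tens[nlev] - tens[nlev - 1L]) /
          (strain_levels[nlev] - strain_levels[nlev - 1L])
      else NA_real_
      c(tens, tan_mod, comp)
    }, error = function(e) NULL)
    if (!is.null(res)) { out[i, ] <- res; ok[i] <- TRUE }
  }
  df <- cbind(combos, as.data.frame(out), ok = ok)
  names(df) <- c("E", "k1", "k2", tcols, "tangent_modulus",
                 "compression_30", "ok")
  structure(df, strain_levels = strain_levels, theta_deg = theta_deg,
            class = c("hgo_sensitivity", "data.frame"))
}

#' Summarize a sensitivity sweep for box-plots
#'
#' For each swept parameter and each output, the quartiles (min, Q1,
#' median, Q3, max) of the output across all combinations of the other
#' parameters, per level.  Levels whose records all failed are reported
#' with `NA` quartiles.
#'
#' @param records an [run_sensitivity()] result.
#' @param outputs output columns to summarize; defaults to the tangent
#'   modulus and the largest-strain tensile stress.
#' @return A long-format data frame with columns `parameter`, `level`,
#'   `output`, `n`, `q0`, `q25`, `q50`, `q75`, `q100`.
#' @export
summarize_sensitivity <- function(records,
                                  outputs = c("tangent_modulus",
                                              grep("^tension_",
                                                   names(records),
                                                   value = TRUE))) {
  stopifnot(inherits(records, "hgo_sensitivity") || is.data.frame(records))
  if (nrow(records) == 0L) stop("empty sensitivity records")
  outputs <- unique(outputs)
  rows <- list()
  for (param in c("E", "k1", "k2")) {
    for (lev in sort(unique(records[[param]]))) {
      sub <- records[records[[param]] == lev & records$ok, , drop = FALSE]
      for (outp in outputs) {
        q <- if (nrow(sub)) quantile(sub[[outp]], c(0, 0.25, 0.5, 0.75, 1),
                                     names = FALSE)
             else rep(NA_real_, 5)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = param, level = lev, output = outp, n = nrow(sub),
          q0 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q100 = q[5])
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
plot.hgo_sensitivity <- function(x, output = "tangent_modulus", ...) {
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (param in c("E", "k1", "k2")) {
    boxplot(x[[output]][x$ok] ~ factor(signif(x[[param]][x$ok], 4)),
            xlab = param, ylab = output, main = paste(output, "vs", param),
            ...)
  }
  invisible(x)
}

#' Write or read a sensitivity sweep as CSV
#'
#' One row per combination, deterministic column order, full precision.
#'
#' @param records an [run_sensitivity()] result.
#' @param path file path.
#' @return `read_sensitivity_csv()` returns the records data frame;
#'   `write_sensitivity_csv()` returns `path` invisibly.
#' @export
write_sensitivity_csv <- function(records, path) {
  df <- as.data.frame(records)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  fmt <- function(v) if (is.logical(v)) as.character(v) else sprintf("%.15g", v)
  body <- do.call(paste, c(lapply(df, fmt), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_sensitivity_csv
#' @export
read_sensitivity_csv <- function(path) {
  df <- read.csv(path)
  structure(df, class = c("hgo_sensitivity", "data.frame"))
}
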
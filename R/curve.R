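## Stress-strain curve container and CSV round trip.

#' Nominal stress-strain curve
#'
#' A uniaxial specimen curve: engineering strain magnitudes paired with
#' nominal stress magnitudes (force per undeformed area, MPa), tagged with
#' the loading mode and, optionally, the annulus region.
#'
#' @param strain engineering strains (positive magnitudes), strictly
#'   increasing.  A leading zero strain is allowed and must pair with zero
#'   stress.
#' @param stress nominal stresses, MPa, non-negative, same length.
#' @param mode `"tension"` or `"compression"`.
#' @param region optional region label.
#' @param metadata optional named list (e.g. fiber-activation flags set by
#'   [simulate_compression()]).
#' @return A data frame of class `"stress_strain_curve"` with columns
#'   `strain` and `stress`, and attributes `mode`, `region`, `metadata`.
#' @examples
#' stress_strain_curve(c(0.1, 0.2), c(0.05, 0.12), mode = "tension")
#' @export
stress_strain_curve <- function(strain, stress,
                                mode = c("tension", "compression"),
                                region = NULL, metadata = list()) {
  mode <- match.arg(mode)
  strain <- as.numeric(strain); stress <- as.numeric(stress)
  if (length(strain) != length(stress))
    stop("strain and stress must have the same length")
  if (length(strain) && any(diff(strain) <= 0))
    stop("strains must be strictly increasing")
  if (any(strain < 0)) stop("strains must be non-negative magnitudes")
  if (any(stress < -1e-12)) stop("stresses must be non-negative magnitudes")
  if (length(strain) && strain[1] == 0 && abs(stress[1]) > 1e-12)
    stop("stress at zero strain must be zero")
  structure(data.frame(strain = strain, stress = stress),
            mode = mode, region = if (is.null(region)) NA_character_ else region,
            metadata = metadata,
            class = c("stress_strain_curve", "data.frame"))
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("%s stress-strain curve (%s), %d points\n",
              tools::toTitleCase(attr(x, "mode")),
              if (is.na(attr(x, "region"))) "unlabelled" else attr(x, "region"),
              nrow(x)))
  print(data.frame(strain = x$strain, stress_mpa = x$stress), row.names = FALSE)
  md <- attr(x, "metadata")
  if (isTRUE(md$fibers_active))
    cat("note: fiber families were active at one or more solved states\n")
  invisible(x)
}

#' @export
plot.stress_strain_curve <- function(x, ...,
                                     xlab = "engineering strain",
                                     ylab = "nominal stress (MPa)",
                                     type = "b") {
  plot(x$strain, x$stress, xlab = xlab, ylab = ylab, type = type, ...)
  invisible(x)
}

#' Read or write a stress-strain curve as CSV
#'
#' The file holds a comment line `# mode=<mode> region=<region>` followed by
#' a `strain,stress_mpa` header and the data rows.
#'
#' @param curve a [stress_strain_curve()].
#' @param path file path.
#' @return `read_curve_csv()` returns a [stress_strain_curve()];
#'   `write_curve_csv()` returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  region <- attr(curve, "region")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# mode=%s region=%s", attr(curve, "mode"),
                     if (is.na(region)) "NA" else region), con)
  writeLines("strain,stress_mpa", con)
  writeLines(sprintf("%.15g,%.15g", curve$strain, curve$stress), con)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  first <- readLines(path, n = 1L)
  mode <- "tension"; region <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("mode=(\\S+)", first))[[1]]
    if (length(m) == 2L) mode <- m[2]
    r <- regmatches(first, regexec("region=(\\S+)", first))[[1]]
    if (length(r) == 2L && r[2] != "NA") region <- r[2]
  }
  df <- read.csv(path, comment.char = "#")
  if (!all(c("strain", "stress_mpa") %in% names(df)))
    stop("curve CSV must have columns 'strain' and 'stress_mpa': ", path)
  stress_strain_curve(df$strain, df$stress_mpa, mode = mode, region = region)
}
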
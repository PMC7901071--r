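#' Fit a hard/soft-iron magnetometer calibration
#'
#' Data-driven ellipsoid calibration: an undistorted magnetometer in a
#' constant ambient field traces a sphere as the tag rotates; hard-iron
#' offsets shift the sphere and soft-iron distortion stretches it into an
#' ellipsoid. The samples are fitted with a least-squares quadric
#' (10-parameter family, constrained to ellipsoids); the hard iron is the
#' ellipsoid center, and the correction matrix is the symmetric inverse
#' square root of the shape matrix scaled so corrected norms match
#' `reference_norm` (the mean raw sample norm). Physical soft-iron
#' distortions are symmetric, so the symmetric square root recovers the
#' field direction and not just its magnitude.
#'
#' @param mag 3-column matrix/tibble of raw magnetometer samples (uT), or a
#'   sensor tibble with `mag_*` columns (only `valid` rows are used when a
#'   `valid` column is present). At least 100 samples spanning diverse
#'   orientations are required.
#' @param max_samples cap on rows used in the fit (subsampled evenly).
#' @return An object of class `soarhmm_calibration`: `hard_iron` (uT),
#'   `correction` (3x3), `reference_norm` (uT), and `norm_cv`, the
#'   coefficient of variation of corrected norms on the fitted samples.
#' @examples
#' u <- matrix(rnorm(3000), ncol = 3)
#' u <- 45 * u / sqrt(rowSums(u^2))
#' cal <- fit_mag_calibration(u)
#' cal$hard_iron
#' @export
fit_mag_calibration <- function(mag, max_samples = 20000L) {
  m <- extract_mag(mag)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 100) {
    stop("calibration needs at least 100 valid magnetometer samples",
         call. = FALSE)
  }
  if (nrow(m) > max_samples) {
    m <- m[seq(1L, nrow(m), length.out = max_samples), , drop = FALSE]
  }
  x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
  D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z,
             2 * x, 2 * y, 2 * z, 1)
  sv <- svd(D, nu = 0)
  # a good ellipsoid fit has exactly one near-null direction; a second one
  # means many quadrics fit (near-coplanar or otherwise degenerate coverage)
  if (sv$d[9] / sv$d[1] < 1e-10) {
    stop("degenerate orientation coverage: samples are near-coplanar, ",
         "the quadric is not identifiable", call. = FALSE)
  }
  v <- sv$v[, 10]
  A <- matrix(c(v[1], v[4], v[5],
                v[4], v[2], v[6],
                v[5], v[6], v[3]), 3, 3)
  if (sum(diag(A)) < 0) { v <- -v; A <- -A }
  ev <- eigen(A, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    stop("degenerate orientation coverage: fitted quadric is not an ",
         "ellipsoid (non-positive shape eigenvalues)", call. = FALSE)
  }
  b <- v[7:9]
  center <- as.numeric(-solve(A, b))
  r2 <- as.numeric(center %*% A %*% center) - v[10]
  if (r2 <= 0) {
    stop("degenerate quadric fit: non-positive ellipsoid radius", call. = FALSE)
  }
  As <- A / r2
  es <- eigen(As, symmetric = TRUE)
  W <- es$vectors %*% diag(sqrt(es$values)) %*% t(es$vectors)
  ref <- mean(sqrt(rowSums(m^2)))
  correction <- ref * W
  corrected <- sweep(m, 2, center) %*% t(correction)
  nrm <- sqrt(rowSums(corrected^2))
  structure(
    list(hard_iron = center, correction = correction,
         reference_norm = ref, norm_cv = stats::sd(nrm) / mean(nrm)),
    class = "soarhmm_calibration"
  )
}

#' Apply a magnetometer calibration
#'
#' Maps raw samples to corrected samples:
#' `m_cal = correction %*% (m - hard_iron)`.
#'
#' @param sensors sensor tibble with `mag_*` columns (or a 3-column matrix).
#' @param calibration a [fit_mag_calibration()] result.
#' @return Same shape as the input with corrected magnetometer values.
#' @export
apply_calibration <- function(sensors, calibration) {
  stopifnot(inherits(calibration, "soarhmm_calibration"))
  if (is.matrix(sensors)) {
    return(sweep(sensors, 2, calibration$hard_iron) %*%
             t(calibration$correction))
  }
  m <- extract_mag(sensors, use_valid = FALSE)
  cm <- sweep(m, 2, calibration$hard_iron) %*% t(calibration$correction)
  out <- sensors
  out$mag_x <- cm[, 1]; out$mag_y <- cm[, 2]; out$mag_z <- cm[, 3]
  out
}

extract_mag <- function(mag, use_valid = TRUE) {
  if (is.matrix(mag)) {
    stopifnot(ncol(mag) == 3)
    return(mag)
  }
  if (all(c("mag_x", "mag_y", "mag_z") %in% names(mag))) {
    m <- cbind(mag$mag_x, mag$mag_y, mag$mag_z)
    if (use_valid && "valid" %in% names(mag)) m <- m[mag$valid, , drop = FALSE]
    return(m)
  }
  m <- as.matrix(mag)
  stopifnot(ncol(m) == 3)
  m
}

#' @export
print.soarhmm_calibration <- function(x, ...) {
  cat("<soarhmm magnetometer calibration>\n")
  cat(sprintf("  hard iron: (%.2f, %.2f, %.2f) uT\n",
              x$hard_iron[1], x$hard_iron[2], x$hard_iron[3]))
  cat(sprintf("  reference norm: %.2f uT, corrected-norm CV: %.3g\n",
              x$reference_norm, x$norm_cv))
  invisible(x)
}
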
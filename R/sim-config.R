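#' Default signal regimes for the three behavioral states
#'
#' Stylized per-state signal parameters used by the deployment generator.
#' The regimes emulate the patterns that distinguish the three movement
#' modes in albatross IMU records: flapping flight carries a strong heave
#' oscillation near the species-typical 2.5-2.7 Hz wingbeat; soaring flight
#' has low wingbeat energy but slow periodic heading arcs (the dynamic
#' soaring cycle) with banked turns and load-factor oscillations; on-water
#' behavior sits near 1 g heave with a weak swell signal and a near-constant
#' heading. These are generator defaults, not claims about real birds.
#'
#' @return A named list with one parameter list per state (`flap`, `soar`,
#'   `water`). Fields: `flap_freq_hz` / `flap_freq_sd_hz` (heave oscillation
#'   frequency, Hz), `heave_osc_amplitude` (g), `amp_lognorm_sd` (per-window
#'   log-scale amplitude jitter), `heading_arc_period_s` /
#'   `heading_arc_period_sd_s` (s), `heading_arc_amplitude_deg` (deg),
#'   `roll_amplitude_deg`, `pitch_amplitude_deg` (banked-turn attitude, deg),
#'   `swell_freq_hz` / `swell_freq_sd_hz` (on-water swell, Hz),
#'   `heading_wander_deg` (slow within-window heading wander, deg),
#'   `dyn_noise_sd` (g per axis), `mean_heave` (g).
#' @examples
#' regime_defaults()$flap$flap_freq_hz
#' @export
regime_defaults <- function() {
  list(
    flap = list(
      state_label = "flap",
      flap_freq_hz = 2.6, flap_freq_sd_hz = 0.1,
      heave_osc_amplitude = 0.9, amp_lognorm_sd = 0.15,
      heading_arc_period_s = NA_real_, heading_arc_period_sd_s = 0,
      heading_arc_amplitude_deg = 0,
      roll_amplitude_deg = 0, pitch_amplitude_deg = 0,
      swell_freq_hz = NA_real_, swell_freq_sd_hz = 0,
      heading_wander_deg = 5, dyn_noise_sd = 0.05, mean_heave = 1
    ),
    soar = list(
      state_label = "soar",
      flap_freq_hz = NA_real_, flap_freq_sd_hz = 0,
      heave_osc_amplitude = 0.25, amp_lognorm_sd = 0.15,
      heading_arc_period_s = 10, heading_arc_period_sd_s = 1,
      heading_arc_amplitude_deg = 80,
      roll_amplitude_deg = 40, pitch_amplitude_deg = 10,
      swell_freq_hz = NA_real_, swell_freq_sd_hz = 0,
      heading_wander_deg = 3, dyn_noise_sd = 0.03, mean_heave = 1
    ),
    water = list(
      state_label = "water",
      flap_freq_hz = NA_real_, flap_freq_sd_hz = 0,
      heave_osc_amplitude = 0.05, amp_lognorm_sd = 0.15,
      heading_arc_period_s = NA_real_, heading_arc_period_sd_s = 0,
      heading_arc_amplitude_deg = 0,
      roll_amplitude_deg = 0, pitch_amplitude_deg = 0,
      swell_freq_hz = 0.1, swell_freq_sd_hz = 0.02,
      heading_wander_deg = 2, dyn_noise_sd = 0.02, mean_heave = 1
    )
  )
}

#' Default per-species transition probability matrices
#'
#' Row-stochastic 3-state matrices (flap, soar, water) used as the generative
#' dwell structure, one per covariate (species) level. The two defaults are
#' close but not identical, so a species effect on transitions is present in
#' generated data. Printed three-decimal estimates are renormalized so each
#' row sums to one exactly.
#'
#' @return Named list of 3x3 matrices with dimnames over the state alphabet.
#' @export
default_tpms <- function() {
  st <- c("flap", "soar", "water")
  g1 <- matrix(c(
    0.778, 0.204, 0.019,
    0.083, 0.900, 0.017,
    0.010, 0.016, 0.974
  ), 3, 3, byrow = TRUE, dimnames = list(st, st))
  g2 <- matrix(c(
    0.781, 0.194, 0.025,
    0.080, 0.911, 0.009,
    0.011, 0.008, 0.980
  ), 3, 3, byrow = TRUE, dimnames = list(st, st))
  lapply(list(A = g1, B = g2), function(g) g / rowSums(g))
}

#' Configuration for the synthetic deployment generator
#'
#' Bundles every knob of the ground-truth generator: study size, window grid,
#' per-species dwell structure, signal regimes, ambient magnetic field,
#' magnetometer distortion, and the tag-mount roll offset.
#'
#' @param n_individuals number of simulated birds.
#' @param windows_per_individual number of 30-s behavior windows per bird.
#' @param window_s window length in seconds.
#' @param fs_hz sampling rate in Hz; `window_s * fs_hz` must be an integer.
#' @param covariate_levels character vector of length `n_individuals`
#'   assigning each bird a species level; defaults to alternating over the
#'   names of `true_tpm`.
#' @param true_tpm named list (one entry per covariate level) of row-stochastic
#'   transition matrices.
#' @param initial_dist initial state distribution; `NULL` uses the stationary
#'   distribution of each bird's transition matrix.
#' @param regimes per-state signal regimes, see [regime_defaults()].
#' @param mag_field ambient magnetic field in the navigation frame
#'   (north, east, up), in microtesla. The default is a 45-uT field with 60
#'   degrees downward inclination.
#' @param hard_iron additive magnetometer offset (uT).
#' @param soft_iron symmetric 3x3 soft-iron distortion matrix.
#' @param mag_noise_sd magnetometer noise sd (uT).
#' @param roll_offset_deg tag-mount roll offset (degrees).
#' @param seed integer seed; the full deployment is reproducible from it.
#' @return A list of class `soarhmm_config`.
#' @examples
#' cfg <- generator_config(n_individuals = 2, windows_per_individual = 20)
#' cfg$fs_hz
#' @export
generator_config <- function(n_individuals = 20,
                             windows_per_individual = 500,
                             window_s = 30,
                             fs_hz = 25,
                             covariate_levels = NULL,
                             true_tpm = default_tpms(),
                             initial_dist = NULL,
                             regimes = regime_defaults(),
                             mag_field = c(22.5, 0, -45 * sin(pi / 3)),
                             hard_iron = c(10, -5, 3),
                             soft_iron = diag(c(1.1, 1.0, 0.9)),
                             mag_noise_sd = 0.1,
                             roll_offset_deg = 5,
                             seed = 1L) {
  stopifnot(n_individuals >= 1, windows_per_individual >= 1)
  n_spw <- window_s * fs_hz
  if (abs(n_spw - round(n_spw)) > 1e-9) {
    stop("window_s * fs_hz must be an integer sample count", call. = FALSE)
  }
  if (is.null(names(true_tpm))) {
    stop("true_tpm must be a named list, one matrix per covariate level",
         call. = FALSE)
  }
  for (lev in names(true_tpm)) check_tpm(true_tpm[[lev]])
  if (is.null(covariate_levels)) {
    covariate_levels <- rep_len(names(true_tpm), n_individuals)
  }
  stopifnot(length(covariate_levels) == n_individuals,
            all(covariate_levels %in% names(true_tpm)))
  if (!is.null(initial_dist)) {
    stopifnot(length(initial_dist) == nrow(true_tpm[[1]]))
    if (abs(sum(initial_dist) - 1) > 1e-9) {
      stop("initial_dist must sum to 1", call. = FALSE)
    }
  }
  if (abs(det(soft_iron)) < 1e-12) {
    stop("soft_iron must be invertible", call. = FALSE)
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      windows_per_individual = as.integer(windows_per_individual),
      window_s = window_s, fs_hz = fs_hz,
      covariate_levels = covariate_levels,
      true_tpm = true_tpm, initial_dist = initial_dist,
      regimes = regimes, mag_field = mag_field,
      hard_iron = hard_iron, soft_iron = soft_iron,
      mag_noise_sd = mag_noise_sd,
      roll_offset_deg = roll_offset_deg,
      seed = as.integer(seed)
    ),
    class = "soarhmm_config"
  )
}

# Validate a row-stochastic matrix; errors name the offending row.
check_tpm <- function(tpm, tol = 1e-12) {
  if (!is.matrix(tpm) || nrow(tpm) != ncol(tpm)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  if (any(tpm < 0)) stop("transition matrix has negative entries", call. = FALSE)
  bad <- which(abs(rowSums(tpm) - 1) > tol)
  if (length(bad)) {
    stop(sprintf("transition matrix row %d sums to %.15f, not 1", bad[1],
                 rowSums(tpm)[bad[1]]), call. = FALSE)
  }
  invisible(tpm)
}

# Stationary distribution by power iteration.
stationary_dist <- function(tpm, iter = 2000L) {
  v <- rep(1 / nrow(tpm), nrow(tpm))
  for (i in seq_len(iter)) v <- as.numeric(v %*% tpm)
  v / sum(v)
}

#' @export
print.soarhmm_config <- function(x, ...) {
  cat("<soarhmm generator config>\n")
  cat(sprintf("  %d individuals x %d windows of %gs at %g Hz\n",
              x$n_individuals, x$windows_per_individual, x$window_s, x$fs_hz))
  cat(sprintf("  covariate levels: %s\n",
              paste(unique(x$covariate_levels), collapse = ", ")))
  cat(sprintf("  |B| = %.1f uT, roll offset %g deg, seed %d\n",
              sqrt(sum(x$mag_field^2)), x$roll_offset_deg, x$seed))
  invisible(x)
}
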
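#' Simulate a Markov state sequence at the window scale
#'
#' Draws a state label per 30-s window from a first-order Markov chain. The
#' chain lives at the window scale so that the generated truth aligns
#' one-to-one with HMM observations.
#'
#' @param tpm square row-stochastic transition matrix; dimnames, if present,
#'   define the state alphabet.
#' @param initial_dist probability vector over states.
#' @param n_windows sequence length (>= 1).
#' @param seed optional integer seed.
#' @return Character vector of state labels (or integer indices when `tpm`
#'   has no dimnames) of length `n_windows`.
#' @examples
#' g <- default_tpms()$A
#' simulate_state_sequence(g, c(1, 0, 0), 10, seed = 1)
#' @export
simulate_state_sequence <- function(tpm, initial_dist, n_windows, seed = NULL) {
  check_tpm(tpm)
  stopifnot(n_windows >= 1, length(initial_dist) == nrow(tpm))
  if (abs(sum(initial_dist) - 1) > 1e-9) {
    stop("initial_dist must sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(tpm)
  cum_tpm <- t(apply(tpm, 1, cumsum))
  u <- runif(n_windows)
  s <- integer(n_windows)
  s[1] <- findInterval(u[1], cumsum(initial_dist), left.open = TRUE) + 1L
  for (t in seq_len(n_windows - 1L)) {
    s[t + 1L] <- findInterval(u[t + 1L], cum_tpm[s[t], ], left.open = TRUE) + 1L
  }
  s <- pmin(s, S)
  if (!is.null(rownames(tpm))) rownames(tpm)[s] else s
}

# Core window renderer on plain matrices; render_window() wraps it in a
# tibble. Returns total/static/dynamic acceleration (g), true heading (deg),
# and pitch/roll (rad). Conservation total = static + dynamic holds exactly,
# noise included in the dynamic part.
render_window_core <- function(state, regime, window_s, fs_hz,
                               mean_heading = 0) {
  n <- as.integer(round(window_s * fs_hz))
  tt <- (seq_len(n) - 1) / fs_hz
  amp <- regime$heave_osc_amplitude
  if (amp < 0 || regime$dyn_noise_sd < 0) {
    stop("regime amplitudes and noise sds must be >= 0", call. = FALSE)
  }
  if (amp > 0 && regime$amp_lognorm_sd > 0) {
    amp <- amp * exp(rnorm(1, 0, regime$amp_lognorm_sd))
  }
  step_sd <- deg2rad(regime$heading_wander_deg) / sqrt(n / 3)
  psi <- deg2rad(mean_heading) + cumsum(rnorm(n, 0, step_sd))
  pitch <- numeric(n)
  roll <- numeric(n)
  dyn_z <- numeric(n)

  if (state == "flap") {
    f <- regime$flap_freq_hz
    if (regime$flap_freq_sd_hz > 0) f <- rnorm(1, f, regime$flap_freq_sd_hz)
    dyn_z <- amp * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
  } else if (state == "soar") {
    per <- regime$heading_arc_period_s
    if (regime$heading_arc_period_sd_s > 0) {
      per <- max(4, rnorm(1, per, regime$heading_arc_period_sd_s))
    }
    ph <- runif(1, 0, 2 * pi)
    arc <- deg2rad(regime$heading_arc_amplitude_deg)
    psi <- psi + arc * sin(2 * pi * tt / per + ph)
    # banked turns: roll follows the heading-arc derivative; pitch and the
    # load-factor heave oscillation cycle twice per arc
    roll <- deg2rad(regime$roll_amplitude_deg) * cos(2 * pi * tt / per + ph)
    pitch <- deg2rad(regime$pitch_amplitude_deg) *
      sin(4 * pi * tt / per + 2 * ph)
    dyn_z <- amp * sin(4 * pi * tt / per + 2 * ph + runif(1, 0, 2 * pi))
  } else if (state == "water") {
    f <- regime$swell_freq_hz
    if (regime$swell_freq_sd_hz > 0) {
      f <- max(0.03, rnorm(1, f, regime$swell_freq_sd_hz))
    }
    dyn_z <- amp * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
  } else {
    stop("unknown state label: ", state, call. = FALSE)
  }

  static <- nav_to_tag(c(0, 0, regime$mean_heave), psi, pitch, roll)
  nz <- regime$dyn_noise_sd
  dyn <- cbind(rnorm(n, 0, nz), rnorm(n, 0, nz), dyn_z + rnorm(n, 0, nz))
  list(
    acc = static + dyn, static = static, dyn = dyn,
    heading_deg = wrap360(rad2deg(psi)), pitch = pitch, roll = roll
  )
}

#' Render one 30-s window of tri-axial acceleration and true heading
#'
#' Generates raw accelerometer samples and the true heading/attitude series
#' for one behavioral window under a state regime. Flapping windows contain a
#' sinusoidal heave oscillation at a frequency drawn from the regime; soaring
#' windows a sinusoidal heading arc with banked turns and a load-factor heave
#' oscillation at twice the arc frequency; on-water windows a weak swell tone
#' with near-constant heading around 1 g heave.
#'
#' @param state one of `"flap"`, `"soar"`, `"water"`.
#' @param regime the matching regime parameter list, see [regime_defaults()].
#' @param window_s,fs_hz window length (s) and sampling rate (Hz);
#'   `window_s * fs_hz` must be an integer.
#' @param seed optional integer seed.
#' @param mean_heading window mean heading in degrees.
#' @return Tibble with `t` (s), total (`acc_x/y/z`), static (`static_*`) and
#'   dynamic (`dyn_*`) acceleration in g, `heading_deg` in [0, 360), and
#'   `pitch`/`roll` in radians. `acc = static + dyn` holds sample-wise.
#' @examples
#' w <- render_window("water", regime_defaults()$water, 30, 25, seed = 1)
#' mean(w$acc_z)
#' @export
render_window <- function(state, regime, window_s, fs_hz, seed = NULL,
                          mean_heading = 0) {
  n <- window_s * fs_hz
  if (abs(n - round(n)) > 1e-9) {
    stop("window_s * fs_hz must be an integer sample count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  r <- render_window_core(state, regime, window_s, fs_hz, mean_heading)
  tibble::tibble(
    t = (seq_len(nrow(r$acc)) - 1) / fs_hz,
    acc_x = r$acc[, 1], acc_y = r$acc[, 2], acc_z = r$acc[, 3],
    static_x = r$static[, 1], static_y = r$static[, 2],
    static_z = r$static[, 3],
    dyn_x = r$dyn[, 1], dyn_y = r$dyn[, 2], dyn_z = r$dyn[, 3],
    heading_deg = r$heading_deg, pitch = r$pitch, roll = r$roll
  )
}

#' Render distorted tri-axial magnetometer samples
#'
#' Rotates the ambient field into the instantaneous tag frame from the true
#' heading and attitude series, then applies hard/soft-iron distortion and
#' sensor noise: `m = soft_iron %*% m_true + hard_iron + noise`.
#'
#' @param heading_deg true heading series (degrees, clockwise from north).
#' @param pitch,roll attitude series in radians (same length as heading).
#' @param mag_field ambient field 3-vector in the navigation frame
#'   (north, east, up), uT.
#' @param hard_iron additive offset 3-vector (uT).
#' @param soft_iron 3x3 distortion matrix (must be invertible).
#' @param noise_sd per-axis Gaussian noise sd (uT).
#' @param seed optional integer seed.
#' @return Tibble with `mag_x`, `mag_y`, `mag_z` (uT).
#' @export
render_magnetometer <- function(heading_deg, pitch, roll, mag_field,
                                hard_iron = c(0, 0, 0),
                                soft_iron = diag(3), noise_sd = 0,
                                seed = NULL) {
  n <- length(heading_deg)
  stopifnot(length(pitch) == n, length(roll) == n)
  if (abs(det(soft_iron)) < 1e-12) {
    stop("soft_iron must be invertible", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- nav_to_tag(mag_field, deg2rad(heading_deg), pitch, roll)
  m <- m %*% t(soft_iron)
  m <- sweep(m, 2, hard_iron, "+")
  if (noise_sd > 0) m <- m + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  tibble::tibble(mag_x = m[, 1], mag_y = m[, 2], mag_z = m[, 3])
}

#' Simulate a full multi-individual IMU deployment with known states
#'
#' Draws a window-scale Markov state sequence per individual, renders raw
#' 25 Hz accelerometer and distorted magnetometer streams window by window,
#' applies the tag-mount roll offset, and returns the raw sensors together
#' with the ground-truth window-state table. Identical configs (including
#' the seed) give identical output.
#'
#' @param config a [generator_config()].
#' @param dir optional directory; when given, one sensor CSV per individual
#'   and a `truth.csv` table are written there (see [write_sensor_csv()]).
#' @param keep_truth_signals keep per-sample true heading/pitch/roll series
#'   (memory-heavy for large configs; used for heading-accuracy checks).
#' @return A list of class `soarhmm_deployment` with elements `sensors`
#'   (named list of tibbles: `t_s`, `acc_x/y/z`, `mag_x/y/z`), `truth`
#'   (tibble: `individual_id`, `window_index`, `true_state`), `meta`
#'   (tibble: `individual_id`, `covariate_level`, `fs_hz`), optionally
#'   `truth_signals`, and `config`.
#' @examples
#' dep <- simulate_deployment(
#'   generator_config(n_individuals = 1, windows_per_individual = 5, seed = 7)
#' )
#' dep$truth
#' @export
simulate_deployment <- function(config, dir = NULL,
                                keep_truth_signals = FALSE) {
  stopifnot(inherits(config, "soarhmm_config"))
  set.seed(config$seed)
  n_ind <- config$n_individuals
  ids <- sprintf("bird%02d", seq_len(n_ind))
  sensors <- vector("list", n_ind)
  names(sensors) <- ids
  truth_signals <- if (keep_truth_signals) setNames(vector("list", n_ind), ids)
  truth <- vector("list", n_ind)
  nw <- config$windows_per_individual
  heading_step_sd <- 25 # deg, between-window drift of the mean heading

  for (i in seq_len(n_ind)) {
    lev <- config$covariate_levels[i]
    tpm <- config$true_tpm[[lev]]
    delta <- config$initial_dist %||% stationary_dist(tpm)
    states <- simulate_state_sequence(tpm, delta, nw)
    mean_head <- wrap360(runif(1, 0, 360) +
                           cumsum(rnorm(nw, 0, heading_step_sd)))
    ws <- vector("list", nw)
    for (w in seq_len(nw)) {
      ws[[w]] <- render_window_core(states[w], config$regimes[[states[w]]],
                                    config$window_s, config$fs_hz,
                                    mean_heading = mean_head[w])
    }
    acc <- do.call(rbind, lapply(ws, `[[`, "acc"))
    heading <- unlist(lapply(ws, `[[`, "heading_deg"), use.names = FALSE)
    pitch <- unlist(lapply(ws, `[[`, "pitch"), use.names = FALSE)
    roll <- unlist(lapply(ws, `[[`, "roll"), use.names = FALSE)
    mag <- render_magnetometer(heading, pitch, roll, config$mag_field,
                               hard_iron = c(0, 0, 0))
    # tag-mount roll offset rotates what both sensors see, then the
    # magnetometer picks up its iron distortion and noise
    off <- rot_x(-deg2rad(config$roll_offset_deg))
    acc <- acc %*% t(off)
    m <- as.matrix(mag) %*% t(off) %*% t(config$soft_iron)
    m <- sweep(m, 2, config$hard_iron, "+")
    if (config$mag_noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, config$mag_noise_sd), nrow(m), 3)
    }
    n <- nrow(acc)
    sensors[[i]] <- tibble::tibble(
      t_s = (seq_len(n) - 1) / config$fs_hz,
      acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
      mag_x = m[, 1], mag_y = m[, 2], mag_z = m[, 3]
    )
    if (keep_truth_signals) {
      truth_signals[[i]] <- tibble::tibble(
        heading_deg = heading, pitch = pitch, roll = roll
      )
    }
    truth[[i]] <- tibble::tibble(
      individual_id = ids[i], window_index = seq_len(nw), true_state = states
    )
  }

  out <- structure(
    list(
      sensors = sensors,
      truth = dplyr::bind_rows(truth),
      meta = tibble::tibble(
        individual_id = ids,
        covariate_level = config$covariate_levels,
        fs_hz = config$fs_hz
      ),
      truth_signals = truth_signals,
      config = config
    ),
    class = "soarhmm_deployment"
  )
  if (!is.null(dir)) write_deployment(out, dir)
  out
}

#' @export
print.soarhmm_deployment <- function(x, ...) {
  cat("<soarhmm synthetic deployment>\n")
  cat(sprintf("  %d individuals, %d truth windows, %g Hz\n",
              length(x$sensors), nrow(x$truth), x$config$fs_hz))
  print(table(x$truth$true_state))
  invisible(x)
}

#' Simulate a window-level feature table directly from HMM parameters
#'
#' Bypasses signal rendering: draws a Markov state chain per individual and
#' per-feature Weibull observations given the states. Used for parameter
#' recovery and covariate discrimination studies where the object of
#' interest is the estimator, not the signal chain.
#'
#' @param params an [hmm_params()] object.
#' @param n_windows windows per individual.
#' @param n_individuals number of individuals.
#' @param covariate_levels optional character vector assigning each
#'   individual a covariate level from `params$cov_levels`.
#' @param seed integer seed.
#' @return Feature tibble with `individual_id`, `window_index`, `covariate`,
#'   `true_state`, `missing`, and one column per feature.
#' @export
simulate_hmm_features <- function(params, n_windows, n_individuals = 1,
                                  covariate_levels = NULL, seed = 1) {
  stopifnot(inherits(params, "soarhmm_params"))
  set.seed(seed)
  if (is.null(covariate_levels)) {
    covariate_levels <- rep_len(params$cov_levels, n_individuals)
  }
  stopifnot(length(covariate_levels) == n_individuals)
  out <- vector("list", n_individuals)
  feats <- params$features
  for (i in seq_len(n_individuals)) {
    gam <- transition_matrix(params, covariate_levels[i])
    st <- simulate_state_sequence(
      matrix(gam, params$n_states, params$n_states,
             dimnames = list(params$state_names, params$state_names)),
      params$delta, n_windows
    )
    si <- match(st, params$state_names)
    x <- sapply(seq_along(feats), function(f) {
      rweibull(n_windows, shape = params$shape[si, f],
               scale = params$scale[si, f])
    })
    x <- matrix(x, n_windows, length(feats),
                dimnames = list(NULL, feats))
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(
        individual_id = sprintf("sim%02d", i),
        window_index = seq_len(n_windows),
        covariate = covariate_levels[i],
        true_state = st, missing = FALSE
      ),
      tibble::as_tibble(x)
    )
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
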
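# Centered running mean with shrinking windows at the ends (cumsum-based).
running_mean <- function(x, L) {
  n <- length(x)
  k <- (L - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Split total acceleration into static and dynamic components
#'
#' The static (postural/gravitational) component is a centered running mean
#' of total acceleration over `smooth_s` seconds; the dynamic component is
#' the remainder, so `static + dynamic` reconstructs the input exactly. The
#' window length is rounded to the nearest odd sample count so the mean is
#' symmetric (51 samples for 2 s at 25 Hz).
#'
#' @param acc 3-column matrix/tibble of total acceleration (surge, sway,
#'   heave) in g, or a sensor tibble with `acc_*` columns.
#' @param fs sampling rate (Hz).
#' @param smooth_s running-mean span in seconds (default 2, the standard
#'   static/dynamic separation scale for flight data).
#' @return List with `static` and `dynamic` 3-column matrices.
#' @examples
#' a <- cbind(0, 0, 1 + sin(2 * pi * 2.6 * (0:749) / 25))
#' sp <- static_dynamic_split(a, fs = 25)
#' max(abs(sp$static + sp$dynamic - a))
#' @export
static_dynamic_split <- function(acc, fs, smooth_s = 2) {
  a <- extract_acc(acc)
  L <- as.integer(round(smooth_s * fs))
  if (L < 1) stop("smooth_s * fs must be >= 1", call. = FALSE)
  if (L %% 2L == 0L) L <- L + 1L
  st <- apply(a, 2, running_mean, L = L)
  list(static = st, dynamic = a - st)
}

extract_acc <- function(acc) {
  if (is.data.frame(acc) && all(c("acc_x", "acc_y", "acc_z") %in% names(acc))) {
    return(cbind(acc$acc_x, acc$acc_y, acc$acc_z))
  }
  a <- as.matrix(acc)
  stopifnot(ncol(a) == 3)
  a
}

#' Overall dynamic body acceleration
#'
#' Per-sample ODBA: the sum of absolute dynamic acceleration over the three
#' axes, a standard proxy of energy expenditure.
#'
#' @param dynamic 3-column matrix/tibble of dynamic acceleration in g.
#' @return Numeric vector of per-sample ODBA (g).
#' @export
odba <- function(dynamic) {
  d <- as.matrix(dynamic)
  stopifnot(ncol(d) == 3)
  rowSums(abs(d))
}

#' Dominant frequencies of a heave window
#'
#' Computes the power spectrum of the mean-removed window and identifies
#' "dominant" frequencies as local maxima with power at least
#' `peak_fraction` of the spectral maximum (DC excluded). `df` is the
#' frequency of the global maximum and `hf` the largest frequency among
#' dominant peaks. An aperiodic (effectively constant) window returns the
#' sentinel `df = hf = 0`.
#'
#' @param x heave window samples (g); at least 2 s long.
#' @param fs sampling rate (Hz).
#' @param peak_fraction relative power floor for a peak to count as
#'   dominant (default 0.05).
#' @return List with `df` and `hf` in Hz.
#' @examples
#' x <- sin(2 * pi * 2.6 * (0:749) / 25)
#' dominant_frequencies(x, 25)
#' @export
dominant_frequencies <- function(x, fs, peak_fraction = 0.05) {
  n <- length(x)
  if (n < 2 * fs) stop("window shorter than 2 s", call. = FALSE)
  p <- Mod(fft(x - mean(x)))^2
  nb <- floor(n / 2)
  p <- p[2:(nb + 1)] # DC excluded
  freq <- seq_len(nb) * fs / n
  maxp <- max(p)
  if (!is.finite(maxp) || maxp < n^2 * 1e-20) {
    return(list(df = 0, hf = 0))
  }
  left <- c(Inf, p[-nb])   # the DC bin does not compete
  right <- c(p[-1], -Inf)
  is_peak <- (p > left & p >= right) | p == maxp
  dominant <- is_peak & p >= peak_fraction * maxp
  list(df = freq[which.max(p)], hf = max(freq[dominant]))
}

#' Circular standard deviation of heading
#'
#' `sqrt(-2 log Rbar)` with `Rbar` the mean resultant length of the heading
#' unit vectors, in radians. Values are floored at `floor_val` and capped at
#' `cap` so they remain inside the Weibull support and finite (`Rbar = 0`
#' would give infinity).
#'
#' @param heading_deg heading samples in degrees; NAs are ignored.
#' @param floor_val,cap numeric bounds (defaults 1e-6 and 4 rad).
#' @return Circular SD in radians, or `NA` with fewer than 2 valid samples.
#' @examples
#' circular_sd(c(0, 90)) # sqrt(log(2))
#' @export
circular_sd <- function(heading_deg, floor_val = 1e-6, cap = 4) {
  h <- heading_deg[!is.na(heading_deg)]
  if (length(h) < 2) return(NA_real_)
  a <- deg2rad(h)
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  if (rbar <= 0) return(cap)
  min(max(sqrt(-2 * log(rbar)), floor_val), cap)
}

#' Summarize calibrated series into per-window movement features
#'
#' Reduces a 25 Hz calibrated record to the eight candidate features over
#' fixed, non-overlapping windows anchored at the record start (incomplete
#' trailing windows are dropped): `df`/`hf` from the FFT of total heave,
#' `ms`/`ss`/`p5` (mean, SD, 95th percentile) of static heave, `iqr` of
#' dynamic heave, `mo` mean ODBA, and `sh` the circular SD of heading.
#' Windows with more than 50% invalid samples are emitted with
#' `missing = TRUE` and no feature values.
#'
#' @param sensors calibrated sensor tibble (`t_s`, `acc_*`, optional
#'   `valid`).
#' @param attitude matching [attitude_heading()] tibble (same grid), or
#'   `NULL` when no magnetometer is available (then `sh` is `NA`).
#' @param window_s window length in seconds (default 30).
#' @param fs sampling rate (Hz); inferred when missing.
#' @param individual_id,covariate identifiers copied into the table.
#' @param smooth_s static/dynamic running-mean span (s).
#' @param peak_fraction dominant-peak floor, see [dominant_frequencies()].
#' @return Feature tibble: `individual_id`, `window_index`, `t_start`,
#'   `df`, `hf`, `ms`, `ss`, `p5`, `iqr`, `mo`, `sh`, `covariate`,
#'   `missing`.
#' @export
window_features <- function(sensors, attitude = NULL, window_s = 30,
                            fs = NULL, individual_id = "ind1",
                            covariate = NA_character_, smooth_s = 2,
                            peak_fraction = 0.05) {
  if (is.null(fs)) fs <- infer_fs(sensors$t_s)
  if (!is.null(attitude) && nrow(attitude) != nrow(sensors)) {
    stop("attitude and sensor series are misaligned", call. = FALSE)
  }
  acc <- extract_acc(sensors)
  sp <- static_dynamic_split(acc, fs = fs, smooth_s = smooth_s)
  ob <- odba(sp$dynamic)
  valid <- if ("valid" %in% names(sensors)) sensors$valid else rep(TRUE, nrow(sensors))
  if (!is.null(attitude)) valid <- valid & attitude$valid
  n_w <- as.integer(round(window_s * fs))
  n_windows <- nrow(sensors) %/% n_w
  rows <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    idx <- ((w - 1L) * n_w + 1L):(w * n_w)
    ok <- valid[idx]
    if (mean(ok) < 0.5) {
      rows[[w]] <- tibble::tibble(
        window_index = w, t_start = sensors$t_s[idx[1]],
        df = NA_real_, hf = NA_real_, ms = NA_real_, ss = NA_real_,
        p5 = NA_real_, iqr = NA_real_, mo = NA_real_, sh = NA_real_,
        missing = TRUE
      )
      next
    }
    freqs <- dominant_frequencies(acc[idx, 3], fs, peak_fraction)
    sh <- if (is.null(attitude)) NA_real_ else {
      circular_sd(ifelse(ok, attitude$heading_deg[idx], NA_real_))
    }
    stz <- sp$static[idx, 3]
    rows[[w]] <- tibble::tibble(
      window_index = w, t_start = sensors$t_s[idx[1]],
      df = freqs$df, hf = freqs$hf,
      ms = mean(stz), ss = sd(stz),
      p5 = as.numeric(quantile(stz, 0.95)),
      iqr = IQR(sp$dynamic[idx, 3]),
      mo = mean(ob[idx]), sh = sh,
      missing = FALSE
    )
  }
  dplyr::bind_cols(
    tibble::tibble(individual_id = individual_id),
    dplyr::bind_rows(rows),
    tibble::tibble(covariate = covariate)
  ) |>
    dplyr::relocate("covariate", .before = "missing") |>
    dplyr::relocate("individual_id")
}

#' Correlation-based feature screening
#'
#' Computes pairwise Pearson correlations over complete rows, then greedily
#' prunes: while any pair exceeds the threshold, the member of the worst
#' pair with the larger mean absolute correlation to all other surviving
#' features is dropped (ties drop the feature listed later). Constant
#' columns have undefined correlations and are dropped first.
#'
#' @param features feature tibble.
#' @param threshold absolute-correlation cutoff (default 0.7).
#' @param feature_cols candidate columns (default the eight features).
#' @return List of class `soarhmm_screen`: `selected`, `dropped`,
#'   `constant`, and the full `cor_matrix`.
#' @export
feature_correlation_screen <- function(features, threshold = 0.7,
                                       feature_cols = c("df", "hf", "ms",
                                                        "ss", "p5", "iqr",
                                                        "mo", "sh")) {
  feature_cols <- intersect(feature_cols, names(features))
  x <- as.data.frame(features[feature_cols])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3 || length(feature_cols) < 2) {
    stop("need at least 2 features with at least 3 complete rows",
         call. = FALSE)
  }
  constant <- names(x)[vapply(x, function(v) sd(v) == 0, logical(1))]
  keep <- setdiff(names(x), constant)
  cm <- suppressWarnings(cor(x))
  work <- abs(cm[keep, keep, drop = FALSE])
  dropped <- character()
  while (length(keep) > 1) {
    off <- work
    diag(off) <- 0
    if (max(off) <= threshold) break
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    pair <- keep[c(worst[["row"]], worst[["col"]])]
    score <- vapply(pair, function(f) {
      others <- setdiff(keep, f)
      mean(work[f, others])
    }, numeric(1))
    # ties drop the feature listed later in feature_cols
    loser <- if (abs(score[1] - score[2]) < 1e-15) {
      pair[which.max(match(pair, feature_cols))]
    } else {
      pair[which.max(score)]
    }
    dropped <- c(dropped, loser)
    keep <- setdiff(keep, loser)
    work <- work[keep, keep, drop = FALSE]
  }
  structure(
    list(selected = keep, dropped = dropped, constant = constant,
         cor_matrix = cm, threshold = threshold),
    class = "soarhmm_screen"
  )
}

#' @export
print.soarhmm_screen <- function(x, ...) {
  cat("<soarhmm feature screen>\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  if (length(x$dropped)) {
    cat("  dropped (|r| >", x$threshold, "):",
        paste(x$dropped, collapse = ", "), "\n")
  }
  if (length(x$constant)) {
    cat("  constant (undefined r):", paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}
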
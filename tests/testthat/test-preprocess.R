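make_series <- function(x, fs, extra = NULL) {
  n <- length(x)
  out <- tibble::tibble(t_s = (seq_len(n) - 1) / fs,
                        acc_x = 0, acc_y = 0, acc_z = x)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

test_that("decimation preserves the passband and kills the alias band", {
  fs <- 75; n <- 7500
  tt <- (seq_len(n) - 1) / fs

  # DC passthrough
  s <- make_series(rep(2.5, n), fs)
  d <- decimate_series(s, 25)
  expect_equal(d$acc_z, rep(2.5, 2500), tolerance = 1e-9)
  expect_equal(nrow(d), n / 3)
  expect_equal(diff(d$t_s)[1], 1 / 25, tolerance = 1e-12)

  # 2 Hz unit sinusoid survives with amplitude within 2% (LS sinusoid fit)
  s <- make_series(sin(2 * pi * 2 * tt), fs)
  d <- decimate_series(s, 25)
  td <- d$t_s
  X <- cbind(sin(2 * pi * 2 * td), cos(2 * pi * 2 * td))
  co <- qr.coef(qr(X), d$acc_z)
  expect_equal(sqrt(sum(co^2)), 1, tolerance = 0.02)

  # 30 Hz (above the 12.5 Hz output Nyquist) is suppressed
  s <- make_series(sin(2 * pi * 30 * tt), fs)
  d <- decimate_series(s, 25)
  expect_lte(sqrt(mean(d$acc_z^2)), 0.01)

  expect_error(decimate_series(make_series(rep(0, 100), 60), 25), "integer")
})

test_that("roll offsets are recovered from resting data", {
  fs <- 25
  rest <- function(deg, n = 1000, sd = 0) {
    a <- matrix(rep(c(0, 0, 1), each = n), n, 3) %*%
      t(soarhmm:::rot_x(-deg * pi / 180))
    if (sd > 0) a <- a + matrix(rnorm(3 * n, 0, sd), n, 3)
    tibble::tibble(t_s = (seq_len(n) - 1) / fs,
                   acc_x = a[, 1], acc_y = a[, 2], acc_z = a[, 3])
  }
  mask <- rep(TRUE, 1000)
  expect_equal(estimate_roll_offset(rest(0), mask), 0, tolerance = 1e-9)
  expect_equal(estimate_roll_offset(rest(10), mask), 10, tolerance = 0.1)

  set.seed(99)
  s <- rest(7, n = 10000, sd = 0.05)
  expect_equal(estimate_roll_offset(s, rep(TRUE, 10000)), 7, tolerance = 0.5)

  expect_error(estimate_roll_offset(rest(0), rep(FALSE, 1000)), "2 s")
})

test_that("frame correction is a rotation with the group property", {
  set.seed(4)
  n <- 200
  s <- tibble::tibble(t_s = (seq_len(n) - 1) / 25,
                      acc_x = rnorm(n), acc_y = rnorm(n), acc_z = rnorm(n),
                      mag_x = rnorm(n, 20), mag_y = rnorm(n),
                      mag_z = rnorm(n, -30))
  expect_equal(correct_frame(s, 0), s)

  twice <- correct_frame(correct_frame(s, 90), 90)
  once <- correct_frame(s, 180)
  expect_equal(as.matrix(twice[-1]), as.matrix(once[-1]), tolerance = 1e-9)

  r <- correct_frame(s, 37)
  norm0 <- sqrt(s$acc_x^2 + s$acc_y^2 + s$acc_z^2)
  norm1 <- sqrt(r$acc_x^2 + r$acc_y^2 + r$acc_z^2)
  expect_equal(norm0, norm1, tolerance = 1e-9)
  mnorm0 <- sqrt(s$mag_x^2 + s$mag_y^2 + s$mag_z^2)
  mnorm1 <- sqrt(r$mag_x^2 + r$mag_y^2 + r$mag_z^2)
  expect_equal(mnorm0, mnorm1, tolerance = 1e-9)

  # closure: correcting by the estimated offset zeroes the masked mean sway
  a <- matrix(rep(c(0, 0, 1), each = n), n, 3) %*%
    t(soarhmm:::rot_x(-8 * pi / 180))
  rest <- tibble::tibble(t_s = (seq_len(n) - 1) / 25,
                         acc_x = a[, 1], acc_y = a[, 2], acc_z = a[, 3])
  off <- estimate_roll_offset(rest, rep(TRUE, n))
  fixed <- correct_frame(rest, off)
  expect_lt(abs(mean(fixed$acc_y)), 1e-6)
})

test_that("magnetometer cleaning trims, despikes, and is idempotent", {
  fs <- 1; n <- 36000 # 10 h at 1 Hz keeps the fixture small
  s <- tibble::tibble(t_s = seq_len(n) - 1, acc_x = 0, acc_y = 0, acc_z = 1,
                      mag_x = 20, mag_y = 5, mag_z = -30)
  s$mag_x[500] <- 520 # isolated spike
  cl <- clean_magnetometer(s, trim_start_s = 7200, trim_end_s = 0,
                           median_window = 5)
  expect_equal(cl$mag_x[500], 20)
  expect_gte(min(cl$t_s[cl$valid]), 7200)
  expect_false(any(cl$valid[cl$t_s < 7200]))

  ramp <- s
  ramp$mag_x <- seq_len(n) * 0.001
  cr <- clean_magnetometer(ramp, 0, 0, 5)
  interior <- 3:(n - 2)
  expect_equal(cr$mag_x[interior], ramp$mag_x[interior], tolerance = 1e-12)

  c2 <- clean_magnetometer(cl, trim_start_s = 7200, median_window = 5)
  expect_equal(c2$mag_x, cl$mag_x, tolerance = 1e-12)

  expect_error(clean_magnetometer(s, trim_start_s = 40000), "trim")
  expect_error(clean_magnetometer(s, median_window = 4), "odd")
})

test_that("tilt-compensated heading honors the frame convention", {
  B <- c(22.5, 0, -39) # field (Bh, 0, -Bv) in nav frame
  lvl <- cbind(0, 0, 1)

  # level tag facing north reads the field as (Bh, 0, -Bv): heading 0
  at <- attitude_heading(lvl, matrix(B, 1, 3))
  expect_equal(at$heading_deg, 0, tolerance = 1e-9)
  expect_equal(at$pitch, 0); expect_equal(at$roll, 0)

  # rotated 90 degrees clockwise about the vertical: heading 90
  m90 <- soarhmm:::nav_to_tag(B, pi / 2, 0, 0)
  expect_equal(attitude_heading(lvl, m90)$heading_deg, 90, tolerance = 1e-9)

  # pitched and rolled tags recover the true heading across the circle
  for (psi in seq(0, 330, by = 30)) {
    pt <- 20 * pi / 180; rl <- 15 * pi / 180
    m <- soarhmm:::nav_to_tag(B, psi * pi / 180, pt, rl)
    g <- soarhmm:::nav_to_tag(c(0, 0, 1), psi * pi / 180, pt, rl)
    at <- attitude_heading(g, m)
    expect_equal(at$heading_deg, psi, tolerance = 0.1)
    expect_equal(at$pitch, pt, tolerance = 1e-9)
    expect_equal(at$roll, rl, tolerance = 1e-9)
  }

  # zero-norm static vector is flagged invalid, not fabricated
  at <- attitude_heading(rbind(c(0, 0, 0), c(0, 0, 1)),
                         rbind(B, B))
  expect_false(at$valid[1])
  expect_true(is.na(at$heading_deg[1]))
  expect_true(at$valid[2])
})

test_that("heading wraps into [0, 360)", {
  expect_equal(soarhmm:::wrap360(359.9 + 0.2), 0.1, tolerance = 1e-9)
  expect_equal(soarhmm:::wrap360(-10), 350)
  expect_true(all(soarhmm:::wrap360(runif(100, -1000, 1000)) >= 0))
  expect_true(all(soarhmm:::wrap360(runif(100, -1000, 1000)) < 360))
})
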
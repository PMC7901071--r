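test_that("state sequences follow the transition structure", {
  # absorbing chain stays in its initial state
  s <- simulate_state_sequence(diag(3), c(1, 0, 0), 50, seed = 1)
  expect_true(all(s == 1))

  # uniform chain: empirical transition frequencies within Monte-Carlo error
  tpm <- matrix(1 / 3, 3, 3)
  s <- simulate_state_sequence(tpm, rep(1 / 3, 3), 30000, seed = 42)
  trans <- table(head(s, -1), tail(s, -1))
  for (i in 1:3) {
    n_i <- sum(trans[i, ])
    phat <- trans[i, ] / n_i
    tol <- 3 * sqrt((1 / 3) * (2 / 3) / n_i)
    expect_true(all(abs(phat - 1 / 3) < tol))
  }

  # default dwell structure: occupancy matches the stationary distribution
  g <- default_tpms()$A
  s <- simulate_state_sequence(g, c(1, 0, 0), 100000, seed = 7)
  pi_hat <- as.numeric(table(factor(s, levels = rownames(g)))) / length(s)
  pi_true <- power_stationary(g)
  expect_true(all(abs(pi_hat - pi_true) <
                    3 * sqrt(pi_true * (1 - pi_true) / length(s)) * 6 + 0.01))
  expect_equal(sum(pi_true), 1, tolerance = 1e-12)
})

test_that("non-stochastic matrices are rejected naming the offending row", {
  bad <- matrix(c(0.5, 0.4, 0.1, 0.3, 0.3, 0.3, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_error(simulate_state_sequence(bad, rep(1 / 3, 3), 10), "row 2")
})

test_that("rendered windows carry the regime's signal structure", {
  reg <- regime_defaults()

  # on-water, zero noise and zero swell: heave pinned at 1 g, heading flat
  rw <- reg$water
  rw$dyn_noise_sd <- 0; rw$heave_osc_amplitude <- 0; rw$heading_wander_deg <- 0
  w <- render_window("water", rw, 30, 25, seed = 1)
  expect_equal(w$acc_z, rep(1, 750), tolerance = 1e-12)
  expect_equal(diff(range(w$heading_deg)), 0)

  # flapping at exactly 2.6 Hz, amplitude 1, no noise: all spectral power in
  # bin 78 of the 750-sample transform (2.6 = 78 * 25/750)
  rf <- reg$flap
  rf$flap_freq_hz <- 2.6; rf$flap_freq_sd_hz <- 0
  rf$heave_osc_amplitude <- 1; rf$amp_lognorm_sd <- 0
  rf$dyn_noise_sd <- 0; rf$heading_wander_deg <- 0
  w <- render_window("flap", rf, 30, 25, seed = 2)
  p <- Mod(fft(w$dyn_z))^2
  expect_equal(which.max(p[2:376]) + 1, 79) # 1-based: bin 79 is 78 cycles
  expect_gt(p[79] / sum(p[2:376]), 0.999)

  # soaring heading arc: circular SD matches the quadrature closed form for
  # a sinusoidal phase signal over whole periods
  rs <- reg$soar
  rs$heading_arc_period_s <- 10; rs$heading_arc_period_sd_s <- 0
  rs$heading_arc_amplitude_deg <- 80
  rs$heading_wander_deg <- 0; rs$dyn_noise_sd <- 0
  w <- render_window("soar", rs, 30, 25, seed = 3)
  expect_equal(circular_sd(w$heading_deg),
               circ_sd_sinusoid(80 * pi / 180), tolerance = 0.01)

  expect_error(
    render_window("flap",
                  utils::modifyList(reg$flap,
                                    list(heave_osc_amplitude = -1)),
                  30, 25),
    "amplitude")
})

test_that("rendered acceleration conserves total = static + dynamic", {
  for (st in c("flap", "soar", "water")) {
    w <- render_window(st, regime_defaults()[[st]], 30, 25, seed = 11)
    tot <- cbind(w$acc_x, w$acc_y, w$acc_z)
    rec <- cbind(w$static_x + w$dyn_x, w$static_y + w$dyn_y,
                 w$static_z + w$dyn_z)
    expect_lt(max(abs(tot - rec)), 1e-12)
  }
})

test_that("rendered magnetometer matches the distortion model", {
  n <- 500
  h <- runif(n, 0, 360); pt <- rep(0, n); rl <- rep(0, n)
  B <- c(22.5, 0, -39)

  m <- render_magnetometer(h, pt, rl, B)
  expect_equal(sqrt(m$mag_x^2 + m$mag_y^2 + m$mag_z^2),
               rep(sqrt(sum(B^2)), n), tolerance = 1e-9)

  hard <- c(10, -5, 3)
  md <- render_magnetometer(h, pt, rl, B, hard_iron = hard)
  expect_equal(colMeans(as.matrix(md) - as.matrix(m)), hard,
               tolerance = 1e-9, ignore_attr = TRUE)

  soft <- diag(c(1.2, 1.0, 0.8))
  ms <- render_magnetometer(h, pt, rl, B, soft_iron = soft)
  nrm <- sqrt(ms$mag_x^2 + ms$mag_y^2 + ms$mag_z^2)
  expect_gt(diff(range(nrm)), 1) # ellipsoid: norms vary over the circle
  # on the heading circle the field direction is a cone; the attainable
  # norms are bounded by the scaled cone extremes
  expect_true(all(nrm <= 1.2 * sqrt(sum(B^2)) + 1e-9))
  expect_true(all(nrm >= 0.8 * sqrt(sum(B^2)) - 1e-9))

  expect_error(render_magnetometer(h, pt, rl, B, soft_iron = matrix(0, 3, 3)),
               "invertible")
})

test_that("deployments are reproducible and labeled one-to-one", {
  cfg <- generator_config(n_individuals = 1, windows_per_individual = 10,
                          seed = 7)
  d1 <- simulate_deployment(cfg)
  d2 <- simulate_deployment(cfg)
  expect_identical(d1$sensors, d2$sensors)
  expect_identical(d1$truth, d2$truth)
  expect_equal(nrow(d1$truth), 10)
  expect_equal(nrow(d1$sensors[[1]]), 10 * 750)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_deployment(d1, dir1); write_deployment(d2, dir2)
  f1 <- file.path(dir1, "bird01.csv"); f2 <- file.path(dir2, "bird01.csv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an all-water deployment has ODBA below the flapping regime", {
  tp <- list(W = matrix(1, 1, 1, dimnames = list("water", "water")))
  cfg <- generator_config(n_individuals = 1, windows_per_individual = 20,
                          true_tpm = tp, initial_dist = 1, seed = 3)
  dep <- simulate_deployment(cfg)
  s <- dep$sensors[[1]]
  sp <- static_dynamic_split(s, fs = 25)
  mo <- mean(odba(sp$dynamic))
  # flapping windows must exceed this by construction: amplitude 0.9 g alone
  # contributes a mean |sin| of 2*0.9/pi
  expect_lt(mo, 2 * 0.9 / pi / 2)
})

test_that("generated feature clouds separate and order across states", {
  cfg <- generator_config(n_individuals = 2, windows_per_individual = 500,
                          seed = 21)
  dep <- simulate_deployment(cfg)
  run_feats <- lapply(names(dep$sensors), function(id) {
    p <- preprocess_individual(dep$sensors[[id]], trim_start_s = 0)
    window_features(p$sensors, p$attitude, individual_id = id)
  })
  ft <- dplyr::bind_rows(run_feats)
  ft <- dplyr::inner_join(ft, dep$truth, by = c("individual_id",
                                                "window_index"))
  expect_gte(nrow(ft), 1000)
  m <- ft |>
    dplyr::group_by(true_state) |>
    dplyr::summarise(hf = mean(hf), sh = mean(sh), p5 = mean(p5))
  hfm <- setNames(m$hf, m$true_state)
  shm <- setNames(m$sh, m$true_state)
  expect_gt(hfm["flap"], hfm["soar"])
  expect_gte(hfm["soar"], hfm["water"])
  expect_lt(shm["water"], shm["soar"])
})
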
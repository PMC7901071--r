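test_that("validation sampling is exact, seeded, and excludes colony rows", {
  ft <- fake_features(14, 60)
  v <- sample_validation_windows(ft, n_per_bird = 50, seed = 5)
  expect_equal(nrow(v), 700)
  expect_true(all(table(v$individual_id) == 50))
  expect_equal(anyDuplicated(v[c("individual_id", "window_index")]), 0)

  v2 <- sample_validation_windows(ft, n_per_bird = 50, seed = 5)
  expect_identical(v, v2)

  # colony-period windows are removed after sampling with a count
  set.seed(5)
  v0 <- sample_validation_windows(ft, n_per_bird = 50, seed = 5)
  picked <- paste(v0$individual_id, v0$window_index)
  colony <- rep(FALSE, nrow(ft))
  colony[match(picked[1:8], paste(ft$individual_id, ft$window_index))] <- TRUE
  v3 <- sample_validation_windows(ft, n_per_bird = 50, colony_mask = colony,
                                  seed = 5)
  expect_equal(nrow(v3), 692)
  expect_equal(attr(v3, "n_colony_excluded"), 8)

  expect_error(
    sample_validation_windows(fake_features(2, 30), n_per_bird = 50),
    "bird01")
})

test_that("confusion matrices tabulate accuracy with exact intervals", {
  lv <- c("flap", "soar", "water")
  perfect <- sample(lv, 60, replace = TRUE)
  cm <- confusion_matrix(perfect, perfect, lv)
  expect_equal(cm$accuracy, 100)
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)

  # hand-tabulated toy: diagonal (8, 9, 9), two errors in 28
  truth <- c(rep("a", 9), rep("b", 9), rep("c", 10))
  asg <- truth
  asg[9] <- "b"   # one a -> b
  asg[28] <- "a"  # one c -> a
  cm <- confusion_matrix(truth, asg, c("a", "b", "c"))
  expect_equal(diag(cm$counts), c(a = 8, b = 9, c = 9))
  expect_equal(cm$accuracy, 100 * 26 / 28, tolerance = 1e-9)
  expect_equal(cm$col_pct[, "a"], c(a = 8, b = 1, c = 0) / 9 * 100)
  expect_equal(unname(colSums(cm$col_pct)), rep(100, 3), tolerance = 1e-9)

  # 636 matches out of 692 rounds to the published-scale 91.9% with the
  # matching exact interval
  truth2 <- rep("a", 692)
  asg2 <- c(rep("a", 636), rep("b", 56))
  cm2 <- confusion_matrix(truth2, asg2, c("a", "b"))
  expect_equal(round(cm2$accuracy, 1), 91.9)
  expect_equal(round(cm2$ci, 1), c(89.6, 93.8))

  expect_error(confusion_matrix(c("a", "q"), c("a", "a"), c("a", "b")),
               "alphabet")
})

test_that("grouped accuracy pools additively and flags empty groups", {
  set.seed(6)
  d <- tibble::tibble(
    true_state = sample(c("x", "y"), 200, replace = TRUE),
    state = sample(c("x", "y"), 200, replace = TRUE),
    covariate = rep(c("A", "B"), each = 100)
  )
  g <- grouped_accuracy(d)
  expect_equal(g$pooled$counts,
               g$groups$A$counts + g$groups$B$counts)

  one <- grouped_accuracy(d[d$covariate == "A", ])
  expect_equal(one$groups$A$counts, one$pooled$counts)

  # constructed separation: the noisier group is less accurate, every seed
  worse <- 0
  for (s in 1:10) {
    set.seed(s)
    truth <- sample(c("x", "y"), 400, replace = TRUE)
    flipA <- rbinom(200, 1, 0.05) == 1
    flipB <- rbinom(200, 1, 0.30) == 1
    asg <- truth
    asg[1:200][flipA] <- ifelse(truth[1:200][flipA] == "x", "y", "x")
    asg[201:400][flipB] <- ifelse(truth[201:400][flipB] == "x", "y", "x")
    dd <- tibble::tibble(true_state = truth, state = asg,
                         covariate = rep(c("A", "B"), each = 200))
    gg <- grouped_accuracy(dd)
    worse <- worse + (gg$groups$B$accuracy < gg$groups$A$accuracy)
  }
  expect_equal(worse, 10)
})

test_that("bouts are maximal runs whose durations tile the record", {
  b <- extract_bouts(c("A", "A", "A", "B", "B", "A"))
  expect_equal(b$state, c("A", "B", "A"))
  expect_equal(b$n_windows, c(3, 2, 1))
  expect_equal(b$duration_min, c(1.5, 1.0, 0.5))

  b1 <- extract_bouts(rep("soar", 77))
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n_windows, 77)

  # mean dwell of a simulated chain approaches the geometric closed form
  g <- default_tpms()$A
  s <- simulate_state_sequence(g, power_stationary(g), 50000, seed = 14)
  b <- extract_bouts(s, window_s = 30)
  for (st in rownames(g)) {
    expected <- 1 / (1 - g[st, st])
    observed <- mean(b$n_windows[b$state == st])
    expect_equal(observed, expected, tolerance = 0.05 * expected)
  }
  expect_equal(sum(b$n_windows), 50000)
})

test_that("activity budgets sum to 100 over at-sea windows", {
  ab <- activity_budget(rep("soar", 40))
  expect_equal(ab$pct, 100)

  s <- rep(c("flap", "soar", "water"), each = 20)
  ab <- activity_budget(s)
  expect_equal(ab$pct, rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(ab$pct), 100, tolerance = 1e-9)

  st <- tibble::tibble(individual_id = "b1", window_index = 1:10,
                       state = rep(c("flap", "water"), 5))
  ab2 <- activity_budget(st, at_sea_mask = c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(sum(ab2$n_windows), 6)
  expect_error(activity_budget(st, at_sea_mask = rep(FALSE, 10)), "empty")
})

test_that("budget differences between two decodings are paired per state", {
  # mirrors comparing budgets from a 3-feature and a 2-feature model
  p <- benchmark_params()
  ft <- simulate_hmm_features(p, 800, seed = 15)
  v1 <- viterbi_decode(ft, p)
  p2 <- hmm_params(p$shape[, 1:2], p$scale[, 1:2], tpm = transition_matrix(p),
                   delta = p$delta, state_names = p$state_names,
                   features = c("hf", "p5"))
  v2 <- viterbi_decode(ft, p2)
  b1 <- activity_budget(v1, levels = p$state_names)
  b2 <- activity_budget(v2, levels = p$state_names)
  d <- dplyr::inner_join(b1, b2, by = c("individual_id", "state"))
  expect_equal(nrow(d), 3)
  expect_true(all(abs(d$pct.x - d$pct.y) < 15))
})
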
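test_that("the Weibull log-density is a density with known special values", {
  expect_equal(weibull_logpdf(1, 1, 1), -1) # exponential(1) at 1
  for (k in c(0.5, 1, 2, 5)) {
    for (lam in c(0.5, 1, 3)) {
      up <- lam * log(1e10)^(1 / k) # inverse-CDF 1 - 1e-10 tail point
      mass <- integrate(function(x) exp(weibull_logpdf(x, k, lam)),
                        lower = 1e-12, upper = up,
                        rel.tol = 1e-9)$value
      expect_equal(mass, 1, tolerance = 1e-6)
      med <- lam * log(2)^(1 / k)
      cdf <- integrate(function(x) exp(weibull_logpdf(x, k, lam)),
                       lower = 1e-12, upper = med, rel.tol = 1e-10)$value
      expect_equal(cdf, 0.5, tolerance = 1e-6)
    }
  }
  expect_error(weibull_logpdf(-1, 1, 1), "floor")
  expect_error(weibull_logpdf(1, -1, 1), "> 0")
})

test_that("emission factors multiply over features and skip missing rows", {
  p <- hmm_params(shape = matrix(c(2, 3), 2, 1), scale = matrix(c(1, 2), 2, 1))
  e <- emission_matrix(matrix(1.3), p)
  expect_equal(as.numeric(e),
               dweibull(1.3, c(2, 3), c(1, 2)), tolerance = 1e-12)

  p2 <- hmm_params(shape = matrix(c(2, 3, 1, 4), 2, 2),
                   scale = matrix(c(1, 2, 3, 1), 2, 2))
  x <- matrix(c(1.3, 0.7), 1, 2)
  e2 <- emission_matrix(x, p2)
  e_f1 <- dweibull(1.3, p2$shape[, 1], p2$scale[, 1])
  e_f2 <- dweibull(0.7, p2$shape[, 2], p2$scale[, 2])
  expect_equal(as.numeric(e2), e_f1 * e_f2, tolerance = 1e-12)

  xm <- rbind(x, c(NA, NA))
  e3 <- emission_matrix(xm, p2)
  expect_equal(e3[2, ], c(1, 1))

  expect_error(emission_matrix(matrix(NaN, 1, 2), p2), "row 1")
})

test_that("the multinomial-logit link produces and inverts matrices", {
  p0 <- hmm_params(shape = matrix(1, 3, 1), scale = matrix(1, 3, 1),
                   beta = matrix(0, 1, 6))
  expect_equal(transition_matrix(p0), matrix(1 / 3, 3, 3),
               ignore_attr = TRUE)

  pn <- hmm_params(shape = matrix(1, 3, 1), scale = matrix(1, 3, 1),
                   beta = matrix(-10, 1, 6))
  expect_true(all(diag(transition_matrix(pn)) > 0.9999))

  # link inversion reproduces the literature-style printed matrix
  g <- default_tpms()$A
  pi_ <- hmm_params(shape = matrix(1, 3, 1), scale = matrix(1, 3, 1),
                    tpm = g)
  expect_equal(transition_matrix(pi_), g, tolerance = 1e-12)
  # and matches the printed three-decimal values after rounding
  expect_equal(round(transition_matrix(pi_), 3),
               matrix(c(0.778, 0.204, 0.019,
                        0.083, 0.900, 0.017,
                        0.010, 0.016, 0.974), 3, 3, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 2e-3)

  expect_error(transition_matrix(pi_, "nope"), "unknown")
  # every produced matrix is row-stochastic to 1e-12
  set.seed(13)
  for (i in 1:20) {
    pr <- hmm_params(shape = matrix(1, 3, 1), scale = matrix(1, 3, 1),
                     beta = matrix(rnorm(12, 0, 3), 2, 6),
                     cov_levels = c("a", "b"))
    for (lv in c("a", "b")) {
      expect_lt(max(abs(rowSums(transition_matrix(pr, lv)) - 1)), 1e-12)
    }
  }
})

test_that("forward log-likelihood matches mixtures and exhaustive paths", {
  inst <- rand_hmm_instance(1, seed = 21)
  ll <- forward_loglik(inst$features, inst$params)
  expect_equal(ll, log(sum(inst$delta * inst$E[1, ])), tolerance = 1e-10)

  inst <- rand_hmm_instance(3, seed = 22)
  ll <- forward_loglik(inst$features, inst$params)
  expect_equal(ll, brute_forward_loglik(inst$E, inst$tpm, inst$delta),
               tolerance = 1e-10)

  # identical emissions across states: the chain marginalizes out
  p_eq <- hmm_params(shape = matrix(2, 3, 1, dimnames = list(NULL, "f1")),
                     scale = matrix(1.5, 3, 1), tpm = default_tpms()$A)
  x <- rweibull(20, 2, 1.5)
  ft <- tibble::tibble(individual_id = "a", window_index = 1:20, f1 = x)
  expect_equal(forward_loglik(ft, p_eq),
               sum(dweibull(pmax(x, 1e-6), 2, 1.5, log = TRUE)),
               tolerance = 1e-10)

  expect_error(soarhmm:::build_chain_data(ft[0, ], "f1"), "empty|usable")
})

test_that("likelihood is invariant under state permutation", {
  inst <- rand_hmm_instance(40, seed = 23)
  ll0 <- forward_loglik(inst$features, inst$params)
  perm <- c(2, 3, 1)
  pp <- hmm_params(
    shape = inst$params$shape[perm, , drop = FALSE],
    scale = inst$params$scale[perm, , drop = FALSE],
    tpm = inst$tpm[perm, perm], delta = inst$delta[perm],
    features = "f1"
  )
  expect_equal(forward_loglik(inst$features, pp), ll0, tolerance = 1e-10)
})

test_that("Viterbi matches degenerate cases and exhaustive argmax", {
  # absorbing start: zero-probability competitors never win
  inst <- rand_hmm_instance(6, seed = 24)
  p_id <- hmm_params(inst$params$shape, inst$params$scale,
                     beta = matrix(-30, 1, 6), delta = c(1 - 2e-12, 1e-12, 1e-12),
                     features = "f1")
  v <- viterbi_decode(inst$features, p_id)
  expect_true(all(v$state_index == 1))

  # uniform chain: per-window argmax of emissions
  p_u <- hmm_params(inst$params$shape, inst$params$scale,
                    beta = matrix(0, 1, 6), features = "f1")
  v <- viterbi_decode(inst$features, p_u)
  expect_equal(v$state_index, apply(inst$E, 1, which.max))

  # exhaustive argmax at T = 3
  inst <- rand_hmm_instance(3, seed = 25)
  v <- viterbi_decode(inst$features, inst$params)
  expect_equal(v$state_index, brute_viterbi(inst$E, inst$tpm, inst$delta)$path)
})

test_that("the Viterbi path beats random paths in joint probability", {
  set.seed(26)
  for (rep in 1:3) {
    inst <- rand_hmm_instance(30, seed = 26 + rep)
    v <- viterbi_decode(inst$features, inst$params)$state_index
    lp_v <- path_logprob(v, inst$E, inst$tpm, inst$delta)
    rnd <- replicate(1000, path_logprob(sample(1:3, 30, replace = TRUE),
                                        inst$E, inst$tpm, inst$delta))
    expect_gte(lp_v, max(rnd))
  }
})

test_that("fitting is deterministic, monotone in restarts, and reduces to
           univariate Weibull ML with one state", {
  p <- benchmark_params()
  ft <- simulate_hmm_features(p, 400, seed = 31)

  f1 <- fit_hmm(ft, n_restarts = 3, seed = 9)
  f2 <- fit_hmm(ft, n_restarts = 3, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)

  # best-of-k log-likelihood is non-decreasing in k (shared restart seeds)
  lls <- vapply(c(1, 3, 6), function(k) {
    fit_hmm(ft, n_restarts = k, seed = 9)$loglik
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))

  # one state: independent Weibull maximum likelihood per feature
  f0 <- fit_hmm(ft, feature_set = "hf", n_states = 1, n_restarts = 2,
                seed = 1)
  direct <- fitdistrplus::fitdist(ft$hf, "weibull")
  expect_equal(f0$loglik, as.numeric(stats::logLik(direct)), tolerance = 1e-4)
  expect_equal(unname(f0$params$shape[1, 1]),
               unname(direct$estimate["shape"]), tolerance = 1e-3)
})

test_that("AIC comparison uses the free-parameter count", {
  p <- benchmark_params()
  ft <- simulate_hmm_features(p, 300, seed = 32)
  fit <- fit_hmm(ft, n_restarts = 2, seed = 2)
  # 3 states x 3 features x 2 + 3*2*1 + 2 = 26 free parameters
  expect_equal(fit$n_par, 26)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 26)

  cmp <- compare_aic(fit, fit)
  expect_equal(cmp$delta_aic, 0)

  fit_b <- fit
  fit_b$aic <- fit_b$aic + 2 # same loglik, one extra parameter
  expect_equal(compare_aic(fit, fit_b)$delta_aic, -2)
  expect_identical(compare_aic(fit, fit_b)$preferred, "fit_a")

  fit_c <- fit
  fit_c$data_hash <- "other"
  expect_error(compare_aic(fit, fit_c), "fingerprint")
})

test_that("state labels resolve by feature means into a permutation", {
  p <- benchmark_params()
  ft <- simulate_hmm_features(p, 1500, seed = 33)
  fit <- fit_hmm(ft, n_restarts = 6, seed = 3)
  lab <- label_states(fit)
  expect_setequal(lab$params$state_names, c("flap", "soar", "water"))
  v <- viterbi_decode(ft, lab)
  expect_gt(mean(v$state == ft$true_state), 0.95)
})

test_that("missing windows are skipped by emissions but bridged by
           transitions", {
  p <- benchmark_params()
  ft <- simulate_hmm_features(p, 60, seed = 34)
  ft$missing[10] <- TRUE
  ft[10, c("hf", "p5", "sh")] <- NA
  ll <- forward_loglik(ft, p)
  expect_true(is.finite(ll))
  v <- viterbi_decode(ft, p)
  expect_false(is.na(v$state_index[10])) # decoded through the chain

  # a long missing run splits the chain and drops those windows
  ft2 <- ft
  ft2$missing[20:35] <- TRUE
  ft2[20:35, c("hf", "p5", "sh")] <- NA
  v2 <- viterbi_decode(ft2, p)
  expect_true(all(is.na(v2$state_index[20:35])))
  expect_false(any(is.na(v2$state_index[36:60])))
})

test_that("pseudo-residuals are standard normal under the true model and
           reject under gross misspecification", {
  p <- benchmark_params()
  ks_p <- function(params_fit, n = 1000, seed) {
    ft <- simulate_hmm_features(p, n, seed = seed)
    pr <- pseudo_residuals(ft, params_fit)
    suppressWarnings(stats::ks.test(pr$resid_hf, "pnorm")$p.value)
  }
  pvals <- vapply(1:100, function(s) ks_p(p, seed = 100 + s), numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)

  p_bad <- p
  p_bad$shape <- p$shape / 2
  pvals_bad <- vapply(1:40, function(s) ks_p(p_bad, seed = 300 + s),
                      numeric(1))
  expect_gte(mean(pvals_bad < 0.01), 0.95)

  # single observation, single state: residual is the probability transform
  p1 <- hmm_params(shape = matrix(2, 1, 1, dimnames = list(NULL, "f1")),
                   scale = matrix(1.5, 1, 1))
  ft1 <- tibble::tibble(individual_id = "a", window_index = 1L, f1 = 0.9)
  pr1 <- pseudo_residuals(ft1, p1)
  expect_equal(pr1$resid_f1, qnorm(pweibull(0.9, 2, 1.5)), tolerance = 1e-10)
})
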
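# Independent oracles used across the suite: exhaustive-path HMM
# computations, power-iteration stationary distributions, quadrature for
# circular spread of sinusoidal heading arcs, and small builders.

# Exhaustive sum over all S^T state paths of delta * emissions * transitions.
brute_forward_loglik <- function(E, tpm, delta) {
  S <- ncol(E); TT <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), TT)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- delta[s[1]] * E[1, s[1]]
    if (TT > 1) {
      for (t in 2:TT) pr <- pr * tpm[s[t - 1], s[t]] * E[t, s[t]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Exhaustive argmax path (first maximum in expand.grid order).
brute_viterbi <- function(E, tpm, delta) {
  S <- ncol(E); TT <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), TT)))
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- log(delta[s[1]]) + log(E[1, s[1]])
    if (TT > 1) {
      for (t in 2:TT) pr <- pr + log(tpm[s[t - 1], s[t]]) + log(E[t, s[t]])
    }
    if (pr > best) { best <- pr; arg <- s }
  }
  list(path = unname(arg), logprob = best)
}

# Joint log-probability of an arbitrary path.
path_logprob <- function(s, E, tpm, delta) {
  pr <- log(delta[s[1]]) + log(E[1, s[1]])
  if (length(s) > 1) {
    for (t in 2:length(s)) pr <- pr + log(tpm[s[t - 1], s[t]]) + log(E[t, s[t]])
  }
  pr
}

power_stationary <- function(tpm, iter = 5000) {
  v <- rep(1 / nrow(tpm), nrow(tpm))
  for (i in seq_len(iter)) v <- as.numeric(v %*% tpm)
  v / sum(v)
}

# Circular SD of a sinusoidal heading signal psi = A sin(theta) over whole
# periods, by dense quadrature of the mean resultant length.
circ_sd_sinusoid <- function(A_rad, n = 200000) {
  th <- seq(0, 2 * pi, length.out = n)
  rbar <- sqrt(mean(cos(A_rad * sin(th)))^2 + mean(sin(A_rad * sin(th)))^2)
  sqrt(-2 * log(rbar))
}

# Random small HMM instance with one Weibull feature.
rand_hmm_instance <- function(TT, S = 3, seed = 1) {
  set.seed(seed)
  tpm <- matrix(stats::rgamma(S * S, 1) + 0.05, S, S)
  tpm <- tpm / rowSums(tpm)
  delta <- stats::rgamma(S, 1) + 0.05
  delta <- delta / sum(delta)
  shape <- matrix(runif(S, 0.6, 4), S, 1,
                  dimnames = list(NULL, "f1"))
  scale <- matrix(runif(S, 0.5, 4), S, 1)
  x <- rweibull(TT, shape = 1.5, scale = 2)
  params <- hmm_params(shape, scale, tpm = tpm, delta = delta)
  ft <- tibble::tibble(individual_id = "a", window_index = seq_len(TT),
                       f1 = x, missing = FALSE)
  E <- exp(soarhmm:::hmm_log_emissions_cpp(matrix(x, ncol = 1), shape, scale))
  list(params = params, features = ft, E = E, tpm = tpm, delta = delta)
}

# Three-state parameter set resembling the default signal regimes in
# feature space; used for recovery and residual studies.
benchmark_params <- function(tpm = default_tpms()$A) {
  hmm_params(
    shape = matrix(c(28, 9, 4.5, 89, 18, 111, 2.8, 25, 2.6), 3, 3,
                   dimnames = list(NULL, c("hf", "p5", "sh"))),
    scale = matrix(c(2.65, 0.21, 0.107, 1.05, 1.10, 1.05,
                     0.071, 1.09, 0.026), 3, 3),
    tpm = tpm, state_names = c("flap", "soar", "water")
  )
}

# A minimal feature table with ids only, for sampling arithmetic.
fake_features <- function(n_birds, n_windows, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(
    individual_id = sprintf("bird%02d", seq_len(n_birds)),
    window_index = seq_len(n_windows)
  ) |>
    dplyr::mutate(hf = runif(dplyr::n()))
}

# Dirichlet-kernel amplitude attenuation of a running mean of length L
# (samples) at frequency f (Hz) and rate fs.
running_mean_gain <- function(f, L, fs) {
  abs(sin(pi * f * L / fs) / (L * sin(pi * f / fs)))
}
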
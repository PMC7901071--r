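# Chain-data assembly shared by the likelihood, fitting, decoding, and
# residual code. Orders windows within individual, floors features into the
# Weibull support, marks missing windows as NA rows, and splits an
# individual's chain into separate segments at missing runs longer than
# max_missing_run (those windows are excluded entirely).
build_chain_data <- function(features, feature_set, covariate = NULL,
                             cov_levels = NULL, feature_floor = 1e-6,
                             max_missing_run = 10) {
  stopifnot(all(c("individual_id", "window_index") %in% names(features)),
            all(feature_set %in% names(features)))
  features <- dplyr::arrange(features, .data$individual_id,
                             .data$window_index)
  obs <- as.matrix(features[feature_set])
  storage.mode(obs) <- "double"
  miss <- !stats::complete.cases(obs)
  if ("missing" %in% names(features)) {
    miss <- miss | isTRUE_vec(features$missing)
  }
  obs[!miss, ] <- pmax(obs[!miss, , drop = FALSE], feature_floor)
  obs[miss, ] <- NA_real_

  if (is.null(covariate)) {
    lev_per_row <- rep("all", nrow(features))
    cov_levels <- cov_levels %||% "all"
  } else {
    stopifnot(covariate %in% names(features))
    lev_per_row <- as.character(features[[covariate]])
    cov_levels <- cov_levels %||% sort(unique(lev_per_row))
    if (any(!lev_per_row %in% cov_levels)) {
      stop("unknown covariate level: ",
           setdiff(lev_per_row, cov_levels)[1], call. = FALSE)
    }
  }

  keep <- rep(TRUE, nrow(features))
  seg_start <- integer(); seg_end <- integer(); seg_cov <- integer()
  ids <- features$individual_id
  for (id in unique(ids)) {
    rows <- which(ids == id)
    lv <- unique(lev_per_row[rows])
    if (length(lv) > 1) {
      stop("individual ", id, " has multiple covariate levels", call. = FALSE)
    }
    r <- rle(miss[rows])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    drop_run <- r$values & r$lengths > max_missing_run
    for (k in which(drop_run)) keep[rows[starts[k]:ends[k]]] <- FALSE
  }
  kept <- which(keep)
  pos_of <- integer(length(keep)); pos_of[kept] <- seq_along(kept)
  for (id in unique(ids)) {
    rows <- which(ids == id & keep)
    if (!length(rows)) next
    breaks <- which(diff(rows) > 1)
    s <- c(rows[1], rows[breaks + 1])
    e <- c(rows[breaks], rows[length(rows)])
    seg_start <- c(seg_start, pos_of[s])
    seg_end <- c(seg_end, pos_of[e])
    seg_cov <- c(seg_cov, rep(match(lev_per_row[rows[1]], cov_levels),
                              length(s)))
  }
  if (!length(seg_start)) stop("empty chain: no usable windows", call. = FALSE)
  list(obs = obs[kept, , drop = FALSE], features = features, kept = kept,
       seg_start = seg_start, seg_end = seg_end, seg_cov = seg_cov,
       cov_levels = cov_levels,
       n_obs = sum(!miss[kept]))
}

isTRUE_vec <- function(x) !is.na(x) & x

gamma_array <- function(params) {
  S <- params$n_states
  vapply(params$cov_levels,
         function(lv) as.numeric(transition_matrix(params, lv)),
         numeric(S * S))
}

chain_loglik <- function(cd, params) {
  le <- hmm_log_emissions_cpp(cd$obs, params$shape, params$scale)
  hmm_forward_loglik_cpp(le, cd$seg_start, cd$seg_end, cd$seg_cov,
                         params$delta, as.numeric(gamma_array(params)))
}

#' Forward-algorithm log-likelihood of a feature table
#'
#' Total log-likelihood over individuals treated as independent realizations
#' of a common model: the sum over chains of
#' `log(delta' diag(e_1) Gamma diag(e_2) ... Gamma diag(e_T) 1)`, computed
#' with per-step scaling so chains of 1e5+ windows neither underflow nor
#' overflow. Missing windows contribute emission factor 1; missing runs
#' longer than `max_missing_run` split the chain into separate segments.
#'
#' @param features feature tibble with `individual_id`, `window_index`, the
#'   model features, and optionally `missing` and a covariate column.
#' @param params an [hmm_params()] object.
#' @param covariate name of the covariate column, or `NULL` when the model
#'   has a single level.
#' @param feature_floor lower floor applied to features (default 1e-6).
#' @param max_missing_run chain-splitting threshold in windows (default 10).
#' @return Log-likelihood (scalar).
#' @export
forward_loglik <- function(features, params, covariate = NULL,
                           feature_floor = 1e-6, max_missing_run = 10) {
  cd <- build_chain_data(features, params$features, covariate,
                         cov_levels = if (length(params$cov_levels) > 1 ||
                                          params$cov_levels[1] != "all")
                           params$cov_levels,
                         feature_floor = feature_floor,
                         max_missing_run = max_missing_run)
  chain_loglik(cd, params)
}

# ---- parameter packing for unconstrained optimization -----------------------

pack_params <- function(params) {
  c(log(as.numeric(params$shape)), log(as.numeric(params$scale)),
    as.numeric(params$beta),
    if (params$n_states > 1) log(params$delta[-1] / params$delta[1]))
}

unpack_params <- function(par, S, FF, L, features, cov_levels, state_names) {
  nsf <- S * FF
  shape <- matrix(exp(par[seq_len(nsf)]), S, FF,
                  dimnames = list(NULL, features))
  scale <- matrix(exp(par[nsf + seq_len(nsf)]), S, FF)
  nb <- S * (S - 1) * L
  beta <- matrix(par[2 * nsf + seq_len(nb)], L, S * (S - 1))
  if (S > 1) {
    alr <- par[2 * nsf + nb + seq_len(S - 1)]
    delta <- c(1, exp(alr)); delta <- delta / sum(delta)
  } else delta <- 1
  hmm_params(shape, scale, beta = beta, delta = delta,
             cov_levels = cov_levels, state_names = state_names,
             features = features)
}

n_free_params <- function(S, FF, L) 2L * S * FF + S * (S - 1L) * L + (S - 1L)

# Lean objective used inside optim: builds the transition array and delta
# straight from the packed vector, skipping the parameter-object machinery.
make_gammas <- function(beta, S, L) {
  if (S == 1) return(rep(1, L))
  offdiag <- as.logical(t(diag(S) == 0))
  g <- numeric(S * S * L)
  for (l in seq_len(L)) {
    eta_off <- beta[1, ]
    if (l > 1) eta_off <- eta_off + beta[l, ]
    eta <- matrix(0, S, S)
    eta[offdiag] <- eta_off
    eta <- t(eta)
    ex <- exp(eta)
    g[(l - 1) * S * S + seq_len(S * S)] <- ex / rowSums(ex)
  }
  g
}

nll_fast <- function(par, cd, S, FF, L) {
  nsf <- S * FF
  shape <- matrix(exp(par[seq_len(nsf)]), S, FF)
  scale <- matrix(exp(par[nsf + seq_len(nsf)]), S, FF)
  nb <- S * (S - 1) * L
  beta <- matrix(par[2 * nsf + seq_len(nb)], L, S * (S - 1))
  if (S > 1) {
    delta <- c(1, exp(par[2 * nsf + nb + seq_len(S - 1)]))
    delta <- delta / sum(delta)
  } else delta <- 1
  le <- hmm_log_emissions_cpp(cd$obs, shape, scale)
  ll <- hmm_forward_loglik_cpp(le, cd$seg_start, cd$seg_end, cd$seg_cov,
                               delta, make_gammas(beta, S, L))
  if (!is.finite(ll)) 1e12 else -ll
}

# Random starting values: per-feature scale anchors drawn from the data
# quantile envelope with a random state-to-anchor assignment; shapes from a
# log-uniform coefficient-of-variation envelope; transitions near a
# diagonally dominant matrix; covariate offsets at zero.
draw_start <- function(obs, S, FF, L) {
  shape <- matrix(0, S, FF); scale <- matrix(0, S, FF)
  for (f in seq_len(FF)) {
    x <- obs[!is.na(obs[, f]), f]
    anchors <- quantile(x, probs = (seq_len(S) - 0.5) / S, names = FALSE)
    perm <- sample.int(S)
    cv <- exp(runif(S, log(0.02), log(1.0)))
    k <- pmax(cv^-1.086, 0.5)
    shape[, f] <- k
    scale[, f] <- pmax(anchors[perm], 1e-5) *
      exp(runif(S, -0.3, 0.3)) / gamma(1 + 1 / k)
  }
  beta <- matrix(0, L, S * (S - 1))
  if (S > 1) beta[1, ] <- -2.8 + runif(S * (S - 1), -0.7, 0.7)
  delta <- rep(1 / S, S)
  list(shape = shape, scale = scale, beta = beta, delta = delta)
}

# Weighted Weibull maximum likelihood via the profile-likelihood score in
# the shape: with centered logs y the root of
# sum(w e^{ky} y)/sum(w e^{ky}) = 1/k. Safeguarded Newton warm-started at
# k0; returns c(shape, scale) or NA when the weight mass is negligible.
wweib_mle <- function(x, w, k0 = 1) {
  sw <- sum(w)
  if (!is.finite(sw) || sw < 1e-10) return(c(NA_real_, NA_real_))
  lx <- log(x)
  mlx <- sum(w * lx) / sw
  y <- lx - mlx
  if (max(abs(y)) < 1e-12) return(c(600, exp(mlx))) # degenerate spread
  pos <- w > 0
  lw <- log(w[pos]); yp <- y[pos]
  k <- min(max(k0, 0.1), 500)
  lo <- 0.05; hi <- 600
  for (it in 1:50) {
    a <- lw + k * yp; a <- a - max(a)
    ez <- exp(a)
    A <- sum(ez); B <- sum(ez * yp); C <- sum(ez * yp^2)
    m1 <- B / A
    h <- m1 - 1 / k
    if (h > 0) hi <- min(hi, k) else lo <- max(lo, k)
    hp <- (C / A - m1^2) + 1 / k^2
    knew <- k - h / hp
    if (!is.finite(knew) || knew <= lo || knew >= hi) knew <- sqrt(lo * hi)
    if (abs(knew - k) < 1e-10 * k) { k <- knew; break }
    k <- knew
  }
  a <- lw + k * yp; m <- max(a)
  lam <- exp(mlx + (m + log(sum(exp(a - m))) - log(sw)) / k)
  c(k, lam)
}

# One EM (Baum-Welch) run from a start list; closed-form M-steps for the
# initial distribution and the per-level transition matrices, profile
# Newton for the Weibull emissions. Returns natural-scale parameters.
em_run <- function(cd, S, FF, L, init, maxiter = 500, tol = 1e-8) {
  shape <- init$shape; scale <- init$scale; delta <- init$delta
  gammas <- make_gammas(init$beta, S, L)
  obs <- cd$obs
  nonmiss <- !is.na(obs[, 1])
  ll_old <- -Inf; converged <- FALSE; ll <- -Inf
  for (it in seq_len(maxiter)) {
    le <- hmm_log_emissions_cpp(obs, shape, scale)
    fb <- hmm_forward_backward_cpp(le, cd$seg_start, cd$seg_end, cd$seg_cov,
                                   delta, gammas, L)
    ll <- fb$loglik
    if (!is.finite(ll)) break
    if (it > 1 && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (S > 1) {
      delta <- fb$delta_num / sum(fb$delta_num)
      xi <- array(fb$xi, c(S, S, L))
      gnew <- array(gammas, c(S, S, L))
      for (l in seq_len(L)) {
        rs <- rowSums(xi[, , l])
        for (i in seq_len(S)) {
          if (rs[i] > 1e-12) gnew[i, , l] <- xi[i, , l] / rs[i]
        }
      }
      gammas <- as.numeric(gnew)
    }
    u <- fb$u
    for (i in seq_len(S)) {
      w <- u[nonmiss, i]
      for (f in seq_len(FF)) {
        res <- wweib_mle(obs[nonmiss, f], w, k0 = shape[i, f])
        if (!is.na(res[1])) { shape[i, f] <- res[1]; scale[i, f] <- res[2] }
      }
    }
  }
  list(loglik = ll, converged = converged, shape = shape, scale = scale,
       gammas = gammas, delta = delta, iter = it)
}

# Convert fitted per-level matrices back to logit coefficients
# (intercept = reference level, offsets for the others).
gammas_to_beta <- function(gammas, S, L) {
  if (S == 1) return(matrix(0, L, 0))
  eta <- t(vapply(seq_len(L), function(l) {
    g <- matrix(gammas[(l - 1) * S * S + seq_len(S * S)], S, S)
    # EM can return exact zeros (events unobserved at a level); floor them
    # so logits stay inside the optimizer box and reconstruct faithfully
    g <- pmax(g, 1e-8)
    tpm_to_eta(g / rowSums(g))
  }, numeric(S * (S - 1))))
  eta <- matrix(eta, L, S * (S - 1))
  if (L > 1) eta[-1, ] <- sweep(eta[-1, , drop = FALSE], 2, eta[1, ])
  eta
}

#' Fit a Weibull-emission HMM by multi-restart maximum likelihood
#'
#' Each restart draws random starting values (per-feature scale anchors from
#' the data quantile envelope with a random state assignment, shapes from a
#' log-uniform coefficient-of-variation envelope, near-diagonal
#' transitions), runs Baum-Welch EM — closed-form M-steps for the initial
#' distribution and the per-covariate-level transition matrices, profile
#' Newton for the Weibull shapes and scales — and then polishes the EM
#' optimum with a quasi-Newton (`L-BFGS-B`) pass on the unconstrained
#' parameterization (log shape/scale, multinomial-logit transition
#' coefficients, additive-log-ratio initial distribution), with a
#' Nelder-Mead fallback. The restart with the largest converged
#' log-likelihood wins; the stability report counts restarts that settle
#' within `1e-3` of it.
#'
#' @inheritParams forward_loglik
#' @param feature_set character vector of feature columns to model
#'   (default the three-feature set `hf`, `p5`, `sh`).
#' @param n_states number of hidden states (default 3).
#' @param n_restarts random restarts (default 25).
#' @param seed integer seed making the whole fit reproducible.
#' @param maxit EM iteration cap per restart.
#' @param init optional [hmm_params()] (or a fitted model) used as one
#'   additional, non-random starting point — the standard warm start when
#'   comparing nested transition models (fit the simpler model, start the
#'   richer one from it). A single-level `init` is expanded to the fit's
#'   covariate levels with zero offsets.
#' @return An object of class `soarhmm_fit`: `params` ([hmm_params()]),
#'   `loglik`, `aic`, `n_par`, `n_obs`, `restarts` (per-restart tibble),
#'   `n_stable`, `feature_set`, `covariate`, `data_hash`.
#' @examples
#' \donttest{
#' p <- hmm_params(shape = matrix(c(2, 2), 2), scale = matrix(c(1, 6), 2),
#'                 tpm = matrix(c(.9, .1, .1, .9), 2, 2))
#' ft <- simulate_hmm_features(p, 300, seed = 1)
#' fit <- fit_hmm(ft, feature_set = "feature1", n_states = 2,
#'                n_restarts = 5, seed = 1)
#' glance(fit)
#' }
#' @export
fit_hmm <- function(features, feature_set = c("hf", "p5", "sh"),
                    n_states = 3, covariate = NULL, n_restarts = 25,
                    seed = 1, feature_floor = 1e-6, max_missing_run = 10,
                    maxit = 500, init = NULL) {
  cd <- build_chain_data(features, feature_set, covariate,
                         feature_floor = feature_floor,
                         max_missing_run = max_missing_run)
  S <- as.integer(n_states)
  FF <- length(feature_set)
  L <- length(cd$cov_levels)
  state_names <- paste0("state", seq_len(S))

  nll <- function(par) nll_fast(par, cd, S, FF, L)
  n_par <- n_free_params(S, FF, L)
  lower <- c(rep(log(0.05), S * FF), rep(-18, S * FF),
             rep(-25, S * (S - 1) * L), rep(-30, max(S - 1, 0)))
  upper <- c(rep(log(600), S * FF), rep(6, S * FF),
             rep(25, S * (S - 1) * L), rep(30, max(S - 1, 0)))

  em_par <- function(em) {
    beta <- gammas_to_beta(em$gammas, S, L)
    par0 <- c(log(pmin(pmax(as.numeric(em$shape), exp(lower[1])),
                       exp(upper[1]))),
              log(as.numeric(em$scale)), as.numeric(beta),
              if (S > 1) log(pmax(em$delta[-1], 1e-12) /
                               max(em$delta[1], 1e-12)))
    pmin(pmax(par0, lower + 1e-9), upper - 1e-9)
  }

  starts <- lapply(seq_len(n_restarts), function(r) {
    set.seed((as.integer(seed) - 1L) * 1009L + r)
    draw_start(cd$obs, S, FF, L)
  })
  if (!is.null(init)) {
    if (inherits(init, "soarhmm_fit")) init <- init$params
    stopifnot(inherits(init, "soarhmm_params"),
              init$n_states == S, length(init$features) == FF)
    beta0 <- matrix(0, L, S * (S - 1))
    beta0[seq_len(nrow(init$beta)), ] <- init$beta
    starts <- c(starts, list(list(shape = init$shape, scale = init$scale,
                                  beta = beta0, delta = init$delta)))
  }
  restarts <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    em <- em_run(cd, S, FF, L, starts[[r]], maxiter = maxit)
    restarts[[r]] <- if (!is.finite(em$loglik)) {
      list(loglik = -Inf, converged = FALSE, par = NULL)
    } else {
      list(loglik = em$loglik, converged = em$converged, par = em_par(em))
    }
  }
  lls <- vapply(restarts, `[[`, numeric(1), "loglik")
  conv <- vapply(restarts, `[[`, logical(1), "converged")
  if (all(!is.finite(lls))) {
    stop("all restarts failed; per-restart log-likelihoods: ",
         paste(round(lls, 2), collapse = ", "), call. = FALSE)
  }
  cand <- if (any(conv & is.finite(lls))) which(conv) else which(is.finite(lls))
  best <- cand[which.max(lls[cand])]
  # quasi-Newton polish of the winning restart
  par_best <- restarts[[best]]$par
  fit <- tryCatch(
    optim(par_best, nll, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 150, factr = 1e7)),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e11) {
    fit <- tryCatch(
      optim(par_best, nll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
  }
  if (!is.null(fit) && is.finite(fit$value) && -fit$value > lls[best]) {
    par_best <- fit$par
  }
  params <- unpack_params(par_best, S, FF, L, feature_set,
                          cd$cov_levels, state_names)
  ll <- -nll(par_best)
  lls[best] <- ll
  structure(
    list(
      params = params, loglik = ll,
      aic = -2 * ll + 2 * n_par, n_par = n_par, n_obs = cd$n_obs,
      restarts = tibble::tibble(restart = seq_along(lls), loglik = lls,
                                converged = conv),
      n_stable = sum(is.finite(lls) & abs(lls - ll) < 1e-3),
      feature_set = feature_set, covariate = covariate,
      cov_levels = cd$cov_levels, seed = seed,
      data_hash = data_hash(cd$obs)
    ),
    class = "soarhmm_fit"
  )
}

data_hash <- function(obs) {
  paste(nrow(obs), ncol(obs),
        format(sum(obs, na.rm = TRUE), digits = 15),
        format(sum(obs^2, na.rm = TRUE), digits = 15), sep = "|")
}

#' Compare two fits by AIC
#'
#' @param fit_a,fit_b [fit_hmm()] results fitted to the same observations
#'   and feature set (checked by a data fingerprint).
#' @return List with `preferred` (`"fit_a"` or `"fit_b"`), `delta_aic`
#'   (`AIC_a - AIC_b`), and both AIC values.
#' @export
compare_aic <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "soarhmm_fit"), inherits(fit_b, "soarhmm_fit"))
  if (!identical(fit_a$data_hash, fit_b$data_hash)) {
    stop("fits are not on the same data (fingerprint mismatch)",
         call. = FALSE)
  }
  d <- fit_a$aic - fit_b$aic
  list(preferred = if (d <= 0) "fit_a" else "fit_b", delta_aic = d,
       aic_a = fit_a$aic, aic_b = fit_b$aic)
}

#' Viterbi decoding of the most likely state sequence
#'
#' Log-space dynamic program returning the single most probable state path
#' per chain segment; ties break toward the lower state index. Missing
#' windows inside a segment are decoded through the transition structure;
#' windows excluded by long missing runs come back as `NA`.
#'
#' @inheritParams forward_loglik
#' @param params an [hmm_params()] object or a [fit_hmm()] result.
#' @return Tibble: `individual_id`, `window_index`, `state_index`, `state`.
#' @export
viterbi_decode <- function(features, params, covariate = NULL,
                           feature_floor = 1e-6, max_missing_run = 10) {
  if (inherits(params, "soarhmm_fit")) {
    covariate <- covariate %||% params$covariate
    params <- params$params
  }
  cd <- build_chain_data(features, params$features, covariate,
                         cov_levels = if (length(params$cov_levels) > 1 ||
                                          params$cov_levels[1] != "all")
                           params$cov_levels,
                         feature_floor = feature_floor,
                         max_missing_run = max_missing_run)
  le <- hmm_log_emissions_cpp(cd$obs, params$shape, params$scale)
  logdelta <- log(params$delta)
  states <- integer(nrow(cd$obs))
  for (g in seq_along(cd$seg_start)) {
    rows <- cd$seg_start[g]:cd$seg_end[g]
    lg <- log(transition_matrix(params, cd$cov_levels[cd$seg_cov[g]]))
    states[rows] <- hmm_viterbi_cpp(le[rows, , drop = FALSE], logdelta, lg)
  }
  out <- cd$features[c("individual_id", "window_index")]
  out$state_index <- NA_integer_
  out$state_index[cd$kept] <- states
  out$state <- params$state_names[out$state_index]
  tibble::as_tibble(out)
}

#' Resolve state labels to behaviors
#'
#' HMM states come out in arbitrary order (label switching); this maps them
#' to behavior names by the fitted feature means: the state with the largest
#' Weibull mean of `hf` is flapping; among the rest the larger mean of `sh`
#' (or of `p5` when `sh` was not modeled) is soaring; the remainder is
#' on-water. Exact ties resolve toward the lower state index with a message.
#'
#' @param fit a 3-state [fit_hmm()] result including `hf`.
#' @return The fit with `params$state_names` replaced by
#'   `c("flap", "soar", "water")` in the resolved order; the permutation is
#'   attached as `fit$state_map`.
#' @export
label_states <- function(fit) {
  stopifnot(inherits(fit, "soarhmm_fit"))
  p <- fit$params
  if (p$n_states != 3 || !"hf" %in% p$features) {
    stop("state labeling needs a 3-state fit including 'hf'", call. = FALSE)
  }
  wmean <- p$scale * gamma(1 + 1 / p$shape)
  colnames(wmean) <- p$features
  hfm <- wmean[, "hf"]
  if (anyDuplicated(hfm)) message("tied hf means; breaking toward lower index")
  flap <- which.max(hfm)
  rest <- setdiff(1:3, flap)
  sec <- if ("sh" %in% p$features) "sh" else {
    message("'sh' absent; falling back to p5 ordering for soar/water")
    "p5"
  }
  soar <- rest[which.max(wmean[rest, sec])]
  water <- setdiff(rest, soar)
  labels <- character(3)
  labels[c(flap, soar, water)] <- c("flap", "soar", "water")
  fit$params$state_names <- labels
  fit$state_map <- setNames(labels, paste0("state", 1:3))
  fit
}

#' Forecast pseudo-residuals
#'
#' Ordinary (one-step-ahead) pseudo-residuals per feature: each observation
#' is pushed through its model-implied conditional CDF given the past,
#' `u_t = sum_i P(S_t = i | x_1..t-1) F_i(x_t)`, then through the standard
#' normal quantile. Under a correctly specified model the residuals are
#' standard normal; departures flag misfit. Missing windows give missing
#' residuals.
#'
#' @inheritParams viterbi_decode
#' @return Tibble with `individual_id`, `window_index`, and one residual
#'   column per feature (named `resid_<feature>`).
#' @export
pseudo_residuals <- function(features, params, covariate = NULL,
                             feature_floor = 1e-6, max_missing_run = 10) {
  if (inherits(params, "soarhmm_fit")) {
    covariate <- covariate %||% params$covariate
    params <- params$params
  }
  cd <- build_chain_data(features, params$features, covariate,
                         cov_levels = if (length(params$cov_levels) > 1 ||
                                          params$cov_levels[1] != "all")
                           params$cov_levels,
                         feature_floor = feature_floor,
                         max_missing_run = max_missing_run)
  le <- hmm_log_emissions_cpp(cd$obs, params$shape, params$scale)
  res <- matrix(NA_real_, nrow(cd$obs), length(params$features))
  for (g in seq_along(cd$seg_start)) {
    rows <- cd$seg_start[g]:cd$seg_end[g]
    gam <- transition_matrix(params, cd$cov_levels[cd$seg_cov[g]])
    pred <- hmm_forward_pred_cpp(le[rows, , drop = FALSE], params$delta, gam)
    for (f in seq_along(params$features)) {
      x <- cd$obs[rows, f]
      cdf <- sapply(seq_len(params$n_states), function(s) {
        pweibull(x, params$shape[s, f], params$scale[s, f])
      })
      cdf <- matrix(cdf, length(rows), params$n_states)
      res[rows, f] <- qnorm(rowSums(pred * cdf))
    }
  }
  out <- cd$features[c("individual_id", "window_index")]
  for (f in seq_along(params$features)) {
    out[[paste0("resid_", params$features[f])]] <- {
      v <- rep(NA_real_, nrow(out)); v[cd$kept] <- res[, f]; v
    }
  }
  tibble::as_tibble(out)
}
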
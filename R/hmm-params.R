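#' Weibull-emission HMM parameters
#'
#' Container for an N-state hidden Markov model with conditionally
#' independent per-feature Weibull state distributions and multinomial-logit
#' transition probabilities, optionally modulated by a categorical covariate
#' (one coefficient set per non-reference level, acting additively on the
#' logit scale; the diagonal is the reference category, `eta_ii = 0`).
#'
#' @param shape,scale `n_states x n_features` matrices of strictly positive
#'   Weibull parameters; `colnames(shape)` names the features.
#' @param tpm a row-stochastic transition matrix, or a named list of one per
#'   covariate level; converted to logit coefficients by the link inversion
#'   `beta0_ij = log(gamma_ij / gamma_ii)`. Ignored when `beta` is given.
#' @param beta coefficient matrix, `n_levels x n_states*(n_states-1)`,
#'   off-diagonal pairs in row-major order (columns named `"i>j"`); row 1 is
#'   the intercept (reference level), further rows are level offsets.
#' @param delta initial state distribution (defaults to uniform).
#' @param cov_levels character vector of covariate levels; first is the
#'   reference.
#' @param state_names optional state labels.
#' @return An object of class `soarhmm_params`.
#' @examples
#' p <- hmm_params(
#'   shape = matrix(c(2, 3), 2, 1), scale = matrix(c(1, 5), 2, 1),
#'   tpm = matrix(c(.9, .1, .2, .8), 2, 2, byrow = TRUE)
#' )
#' transition_matrix(p)
#' @export
hmm_params <- function(shape, scale, tpm = NULL, beta = NULL, delta = NULL,
                       cov_levels = "all", state_names = NULL,
                       features = NULL) {
  shape <- as.matrix(shape); scale <- as.matrix(scale)
  stopifnot(all(dim(shape) == dim(scale)), all(shape > 0), all(scale > 0))
  S <- nrow(shape)
  stopifnot(S >= 1)
  features <- features %||% colnames(shape) %||%
    paste0("feature", seq_len(ncol(shape)))
  state_names <- state_names %||%
    (if (!is.null(tpm) && is.matrix(tpm) && !is.null(rownames(tpm)))
      rownames(tpm) else paste0("state", seq_len(S)))
  L <- length(cov_levels)
  if (is.null(beta)) {
    if (S == 1) {
      beta <- matrix(0, L, 0)
    } else if (is.null(tpm)) {
      beta <- matrix(0, L, S * (S - 1))
    } else {
      tpml <- if (is.matrix(tpm)) setNames(rep(list(tpm), L), cov_levels) else tpm
      beta <- t(vapply(cov_levels, function(lv) tpm_to_eta(tpml[[lv]]),
                       numeric(S * (S - 1))))
      if (L > 1) beta[-1, ] <- sweep(beta[-1, , drop = FALSE], 2, beta[1, ])
      beta <- matrix(beta, L, S * (S - 1))
    }
  }
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == L, ncol(beta) == S * (S - 1))
  colnames(beta) <- pair_names(S)
  delta <- delta %||% rep(1 / S, S)
  stopifnot(length(delta) == S, abs(sum(delta) - 1) < 1e-9)
  structure(
    list(n_states = S, features = features, shape = shape, scale = scale,
         beta = beta, cov_levels = cov_levels, delta = delta,
         state_names = state_names),
    class = "soarhmm_params"
  )
}

pair_names <- function(S) {
  if (S < 2) return(character())
  p <- expand.grid(j = seq_len(S), i = seq_len(S))[, 2:1]
  p <- p[p$i != p$j, ]
  p <- p[order(p$i, p$j), ]
  paste0(p$i, ">", p$j)
}

# Invert the multinomial-logit link for a single row-stochastic matrix.
tpm_to_eta <- function(tpm) {
  check_tpm(tpm, tol = 1e-9)
  S <- nrow(tpm)
  eta <- log(tpm / diag(tpm))
  as.numeric(t(eta))[as.logical(t(diag(S) == 0))]
}

#' Transition probability matrix at a covariate level
#'
#' Builds the row-stochastic matrix from the multinomial-logit coefficients:
#' `gamma_ij = exp(eta_ij) / sum_j exp(eta_ij)` with `eta_ii = 0` and
#' `eta_ij = beta0_ij + beta_level_ij`.
#'
#' @param params an [hmm_params()] object (or a fitted model).
#' @param level covariate level (default: the reference level).
#' @return `n_states x n_states` row-stochastic matrix.
#' @export
transition_matrix <- function(params, level = NULL) {
  if (inherits(params, "soarhmm_fit")) params <- params$params
  stopifnot(inherits(params, "soarhmm_params"))
  S <- params$n_states
  if (S == 1) return(matrix(1, 1, 1))
  level <- level %||% params$cov_levels[1]
  li <- match(level, params$cov_levels)
  if (is.na(li)) {
    stop("unknown covariate level: ", level, call. = FALSE)
  }
  eta_off <- params$beta[1, ]
  if (li > 1) eta_off <- eta_off + params$beta[li, ]
  eta <- matrix(0, S, S)
  eta[t(diag(S) == 0)] <- eta_off # fill by row
  eta <- t(eta)
  g <- exp(eta)
  g <- g / rowSums(g)
  dimnames(g) <- list(params$state_names, params$state_names)
  g
}

#' @export
print.soarhmm_params <- function(x, ...) {
  cat(sprintf("<soarhmm HMM parameters: %d states, %d features (%s)>\n",
              x$n_states, length(x$features),
              paste(x$features, collapse = ", ")))
  cat("shape:\n"); print(round(x$shape, 4))
  cat("scale:\n"); print(round(x$scale, 4))
  cat("Gamma (", x$cov_levels[1], "):\n", sep = "")
  print(round(transition_matrix(x), 4))
  invisible(x)
}

#' Weibull log-density
#'
#' Thin validated wrapper around the Weibull density on the log scale; the
#' state-dependent distribution of every feature. Observations must be
#' strictly positive (callers floor features before fitting).
#'
#' @param x positive observation(s).
#' @param shape,scale positive Weibull parameters.
#' @return Log-density values.
#' @examples
#' weibull_logpdf(1, 1, 1) # exponential(1) at 1: -1
#' @export
weibull_logpdf <- function(x, shape, scale) {
  if (any(x <= 0)) stop("x must be > 0; floor features first", call. = FALSE)
  if (any(shape <= 0) || any(scale <= 0)) {
    stop("shape and scale must be > 0", call. = FALSE)
  }
  dweibull(x, shape = shape, scale = scale, log = TRUE)
}

#' Per-window per-state emission factors
#'
#' Entry (t, i) is the product over included features of the Weibull density
#' under state i. Missing windows contribute a factor of 1 in every state,
#' so parameters are informed by non-missing observations only while the
#' transition structure still spans the gap.
#'
#' @param obs numeric matrix (windows x features); rows with any `NA` are
#'   treated as missing. Non-missing rows must be strictly positive and
#'   NaN-free.
#' @param params an [hmm_params()] object.
#' @param log return log factors (default FALSE).
#' @return Matrix of emission factors (windows x states).
#' @export
emission_matrix <- function(obs, params, log = FALSE) {
  obs <- as.matrix(obs)
  stopifnot(ncol(obs) == length(params$features))
  bad <- which(apply(obs, 1, function(r) any(is.nan(r))))
  if (length(bad)) {
    stop("NaN in non-missing observation row ", bad[1], call. = FALSE)
  }
  le <- hmm_log_emissions_cpp(obs, params$shape, params$scale)
  if (log) le else exp(le)
}
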
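#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weibull log-density; callers guarantee x, k, lam > 0.
static inline double dweib_log(double x, double k, double lam) {
  double z = x / lam;
  return std::log(k / lam) + (k - 1.0) * std::log(z) - std::pow(z, k);
}

// Per-window per-state log emission factors. obs is T x F; a row with any NA
// is a missing window and contributes log-factor 0 for every state (the
// window is skipped by the emission part of the likelihood). shape and scale
// are S x F.
// [[Rcpp::export]]
NumericMatrix hmm_log_emissions_cpp(NumericMatrix obs, NumericMatrix shape,
                                    NumericMatrix scale) {
  int T = obs.nrow(), F = obs.ncol(), S = shape.nrow();
  NumericMatrix le(T, S);
  for (int t = 0; t < T; ++t) {
    bool miss = false;
    for (int f = 0; f < F; ++f)
      if (NumericMatrix::is_na(obs(t, f))) { miss = true; break; }
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      if (!miss)
        for (int f = 0; f < F; ++f)
          acc += dweib_log(obs(t, f), shape(s, f), scale(s, f));
      le(t, s) = acc;
    }
  }
  return le;
}

// Scaled forward pass over independent segments (individuals, or pieces of an
// individual split at long missing runs). seg_start/seg_end are 1-based row
// ranges into logemis; seg_cov is the 1-based covariate level per segment
// selecting a slice of gammas (an S x S x L array, column-major, with
// gammas[i + S*j + S*S*l] = P(i -> j | level l+1)). Returns the total
// log-likelihood. Scaling keeps chains of 1e5+ windows finite.
// [[Rcpp::export]]
double hmm_forward_loglik_cpp(NumericMatrix logemis, IntegerVector seg_start,
                              IntegerVector seg_end, IntegerVector seg_cov,
                              NumericVector delta, NumericVector gammas) {
  int S = logemis.ncol();
  int nseg = seg_start.size();
  double ll = 0.0;
  std::vector<double> alpha(S), tmp(S);
  for (int g = 0; g < nseg; ++g) {
    int a = seg_start[g] - 1, b = seg_end[g] - 1;
    std::size_t off = (std::size_t)(seg_cov[g] - 1) * S * S;
    double m = logemis(a, 0);
    for (int s = 1; s < S; ++s) m = std::max(m, logemis(a, s));
    double c = 0.0;
    for (int s = 0; s < S; ++s) {
      alpha[s] = delta[s] * std::exp(logemis(a, s) - m);
      c += alpha[s];
    }
    if (!(c > 0.0) || !std::isfinite(c)) return R_NegInf;
    ll += m + std::log(c);
    for (int s = 0; s < S; ++s) alpha[s] /= c;
    for (int t = a + 1; t <= b; ++t) {
      m = logemis(t, 0);
      for (int s = 1; s < S; ++s) m = std::max(m, logemis(t, s));
      c = 0.0;
      for (int j = 0; j < S; ++j) {
        double sum = 0.0;
        for (int i = 0; i < S; ++i) sum += alpha[i] * gammas[off + i + S * j];
        tmp[j] = sum * std::exp(logemis(t, j) - m);
        c += tmp[j];
      }
      if (!(c > 0.0) || !std::isfinite(c)) return R_NegInf;
      ll += m + std::log(c);
      for (int j = 0; j < S; ++j) alpha[j] = tmp[j] / c;
    }
  }
  return ll;
}

// One-step-ahead (forecast) state probabilities P(S_t = i | x_1..t-1) for a
// single segment; row t=1 is delta. Used for forecast pseudo-residuals.
// [[Rcpp::export]]
NumericMatrix hmm_forward_pred_cpp(NumericMatrix logemis, NumericVector delta,
                                   NumericMatrix gamma) {
  int T = logemis.nrow(), S = logemis.ncol();
  NumericMatrix pred(T, S);
  std::vector<double> alpha(S), tmp(S);
  for (int s = 0; s < S; ++s) pred(0, s) = delta[s];
  double m = logemis(0, 0);
  for (int s = 1; s < S; ++s) m = std::max(m, logemis(0, s));
  double c = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha[s] = delta[s] * std::exp(logemis(0, s) - m);
    c += alpha[s];
  }
  for (int s = 0; s < S; ++s) alpha[s] /= c;
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < S; ++j) {
      double sum = 0.0;
      for (int i = 0; i < S; ++i) sum += alpha[i] * gamma(i, j);
      pred(t, j) = sum;
    }
    m = logemis(t, 0);
    for (int s = 1; s < S; ++s) m = std::max(m, logemis(t, s));
    for (int j = 0; j < S; ++j) {
      tmp[j] = pred(t, j) * std::exp(logemis(t, j) - m);
      c += tmp[j];
    }
    for (int j = 0; j < S; ++j) alpha[j] = tmp[j] / c;
  }
  return pred;
}

// Forward-backward (Baum-Welch E-step) over independent segments with
// per-step scaling. Returns the total log-likelihood, the smoothed state
// probabilities u (T x S), the expected transition counts accumulated per
// covariate level (S*S*L, same layout as `gammas`), and the sum over
// segments of the time-1 posteriors (numerator of the delta update).
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericMatrix logemis, IntegerVector seg_start,
                              IntegerVector seg_end, IntegerVector seg_cov,
                              NumericVector delta, NumericVector gammas,
                              int n_levels) {
  int S = logemis.ncol(), T = logemis.nrow();
  int nseg = seg_start.size();
  NumericMatrix u(T, S);
  NumericVector xi((std::size_t)S * S * n_levels);
  NumericVector delta_num(S);
  double ll = 0.0;
  for (int g = 0; g < nseg; ++g) {
    int a = seg_start[g] - 1, b = seg_end[g] - 1;
    int Tg = b - a + 1;
    std::size_t off = (std::size_t)(seg_cov[g] - 1) * S * S;
    std::vector<double> ehat((std::size_t)Tg * S);
    std::vector<double> alpha((std::size_t)Tg * S);
    std::vector<double> cvec(Tg);
    for (int t = 0; t < Tg; ++t) {
      double m = logemis(a + t, 0);
      for (int s = 1; s < S; ++s) m = std::max(m, logemis(a + t, s));
      for (int s = 0; s < S; ++s)
        ehat[(std::size_t)t * S + s] = std::exp(logemis(a + t, s) - m);
      ll += m; // emission max-shift enters the log-likelihood directly
    }
    // scaled forward
    double c = 0.0;
    for (int s = 0; s < S; ++s) {
      alpha[s] = delta[s] * ehat[s];
      c += alpha[s];
    }
    if (!(c > 0.0)) return List::create(_["loglik"] = R_NegInf);
    cvec[0] = c;
    for (int s = 0; s < S; ++s) alpha[s] /= c;
    ll += std::log(c);
    for (int t = 1; t < Tg; ++t) {
      c = 0.0;
      for (int j = 0; j < S; ++j) {
        double sum = 0.0;
        for (int i = 0; i < S; ++i)
          sum += alpha[(std::size_t)(t - 1) * S + i] * gammas[off + i + S * j];
        double v = sum * ehat[(std::size_t)t * S + j];
        alpha[(std::size_t)t * S + j] = v;
        c += v;
      }
      if (!(c > 0.0)) return List::create(_["loglik"] = R_NegInf);
      cvec[t] = c;
      for (int j = 0; j < S; ++j) alpha[(std::size_t)t * S + j] /= c;
      ll += std::log(c);
    }
    // scaled backward, posteriors, pair counts
    std::vector<double> beta(S, 1.0), bnext(S);
    for (int s = 0; s < S; ++s)
      u(b, s) = alpha[(std::size_t)(Tg - 1) * S + s];
    for (int t = Tg - 2; t >= 0; --t) {
      for (int i = 0; i < S; ++i) {
        double sum = 0.0;
        for (int j = 0; j < S; ++j)
          sum += gammas[off + i + S * j] * ehat[(std::size_t)(t + 1) * S + j] *
                 beta[j];
        bnext[i] = sum / cvec[t + 1];
      }
      for (int i = 0; i < S; ++i) {
        for (int j = 0; j < S; ++j) {
          xi[off + i + S * j] += alpha[(std::size_t)t * S + i] *
            gammas[off + i + S * j] * ehat[(std::size_t)(t + 1) * S + j] *
            beta[j] / cvec[t + 1];
        }
      }
      beta = bnext;
      double norm = 0.0;
      for (int s = 0; s < S; ++s) {
        u(a + t, s) = alpha[(std::size_t)t * S + s] * beta[s];
        norm += u(a + t, s);
      }
      for (int s = 0; s < S; ++s) u(a + t, s) /= norm;
    }
    for (int s = 0; s < S; ++s) delta_num[s] += u(a, s);
  }
  return List::create(_["loglik"] = ll, _["u"] = u, _["xi"] = xi,
                      _["delta_num"] = delta_num);
}

// Log-space Viterbi for one segment; ties broken toward the lower state
// index (strict inequality when scanning candidates in ascending order).
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logemis, NumericVector logdelta,
                              NumericMatrix loggamma) {
  int T = logemis.nrow(), S = logemis.ncol();
  NumericMatrix v(T, S);
  IntegerMatrix bp(T, S);
  for (int s = 0; s < S; ++s) v(0, s) = logdelta[s] + logemis(0, s);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < S; ++j) {
      double best = v(t - 1, 0) + loggamma(0, j);
      int arg = 0;
      for (int i = 1; i < S; ++i) {
        double cand = v(t - 1, i) + loggamma(i, j);
        if (cand > best) { best = cand; arg = i; }
      }
      v(t, j) = best + logemis(t, j);
      bp(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = v(T - 1, 0);
  int arg = 0;
  for (int s = 1; s < S; ++s)
    if (v(T - 1, s) > best) { best = v(T - 1, s); arg = s; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = bp(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
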
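#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit-duration (semi-Markov) recursions for left-to-right chains with
// categorical emissions, an absorbing non-emitting end state and complete
// final zones.  All probability inputs arrive as logs with log(0) encoded as
// a large negative finite number (BIG_NEG) so that differences of cumulative
// emission sums never produce NaN.

static const double BIG_NEG = -1e100;

static inline double lse(const std::vector<double>& v) {
  double m = BIG_NEG;
  for (double x : v) if (x > m) m = x;
  if (m <= BIG_NEG) return BIG_NEG;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// Cumulative per-state emission log-probabilities, split into the finite
// part and a count of zero-probability (masked) positions so that window
// sums never lose an impossibility to floating-point absorption:
// ce_fin(j, t) = sum of finite log b_j(y_s) over s <= t, ce_zero(j, t) =
// number of masked positions among s <= t.  A window's emission log-sum is
// finite iff its masked-position count is zero.
struct EmisCum {
  NumericMatrix fin;
  IntegerMatrix zero;
  double operator()(int j, int a, int b) const {  // positions a+1 .. b
    if (zero(j, b) - zero(j, a) > 0) return BIG_NEG;
    return fin(j, b) - fin(j, a);
  }
};

static EmisCum emis_cumsum(const IntegerVector& obs,
                           const NumericMatrix& log_emis) {
  int T = obs.size(), K = log_emis.nrow();
  EmisCum ce{NumericMatrix(K, T + 1), IntegerMatrix(K, T + 1)};
  for (int j = 0; j < K; ++j) {
    ce.fin(j, 0) = 0.0;
    ce.zero(j, 0) = 0;
    for (int t = 0; t < T; ++t) {
      double le = log_emis(j, obs[t]);
      bool masked = le <= BIG_NEG / 2;
      ce.fin(j, t + 1) = ce.fin(j, t) + (masked ? 0.0 : le);
      ce.zero(j, t + 1) = ce.zero(j, t) + (masked ? 1 : 0);
    }
  }
  return ce;
}

// Forward pass.  alpha(t, j) = log P(y_1..t, zone of state j ends at t).
// inflow(t, j) = log P(y_1..t, some zone ends at t, next state is j), t>=1.
// Returns loglik = log P(y_1..T, termination at T).
static double forward_pass(const IntegerVector& obs,
                           const NumericVector& log_init,
                           const NumericMatrix& log_trans,
                           const NumericMatrix& log_dur,
                           const EmisCum& ce,
                           NumericMatrix& alpha,
                           NumericMatrix& inflow) {
  int T = obs.size(), K = log_init.size();
  std::vector<double> acc;
  for (int t = 1; t <= T; ++t) {
    for (int j = 0; j < K; ++j) {
      acc.clear();
      int umax = std::min(t, log_dur.ncol());
      for (int u = 1; u <= umax; ++u) {
        double e = ce(j, t - u, t);
        double entry = (u == t) ? log_init[j]
                                : ((t - u >= 1) ? inflow(t - u, j) : BIG_NEG);
        double v = log_dur(j, u - 1) + e + entry;
        if (v > BIG_NEG) acc.push_back(v);
      }
      alpha(t, j) = acc.empty() ? BIG_NEG : lse(acc);
    }
    if (t < T) {
      for (int j = 0; j < K; ++j) {
        acc.clear();
        for (int i = 0; i < j; ++i) {
          double v = alpha(t, i) + log_trans(i, j);
          if (v > BIG_NEG) acc.push_back(v);
        }
        inflow(t, j) = acc.empty() ? BIG_NEG : lse(acc);
      }
    }
  }
  std::vector<double> fin;
  for (int j = 0; j < K; ++j) {
    double v = alpha(T, j) + log_trans(j, K);
    if (v > BIG_NEG) fin.push_back(v);
  }
  return fin.empty() ? BIG_NEG : lse(fin);
}

// [[Rcpp::export(name = ".hsmm_forward_cpp")]]
double hsmm_forward_cpp(IntegerVector obs, NumericVector log_init,
                        NumericMatrix log_trans, NumericMatrix log_dur,
                        NumericMatrix log_emis) {
  int T = obs.size(), K = log_init.size();
  EmisCum ce = emis_cumsum(obs, log_emis);
  NumericMatrix alpha(T + 1, K), inflow(T + 1, K);
  std::fill(alpha.begin(), alpha.end(), BIG_NEG);
  std::fill(inflow.begin(), inflow.end(), BIG_NEG);
  return forward_pass(obs, log_init, log_trans, log_dur, ce, alpha, inflow);
}

// E-step accumulators for one sequence.  Returns loglik plus expected counts:
// init (K), trans (K x K+1), dur (K x T), emis (K x n_symbols).
// [[Rcpp::export(name = ".hsmm_estep_cpp")]]
List hsmm_estep_cpp(IntegerVector obs, NumericVector log_init,
                    NumericMatrix log_trans, NumericMatrix log_dur,
                    NumericMatrix log_emis) {
  int T = obs.size(), K = log_init.size(), M = log_emis.ncol();
  EmisCum ce = emis_cumsum(obs, log_emis);
  NumericMatrix alpha(T + 1, K), inflow(T + 1, K);
  std::fill(alpha.begin(), alpha.end(), BIG_NEG);
  std::fill(inflow.begin(), inflow.end(), BIG_NEG);
  double L = forward_pass(obs, log_init, log_trans, log_dur, ce, alpha, inflow);

  NumericVector c_init(K);
  NumericMatrix c_trans(K, K + 1), c_dur(K, T), c_emis(K, M);
  if (L <= BIG_NEG / 2) {
    return List::create(_["loglik"] = R_NegInf, _["init"] = c_init,
                        _["trans"] = c_trans, _["dur"] = c_dur,
                        _["emis"] = c_emis);
  }

  // beta(t, j): log P(y_{t+1..T}, termination | zone of j ends at t)
  // inb(t, j):  log P(y_{t+1..T}, termination | zone of j starts at t+1)
  NumericMatrix beta(T + 1, K), inb(T + 1, K);
  std::fill(beta.begin(), beta.end(), BIG_NEG);
  std::fill(inb.begin(), inb.end(), BIG_NEG);
  std::vector<double> acc;
  for (int j = 0; j < K; ++j) beta(T, j) = log_trans(j, K);
  for (int t = T - 1; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      acc.clear();
      int umax = std::min(T - t, log_dur.ncol());
      for (int u = 1; u <= umax; ++u) {
        double v = log_dur(k, u - 1) + ce(k, t, t + u) + beta(t + u, k);
        if (v > BIG_NEG) acc.push_back(v);
      }
      inb(t, k) = acc.empty() ? BIG_NEG : lse(acc);
    }
    for (int j = 0; j < K; ++j) {
      acc.clear();
      for (int k = j + 1; k < K; ++k) {
        double v = log_trans(j, k) + inb(t, k);
        if (v > BIG_NEG) acc.push_back(v);
      }
      beta(t, j) = acc.empty() ? BIG_NEG : lse(acc);
    }
  }

  // initial counts: entry into j at position 1
  for (int j = 0; j < K; ++j) {
    double v = log_init[j] + inb(0, j) - L;
    if (v > BIG_NEG) c_init[j] += std::exp(v);
  }
  // transition counts between transient states, and into the end state
  for (int t = 1; t <= T - 1; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = i + 1; j < K; ++j) {
        double v = alpha(t, i) + log_trans(i, j) + inb(t, j) - L;
        if (v > BIG_NEG) c_trans(i, j) += std::exp(v);
      }
  for (int i = 0; i < K; ++i) {
    double v = alpha(T, i) + log_trans(i, K) - L;
    if (v > BIG_NEG) c_trans(i, K) += std::exp(v);
  }
  // segment posteriors -> duration and emission counts
  for (int t = 0; t <= T - 1; ++t)
    for (int j = 0; j < K; ++j) {
      double entry = (t == 0) ? log_init[j] : inflow(t, j);
      if (entry <= BIG_NEG) continue;
      int umax = std::min(T - t, log_dur.ncol());
      for (int u = 1; u <= umax; ++u) {
        double v = entry + log_dur(j, u - 1) + ce(j, t, t + u) +
                   beta(t + u, j) - L;
        if (v <= -700.0) continue;
        double p = std::exp(v);
        c_dur(j, u - 1) += p;
        for (int s = t; s < t + u; ++s) c_emis(j, obs[s]) += p;
      }
    }

  return List::create(_["loglik"] = L, _["init"] = c_init,
                      _["trans"] = c_trans, _["dur"] = c_dur,
                      _["emis"] = c_emis);
}

// Explicit-duration Viterbi.  Ties are broken deterministically: candidates
// are scanned with states and durations ascending and replaced only on a
// strict improvement, so the lowest state index (and then the shorter
// duration) wins.  Returns 1-based state per node and the log joint.
// [[Rcpp::export(name = ".hsmm_viterbi_cpp")]]
List hsmm_viterbi_cpp(IntegerVector obs, NumericVector log_init,
                      NumericMatrix log_trans, NumericMatrix log_dur,
                      NumericMatrix log_emis) {
  int T = obs.size(), K = log_init.size();
  EmisCum ce = emis_cumsum(obs, log_emis);
  NumericMatrix delta(T + 1, K);
  IntegerMatrix back_u(T + 1, K), back_i(T + 1, K);
  std::fill(delta.begin(), delta.end(), BIG_NEG);

  // best_in(t, j): max over i<j of delta(t, i) + log_trans(i, j)
  NumericMatrix best_in(T + 1, K);
  IntegerMatrix best_in_arg(T + 1, K);
  std::fill(best_in.begin(), best_in.end(), BIG_NEG);

  for (int t = 1; t <= T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = BIG_NEG;
      int bu = -1, bi = -1;
      int umax = std::min(t, log_dur.ncol());
      for (int u = 1; u <= umax; ++u) {
        double e = ce(j, t - u, t);
        double entry, ei = -1;
        if (u == t) {
          entry = log_init[j];
        } else if (t - u >= 1) {
          entry = best_in(t - u, j);
          ei = best_in_arg(t - u, j);
        } else {
          entry = BIG_NEG;
        }
        double v = log_dur(j, u - 1) + e + entry;
        if (v > best) { best = v; bu = u; bi = (int)ei; }
      }
      delta(t, j) = best;
      back_u(t, j) = bu;
      back_i(t, j) = bi;
    }
    if (t < T) {
      for (int j = 0; j < K; ++j) {
        double best = BIG_NEG; int arg = -1;
        for (int i = 0; i < j; ++i) {
          double v = delta(t, i) + log_trans(i, j);
          if (v > best) { best = v; arg = i; }
        }
        best_in(t, j) = best;
        best_in_arg(t, j) = arg;
      }
    }
  }

  double best = BIG_NEG; int bj = -1;
  for (int j = 0; j < K; ++j) {
    double v = delta(T, j) + log_trans(j, K);
    if (v > best) { best = v; bj = j; }
  }
  if (bj < 0 || best <= BIG_NEG / 2) {
    return List::create(_["states"] = IntegerVector(0),
                        _["log_joint"] = R_NegInf);
  }

  IntegerVector states(T);
  int t = T, j = bj;
  while (t > 0) {
    int u = back_u(t, j), i = back_i(t, j);
    for (int s = t - u; s < t; ++s) states[s] = j + 1;
    t -= u;
    j = i;
  }
  return List::create(_["states"] = states, _["log_joint"] = best);
}
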
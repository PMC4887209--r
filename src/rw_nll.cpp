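#include <Rcpp.h>
using namespace Rcpp;

// Forward-pass negative log-likelihood of a Rescorla-Wagner learner with
// Boltzmann (softmax) action selection over 3 options. Values are reset to
// init_value at every session start (session boundaries are where
// session_index changes). choices are 0-based option indices.
// [[Rcpp::export(name = ".rw_nll_cpp")]]
double rw_nll_cpp(IntegerVector choices, IntegerVector rewards,
                  IntegerVector session_index, double alpha, double beta,
                  double init_value) {
  int n = choices.size();
  if (n == 0) stop("empty trial sequence");
  double v[3];
  double nll = 0.0;
  int cur_session = session_index[0] - 1;  // force reset on first trial
  for (int t = 0; t < n; ++t) {
    if (session_index[t] != cur_session) {
      v[0] = v[1] = v[2] = init_value;
      cur_session = session_index[t];
    }
    double m = std::max(v[0], std::max(v[1], v[2]));
    double e0 = std::exp(beta * (v[0] - m));
    double e1 = std::exp(beta * (v[1] - m));
    double e2 = std::exp(beta * (v[2] - m));
    double z = e0 + e1 + e2;
    int c = choices[t];
    if (c < 0 || c > 2) stop("choice out of range at trial %d", t + 1);
    double p = (c == 0 ? e0 : (c == 1 ? e1 : e2)) / z;
    if (p <= 0.0) return R_PosInf;
    nll -= std::log(p);
    v[c] += alpha * (rewards[t] - v[c]);
  }
  return nll;
}

// Forward-simulated value traces given the actual choice/reward sequence of
// a single session. Returns a T x 3 matrix of values *before* each trial's
// update (the values the choice at trial t was based on), with row T+1
// omitted.
// [[Rcpp::export(name = ".rw_values_cpp")]]
NumericMatrix rw_values_cpp(IntegerVector choices, IntegerVector rewards,
                            double alpha, double init_value) {
  int n = choices.size();
  NumericMatrix out(n, 3);
  double v[3] = {init_value, init_value, init_value};
  for (int t = 0; t < n; ++t) {
    out(t, 0) = v[0]; out(t, 1) = v[1]; out(t, 2) = v[2];
    int c = choices[t];
    if (c < 0 || c > 2) stop("choice out of range at trial %d", t + 1);
    v[c] += alpha * (rewards[t] - v[c]);
  }
  return out;
}
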
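#include <Rcpp.h>
using namespace Rcpp;

// Replay the SR agent over a choice sequence with fixed (gamma, beta) and
// accumulate the negative log-likelihood of the observed choices over
// trials [span_start, span_end] (1-based, inclusive). choice/s2 are 0-based
// codes (0 = S1_PLUS / S2_PLUS).
// [[Rcpp::export]]
double sr_negloglik_cpp(IntegerVector choice, IntegerVector s2,
                        IntegerVector reward, double gamma, double beta,
                        double alpha_T, double alpha_R,
                        int span_start, int span_end,
                        NumericVector T_init, NumericVector R_init) {
  int n = choice.size();
  double T[2][2] = {{T_init[0], T_init[1]}, {T_init[2], T_init[3]}};
  double R[2] = {R_init[0], R_init[1]};
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double q0 = T[0][0] * R[0] + T[0][1] * R[1];
    double q1 = T[1][0] * R[0] + T[1][1] * R[1];
    if (i + 1 >= span_start && i + 1 <= span_end) {
      double z0 = beta * q0, z1 = beta * q1;
      double m = z0 > z1 ? z0 : z1;
      double lse = m + std::log(std::exp(z0 - m) + std::exp(z1 - m));
      double lp = (choice[i] == 0 ? z0 : z1) - lse;
      nll -= lp;
    }
    int c = choice[i], o = s2[i], u = 1 - o;
    T[c][o] = (1.0 - alpha_T) * T[c][o] + alpha_T * gamma;
    T[c][u] = (1.0 - alpha_T) * T[c][u];
    R[o] = (1.0 - alpha_R) * R[o] + alpha_R * gamma * (reward[i] ? 1.0 : 0.0);
  }
  return nll;
}

// Replay as above but return the pre-choice value estimates per trial:
// columns q_s1_plus, q_s1_minus, q_s2_plus, q_s2_minus.
// [[Rcpp::export]]
NumericMatrix sr_replay_values_cpp(IntegerVector choice, IntegerVector s2,
                                   IntegerVector reward, NumericVector gamma,
                                   double alpha_T, double alpha_R,
                                   NumericVector T_init, NumericVector R_init) {
  int n = choice.size();
  double T[2][2] = {{T_init[0], T_init[1]}, {T_init[2], T_init[3]}};
  double R[2] = {R_init[0], R_init[1]};
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = T[0][0] * R[0] + T[0][1] * R[1];
    out(i, 1) = T[1][0] * R[0] + T[1][1] * R[1];
    out(i, 2) = R[0];
    out(i, 3) = R[1];
    int c = choice[i], o = s2[i], u = 1 - o;
    double g = gamma[i];
    T[c][o] = (1.0 - alpha_T) * T[c][o] + alpha_T * g;
    T[c][u] = (1.0 - alpha_T) * T[c][u];
    R[o] = (1.0 - alpha_R) * R[o] + alpha_R * g * (reward[i] ? 1.0 : 0.0);
  }
  return out;
}

// Two-weight LMS canceller with a sine/cosine reference pair at f0.
// Returns the error signal (input minus the adapted interference estimate).
// [[Rcpp::export]]
NumericVector lms_notch_cpp(NumericVector x, double fs, double f0, double mu) {
  int n = x.size();
  NumericVector out(n);
  double w1 = 0.0, w2 = 0.0;
  double wstep = 2.0 * M_PI * f0 / fs;
  for (int i = 0; i < n; ++i) {
    double r1 = std::sin(wstep * i);
    double r2 = std::cos(wstep * i);
    double y = w1 * r1 + w2 * r2;
    double e = x[i] - y;
    out[i] = e;
    w1 += 2.0 * mu * e * r1;
    w2 += 2.0 * mu * e * r2;
  }
  return out;
}

// Median of non-overlapping blocks of length `factor` along a vector.
// [[Rcpp::export]]
NumericVector block_median_cpp(NumericVector x, int factor) {
  int nb = x.size() / factor;
  NumericVector out(nb);
  std::vector<double> buf(factor);
  for (int b = 0; b < nb; ++b) {
    for (int k = 0; k < factor; ++k) buf[k] = x[b * factor + k];
    std::sort(buf.begin(), buf.end());
    if (factor % 2 == 1) out[b] = buf[factor / 2];
    else out[b] = 0.5 * (buf[factor / 2 - 1] + buf[factor / 2]);
  }
  return out;
}

// Label 4-connected components of a logical matrix (0 = background).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != TRUE || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        int pi = p.first, pj = p.second;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) == TRUE && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(std::make_pair(qi, qj));
          }
        }
      }
    }
  }
  return lab;
}
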
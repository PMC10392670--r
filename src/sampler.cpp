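// Monte Carlo engine for the Gaussian-mixture rigid-base-pair model under
// an optional quadratic end-to-end-twist bias.
//
// Sampling scheme (see the methods vignette):
//  * substate labels, unbiased: exact forward-filter / backward-sample over
//    the marginal label chain (parameters integrated out), giving i.i.d.
//    frames even with nearest-neighbour label coupling.
//  * substate labels, biased multimodal: Metropolis sweeps on the
//    *collapsed* label distribution -- the bias couples only the Gaussian
//    CV marginal, so integrating the parameters out gives the closed-form
//    label weight  G(mu, V) = -1/2 log(1 + cV) - c (mu - ref)^2 / (2(1+cV))
//    with c = 2 beta k_tw and (mu, V) the label-dependent mean and variance
//    of the end-to-end twist. Collapsing removes the label/parameter
//    stickiness a naive Gibbs alternation would suffer across substates
//    separated by many standard deviations.
//  * parameters given labels: exact joint Gaussian. The bias is a rank-one
//    precision update on the in-region twists, handled by Matheron-style
//    conditioning of unbiased blockwise draws.
// All randomness comes from R's RNG, so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct StepModel {
  int K;
  arma::mat means;   // 6 x K
  arma::cube L;      // 6 x 6 x K (lower Cholesky of covariance)
  arma::mat SigTw;   // 6 x K (covariance column of the twist coordinate)
  arma::vec sTT;     // K (twist-twist covariance)
  arma::vec beps;    // K (beta * epsilon)
  arma::vec logw0;   // K (marginal label log-weights)
};

static const int TW = 5;  // 0-based index of twist in the 6-vector

// Exact marginal-chain sampling of labels (no bias): forward filter with
// node weights logw0 and pair penalty -betaJ for differing labels of
// adjacent multi-substate steps, then backward sampling.
static void sample_labels_marginal(const std::vector<StepModel>& sm,
                                   double betaJ, arma::ivec& s) {
  const int n = sm.size();
  std::vector<arma::vec> alpha(n);
  for (int i = 0; i < n; ++i) {
    const arma::vec& w = sm[i].logw0;
    if (i == 0) {
      alpha[i] = w;
    } else {
      const bool couple = betaJ != 0.0 && sm[i - 1].K > 1 && sm[i].K > 1;
      arma::vec a(sm[i].K);
      for (int k = 0; k < sm[i].K; ++k) {
        arma::vec prev = alpha[i - 1];
        if (couple)
          for (int kp = 0; kp < sm[i - 1].K; ++kp)
            if (kp != k) prev(kp) -= betaJ;
        double m = prev.max();
        a(k) = w(k) + m + std::log(arma::sum(arma::exp(prev - m)));
      }
      alpha[i] = a;
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    arma::vec lp = alpha[i];
    if (i < n - 1) {
      const bool couple = betaJ != 0.0 && sm[i].K > 1 && sm[i + 1].K > 1;
      if (couple)
        for (int k = 0; k < sm[i].K; ++k)
          if (k != s(i + 1)) lp(k) -= betaJ;
    }
    lp -= lp.max();
    arma::vec p = arma::exp(lp);
    p /= arma::sum(p);
    double u = R::unif_rand(), acc = 0.0;
    int pick = sm[i].K - 1;
    for (int k = 0; k < sm[i].K; ++k) {
      acc += p(k);
      if (u <= acc) { pick = k; break; }
    }
    s(i) = pick;
  }
}

// [[Rcpp::export]]
List sample_ensemble_cpp(List steps, double betaJ, double k_bias, double beta,
                         double ref, IntegerVector region1, int n_frames,
                         int burnin, int keep_mode, bool keep_labels,
                         NumericMatrix start_x, IntegerVector start_labels,
                         bool gibbs) {
  const int n = steps.size();
  std::vector<StepModel> sm(n);
  bool multimodal = false;
  for (int i = 0; i < n; ++i) {
    List st = steps[i];
    StepModel& m = sm[i];
    m.K = as<int>(st["K"]);
    m.means = as<arma::mat>(st["means"]);
    m.L = as<arma::cube>(st["L"]);
    m.SigTw = as<arma::mat>(st["SigTw"]);
    m.sTT = as<arma::vec>(st["sTT"]);
    m.beps = as<arma::vec>(st["beps"]);
    m.logw0 = as<arma::vec>(st["logw0"]);
    if (m.K > 1) multimodal = true;
  }
  const int R = region1.size();
  arma::uvec region(R);
  std::vector<bool> in_region(n, false);
  for (int r = 0; r < R; ++r) {
    region(r) = region1[r] - 1;
    in_region[region(r)] = true;
  }
  const bool biased = k_bias > 0.0;
  const double c_bias = 2.0 * beta * k_bias;       // CV precision added
  const double sigma2 = biased ? 1.0 / c_bias : 0.0;

  arma::vec cv(n_frames, arma::fill::zeros);
  arma::mat twists;
  if (keep_mode >= 1) twists.set_size(n_frames, R);
  arma::cube pk;
  if (keep_mode == 2) pk.set_size(n_frames, R, 6);
  else if (keep_mode >= 3) pk.set_size(n_frames, n, 6);
  IntegerMatrix labels_out(keep_labels ? n_frames : 0,
                           keep_labels ? n : 0);
  arma::vec tw_sum(n, arma::fill::zeros);
  arma::mat occ(6, n, arma::fill::zeros);  // substate occupancy (<= 6 shown)
  double mh_accept = 0.0, mh_attempt = 0.0;

  arma::mat x(6, n, arma::fill::zeros);
  arma::ivec s(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    int k0 = (i < start_labels.size()) ? start_labels[i] : 0;
    if (k0 < 0 || k0 >= sm[i].K) k0 = 0;
    s(i) = k0;
    if (start_x.nrow() == 6 && start_x.ncol() == n)
      for (int d = 0; d < 6; ++d) x(d, i) = start_x(d, i);
    else
      x.col(i) = sm[i].means.col(k0);
  }
  // running label-dependent CV mean and variance over the region
  double mu_cv = 0.0, V_cv = 0.0;
  for (int r = 0; r < R; ++r) {
    const int i = region(r);
    mu_cv += sm[i].means(TW, s(i));
    V_cv += sm[i].sTT(s(i));
  }
  auto Gterm = [&](double mu, double V) {
    const double q = 1.0 + c_bias * V;
    return -0.5 * std::log(q) - c_bias * (mu - ref) * (mu - ref) / (2.0 * q);
  };

  RNGScope scope;
  const int total = n_frames + burnin;
  const bool use_mh = gibbs && multimodal && biased;
  for (int t = 0; t < total; ++t) {
    // --- substate labels ---
    if (use_mh) {
      for (int i = 0; i < n; ++i) {
        if (sm[i].K < 2) continue;
        int prop = (int)std::floor(R::unif_rand() * (sm[i].K - 1));
        if (prop >= s(i)) ++prop;
        if (prop >= sm[i].K) prop = sm[i].K - 1;
        double dlog = sm[i].logw0(prop) - sm[i].logw0(s(i));
        if (betaJ != 0.0) {
          if (i > 0 && sm[i - 1].K > 1)
            dlog -= betaJ * ((prop != s(i - 1)) - (s(i) != s(i - 1)));
          if (i < n - 1 && sm[i + 1].K > 1)
            dlog -= betaJ * ((prop != s(i + 1)) - (s(i) != s(i + 1)));
        }
        double mu2 = mu_cv, V2 = V_cv;
        if (in_region[i]) {
          mu2 += sm[i].means(TW, prop) - sm[i].means(TW, s(i));
          V2 += sm[i].sTT(prop) - sm[i].sTT(s(i));
          dlog += Gterm(mu2, V2) - Gterm(mu_cv, V_cv);
        }
        mh_attempt += 1.0;
        if (dlog >= 0.0 || R::unif_rand() < std::exp(dlog)) {
          s(i) = prop;
          mu_cv = mu2; V_cv = V2;
          mh_accept += 1.0;
        }
      }
    } else if (multimodal || betaJ != 0.0) {
      sample_labels_marginal(sm, betaJ, s);
    }
    // --- parameters given labels: blockwise exact draw ---
    for (int i = 0; i < n; ++i) {
      arma::vec z(6);
      for (int d = 0; d < 6; ++d) z(d) = R::norm_rand();
      x.col(i) = sm[i].means.col(s(i)) + sm[i].L.slice(s(i)) * z;
    }
    if (biased) {
      double cv0 = 0.0, stot = 0.0;
      for (int r = 0; r < R; ++r) {
        cv0 += x(TW, region(r));
        stot += sm[region(r)].sTT(s(region(r)));
      }
      const double eps0 = R::norm_rand() * std::sqrt(sigma2);
      const double a = (ref - cv0 - eps0) / (stot + sigma2);
      for (int r = 0; r < R; ++r)
        x.col(region(r)) += sm[region(r)].SigTw.col(s(region(r))) * a;
    }
    if (t < burnin) continue;
    const int f = t - burnin;
    double c = 0.0;
    for (int r = 0; r < R; ++r) c += x(TW, region(r));
    cv(f) = c;
    for (int i = 0; i < n; ++i) {
      tw_sum(i) += x(TW, i);
      if (s(i) < 6) occ(s(i), i) += 1.0;
    }
    if (keep_mode >= 1)
      for (int r = 0; r < R; ++r) twists(f, r) = x(TW, region(r));
    if (keep_mode == 2) {
      for (int r = 0; r < R; ++r)
        for (int d = 0; d < 6; ++d) pk(f, r, d) = x(d, region(r));
    } else if (keep_mode >= 3) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 6; ++d) pk(f, i, d) = x(d, i);
    }
    if (keep_labels)
      for (int i = 0; i < n; ++i) labels_out(f, i) = s(i) + 1;
  }
  List out = List::create(
    _["cv"] = cv,
    _["step_twist_mean"] = tw_sum / n_frames,
    _["occupancy"] = occ / n_frames,
    _["acceptance_rate"] = mh_attempt > 0 ? mh_accept / mh_attempt : NA_REAL,
    _["final_x"] = x,
    _["final_labels"] = IntegerVector(s.begin(), s.end()));
  if (keep_mode >= 1) out["twists"] = twists;
  if (keep_mode >= 2) out["params"] = pk;
  if (keep_labels) out["labels"] = labels_out;
  return out;
}
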
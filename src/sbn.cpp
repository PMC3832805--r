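#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log(sigma(eta)), numerically stable.
static inline double lsig(double eta) {
  if (eta >= 0.0) return -std::log1p(std::exp(-eta));
  return eta - std::log1p(std::exp(eta));
}

static inline double sig(double eta) { return 1.0 / (1.0 + std::exp(-eta)); }

// log Bernoulli(x; sigma(eta)) for x in {0,1}
static inline double lbern(int x, double eta) {
  return x ? lsig(eta) : lsig(-eta);
}

static inline double logsumexp2(double a, double b) {
  double m = a > b ? a : b;
  if (m == R_NegInf) return R_NegInf;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Unpacked network structure (all indices 0-based, matching build_model()).
struct Net {
  int nL, nO, actionCol;
  std::vector<int> biasLat, biasObs;
  // per observable node: latent edges (latent index, theta index of weight)
  std::vector<std::vector<std::pair<int,int> > > latEdges;
  // per observable node: theta index of action->node weight, -1 if none
  std::vector<int> actW;

  explicit Net(const List& model) {
    nL = as<int>(model["n_latent"]);
    nO = as<int>(model["n_obs"]);
    actionCol = as<int>(model["action_col"]);
    biasLat = as<std::vector<int> >(model["bias_latent"]);
    biasObs = as<std::vector<int> >(model["bias_obs"]);
    IntegerVector ec = model["e_child"], et = model["e_type"],
      ep = model["e_parent"], ew = model["e_w"];
    latEdges.assign(nO, std::vector<std::pair<int,int> >());
    actW.assign(nO, -1);
    for (int i = 0; i < ec.size(); ++i) {
      if (et[i] == 0) latEdges[ec[i]].push_back(std::make_pair(ep[i], ew[i]));
      else actW[ec[i]] = ew[i];
    }
  }
};

// Log-likelihood contributions of one trial row under one theta, summed
// over all 2^nL latent configurations; the action node is additionally
// marginalized when it is unobserved but one of its children is observed.
static double trial_loglik_row(const std::vector<double>& theta,
                               const Net& net, const int* x) {
  const int nC = 1 << net.nL;
  bool aObs = net.actionCol >= 0 && x[net.actionCol] >= 0;
  int aVal = aObs ? x[net.actionCol] : 0;
  bool needA = false;
  if (net.actionCol >= 0 && !aObs) {
    for (int j = 0; j < net.nO; ++j)
      if (net.actW[j] >= 0 && x[j] >= 0) { needA = true; break; }
  }
  // latent prior log-terms
  std::vector<double> lp1(net.nL), lp0(net.nL);
  for (int h = 0; h < net.nL; ++h) {
    double b = theta[net.biasLat[h]];
    lp1[h] = lsig(b);
    lp0[h] = lsig(-b);
  }
  double total = R_NegInf;
  for (int c = 0; c < nC; ++c) {
    double ll = 0.0;
    for (int h = 0; h < net.nL; ++h) ll += (c >> h & 1) ? lp1[h] : lp0[h];
    double sA0 = 0.0, sA1 = 0.0;  // action-child terms when A marginalized
    for (int j = 0; j < net.nO; ++j) {
      if (x[j] < 0) continue;
      if (j == net.actionCol) { ll += lbern(x[j], theta[net.biasObs[j]]); continue; }
      double eta = theta[net.biasObs[j]];
      const std::vector<std::pair<int,int> >& le = net.latEdges[j];
      for (size_t k = 0; k < le.size(); ++k)
        if (c >> le[k].first & 1) eta += theta[le[k].second];
      if (net.actW[j] >= 0 && net.actionCol >= 0 && !aObs) {
        // A unobserved: split by the two action states
        sA0 += lbern(x[j], eta);
        sA1 += lbern(x[j], eta + theta[net.actW[j]]);
      } else {
        if (net.actW[j] >= 0 && aObs && aVal)
          eta += theta[net.actW[j]];
        ll += lbern(x[j], eta);
      }
    }
    if (needA) {
      double bA = theta[net.biasObs[net.actionCol]];
      ll += logsumexp2(lsig(-bA) + sA0, lsig(bA) + sA1);
    }
    total = logsumexp2(total, ll);
  }
  return total;
}

// Fast path used by the sampler: per observed node, the Bernoulli
// log-term depends only on the states of its few latent parents, so it is
// tabulated over those 2^p patterns once per trial row and looked up per
// configuration. Falls back to the generic row kernel when the action
// node must be marginalized (unobserved action with an observed child).
static double trial_loglik_row_fast(const std::vector<double>& theta,
                                    const Net& net, const int* x,
                                    const std::vector<double>& lp1,
                                    const std::vector<double>& lp0) {
  const int nC = 1 << net.nL;
  bool aObs = net.actionCol >= 0 && x[net.actionCol] >= 0;
  if (net.actionCol >= 0 && !aObs) {
    for (int j = 0; j < net.nO; ++j)
      if (net.actW[j] >= 0 && x[j] >= 0)
        return trial_loglik_row(theta, net, x);  // needs A-marginalization
  }
  int aVal = aObs ? x[net.actionCol] : 0;
  double base = 0.0;  // config-independent terms
  // per observed node with latent parents: table over parent patterns
  std::vector<int> nodes;  // nodes with latent parents, observed
  std::vector<std::vector<double> > tables;
  for (int j = 0; j < net.nO; ++j) {
    if (x[j] < 0) continue;
    if (j == net.actionCol) { base += lbern(x[j], theta[net.biasObs[j]]); continue; }
    const std::vector<std::pair<int,int> >& le = net.latEdges[j];
    double eta0 = theta[net.biasObs[j]];
    if (net.actW[j] >= 0 && aObs && aVal) eta0 += theta[net.actW[j]];
    if (le.empty()) { base += lbern(x[j], eta0); continue; }
    if (le.size() > 8) return trial_loglik_row(theta, net, x);
    int np = (int)le.size();
    std::vector<double> tab(1 << np);
    for (int p = 0; p < (1 << np); ++p) {
      double eta = eta0;
      for (int k = 0; k < np; ++k)
        if (p >> k & 1) eta += theta[le[k].second];
      tab[p] = lbern(x[j], eta);
    }
    nodes.push_back(j);
    tables.push_back(tab);
  }
  double total = R_NegInf;
  for (int c = 0; c < nC; ++c) {
    double ll = base;
    for (int h = 0; h < net.nL; ++h) ll += (c >> h & 1) ? lp1[h] : lp0[h];
    for (size_t m = 0; m < nodes.size(); ++m) {
      const std::vector<std::pair<int,int> >& le = net.latEdges[nodes[m]];
      int p = 0;
      for (size_t k = 0; k < le.size(); ++k)
        if (c >> le[k].first & 1) p |= 1 << k;
      ll += tables[m][p];
    }
    total = logsumexp2(total, ll);
  }
  return total;
}

static double trials_loglik_all(const std::vector<double>& theta,
                                const Net& net, const IntegerMatrix& X,
                                const IntegerVector& mult) {
  double out = 0.0;
  int n = X.nrow(), nO = X.ncol();
  std::vector<double> lp1(net.nL), lp0(net.nL);
  for (int h = 0; h < net.nL; ++h) {
    double b = theta[net.biasLat[h]];
    lp1[h] = lsig(b);
    lp0[h] = lsig(-b);
  }
  std::vector<int> row(nO);
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < nO; ++j) row[j] = X(t, j);
    out += mult[t] * trial_loglik_row_fast(theta, net, row.data(), lp1, lp0);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_trials_loglik(NumericVector theta, List model, IntegerMatrix X,
                         IntegerVector mult) {
  Net net(model);
  std::vector<double> th = as<std::vector<double> >(theta);
  return trials_loglik_all(th, net, X, mult);
}

// Exact posterior over latent configurations given one evidence row.
// Configuration c encodes latent h as bit h (latent order of the spec).
// [[Rcpp::export]]
NumericVector cpp_latent_posterior(NumericVector theta, List model,
                                   IntegerVector x) {
  Net net(model);
  std::vector<double> th = as<std::vector<double> >(theta);
  const int nC = 1 << net.nL;
  NumericVector logp(nC);
  // per-configuration unnormalized log posterior: reuse the row kernel by
  // clamping each configuration via the latent prior decomposition
  bool aObs = net.actionCol >= 0 && x[net.actionCol] >= 0;
  int aVal = aObs ? x[net.actionCol] : 0;
  bool needA = false;
  if (net.actionCol >= 0 && !aObs) {
    for (int j = 0; j < net.nO; ++j)
      if (net.actW[j] >= 0 && x[j] >= 0) { needA = true; break; }
  }
  for (int c = 0; c < nC; ++c) {
    double ll = 0.0;
    for (int h = 0; h < net.nL; ++h) {
      double b = th[net.biasLat[h]];
      ll += (c >> h & 1) ? lsig(b) : lsig(-b);
    }
    double sA0 = 0.0, sA1 = 0.0;
    for (int j = 0; j < net.nO; ++j) {
      if (x[j] < 0) continue;
      if (j == net.actionCol) { ll += lbern(x[j], th[net.biasObs[j]]); continue; }
      double eta = th[net.biasObs[j]];
      const std::vector<std::pair<int,int> >& le = net.latEdges[j];
      for (size_t k = 0; k < le.size(); ++k)
        if (c >> le[k].first & 1) eta += th[le[k].second];
      if (net.actW[j] >= 0 && net.actionCol >= 0 && !aObs) {
        sA0 += lbern(x[j], eta);
        sA1 += lbern(x[j], eta + th[net.actW[j]]);
      } else {
        if (net.actW[j] >= 0 && aObs && aVal) eta += th[net.actW[j]];
        ll += lbern(x[j], eta);
      }
    }
    if (needA) {
      double bA = th[net.biasObs[net.actionCol]];
      ll += logsumexp2(lsig(-bA) + sA0, lsig(bA) + sA1);
    }
    logp[c] = ll;
  }
  double m = Rcpp::max(logp);
  NumericVector p = Rcpp::exp(logp - m);
  return p / Rcpp::sum(p);
}

// Posterior-predictive probability of one food node under a clamped action
// state, per posterior draw: sum over latent configurations of
// P(config | evidence) * sigma(bias_food + active latent weights +
// action_state * w_action_food). The action is an intervention: it is set,
// never used as evidence about the latents.
// [[Rcpp::export]]
NumericVector cpp_predict_food(NumericMatrix draws, List model,
                               IntegerVector x, int action_state,
                               int food_col) {
  Net net(model);
  const int nC = 1 << net.nL;
  int nDraws = draws.nrow();
  NumericVector out(nDraws);
  std::vector<double> th(draws.ncol());
  for (int d = 0; d < nDraws; ++d) {
    for (int k = 0; k < draws.ncol(); ++k) th[k] = draws(d, k);
    NumericVector post = cpp_latent_posterior(wrap(th), model, x);
    double p = 0.0;
    for (int c = 0; c < nC; ++c) {
      double eta = th[net.biasObs[food_col]];
      const std::vector<std::pair<int,int> >& le = net.latEdges[food_col];
      for (size_t k = 0; k < le.size(); ++k)
        if (c >> le[k].first & 1) eta += th[le[k].second];
      if (net.actW[food_col] >= 0 && action_state)
        eta += th[net.actW[food_col]];
      p += post[c] * sig(eta);
    }
    out[d] = p;
  }
  return out;
}

// Blocked random-walk Metropolis over theta, one Gaussian proposal per
// free parameter per sweep, in canonical parameter order. Proposal scales
// are adapted toward the target acceptance rate during burn-in (multiplied
// by exp(rate - target) every adapt_interval sweeps) and frozen afterward.
// Uses R's RNG so set.seed() in R makes chains reproducible.
// [[Rcpp::export]]
List cpp_run_chain(NumericVector theta0, List model, IntegerMatrix X,
                   IntegerVector mult, NumericVector prior_mean,
                   NumericVector prior_sd, LogicalVector sample_mask,
                   int n_iterations, int n_burn_in, int thinning,
                   NumericVector scale0, int adapt_interval,
                   double target_accept) {
  Net net(model);
  int nP = theta0.size();
  std::vector<double> theta = as<std::vector<double> >(theta0);
  std::vector<double> scales = as<std::vector<double> >(scale0);

  double cur = trials_loglik_all(theta, net, X, mult);
  for (int k = 0; k < nP; ++k)
    cur += R::dnorm(theta[k], prior_mean[k], prior_sd[k], 1);
  if (!R_finite(cur))
    stop("log-posterior is not finite at the initial configuration");

  int nKeep = (n_iterations - n_burn_in) / thinning;
  NumericMatrix draws(nKeep, nP);
  std::vector<int> accWin(nP, 0), accPost(nP, 0);
  int nPost = 0, kept = 0;

  for (int iter = 1; iter <= n_iterations; ++iter) {
    bool burn = iter <= n_burn_in;
    for (int k = 0; k < nP; ++k) {
      if (!sample_mask[k]) continue;
      double old = theta[k];
      theta[k] = old + R::rnorm(0.0, scales[k]);
      double prop = trials_loglik_all(theta, net, X, mult);
      for (int j = 0; j < nP; ++j)
        prop += R::dnorm(theta[j], prior_mean[j], prior_sd[j], 1);
      if (std::log(unif_rand()) < prop - cur) {
        cur = prop;
        accWin[k]++;
        if (!burn) accPost[k]++;
      } else {
        theta[k] = old;
      }
    }
    if (!burn) nPost++;
    if (burn && iter % adapt_interval == 0) {
      for (int k = 0; k < nP; ++k) {
        if (!sample_mask[k]) continue;
        double rate = (double)accWin[k] / adapt_interval;
        scales[k] *= std::exp(rate - target_accept);
        accWin[k] = 0;
      }
    }
    if (!burn && (iter - n_burn_in) % thinning == 0 && kept < nKeep) {
      for (int k = 0; k < nP; ++k) draws(kept, k) = theta[k];
      kept++;
    }
  }
  NumericVector acc(nP);
  for (int k = 0; k < nP; ++k)
    acc[k] = sample_mask[k] && nPost > 0 ? (double)accPost[k] / nPost : NA_REAL;
  return List::create(_["draws"] = draws, _["acceptance"] = acc,
                      _["scales"] = wrap(scales));
}
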
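#include <Rcpp.h>
using namespace Rcpp;

// GMYC likelihood kernels.
//
// The mixed waiting-interval log-likelihood at fixed scaling exponents
// (p_spec, p_coal) is, over positive-length intervals i,
//   sum_i log(l1*A_i + l2*C_i) - l1*sum(A_i x_i) - l2*sum(C_i x_i)
// with A_i = n_spec_i^p_spec and C_i = sum_j (n_ij (n_ij-1))^p_coal.
// It is concave in the rates (l1, l2), so the profile over rates is computed
// by a damped Newton iteration started from the modified Moran estimators
// (event count of a class / scaled branch time of that class), with
// closed-form handling of single-class and boundary cases. The outer
// optimization over the exponents is a Nelder-Mead simplex on the log scale,
// warm-starting the rate iteration between objective evaluations.

struct Workspace {
  std::vector<double> A, C;
  const NumericVector& xp;
  const IntegerVector& ia_pos;
  const NumericVector& log_ap;
  const NumericVector& log_ccv;
  const IntegerVector& cip;
  int Es, Ec;
  double warm1, warm2;

  Workspace(const NumericVector& xp_, const IntegerVector& ia_pos_,
            const NumericVector& log_ap_, const NumericVector& log_ccv_,
            const IntegerVector& cip_, int Es_, int Ec_)
    : A(xp_.size()), C(xp_.size()), xp(xp_), ia_pos(ia_pos_),
      log_ap(log_ap_), log_ccv(log_ccv_), cip(cip_), Es(Es_), Ec(Ec_),
      warm1(-1.0), warm2(-1.0) {}

  void covariates(double p1, double p2) {
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    for (int i = 0; i < ia_pos.size(); ++i)
      A[ia_pos[i] - 1] = std::exp(p1 * log_ap[i]);
    for (int i = 0; i < cip.size(); ++i)
      C[cip[i] - 1] += std::exp(p2 * log_ccv[i]);
  }

  double ll_at(double l1, double l2, double Sa, double Sc) const {
    double s = 0.0;
    const int n = (int) A.size();
    for (int i = 0; i < n; ++i) {
      double b = l1 * A[i] + l2 * C[i];
      if (b <= 0.0) return R_NegInf;
      s += std::log(b);
    }
    return s - l1 * Sa - l2 * Sc;
  }

  // rate estimation at the current covariates; returns the lnL and leaves
  // the rates in l1out/l2out. With `exact` false this is the Moran plug-in
  // of the original method (events of a class / scaled branch time of the
  // class), which is the exact MLE whenever only one class is present; with
  // `exact` true the concave rate likelihood is maximized by damped Newton.
  double profile(double& l1out, double& l2out, bool warm, bool exact) {
    const int np = (int) A.size();
    double Sa = 0.0, Sc = 0.0;
    for (int i = 0; i < np; ++i) {
      Sa += A[i] * xp[i];
      Sc += C[i] * xp[i];
    }
    double l1 = (Es > 0 && Sa > 0.0) ? Es / Sa : 0.0;
    double l2 = (Ec > 0 && Sc > 0.0) ? Ec / Sc : 0.0;
    if (l1 == 0.0) {                       // single class: Moran is exact
      l2 = (Sc > 0.0) ? np / Sc : 0.0;
      l1out = 0.0; l2out = l2;
      return ll_at(0.0, l2, Sa, Sc);
    }
    if (l2 == 0.0) {
      l1 = (Sa > 0.0) ? np / Sa : 0.0;
      l1out = l1; l2out = 0.0;
      return ll_at(l1, 0.0, Sa, Sc);
    }
    if (!exact) {
      l1out = l1; l2out = l2;
      return ll_at(l1, l2, Sa, Sc);
    }
    if (warm && warm1 > 0.0 && warm2 > 0.0) { l1 = warm1; l2 = warm2; }
    double ll = ll_at(l1, l2, Sa, Sc);
    if (!R_finite(ll)) { l1 = Es / Sa; l2 = Ec / Sc; ll = ll_at(l1, l2, Sa, Sc); }
    for (int it = 0; it < 100; ++it) {
      double g1 = -Sa, g2 = -Sc, h11 = 0.0, h12 = 0.0, h22 = 0.0;
      for (int i = 0; i < np; ++i) {
        double b = l1 * A[i] + l2 * C[i];
        double u = A[i] / b, v = C[i] / b;
        g1 += u; g2 += v;
        h11 += u * u; h12 += u * v; h22 += v * v;
      }
      double det = h11 * h22 - h12 * h12;
      double s1, s2;
      if (det > 1e-300) {
        s1 = (h22 * g1 - h12 * g2) / det;
        s2 = (h11 * g2 - h12 * g1) / det;
      } else {
        s1 = g1 / h11; s2 = g2 / h22;
      }
      double damp = 1.0, n1 = l1, n2 = l2, nll = ll;
      bool moved = false;
      while (damp >= 1e-12) {
        n1 = l1 + damp * s1; n2 = l2 + damp * s2;
        if (n1 >= 0.0 && n2 >= 0.0) {
          nll = ll_at(n1, n2, Sa, Sc);
          if (R_finite(nll) && nll >= ll - 1e-12) { moved = true; break; }
        }
        damp *= 0.5;
      }
      if (!moved) break;
      bool conv = std::fabs(nll - ll) < 1e-12 &&
        std::max(std::fabs(g1) * l1, std::fabs(g2) * l2) < 1e-9 * np;
      l1 = n1; l2 = n2; ll = nll;
      if (conv) break;
    }
    // boundary maxima (one rate at zero)
    bool allC = true, allA = true;
    for (int i = 0; i < np; ++i) {
      if (C[i] <= 0.0) allC = false;
      if (A[i] <= 0.0) allA = false;
    }
    if (allC && Sc > 0.0) {
      double ll0 = ll_at(0.0, np / Sc, Sa, Sc);
      if (ll0 > ll) { l1 = 0.0; l2 = np / Sc; ll = ll0; }
    }
    if (allA && Sa > 0.0) {
      double ll0 = ll_at(np / Sa, 0.0, Sa, Sc);
      if (ll0 > ll) { l1 = np / Sa; l2 = 0.0; ll = ll0; }
    }
    l1out = l1; l2out = l2;
    if (l1 > 0.0 && l2 > 0.0) { warm1 = l1; warm2 = l2; }
    return ll;
  }

  double pmax;
  bool exact;

  // negative profiled log-likelihood as a function of z = log(p)
  double objective(double z1, double z2) {
    double p1 = std::exp(z1), p2 = std::exp(z2);
    if (p1 > pmax || p2 > pmax) return 1e10 * (1.0 + p1 + p2);
    covariates(p1, p2);
    double l1, l2;
    double ll = profile(l1, l2, true, exact);
    return R_finite(ll) ? -ll : 1e10;
  }
};

// [[Rcpp::export]]
List profile_rates_cpp(NumericVector xp, IntegerVector ia_pos,
                       NumericVector log_ap, NumericVector log_ccv,
                       IntegerVector cip, double p_spec, double p_coal,
                       int n_spec_events, int n_coal_events,
                       bool exact = true) {
  Workspace w(xp, ia_pos, log_ap, log_ccv, cip, n_spec_events, n_coal_events);
  w.pmax = 1e300;
  w.covariates(p_spec, p_coal);
  double l1, l2;
  double ll = w.profile(l1, l2, false, exact);
  return List::create(_["l1"] = l1, _["l2"] = l2, _["ll"] = ll);
}

// Nelder-Mead over z = (log p_spec, log p_coal); same convergence rule as
// stats::optim (relative tolerance on the simplex function values)
// [[Rcpp::export]]
List fit_exponents_cpp(NumericVector xp, IntegerVector ia_pos,
                       NumericVector log_ap, NumericVector log_ccv,
                       IntegerVector cip, int n_spec_events,
                       int n_coal_events, NumericVector z_start,
                       double reltol, int maxit, double pmax,
                       bool exact = false) {
  Workspace w(xp, ia_pos, log_ap, log_ccv, cip, n_spec_events, n_coal_events);
  w.pmax = pmax;
  w.exact = exact;
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  double sx[3][2], sf[3];
  sx[0][0] = z_start[0];       sx[0][1] = z_start[1];
  sx[1][0] = z_start[0] + 0.1; sx[1][1] = z_start[1];
  sx[2][0] = z_start[0];       sx[2][1] = z_start[1] + 0.1;
  for (int i = 0; i < 3; ++i) sf[i] = w.objective(sx[i][0], sx[i][1]);
  int nev = 3, conv = 1;
  while (nev < maxit) {
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (sf[i] < sf[lo]) lo = i;
      if (sf[i] > sf[hi]) hi = i;
    }
    if (std::fabs(sf[hi] - sf[lo]) <=
        reltol * (std::fabs(sf[lo]) + reltol)) { conv = 0; break; }
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < 3; ++i) if (i != hi) { cx += sx[i][0]; cy += sx[i][1]; }
    cx /= 2.0; cy /= 2.0;
    double rx = cx + alpha * (cx - sx[hi][0]), ry = cy + alpha * (cy - sx[hi][1]);
    double fr = w.objective(rx, ry); ++nev;
    if (fr < sf[lo]) {
      double ex = cx + gamma * (rx - cx), ey = cy + gamma * (ry - cy);
      double fe = w.objective(ex, ey); ++nev;
      if (fe < fr) { sx[hi][0] = ex; sx[hi][1] = ey; sf[hi] = fe; }
      else { sx[hi][0] = rx; sx[hi][1] = ry; sf[hi] = fr; }
    } else {
      bool better_than_second = false;
      for (int i = 0; i < 3; ++i)
        if (i != hi && fr < sf[i]) { better_than_second = true; break; }
      if (better_than_second) {
        sx[hi][0] = rx; sx[hi][1] = ry; sf[hi] = fr;
      } else {
        double kx = cx + rho * (sx[hi][0] - cx), ky = cy + rho * (sx[hi][1] - cy);
        double fk = w.objective(kx, ky); ++nev;
        if (fk < sf[hi]) { sx[hi][0] = kx; sx[hi][1] = ky; sf[hi] = fk; }
        else {
          for (int i = 0; i < 3; ++i) {
            if (i == lo) continue;
            sx[i][0] = sx[lo][0] + sigma * (sx[i][0] - sx[lo][0]);
            sx[i][1] = sx[lo][1] + sigma * (sx[i][1] - sx[lo][1]);
            sf[i] = w.objective(sx[i][0], sx[i][1]); ++nev;
          }
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (sf[i] < sf[lo]) lo = i;
  double p1 = std::min(std::exp(sx[lo][0]), pmax);
  double p2 = std::min(std::exp(sx[lo][1]), pmax);
  w.covariates(p1, p2);
  double l1, l2;
  double ll = w.profile(l1, l2, false, exact);
  return List::create(_["p_spec"] = p1, _["p_coal"] = p2,
                      _["lambda_spec"] = l1, _["lambda_coal"] = l2,
                      _["ll"] = ll, _["convergence"] = conv,
                      _["evals"] = nev);
}

// interval sweep: given the per-event process id (0 = diversification,
// j > 0 = coalescent within cluster j) in age order, the waiting times, and
// the initial lineage counts, produce the per-interval counts and the
// flattened per-cluster n(n-1) table. Mirrors the bookkeeping rules: a
// coalescent event decrements its cluster; when a cluster reaches one
// lineage its stem joins the diversification process; a diversification
// event merges two stems.
// [[Rcpp::export]]
List intervals_sweep_cpp(IntegerVector ev_proc, NumericVector x,
                         IntegerVector ncoal0, int nspec0) {
  const int ne = ev_proc.size();
  std::vector<int> ncoal(ncoal0.begin(), ncoal0.end());
  int nspec = nspec0;
  IntegerVector nspec_i(ne), ev_class(ne);
  NumericVector ev_val(ne);
  std::vector<double> cc;
  std::vector<int> ci;
  std::vector<int> live;
  live.reserve(ncoal.size());
  for (size_t j = 0; j < ncoal.size(); ++j)
    if (ncoal[j] >= 2) live.push_back((int) j);
  for (int i = 0; i < ne; ++i) {
    nspec_i[i] = nspec;
    for (size_t u = 0; u < live.size(); ++u) {
      int j = live[u];
      cc.push_back((double) ncoal[j] * (ncoal[j] - 1));
      ci.push_back(i + 1);
    }
    int j = ev_proc[i];
    if (j == 0) {
      if (nspec < 2) stop("invalid delimitation: speciation event without two stems");
      ev_class[i] = 1;
      ev_val[i] = nspec;
      --nspec;
    } else {
      int& n = ncoal[j - 1];
      if (n < 2) stop("invalid delimitation: coalescent event without two lineages");
      ev_class[i] = 2;
      ev_val[i] = (double) n * (n - 1);
      --n;
      if (n == 1) {          // cluster MRCA reached: stem becomes a
        n = 0;               // diversification lineage
        ++nspec;
        for (size_t u = 0; u < live.size(); ++u)
          if (live[u] == j - 1) { live.erase(live.begin() + u); break; }
      }
    }
  }
  return List::create(_["nspec_i"] = nspec_i, _["ev_class"] = ev_class,
                      _["ev_val"] = ev_val, _["cc"] = NumericVector(cc.begin(), cc.end()),
                      _["ci"] = IntegerVector(ci.begin(), ci.end()));
}
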
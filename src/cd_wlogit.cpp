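#include <Rcpp.h>
using namespace Rcpp;

// Penalized weighted logistic regression by cyclic coordinate descent on the
// IRLS quadratic approximation, warm-started along a descending lambda path.
//
// Loss (weights normalized to sum 1, intercept unpenalized):
//   sum_j wt_j * [ -y_j eta_j + log(1 + exp(eta_j)) ]
//     + lambda * ( alpha * ||beta||_1 + (1 - alpha)/2 * ||beta||_2^2 )

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double wlogit_objective(const NumericMatrix &X, const NumericVector &y,
                               const NumericVector &wt, double b0,
                               const std::vector<double> &beta, double lambda,
                               double alpha) {
  const int n = X.nrow(), p = X.ncol();
  double nll = 0.0;
  for (int j = 0; j < n; ++j) {
    double eta = b0;
    for (int k = 0; k < p; ++k) eta += X(j, k) * beta[k];
    double l = (eta > 0.0 ? eta + std::log1p(std::exp(-eta))
                          : std::log1p(std::exp(eta))) - y[j] * eta;
    nll += wt[j] * l;
  }
  double pen = 0.0;
  for (int k = 0; k < p; ++k)
    pen += alpha * std::fabs(beta[k]) +
           0.5 * (1.0 - alpha) * beta[k] * beta[k];
  return nll + lambda * pen;
}

// [[Rcpp::export(name = ".cd_wlogit_path")]]
List cd_wlogit_path(NumericMatrix X, NumericVector y, NumericVector w,
                    NumericVector lambda, double alpha, double tol,
                    int max_outer, int max_inner, bool trace) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();

  // normalize weights to sum 1 so lambda has a location-independent scale
  double wsum = 0.0;
  for (int j = 0; j < n; ++j) wsum += w[j];
  if (wsum <= 0.0) stop("total observation weight must be positive");
  NumericVector wt(n);
  for (int j = 0; j < n; ++j) wt[j] = w[j] / wsum;

  double pbar = 0.0;
  for (int j = 0; j < n; ++j) pbar += wt[j] * y[j];
  if (pbar <= 0.0 || pbar >= 1.0)
    stop("degenerate design: effective outcomes are all 0 or all 1");

  // warm-start state: null model at the weighted mean
  double b0 = std::log(pbar / (1.0 - pbar));
  std::vector<double> beta(p, 0.0);

  NumericVector out_b0(nlam), out_obj(nlam);
  IntegerVector out_iter(nlam);
  LogicalVector out_conv(nlam);
  NumericMatrix out_beta(p, nlam);
  List obj_traces(nlam);

  std::vector<double> eta(n), prob(n), v(n), r(n), xv(p);

  for (int t = 0; t < nlam; ++t) {
    const double lam = lambda[t];
    const double lam1 = lam * alpha;        // L1 part
    const double lam2 = lam * (1.0 - alpha); // L2 part
    bool converged = false;
    int n_pass = 0;
    std::vector<double> tr;
    double obj_prev = wlogit_objective(X, y, wt, b0, beta, lam, alpha);
    if (trace) tr.push_back(obj_prev);

    for (int outer = 0; outer < max_outer; ++outer) {
      // IRLS quadratic at current parameters
      for (int j = 0; j < n; ++j) {
        double e = b0;
        for (int k = 0; k < p; ++k) e += X(j, k) * beta[k];
        eta[j] = e;
        double pj = 1.0 / (1.0 + std::exp(-e));
        prob[j] = pj;
        double pq = pj * (1.0 - pj);
        if (pq < 1e-9) pq = 1e-9; // guard against saturated probabilities
        v[j] = wt[j] * pq;
        r[j] = (y[j] - pj) / pq; // working residual z - eta
      }
      for (int k = 0; k < p; ++k) {
        double s = 0.0;
        for (int j = 0; j < n; ++j) s += v[j] * X(j, k) * X(j, k);
        xv[k] = s;
      }

      const double b0_in = b0;
      const std::vector<double> beta_in = beta;

      // inner cyclic coordinate descent on the quadratic
      for (int pass = 0; pass < max_inner; ++pass) {
        double dmax = 0.0;
        double vr = 0.0, vsum = 0.0;
        for (int j = 0; j < n; ++j) { vr += v[j] * r[j]; vsum += v[j]; }
        double db0 = vr / vsum;
        if (db0 != 0.0) {
          b0 += db0;
          for (int j = 0; j < n; ++j) r[j] -= db0;
          dmax = std::max(dmax, std::fabs(db0));
        }
        for (int k = 0; k < p; ++k) {
          double g = xv[k] * beta[k];
          for (int j = 0; j < n; ++j) g += v[j] * X(j, k) * r[j];
          double bk = soft_threshold(g, lam1) / (xv[k] + lam2);
          double d = bk - beta[k];
          if (d != 0.0) {
            beta[k] = bk;
            for (int j = 0; j < n; ++j) r[j] -= d * X(j, k);
            dmax = std::max(dmax, std::fabs(d));
          }
        }
        ++n_pass;
        if (dmax < tol) break;
      }

      // backtrack toward the previous iterate if the true objective rose
      double obj_new = wlogit_objective(X, y, wt, b0, beta, lam, alpha);
      int halvings = 0;
      while (obj_new > obj_prev + 1e-12 && halvings < 30) {
        b0 = 0.5 * (b0 + b0_in);
        for (int k = 0; k < p; ++k) beta[k] = 0.5 * (beta[k] + beta_in[k]);
        obj_new = wlogit_objective(X, y, wt, b0, beta, lam, alpha);
        ++halvings;
      }
      if (trace) tr.push_back(obj_new);

      double dpar = std::fabs(b0 - b0_in);
      for (int k = 0; k < p; ++k)
        dpar = std::max(dpar, std::fabs(beta[k] - beta_in[k]));
      obj_prev = obj_new;
      if (dpar < tol) { converged = true; break; }
    }

    // snap numerically-zero coefficients for sparsity accounting
    for (int k = 0; k < p; ++k)
      if (std::fabs(beta[k]) < 1e-10) beta[k] = 0.0;

    out_b0[t] = b0;
    for (int k = 0; k < p; ++k) out_beta(k, t) = beta[k];
    out_obj[t] = wlogit_objective(X, y, wt, b0, beta, lam, alpha);
    out_iter[t] = n_pass;
    out_conv[t] = converged;
    if (trace) obj_traces[t] = wrap(tr);
  }

  List res = List::create(
      _["intercept"] = out_b0, _["beta"] = out_beta, _["lambda"] = lambda,
      _["objective"] = out_obj, _["n_iter"] = out_iter,
      _["converged"] = out_conv);
  if (trace) res["obj_trace"] = obj_traces;
  return res;
}
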
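#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// squared distances from every row of X to one point
static arma::vec dist2_to_point(const arma::mat& X, const arma::vec& xsq,
                                const arma::rowvec& c) {
  return xsq - 2.0 * (X * c.t()) + arma::dot(c, c);
}

// kmeans++ seeding using R's RNG stream (unif_rand), so results are
// deterministic under set.seed()
static arma::mat kmeanspp(const arma::mat& X, const arma::vec& xsq,
                          arma::uword k) {
  const arma::uword n = X.n_rows;
  arma::mat centers(k, X.n_cols);
  arma::uword first = std::min((arma::uword)(unif_rand() * n), n - 1);
  centers.row(0) = X.row(first);
  if (k == 1) return centers;
  arma::vec d2 = arma::clamp(dist2_to_point(X, xsq, centers.row(0)),
                             0.0, arma::datum::inf);
  for (arma::uword j = 1; j < k; ++j) {
    double tot = arma::accu(d2);
    arma::uword pick;
    if (tot <= 0.0) {
      pick = std::min((arma::uword)(unif_rand() * n), n - 1);
    } else {
      double u = unif_rand() * tot, cum = 0.0;
      pick = n - 1;
      for (arma::uword i = 0; i < n; ++i) {
        cum += d2(i);
        if (u <= cum) { pick = i; break; }
      }
    }
    centers.row(j) = X.row(pick);
    if (j + 1 < k) {
      d2 = arma::min(d2, arma::clamp(dist2_to_point(X, xsq, centers.row(j)),
                                     0.0, arma::datum::inf));
    }
  }
  return centers;
}

// Lloyd iterations for k-means from given starting centers.
//
// X: n x p data (rows = observations), centers: k x p starting centers.
// Iterates assign/update until the assignment is stable or max_iter is
// reached. An empty cluster is repaired by reseeding its center at the
// point farthest from its (updated) assigned center; singleton donor
// clusters are protected so no cluster is emptied by the repair.
//
// Returns 1-based labels, final centers, the total within-cluster sum of
// squares after each assignment step (non-increasing by construction),
// the iteration count and a convergence flag.
// [[Rcpp::export]]
List lloyd_iterate(const arma::mat& X, arma::mat centers, int max_iter) {
  const arma::uword n = X.n_rows, p = X.n_cols, k = centers.n_rows;
  arma::uvec labels(n, arma::fill::zeros);
  arma::uvec prev(n);
  prev.fill(k + 1);  // force at least one iteration
  std::vector<double> trace;
  bool converged = false;

  arma::vec xsq = arma::sum(arma::square(X), 1);

  for (int iter = 0; iter < max_iter; ++iter) {
    arma::vec csq = arma::sum(arma::square(centers), 1);
    arma::mat cross = X * centers.t();  // n x k
    double inertia = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double best = R_PosInf;
      arma::uword bj = 0;
      for (arma::uword j = 0; j < k; ++j) {
        double d2 = xsq(i) - 2.0 * cross(i, j) + csq(j);
        if (d2 < best) { best = d2; bj = j; }
      }
      labels(i) = bj;
      inertia += std::max(best, 0.0);
    }
    trace.push_back(inertia);

    if (arma::all(labels == prev)) { converged = true; break; }
    prev = labels;

    arma::mat newc(k, p, arma::fill::zeros);
    arma::vec cnt(k, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) {
      newc.row(labels(i)) += X.row(i);
      cnt(labels(i)) += 1.0;
    }
    for (arma::uword j = 0; j < k; ++j) {
      if (cnt(j) > 0) {
        newc.row(j) /= cnt(j);
      } else {
        double worst = -1.0;
        arma::uword wi = 0;
        for (arma::uword i = 0; i < n; ++i) {
          arma::uword ci = labels(i);
          double d2 = xsq(i) - 2.0 * arma::dot(X.row(i), newc.row(ci)) +
                      arma::dot(newc.row(ci), newc.row(ci));
          if (cnt(ci) > 1 && d2 > worst) { worst = d2; wi = i; }
        }
        newc.row(j) = X.row(wi);
      }
    }
    centers = newc;
  }

  return List::create(
      _["labels"] = IntegerVector(labels.begin(), labels.end()),
      _["centers"] = centers,
      _["inertia_trace"] = NumericVector(trace.begin(), trace.end()),
      _["n_iter"] = (int)trace.size(),
      _["converged"] = converged);
}

// Best of n_init kmeans++/Lloyd restarts by total within-cluster SS.
// Consumes R's RNG stream, so deterministic under set.seed().
// [[Rcpp::export]]
List kmeans_restarts(const arma::mat& X, int k, int n_init, int max_iter) {
  arma::vec xsq = arma::sum(arma::square(X), 1);
  List best;
  double best_w = R_PosInf;
  for (int i = 0; i < n_init; ++i) {
    arma::mat c0 = kmeanspp(X, xsq, (arma::uword)k);
    List fit = lloyd_iterate(X, c0, max_iter);
    NumericVector tr = fit["inertia_trace"];
    double w = tr[tr.size() - 1];
    if (w < best_w) { best_w = w; best = fit; }
    if (k == 1) break;
  }
  return best;
}
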
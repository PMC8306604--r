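#include <RcppArmadillo.h>
using namespace Rcpp;

// Transition matrices exp(Q*t) for a set of branch lengths. The generator is
// eigendecomposed once; per-branch matrices come from the spectral form, with
// a scaling-and-squaring fallback when Q is (near-)defective. Tiny negative
// entries from roundoff are clipped and rows renormalised.
static arma::cube edge_pmats_internal(const arma::mat& Q, const arma::vec& lens) {
  const unsigned int k = Q.n_rows, ne = lens.n_elem;
  arma::cube P(k, k, ne);

  arma::cx_vec eval;
  arma::cx_mat evec, evinv;
  bool spectral = arma::eig_gen(eval, evec, Q);
  if (spectral) spectral = arma::inv(evinv, evec);
  if (spectral) {
    arma::cx_mat recon = evec * arma::diagmat(eval) * evinv;
    double err = arma::norm(arma::real(recon) - Q, "inf") +
                 arma::norm(arma::imag(recon), "inf");
    spectral = err < 1e-9 * (1.0 + arma::norm(Q, "inf"));
  }

  for (unsigned int e = 0; e < ne; ++e) {
    arma::mat Pe;
    if (spectral) {
      Pe = arma::real(evec * arma::diagmat(arma::exp(eval * lens[e])) * evinv);
    } else {
      Pe = arma::expmat(Q * lens[e]);
    }
    Pe.elem(arma::find(Pe < 0.0)).zeros();
    arma::vec rs = arma::sum(Pe, 1);
    for (unsigned int i = 0; i < k; ++i)
      if (rs[i] > 0.0) Pe.row(i) /= rs[i];
    P.slice(e) = Pe;
  }
  return P;
}

// [[Rcpp::export]]
arma::cube ctmc_edge_pmats_cpp(const arma::mat& Q, const arma::vec& lens) {
  return edge_pmats_internal(Q, lens);
}

// Felsenstein pruning up-pass. `edge` must be in postorder (children before
// parents), 1-based ape node ids; tips are 1..n_tip, states 1..k.
// Returns per-node conditional likelihoods with per-node log scale factors.
// [[Rcpp::export]]
List ctmc_partials_cpp(const IntegerMatrix& edge, const NumericVector& lens,
                       int n_tip, int n_node, const IntegerVector& tip_states,
                       const arma::mat& Q) {
  const int k = Q.n_rows;
  arma::cube P = edge_pmats_internal(Q, as<arma::vec>(lens));

  arma::mat part(n_node, k, arma::fill::zeros);
  arma::vec logsc(n_node, arma::fill::zeros);
  std::vector<bool> seen(n_node, false);
  for (int i = 0; i < n_tip; ++i) {
    part(i, tip_states[i] - 1) = 1.0;
    seen[i] = true;
  }

  const int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    // contrib_i = sum_j P(i,j) L_c(j)
    arma::rowvec contrib = part.row(c) * P.slice(e).t();
    if (!seen[p]) {
      part.row(p) = contrib;
      logsc[p] = logsc[c];
      seen[p] = true;
    } else {
      part.row(p) %= contrib;
      logsc[p] += logsc[c];
    }
    double m = part.row(p).max();
    if (m > 0.0) {
      part.row(p) /= m;
      logsc[p] += std::log(m);
    }
  }
  return List::create(_["partials"] = part, _["logscale"] = logsc);
}
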
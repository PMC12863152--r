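// Compiled cores: AAHC clustering of topographies and first-order Markov
// segment-label sampling.  Both are deterministic given their inputs (the
// sampler draws through R's RNG, so set.seed() governs it).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Top eigenvector / eigenvalue of a symmetric C x C scatter matrix.
static void top_eig(const arma::mat& S, arma::vec& v, double& lam) {
  arma::vec eigval;
  arma::mat eigvec;
  arma::eig_sym(eigval, eigvec, S);
  lam = eigval(eigval.n_elem - 1);
  v = eigvec.col(eigvec.n_elem > 0 ? eigvec.n_cols - 1 : 0);
  // deterministic sign: largest-magnitude element positive
  arma::uword i = arma::index_max(arma::abs(v));
  if (v(i) < 0) v = -v;
}

// AAHC: columns of V are centered, unit-norm maps; w2 are squared weights
// (GFP^2).  Cluster centroid = top eigenvector of sum_i w2_i v_i v_i^T over
// members; its top eigenvalue is the cluster's (unnormalised) GEV
// contribution.  Victim = cluster with smallest contribution; freed maps are
// reassigned by maximal |corr| to surviving centroids.  Ties go to the
// lowest cluster index (std index order preserves this).
// [[Rcpp::export]]
List aahc_core(const arma::mat& V, const arma::vec& w2, int K) {
  const int C = V.n_rows;
  const int n = V.n_cols;
  if (n < K) stop("fewer maps than clusters");

  std::vector< std::vector<int> > members(n);
  std::vector<arma::mat> scatter(n);          // lazily allocated (>=2 members)
  std::vector<double> contrib(n);
  // compacted storage: column p of cent holds the centroid (unit norm) of
  // cluster cluster_at[p]; pos_of inverts the mapping
  arma::mat cent(C, n);
  std::vector<int> cluster_at(n), pos_of(n);
  int n_alive = n;

  for (int i = 0; i < n; ++i) {
    members[i].push_back(i);
    cent.col(i) = V.col(i);                   // single member: centroid = map
    contrib[i] = w2(i);
    cluster_at[i] = i;
    pos_of[i] = i;
  }
  std::vector<int> assign(n);
  for (int i = 0; i < n; ++i) assign[i] = i;

  while (n_alive > K) {
    // victim: lowest contribution, ties -> lowest cluster index
    int victim = -1;
    double best = R_PosInf;
    for (int p = 0; p < n_alive; ++p) {
      const int k = cluster_at[p];
      if (contrib[k] < best || (contrib[k] == best && k < victim)) {
        best = contrib[k];
        victim = k;
      }
    }
    // remove victim from the compacted store (swap with last column)
    {
      const int p = pos_of[victim];
      const int last = n_alive - 1;
      if (p != last) {
        cent.col(p) = cent.col(last);
        cluster_at[p] = cluster_at[last];
        pos_of[cluster_at[p]] = p;
      }
      --n_alive;
    }
    std::vector<int> freed;
    freed.swap(members[victim]);
    scatter[victim].reset();

    // batched scores: |centroids^T freed| via BLAS
    const int m = (int)freed.size();
    arma::mat F(C, m);
    for (int f = 0; f < m; ++f) F.col(f) = V.col(freed[f]);
    arma::mat S = arma::abs(cent.head_cols(n_alive).t() * F);  // n_alive x m

    std::vector<int> touched;
    for (int f = 0; f < m; ++f) {
      const int i = freed[f];
      const double* sc = S.colptr(f);
      double bestr = -1.0;
      int bestk = -1;
      for (int p = 0; p < n_alive; ++p) {
        const int k = cluster_at[p];
        if (sc[p] > bestr + 1e-15 ||
            (std::fabs(sc[p] - bestr) <= 1e-15 && k < bestk)) {
          bestr = sc[p];
          bestk = k;
        }
      }
      if (members[bestk].size() == 1 && scatter[bestk].n_elem == 0) {
        const int j = members[bestk][0];
        scatter[bestk] = w2(j) * (V.col(j) * V.col(j).t());
      }
      members[bestk].push_back(i);
      if (scatter[bestk].n_elem)
        scatter[bestk] += w2(i) * (V.col(i) * V.col(i).t());
      assign[i] = bestk;
      bool seen = false;
      for (size_t t = 0; t < touched.size(); ++t)
        if (touched[t] == bestk) { seen = true; break; }
      if (!seen) touched.push_back(bestk);
    }
    // recompute centroids + contributions of clusters that gained members
    for (size_t t = 0; t < touched.size(); ++t) {
      const int k = touched[t];
      double lam;
      arma::vec v(C);
      top_eig(scatter[k], v, lam);
      cent.col(pos_of[k]) = v;
      contrib[k] = lam;
    }
  }

  // compress surviving cluster ids to 0..K-1 in ascending cluster order
  std::vector<int> order(cluster_at.begin(), cluster_at.begin() + n_alive);
  std::sort(order.begin(), order.end());
  std::vector<int> newid(n, -1);
  arma::mat cents(C, K);
  for (int p = 0; p < K; ++p) {
    newid[order[p]] = p;
    cents.col(p) = cent.col(pos_of[order[p]]);
  }
  IntegerVector out_assign(n);
  for (int i = 0; i < n; ++i) out_assign[i] = newid[assign[i]];
  return List::create(_["assignment"] = out_assign,
                      _["centroids"] = cents);
}

// Zero-phase IIR filtering of a channels x samples matrix: each row is
// filtered forward then backward (direct form II transposed) after odd
// reflection padding of length pad at both ends, matching the usual
// filtfilt edge treatment.
static void filt_inplace(const arma::vec& b, const arma::vec& a,
                         arma::rowvec& x) {
  const int nb = b.n_elem, na = a.n_elem, n = x.n_elem;
  const int nz = std::max(na, nb) - 1;
  arma::vec z(nz, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double xi = x(i);
    double yi = b(0) * xi + (nz > 0 ? z(0) : 0.0);
    for (int j = 1; j < nz; ++j) {
      double bj = j < nb ? b(j) : 0.0;
      double aj = j < na ? a(j) : 0.0;
      z(j - 1) = bj * xi + z(j) - aj * yi;
    }
    if (nz > 0) {
      double bl = nz < nb ? b(nz) : 0.0;
      double al = nz < na ? a(nz) : 0.0;
      z(nz - 1) = bl * xi - al * yi;
    }
    x(i) = yi;
  }
}

// [[Rcpp::export]]
arma::mat filtfilt_mat(const arma::vec& b, const arma::vec& a,
                       const arma::mat& X, int pad) {
  const int C = X.n_rows, n = X.n_cols;
  if (pad >= n) pad = n - 1;
  arma::mat out(C, n);
  for (int c = 0; c < C; ++c) {
    arma::rowvec x(n + 2 * pad);
    // odd reflection about the end points
    for (int i = 0; i < pad; ++i)
      x(i) = 2 * X(c, 0) - X(c, pad - i);
    for (int i = 0; i < n; ++i) x(pad + i) = X(c, i);
    for (int i = 0; i < pad; ++i)
      x(pad + n + i) = 2 * X(c, n - 1) - X(c, n - 2 - i);
    filt_inplace(b, a, x);
    x = arma::reverse(x);
    filt_inplace(b, a, x);
    x = arma::reverse(x);
    out.row(c) = x.subvec(pad, pad + n - 1);
  }
  return out;
}

// Sample n_segments labels of a first-order Markov chain over K states with
// zero-diagonal row-stochastic transition matrix P (rows: from).  init < 0
// draws the first label uniformly.  Uses R's RNG.
// [[Rcpp::export]]
IntegerVector markov_labels(const arma::mat& P, int n_segments, int init) {
  const int K = P.n_rows;
  IntegerVector out(n_segments);
  int cur;
  if (init >= 0) {
    cur = init;
  } else {
    cur = (int)std::floor(unif_rand() * K);
    if (cur >= K) cur = K - 1;
  }
  out[0] = cur + 1;
  for (int s = 1; s < n_segments; ++s) {
    double u = unif_rand();
    double acc = 0.0;
    int nxt = -1;
    for (int j = 0; j < K; ++j) {
      acc += P(cur, j);
      if (u <= acc) { nxt = j; break; }
    }
    if (nxt < 0) {
      // numerical slack: fall back to the last state with positive mass
      for (int j = K - 1; j >= 0; --j) if (P(cur, j) > 0) { nxt = j; break; }
    }
    cur = nxt;
    out[s] = cur + 1;
  }
  return out;
}
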
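#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Column-wise accumulation of L1 distances from every row of X to one
// centroid; cache-friendly for R's column-major layout.
static void dist_to_centroid(const NumericMatrix& X, const double* cen,
                             std::vector<double>& acc) {
  const int n = X.nrow(), d = X.ncol();
  std::fill(acc.begin(), acc.end(), 0.0);
  for (int j = 0; j < d; ++j) {
    const double cj = cen[j];
    const double* col = &X(0, j);
    for (int i = 0; i < n; ++i) acc[i] += std::fabs(col[i] - cj);
  }
}

// median of a scratch buffer (mean-of-middle for even counts)
static double buf_median(std::vector<double>& buf) {
  const size_t m = buf.size();
  const size_t h = m / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double hi = buf[h];
  if (m % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return 0.5 * (lo + hi);
}

// k-means++-style seeding with L1 distances, using R's RNG
static void seed_centroids(const NumericMatrix& X, int k,
                           std::vector<std::vector<double>>& cen) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> mind(n, R_PosInf), acc(n);
  int first = (int)std::floor(unif_rand() * n);
  if (first >= n) first = n - 1;
  for (int j = 0; j < d; ++j) cen[0][j] = X(first, j);
  for (int c = 1; c < k; ++c) {
    dist_to_centroid(X, cen[c - 1].data(), acc);
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      if (acc[i] < mind[i]) mind[i] = acc[i];
      tot += mind[i];
    }
    int pick;
    if (tot <= 0) {
      pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
    } else {
      double u = unif_rand() * tot, cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += mind[i];
        if (u <= cum) { pick = i; break; }
      }
    }
    for (int j = 0; j < d; ++j) cen[c][j] = X(pick, j);
  }
}

// [[Rcpp::export(name = ".kmeans_l1_cpp")]]
List kmeans_l1_cpp(NumericMatrix X, int k, int n_init, int max_iter,
                   Nullable<NumericMatrix> init_centroids = R_NilValue) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1 || k > n) stop("k must be between 1 and nrow(X)");

  std::vector<int> best_labels(n);
  std::vector<std::vector<double>> best_cen(k, std::vector<double>(d));
  double best_cost = R_PosInf;
  int best_iter = 0, best_init = 0, total_reseeds = 0;

  const bool fixed_init = init_centroids.isNotNull();
  NumericMatrix init_mat;
  if (fixed_init) {
    init_mat = NumericMatrix(init_centroids);
    if (init_mat.nrow() != k || init_mat.ncol() != d)
      stop("init_centroids must be k x ncol(X)");
    n_init = 1;
  }

  std::vector<std::vector<double>> cen(k, std::vector<double>(d));
  std::vector<double> acc(n);
  std::vector<double> dmin(n);
  std::vector<int> labels(n), prev(n);
  std::vector<std::vector<int>> members(k);
  std::vector<double> buf;

  for (int init = 0; init < n_init; ++init) {
    if (fixed_init) {
      for (int c = 0; c < k; ++c)
        for (int j = 0; j < d; ++j) cen[c][j] = init_mat(c, j);
    } else {
      seed_centroids(X, k, cen);
    }
    std::fill(prev.begin(), prev.end(), -1);
    double cost = R_PosInf;
    int iter = 0;
    for (iter = 0; iter < max_iter; ++iter) {
      // assignment
      for (int c = 0; c < k; ++c) {
        dist_to_centroid(X, cen[c].data(), acc);
        if (c == 0) {
          for (int i = 0; i < n; ++i) { dmin[i] = acc[i]; labels[i] = 0; }
        } else {
          for (int i = 0; i < n; ++i)
            if (acc[i] < dmin[i]) { dmin[i] = acc[i]; labels[i] = c; }
        }
      }
      // empty-cluster repair: reseed at the point farthest from its centroid
      for (int c = 0; c < k; ++c) members[c].clear();
      for (int i = 0; i < n; ++i) members[labels[i]].push_back(i);
      for (int c = 0; c < k; ++c) {
        if (!members[c].empty()) continue;
        int far = 0; double fd = -1.0;
        for (int i = 0; i < n; ++i)
          if (members[labels[i]].size() > 1 && dmin[i] > fd) {
            fd = dmin[i]; far = i;
          }
        std::vector<int>& old_m = members[labels[far]];
        old_m.erase(std::find(old_m.begin(), old_m.end(), far));
        labels[far] = c;
        dmin[far] = 0.0;
        members[c].push_back(far);
        for (int j = 0; j < d; ++j) cen[c][j] = X(far, j);
        ++total_reseeds;
      }
      cost = 0.0;
      for (int i = 0; i < n; ++i) cost += dmin[i];
      if (labels == prev) break;
      prev = labels;
      // median update
      for (int c = 0; c < k; ++c) {
        const std::vector<int>& m = members[c];
        if (m.empty()) continue;
        buf.resize(m.size());
        for (int j = 0; j < d; ++j) {
          const double* col = &X(0, j);
          for (size_t t = 0; t < m.size(); ++t) buf[t] = col[m[t]];
          cen[c][j] = buf_median(buf);
        }
      }
    }
    if (cost < best_cost) {
      best_cost = cost;
      best_labels = labels;
      best_cen = cen;
      best_iter = iter + 1;
      best_init = init + 1;
    }
  }

  IntegerVector out_labels(n);
  for (int i = 0; i < n; ++i) out_labels[i] = best_labels[i] + 1;
  NumericMatrix out_cen(k, d);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < d; ++j) out_cen(c, j) = best_cen[c][j];
  return List::create(_["labels"] = out_labels,
                      _["centroids"] = out_cen,
                      _["cost"] = best_cost,
                      _["iterations"] = best_iter,
                      _["best_init"] = best_init,
                      _["n_reseeds"] = total_reseeds);
}

// Pairwise L1 distances between columns of Xt (variables x points layout,
// so each point is a contiguous column).
// [[Rcpp::export(name = ".pairwise_l1_cpp")]]
NumericMatrix pairwise_l1_cpp(NumericMatrix Xt) {
  const int d = Xt.nrow(), n = Xt.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xt(0, i);
    for (int j = i + 1; j < n; ++j) {
      const double* xj = &Xt(0, j);
      double s = 0.0;
      for (int l = 0; l < d; ++l) s += std::fabs(xi[l] - xj[l]);
      D(i, j) = s;
      D(j, i) = s;
    }
  }
  return D;
}
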
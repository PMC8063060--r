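#include <Rcpp.h>
using namespace Rcpp;

// Deterministic PAM (k-medoids): BUILD then SWAP on a full dissimilarity
// matrix. All ties are broken toward the lowest index so that repeated runs
// on identical input give identical output. Labels are 1..k in order of the
// sorted medoid indices.

static double total_cost(const NumericMatrix &d, const std::vector<int> &med,
                         int n) {
  double cost = 0.0;
  for (int j = 0; j < n; ++j) {
    double best = R_PosInf;
    for (size_t m = 0; m < med.size(); ++m) {
      double v = d(j, med[m]);
      if (v < best) best = v;
    }
    cost += best;
  }
  return cost;
}

// [[Rcpp::export(name = ".pam_cpp")]]
List pam_cpp(NumericMatrix d, int k) {
  const int n = d.nrow();
  std::vector<int> med;
  med.reserve(k);
  std::vector<bool> is_med(n, false);

  // BUILD: first medoid minimizes row sums; each next maximizes cost decrease
  {
    double best = R_PosInf;
    int best_i = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += d(j, i);
      if (s < best - 1e-12) { best = s; best_i = i; }
    }
    med.push_back(best_i);
    is_med[best_i] = true;
  }
  std::vector<double> dnear(n);
  for (int j = 0; j < n; ++j) dnear[j] = d(j, med[0]);
  while ((int)med.size() < k) {
    double best_gain = -1.0;
    int best_c = -1;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double gain = 0.0;
      for (int j = 0; j < n; ++j) {
        double diff = dnear[j] - d(j, c);
        if (diff > 0) gain += diff;
      }
      if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
    }
    med.push_back(best_c);
    is_med[best_c] = true;
    for (int j = 0; j < n; ++j)
      if (d(j, best_c) < dnear[j]) dnear[j] = d(j, best_c);
  }

  // SWAP: replace one medoid by one non-medoid while any swap lowers cost.
  // For each candidate h the deltas for removing every medoid are accumulated
  // in a single pass over the items (FastPAM1-style), giving O(n^2) per
  // iteration; the chosen swap is identical to the exhaustive search.
  if (k < n) {
    std::vector<double> d1(n), d2(n);   // nearest / second-nearest medoid dist
    std::vector<int> n1(n);             // index into med of nearest medoid
    std::vector<double> dm(k);
    bool improved = true;
    while (improved) {
      improved = false;
      for (int j = 0; j < n; ++j) {
        double b1 = R_PosInf, b2 = R_PosInf;
        int bi = 0;
        for (size_t m = 0; m < med.size(); ++m) {
          double v = d(j, med[m]);
          if (v < b1) { b2 = b1; b1 = v; bi = (int)m; }
          else if (v < b2) b2 = v;
        }
        d1[j] = b1; d2[j] = b2; n1[j] = bi;
      }
      double best_delta = -1e-12;
      int best_m = -1, best_h = -1;
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        // s: shared gain over items whose nearest medoid is kept;
        // dm[m]: correction for items losing medoid m
        double s = 0.0;
        std::fill(dm.begin(), dm.end(), 0.0);
        for (int j = 0; j < n; ++j) {
          double djh = d(j, h);
          double gain = djh - d1[j];
          if (gain < 0) s += gain;
          int m = n1[j];
          double repl = (djh < d2[j] ? djh : d2[j]) - d1[j];
          dm[m] += repl - (gain < 0 ? gain : 0.0);
        }
        for (int m = 0; m < k; ++m) {
          double delta = s + dm[m];
          if (delta < best_delta) { best_delta = delta; best_m = m; best_h = h; }
        }
      }
      if (best_m >= 0) {
        is_med[med[best_m]] = false;
        med[best_m] = best_h;
        is_med[best_h] = true;
        improved = true;
      }
    }
  }

  std::sort(med.begin(), med.end());
  IntegerVector medoids(k), labels(n);
  for (int m = 0; m < k; ++m) medoids[m] = med[m] + 1;
  for (int j = 0; j < n; ++j) {
    double best = R_PosInf;
    int bi = 0;
    for (int m = 0; m < k; ++m) {
      double v = d(j, med[m]);
      if (v < best - 1e-15) { best = v; bi = m; }
    }
    labels[j] = bi + 1;
  }
  return List::create(_["medoids"] = medoids, _["labels"] = labels,
                      _["cost"] = total_cost(d, med, n));
}
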
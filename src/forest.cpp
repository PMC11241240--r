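// Random forest classifier used by the ligand-function pipeline.
//
// Configuration mirrors the conventional scikit-learn-style classifier:
// Gini splits, a random subset of mtry features per node, optional depth cap,
// min_samples_split / min_samples_leaf, per-class sample weights, no
// bootstrap resampling (every tree sees all rows; randomness comes from the
// feature subsets), and probability averaging across trees at predict time.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;          // -1 = leaf
  double threshold = 0.0;    // go left if x <= threshold
  int left = -1, right = -1;
  std::vector<double> probs; // class distribution (leaves only)
};

struct BuildTask {
  int node;
  std::vector<int> idx;
  int depth;
};

std::vector<double> class_probs(const std::vector<int>& idx,
                                const IntegerVector& y,
                                const std::vector<double>& w, int K) {
  std::vector<double> p(K, 0.0);
  double tot = 0.0;
  for (int i : idx) {
    p[y[i]] += w[y[i]];
    tot += w[y[i]];
  }
  if (tot > 0) for (int k = 0; k < K; ++k) p[k] /= tot;
  return p;
}

bool is_pure(const std::vector<int>& idx, const IntegerVector& y) {
  for (size_t i = 1; i < idx.size(); ++i)
    if (y[idx[i]] != y[idx[0]]) return false;
  return true;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                NumericVector class_weights, int n_trees, int mtry,
                int max_depth, int min_split, int min_leaf, int seed) {
  const int n = X.nrow(), p = X.ncol(), K = n_classes;
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<double> w(class_weights.begin(), class_weights.end());

  List forest(n_trees);
  std::vector<int> feat_pool(p);
  std::iota(feat_pool.begin(), feat_pool.end(), 0);

  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng(static_cast<unsigned>(seed) * 2654435761u + t);
    std::vector<Node> nodes;
    nodes.emplace_back();
    std::vector<BuildTask> stack;
    std::vector<int> all(n);
    std::iota(all.begin(), all.end(), 0);
    stack.push_back({0, std::move(all), 0});

    while (!stack.empty()) {
      BuildTask task = std::move(stack.back());
      stack.pop_back();
      std::vector<int>& idx = task.idx;
      Node& nd = nodes[task.node];

      bool stop = (int)idx.size() < min_split ||
                  (max_depth > 0 && task.depth >= max_depth) ||
                  is_pure(idx, y);
      int best_f = -1;
      double best_thr = 0.0, best_gain = -1.0;
      if (!stop) {
        // weighted class totals of the node
        std::vector<double> tot(K, 0.0);
        double W = 0.0;
        for (int i : idx) { tot[y[i]] += w[y[i]]; W += w[y[i]]; }
        double parent_sq = 0.0;
        for (int k = 0; k < K; ++k) parent_sq += tot[k] * tot[k];
        const double parent_score = parent_sq / W;

        // sample mtry features without replacement
        for (int m = 0; m < mtry; ++m) {
          std::uniform_int_distribution<int> pick(m, p - 1);
          std::swap(feat_pool[m], feat_pool[pick(rng)]);
        }
        std::vector<std::pair<double, int>> vals(idx.size());
        for (int m = 0; m < mtry; ++m) {
          const int f = feat_pool[m];
          for (size_t i = 0; i < idx.size(); ++i)
            vals[i] = {X(idx[i], f), idx[i]};
          std::sort(vals.begin(), vals.end());
          std::vector<double> left(K, 0.0);
          double WL = 0.0;
          int nl = 0;
          const int ntot = (int)vals.size();
          for (int i = 0; i + 1 < ntot; ++i) {
            const int yi = y[vals[i].second];
            left[yi] += w[yi];
            WL += w[yi];
            ++nl;
            if (vals[i].first == vals[i + 1].first) continue;
            if (nl < min_leaf || ntot - nl < min_leaf) continue;
            double lsq = 0.0, rsq = 0.0;
            for (int k = 0; k < K; ++k) {
              lsq += left[k] * left[k];
              const double r = tot[k] - left[k];
              rsq += r * r;
            }
            const double score = lsq / WL + rsq / (W - WL);
            const double gain = score - parent_score;
            if (gain > best_gain + 1e-12) {
              best_gain = gain;
              best_f = f;
              best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
            }
          }
        }
        if (best_f < 0 || best_gain <= 1e-12) stop = true;
      }

      if (stop) {
        nd.feature = -1;
        nd.probs = class_probs(idx, y, w, K);
        continue;
      }
      std::vector<int> li, ri;
      for (int i : idx) {
        if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
      }
      nd.feature = best_f;
      nd.threshold = best_thr;
      const int l = (int)nodes.size();
      nodes.emplace_back();
      const int r = (int)nodes.size();
      nodes.emplace_back();
      nodes[task.node].left = l;
      nodes[task.node].right = r;
      stack.push_back({l, std::move(li), task.depth + 1});
      stack.push_back({r, std::move(ri), task.depth + 1});
    }

    const int nn = (int)nodes.size();
    IntegerVector feature(nn), left(nn), right(nn);
    NumericVector threshold(nn);
    NumericMatrix probs(nn, K);
    for (int i = 0; i < nn; ++i) {
      feature[i] = nodes[i].feature;
      threshold[i] = nodes[i].threshold;
      left[i] = nodes[i].left;
      right[i] = nodes[i].right;
      if (nodes[i].feature < 0)
        for (int k = 0; k < K; ++k) probs(i, k) = nodes[i].probs[k];
    }
    forest[t] = List::create(_["feature"] = feature,
                             _["threshold"] = threshold,
                             _["left"] = left, _["right"] = right,
                             _["probs"] = probs);
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix X, int n_classes) {
  const int n = X.nrow(), K = n_classes, T = forest.size();
  NumericMatrix out(n, K);
  for (int t = 0; t < T; ++t) {
    List tree = forest[t];
    IntegerVector feature = tree["feature"];
    NumericVector threshold = tree["threshold"];
    IntegerVector left = tree["left"], right = tree["right"];
    NumericMatrix probs = tree["probs"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      for (int k = 0; k < K; ++k) out(i, k) += probs(node, k);
    }
  }
  if (T > 0) for (int i = 0; i < n; ++i) for (int k = 0; k < K; ++k) out(i, k) /= T;
  return out;
}
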
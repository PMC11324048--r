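// Exact path-dependent Shapley attribution for tree ensembles.
//
// Polynomial-time algorithm tracking, along each root-to-leaf path, the
// proportion of feature-subset permutations that flow to the leaf when a
// path feature is present (one_fraction) or absent (zero_fraction,
// cover-weighted). Working precision is double throughout so the
// additivity identity base + sum(phi) = margin holds to ~1e-12.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; i--) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1.0) / (unique_depth + 1.0);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / (unique_depth + 1.0);
  }
}

static void unwind_path(PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1.0) /
                               ((i + 1.0) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                               (unique_depth - i) / (unique_depth + 1.0);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1.0)) /
                               (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *unique_path,
                               int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1.0) /
                         ((i + 1.0) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight -
                         tmp * zero_fraction *
                             ((unique_depth - i) / (unique_depth + 1.0));
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / (unique_depth + 1.0));
    }
  }
  return total;
}

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<int> left, right;
  std::vector<double> threshold, value, cover;
};

static void tree_shap_recursive(const Tree &tr, const double *x, double *phi,
                                int node, int unique_depth,
                                PathElement *parent_unique_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tr.feature[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * tr.value[node];
    }
    return;
  }

  const int split_feature = tr.feature[node];
  // feature values are stored in float32 by the boosting library; compare
  // in that precision so boundary samples take the same branch
  const int hot = ((float)x[split_feature] < (float)tr.threshold[node])
                      ? tr.left[node] : tr.right[node];
  const int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  const double w = tr.cover[node];
  const double hot_zero_fraction = tr.cover[hot] / w;
  const double cold_zero_fraction = tr.cover[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tr, x, phi, hot, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tr, x, phi, cold, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0,
                      split_feature);
}

static int tree_max_depth(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return 1;
  return 1 + std::max(tree_max_depth(tr, tr.left[node]),
                      tree_max_depth(tr, tr.right[node]));
}

static double tree_expected(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  const double cl = tr.cover[tr.left[node]];
  const double cr = tr.cover[tr.right[node]];
  return (cl * tree_expected(tr, tr.left[node]) +
          cr * tree_expected(tr, tr.right[node])) / (cl + cr);
}

static double tree_margin(const Tree &tr, const double *x) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    node = ((float)x[tr.feature[node]] < (float)tr.threshold[node])
               ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

static Tree as_tree(const List &t) {
  Tree tr;
  tr.feature = as<std::vector<int> >(t["feature"]);
  tr.left = as<std::vector<int> >(t["left"]);
  tr.right = as<std::vector<int> >(t["right"]);
  tr.threshold = as<std::vector<double> >(t["threshold"]);
  tr.value = as<std::vector<double> >(t["value"]);
  tr.cover = as<std::vector<double> >(t["cover"]);
  return tr;
}

// [[Rcpp::export]]
List treeshap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericMatrix phi(n, p);
  NumericVector margin(n);
  double expected = 0.0;

  std::vector<Tree> parsed(ntree);
  int maxd = 1;
  for (int t = 0; t < ntree; ++t) {
    parsed[t] = as_tree(trees[t]);
    maxd = std::max(maxd, tree_max_depth(parsed[t], 0));
    expected += tree_expected(parsed[t], 0);
  }

  std::vector<PathElement> arena((maxd + 2) * (maxd + 2));
  std::vector<double> xrow(p), phirow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(phirow.begin(), phirow.end(), 0.0);
    double m = 0.0;
    for (int t = 0; t < ntree; ++t) {
      tree_shap_recursive(parsed[t], xrow.data(), phirow.data(), 0, 0,
                          arena.data(), 1.0, 1.0, -1);
      m += tree_margin(parsed[t], xrow.data());
    }
    for (int j = 0; j < p; ++j) phi(i, j) = phirow[j];
    margin[i] = m;
  }
  return List::create(_["contributions"] = phi, _["expected"] = expected,
                      _["margin"] = margin);
}
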
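// Exact path-dependent Shapley values for tree ensembles (polynomial
// TreeSHAP). The value function v(S) is the tree-walk expectation: at a
// split whose feature is in S the branch the instance takes is followed,
// otherwise both children are averaged with their cover fractions. The
// algorithm keeps, along each root-to-leaf path, the polynomial of subset
// weights for every feature on the path (EXTEND/UNWIND recursions), giving
// exact Shapley values in O(leaves * depth^2) per instance. The ensemble
// attribution is the sum over trees; the base value is v(empty).

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Tree {
  IntegerVector left, right, feature;
  NumericVector threshold, value, cover;
  int cmp; // 0: go left when x < thr (xgboost), 1: when x <= thr (randomForest)
};

struct PathElem {
  int d;        // feature of this path element (-1 for the root placeholder)
  double z;     // fraction of zero (unconditioned) paths flowing through
  double o;     // fraction of one (conditioned) paths flowing through
  double w;     // subset weight polynomial coefficient
};

void extend_path(std::vector<PathElem>& m, double pz, double po, int pi) {
  int l = m.size();
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1.0) / (l + 1.0);
    m[i].w = pz * m[i].w * (l - i) / (l + 1.0);
  }
}

std::vector<PathElem> unwind_path(const std::vector<PathElem>& m, int i) {
  int l = m.size() - 1;           // index of last element
  std::vector<PathElem> out(m.begin(), m.end() - 1);
  double n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (m[i].o != 0) {
      double t = out[j].w;
      out[j].w = n * (l + 1.0) / ((j + 1.0) * m[i].o);
      n = t - out[j].w * m[i].z * (l - j) / (l + 1.0);
    } else {
      out[j].w = out[j].w * (l + 1.0) / (m[i].z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    out[j].d = m[j + 1].d;
    out[j].z = m[j + 1].z;
    out[j].o = m[j + 1].o;
  }
  return out;
}

double unwound_sum(const std::vector<PathElem>& m, int i) {
  int l = m.size() - 1;
  double total = 0.0, n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (m[i].o != 0) {
      double t = n * (l + 1.0) / ((j + 1.0) * m[i].o);
      total += t;
      n = m[j].w - t * m[i].z * (l - j) / (l + 1.0);
    } else {
      total += m[j].w * (l + 1.0) / (m[i].z * (l - j));
    }
  }
  return total;
}

void tree_recurse(const Tree& tr, const NumericMatrix& X, int row,
                  std::vector<double>& phi, int node,
                  std::vector<PathElem> m, double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  if (tr.feature[node] < 0) { // leaf
    for (int i = 1; i < (int)m.size(); ++i) {
      double w = unwound_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * tr.value[node];
    }
    return;
  }
  int f = tr.feature[node];
  double x = X(row, f);
  bool goes_left = tr.cmp == 1 ? (x <= tr.threshold[node])
                               : (x < tr.threshold[node]);
  int hot = goes_left ? tr.left[node] : tr.right[node];
  int cold = goes_left ? tr.right[node] : tr.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < (int)m.size(); ++i)
    if (m[i].d == f) { k = i; break; }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    m = unwind_path(m, k);
  }
  double rj = tr.cover[node];
  tree_recurse(tr, X, row, phi, hot, m, iz * tr.cover[hot] / rj, io, f);
  tree_recurse(tr, X, row, phi, cold, m, iz * tr.cover[cold] / rj, 0.0, f);
}

double expected_value(const Tree& tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  double rj = tr.cover[node];
  return tr.cover[tr.left[node]] / rj * expected_value(tr, tr.left[node]) +
         tr.cover[tr.right[node]] / rj * expected_value(tr, tr.right[node]);
}

} // namespace

// [[Rcpp::export]]
List treeshap_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  double base = 0.0;
  for (int tix = 0; tix < trees.size(); ++tix) {
    List tl = trees[tix];
    Tree tr{tl["left"], tl["right"], tl["feature"], tl["threshold"],
            tl["value"], tl["cover"], as<int>(tl["cmp"])};
    base += expected_value(tr, 0);
    for (int i = 0; i < n; ++i) {
      std::vector<double> ph(p, 0.0);
      tree_recurse(tr, X, i, ph, 0, {}, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += ph[j];
    }
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
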
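#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <stack>
using namespace Rcpp;

// CART regression trees grown by variance-reduction splits. Every feature is
// a candidate at every split (no mtry subsampling); randomness enters only
// through the bootstrap row indices supplied from R, so all RNG stays under
// R's seed control.

struct TreeBuf {
  std::vector<int> var, left, right;
  std::vector<double> split, value;
  int add_node() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    split.push_back(0.0); value.push_back(0.0);
    return (int)var.size() - 1;
  }
};

struct Task {
  int node;
  int depth;
  std::vector<int> rows;
};

static void grow_tree(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int> rows, int min_split, int max_depth,
                      TreeBuf& T) {
  const int p = X.ncol();
  std::stack<Task> st;
  int root = T.add_node();
  st.push(Task{root, 0, std::move(rows)});

  while (!st.empty()) {
    Task task = std::move(st.top());
    st.pop();
    const std::vector<int>& r = task.rows;
    const int n = (int)r.size();

    double sum = 0.0, sumsq = 0.0;
    for (int i = 0; i < n; ++i) { sum += y[r[i]]; sumsq += y[r[i]] * y[r[i]]; }
    const double mean = sum / n;
    T.value[task.node] = mean;
    const double sse = sumsq - sum * mean;

    bool leaf = n < min_split || sse <= 1e-12 ||
                (max_depth > 0 && task.depth >= max_depth);
    int best_var = -1;
    double best_split = 0.0, best_score = sum * sum / n;
    std::vector<int> bestL, bestR;

    if (!leaf) {
      std::vector<std::pair<double, double> > xy(n);  // (x, y) within node
      for (int j = 0; j < p; ++j) {
        const double* xj = &X(0, j);
        for (int i = 0; i < n; ++i) xy[i] = {xj[r[i]], y[r[i]]};
        std::stable_sort(xy.begin(), xy.end(),
                         [](const std::pair<double, double>& a,
                            const std::pair<double, double>& b) {
                           return a.first < b.first;
                         });
        double sL = 0.0;
        for (int i = 0; i < n - 1; ++i) {
          sL += xy[i].second;
          if (xy[i].first >= xy[i + 1].first) continue;  // tied x values
          const int nL = i + 1, nR = n - nL;
          const double sR = sum - sL;
          const double score = sL * sL / nL + sR * sR / nR;
          if (score > best_score + 1e-12) {  // strict: first (j, split) wins ties
            best_score = score;
            best_var = j;
            best_split = (xy[i].first + xy[i + 1].first) / 2.0;
          }
        }
      }
      if (best_var >= 0) {
        bestL.reserve(n); bestR.reserve(n);
        for (int i = 0; i < n; ++i) {
          if (X(r[i], best_var) <= best_split) bestL.push_back(r[i]);
          else bestR.push_back(r[i]);
        }
        if (bestL.empty() || bestR.empty()) best_var = -1;  // degenerate
      }
    }

    if (best_var < 0) {
      T.var[task.node] = -1;  // leaf
      continue;
    }
    T.var[task.node] = best_var;
    T.split[task.node] = best_split;
    int nl = T.add_node(), nr = T.add_node();
    T.left[task.node] = nl;
    T.right[task.node] = nr;
    st.push(Task{nl, task.depth + 1, std::move(bestL)});
    st.push(Task{nr, task.depth + 1, std::move(bestR)});
  }
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, IntegerMatrix boot,
                     int min_split, int max_depth) {
  const int ntrees = boot.nrow();
  List forest(ntrees);
  for (int t = 0; t < ntrees; ++t) {
    std::vector<int> rows(boot.ncol());
    for (int i = 0; i < boot.ncol(); ++i) rows[i] = boot(t, i) - 1;  // 1-based
    TreeBuf T;
    grow_tree(X, y, std::move(rows), min_split, max_depth, T);
    forest[t] = List::create(
        _["var"] = IntegerVector(T.var.begin(), T.var.end()),
        _["split"] = NumericVector(T.split.begin(), T.split.end()),
        _["left"] = IntegerVector(T.left.begin(), T.left.end()),
        _["right"] = IntegerVector(T.right.begin(), T.right.end()),
        _["value"] = NumericVector(T.value.begin(), T.value.end()));
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int ntrees = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntrees; ++t) {
    List tree = forest[t];
    IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
    NumericVector split = tree["split"], value = tree["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (var[node] >= 0)
        node = (X(i, var[node]) <= split[node]) ? left[node] : right[node];
      out[i] += value[node];
    }
  }
  return out / (double)ntrees;
}
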
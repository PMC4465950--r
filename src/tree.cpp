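#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Standardized two-group log-rank statistic over the node's subjects.
// ord: subject indices sorted by ascending follow-up time; grp flags
// membership in group 1. Returns NA when the summed hypergeometric
// variance is (numerically) zero -- the "no information" sentinel.
static double logrank_stat(const std::vector<int>& ord,
                           const double* time, const double* status,
                           const std::vector<char>& grp) {
  double Y = static_cast<double>(ord.size());
  double Y1 = 0.0;
  for (int i : ord) if (grp[i]) Y1 += 1.0;
  double OE = 0.0, V = 0.0;
  std::size_t i = 0, n = ord.size();
  while (i < n) {
    double t = time[ord[i]];
    double d = 0.0, d1 = 0.0, m = 0.0, m1 = 0.0;
    std::size_t j = i;
    while (j < n && time[ord[j]] == t) {
      m += 1.0;
      if (grp[ord[j]]) m1 += 1.0;
      if (status[ord[j]] == 1.0) {
        d += 1.0;
        if (grp[ord[j]]) d1 += 1.0;
      }
      ++j;
    }
    if (d > 0.0) {
      OE += d1 - d * Y1 / Y;
      if (Y > 1.0)
        V += d * (Y1 / Y) * (1.0 - Y1 / Y) * (Y - d) / (Y - 1.0);
    }
    Y -= m;
    Y1 -= m1;
    i = j;
  }
  if (V <= 1e-12) return NA_REAL;
  return OE / std::sqrt(V);
}

// [[Rcpp::export]]
double cpp_logrank_split_stat(NumericVector time, NumericVector status,
                              IntegerVector membership) {
  int n = time.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  std::vector<char> grp(n);
  for (int i = 0; i < n; ++i) grp[i] = membership[i] != 0;
  return logrank_stat(ord, REAL(time), REAL(status), grp);
}

struct BestSplit {
  int var = -1;
  double thresh = NA_REAL;
  double stat = -1.0;  // |log-rank|; admissible splits have stat >= 0
};

// Exhaustive scan over all variables and midpoint thresholds; splits
// send x[var] <= thresh left. Ties broken toward the earliest variable
// and smallest threshold (strict improvement required).
//
// The node's risk tables are pre-binned on its distinct event times:
// each subject carries a removal bin (last event time it is at risk
// for; censored subjects tied with an event time stay at risk there)
// and, for events, its event bin. Sweeping thresholds in ascending
// covariate order then only moves subjects into the left group
// incrementally, and each candidate evaluation is a single pass over
// the event-time bins rather than over all subjects.
static BestSplit find_best_split(const std::vector<int>& rows,
                                 const NumericMatrix& X,
                                 const double* time, const double* status,
                                 int min_node) {
  BestSplit best;
  int n_node = static_cast<int>(rows.size());

  std::vector<double> etime;
  for (int r : rows)
    if (status[r] == 1.0) etime.push_back(time[r]);
  std::sort(etime.begin(), etime.end());
  etime.erase(std::unique(etime.begin(), etime.end()), etime.end());
  int T = static_cast<int>(etime.size());
  if (T == 0) return best;

  // per local subject: removal bin (-1 = never at risk at an event
  // time) and event bin (-1 for censored)
  std::vector<int> rem_bin(n_node), ev_bin(n_node, -1);
  std::vector<double> d_tot(T, 0.0), m_rem(T, 0.0);
  double Y0 = 0.0;
  for (int i = 0; i < n_node; ++i) {
    int r = rows[i];
    int b = static_cast<int>(
        std::upper_bound(etime.begin(), etime.end(), time[r]) -
        etime.begin()) - 1;
    rem_bin[i] = b;
    if (b >= 0) {
      Y0 += 1.0;
      m_rem[b] += 1.0;
    }
    if (status[r] == 1.0) {
      ev_bin[i] = b;  // an event's time is one of the bins
      d_tot[b] += 1.0;
    }
  }

  std::vector<double> d1(T), m1_rem(T);
  std::vector<std::pair<double, int>> vals(n_node);  // (x value, local idx)
  for (int v = 0; v < X.ncol(); ++v) {
    for (int i = 0; i < n_node; ++i)
      vals[i] = std::make_pair(X(rows[i], v), i);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;  // constant
    std::fill(d1.begin(), d1.end(), 0.0);
    std::fill(m1_rem.begin(), m1_rem.end(), 0.0);
    double Y1_0 = 0.0;
    int i = 0;
    while (i < n_node) {
      double xv = vals[i].first;
      int j = i;
      while (j < n_node && vals[j].first == xv) {
        int li = vals[j].second;  // subject moves into the left child
        if (rem_bin[li] >= 0) {
          Y1_0 += 1.0;
          m1_rem[rem_bin[li]] += 1.0;
        }
        if (ev_bin[li] >= 0) d1[ev_bin[li]] += 1.0;
        ++j;
      }
      if (j >= n_node) break;  // no right child remains
      if (j >= min_node && n_node - j >= min_node) {
        double Y = Y0, Y1 = Y1_0, OE = 0.0, V = 0.0;
        for (int b = 0; b < T; ++b) {
          double d = d_tot[b];
          OE += d1[b] - d * Y1 / Y;
          if (Y > 1.0)
            V += d * (Y1 / Y) * (1.0 - Y1 / Y) * (Y - d) / (Y - 1.0);
          Y -= m_rem[b];
          Y1 -= m1_rem[b];
        }
        if (V > 1e-12) {
          double s = std::fabs(OE / std::sqrt(V));
          if (s > best.stat) {
            best.stat = s;
            best.var = v;
            best.thresh = (xv + vals[j].first) / 2.0;
          }
        }
      }
      i = j;
    }
  }
  return best;
}

// Nelson-Aalen CHF of the given subjects, evaluated on grid (sorted
// ascending): CHF(t) = sum_{event times u <= t} d(u) / Y(u).
static std::vector<double> nelson_aalen(const std::vector<int>& rows,
                                        const double* time,
                                        const double* status,
                                        const NumericVector& grid) {
  std::vector<int> ord(rows);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  std::vector<double> u;   // distinct event times
  std::vector<double> inc; // d(u)/Y(u)
  double Y = static_cast<double>(ord.size());
  std::size_t i = 0, n = ord.size();
  while (i < n) {
    double t = time[ord[i]];
    double d = 0.0, m = 0.0;
    std::size_t j = i;
    while (j < n && time[ord[j]] == t) {
      m += 1.0;
      if (status[ord[j]] == 1.0) d += 1.0;
      ++j;
    }
    if (d > 0.0) {
      u.push_back(t);
      inc.push_back(d / Y);
    }
    Y -= m;
    i = j;
  }
  std::vector<double> chf(grid.size());
  double acc = 0.0;
  std::size_t k = 0;
  for (int g = 0; g < grid.size(); ++g) {
    while (k < u.size() && u[k] <= grid[g]) acc += inc[k++];
    chf[g] = acc;
  }
  return chf;
}

// [[Rcpp::export]]
NumericVector cpp_nelson_aalen(NumericVector time, NumericVector status,
                               NumericVector grid) {
  int n = time.size();
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  std::vector<double> chf =
      nelson_aalen(rows, REAL(time), REAL(status), grid);
  return wrap(chf);
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericVector time, NumericVector status,
                    int min_node_size) {
  int n = X.nrow();
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  BestSplit bs =
      find_best_split(rows, X, REAL(time), REAL(status), min_node_size);
  return List::create(_["var"] = bs.var + 1, _["thresh"] = bs.thresh,
                      _["stat"] = bs.var < 0 ? NA_REAL : bs.stat);
}

// Grows a survival CART by greedy |log-rank| maximization. Returns a
// flat node table (0-based child indices, -1 = none) plus per-leaf
// Nelson-Aalen CHFs on the tree grid (the training data's distinct
// event times) and each training row's leaf assignment.
// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector time, NumericVector status,
                   int min_node_size) {
  int n = X.nrow();
  const double* tp = REAL(time);
  const double* sp = REAL(status);

  std::vector<double> gset;
  for (int i = 0; i < n; ++i)
    if (sp[i] == 1.0) gset.push_back(tp[i]);
  std::sort(gset.begin(), gset.end());
  gset.erase(std::unique(gset.begin(), gset.end()), gset.end());
  NumericVector grid = wrap(gset);

  std::vector<int> var, left, right, size;
  std::vector<double> thresh;
  std::vector<std::vector<double>> chfs;
  std::vector<int> leaf_of(n, -1);

  struct Task { std::vector<int> rows; int slot; };
  std::vector<Task> stack;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  stack.push_back({all, -1});
  // slot -1 means root; otherwise index into left/right to fill via sign
  std::vector<std::pair<int, bool>> pending; // (parent, is_left)
  pending.push_back({-1, false});

  while (!stack.empty()) {
    Task task = std::move(stack.back());
    stack.pop_back();
    std::pair<int, bool> link = pending.back();
    pending.pop_back();

    int id = static_cast<int>(var.size());
    var.push_back(-1);
    thresh.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    size.push_back(static_cast<int>(task.rows.size()));
    chfs.push_back(std::vector<double>());
    if (link.first >= 0) {
      if (link.second) left[link.first] = id; else right[link.first] = id;
    }

    int n_node = static_cast<int>(task.rows.size());
    int events = 0;
    for (int r : task.rows) if (sp[r] == 1.0) ++events;

    BestSplit bs;
    if (n_node >= 2 * min_node_size && events >= 1)
      bs = find_best_split(task.rows, X, tp, sp, min_node_size);

    if (bs.var < 0) {  // leaf
      chfs[id] = nelson_aalen(task.rows, tp, sp, grid);
      for (int r : task.rows) leaf_of[r] = id;
      continue;
    }
    var[id] = bs.var;
    thresh[id] = bs.thresh;
    std::vector<int> lrows, rrows;
    for (int r : task.rows) {
      if (X(r, bs.var) <= bs.thresh) lrows.push_back(r);
      else rrows.push_back(r);
    }
    // push right first so the left child is numbered first (preorder)
    stack.push_back({std::move(rrows), 0});
    pending.push_back({id, false});
    stack.push_back({std::move(lrows), 0});
    pending.push_back({id, true});
  }

  List chf_list(chfs.size());
  for (std::size_t i = 0; i < chfs.size(); ++i)
    chf_list[i] = wrap(chfs[i]);

  return List::create(
      _["var"] = wrap(var), _["thresh"] = wrap(thresh),
      _["left"] = wrap(left), _["right"] = wrap(right),
      _["size"] = wrap(size), _["chf"] = chf_list,
      _["grid"] = grid, _["leaf_of"] = wrap(leaf_of));
}

// Routes each row of X to its leaf; x <= thresh goes left.
// [[Rcpp::export]]
IntegerVector cpp_predict_leaf(IntegerVector var, NumericVector thresh,
                               IntegerVector left, IntegerVector right,
                               NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (var[node] >= 0) {
      node = (X(i, var[node]) <= thresh[node]) ? left[node] : right[node];
    }
    out[i] = node;
  }
  return out;
}
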
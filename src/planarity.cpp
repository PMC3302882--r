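// Left-right planarity test (de Fraysseix-Rosenstiehl criterion, iterative
// formulation after Brandes) and the greedy PMFG edge-selection loop.
//
// The test decides, for a simple undirected graph, whether a planar embedding
// exists. It orients the graph by DFS, computes low-points and a nesting
// order for the out-edges, and then checks that the return edges admit a
// consistent left/right partition, maintained as a stack of conflict pairs
// of intervals. Edges are integer ids; -1 plays the role of "none".

#include <Rcpp.h>
#include <algorithm>
#include <utility>
#include <vector>

namespace {

struct Interval {
  int lo = -1, hi = -1;
  bool empty() const { return lo == -1 && hi == -1; }
};

struct ConflictPair {
  Interval L, R;
};

class LRPlanarity {
 public:
  LRPlanarity(int n, const std::vector<std::pair<int, int> >& edges) : n_(n) {
    adj_.assign(n_, std::vector<std::pair<int, int> >());
    int m = static_cast<int>(edges.size());
    und_used_.assign(m, 0);
    for (int id = 0; id < m; ++id) {
      int u = edges[id].first, v = edges[id].second;
      adj_[u].push_back(std::make_pair(v, id));
      adj_[v].push_back(std::make_pair(u, id));
    }
    m_ = m;
  }

  bool run() {
    if (n_ > 2 && m_ > 3 * n_ - 6) return false;
    height_.assign(n_, -1);
    parent_edge_.assign(n_, -1);
    out_.assign(n_, std::vector<int>());
    esrc_.reserve(m_);
    for (int v = 0; v < n_; ++v) {
      if (height_[v] == -1) {
        height_[v] = 0;
        roots_.push_back(v);
        dfs_orient(v);
      }
    }
    // order out-edges by nesting depth (stable keeps creation order on ties)
    ordered_ = out_;
    for (int v = 0; v < n_; ++v) {
      std::stable_sort(ordered_[v].begin(), ordered_[v].end(),
                       [this](int a, int b) { return nest_[a] < nest_[b]; });
    }
    int ne = static_cast<int>(esrc_.size());
    stack_bottom_.assign(ne, 0);
    lowpt_edge_.assign(ne, -1);
    ref_.assign(ne, -1);
    side_.assign(ne, 1);
    S_.clear();
    for (size_t i = 0; i < roots_.size(); ++i)
      if (!dfs_test(roots_[i])) return false;
    return true;
  }

 private:
  int n_, m_;
  std::vector<std::vector<std::pair<int, int> > > adj_;
  std::vector<char> und_used_;
  std::vector<int> height_, parent_edge_, roots_;
  // oriented edges
  std::vector<int> esrc_, edst_, low_, low2_, nest_;
  std::vector<std::vector<int> > out_, ordered_;
  // testing state
  std::vector<ConflictPair> S_;
  std::vector<int> stack_bottom_, lowpt_edge_, ref_, side_;

  int new_edge(int v, int w) {
    esrc_.push_back(v);
    edst_.push_back(w);
    low_.push_back(height_[v]);
    low2_.push_back(height_[v]);
    nest_.push_back(0);
    int id = static_cast<int>(esrc_.size()) - 1;
    out_[v].push_back(id);
    return id;
  }

  void dfs_orient(int v) {
    int e = parent_edge_[v];
    for (size_t it = 0; it < adj_[v].size(); ++it) {
      int w = adj_[v][it].first, uid = adj_[v][it].second;
      if (und_used_[uid]) continue;
      und_used_[uid] = 1;
      int vw = new_edge(v, w);
      if (height_[w] == -1) {  // tree edge
        parent_edge_[w] = vw;
        height_[w] = height_[v] + 1;
        dfs_orient(w);
      } else {  // back edge
        low_[vw] = height_[w];
      }
      nest_[vw] = 2 * low_[vw] + (low2_[vw] < height_[v] ? 1 : 0);
      if (e != -1) {
        if (low_[vw] < low_[e]) {
          low2_[e] = std::min(low_[e], low2_[vw]);
          low_[e] = low_[vw];
        } else if (low_[vw] > low_[e]) {
          low2_[e] = std::min(low2_[e], low_[vw]);
        } else {
          low2_[e] = std::min(low2_[e], low2_[vw]);
        }
      }
    }
  }

  bool conflicting(const Interval& I, int b) const {
    return !I.empty() && I.hi != -1 && low_[I.hi] > low_[b];
  }

  int lowest(const ConflictPair& P) const {
    if (P.L.empty()) return low_[P.R.lo];
    if (P.R.empty()) return low_[P.L.lo];
    return std::min(low_[P.L.lo], low_[P.R.lo]);
  }

  bool dfs_test(int v) {
    int e = parent_edge_[v];
    for (size_t it = 0; it < ordered_[v].size(); ++it) {
      int ei = ordered_[v][it];
      int w = edst_[ei];
      stack_bottom_[ei] = static_cast<int>(S_.size());
      if (ei == parent_edge_[w]) {  // tree edge
        if (!dfs_test(w)) return false;
      } else {  // back edge
        lowpt_edge_[ei] = ei;
        ConflictPair P;
        P.R.lo = ei;
        P.R.hi = ei;
        S_.push_back(P);
      }
      if (low_[ei] < height_[v]) {  // ei has a return edge
        if (ei == ordered_[v][0]) {
          lowpt_edge_[e] = lowpt_edge_[ei];
        } else if (!add_constraints(ei, e)) {
          return false;
        }
      }
    }
    if (e != -1) remove_back_edges(e);
    return true;
  }

  bool add_constraints(int ei, int e) {
    ConflictPair P;
    // merge return edges of ei into P.R
    for (;;) {
      if (S_.empty()) return false;
      ConflictPair Q = S_.back();
      S_.pop_back();
      if (!Q.L.empty()) std::swap(Q.L, Q.R);
      if (!Q.L.empty()) return false;  // not planar
      if (low_[Q.R.lo] > low_[e]) {
        if (P.R.empty())
          P.R = Q.R;
        else
          ref_[P.R.lo] = Q.R.hi;
        P.R.lo = Q.R.lo;
      } else {  // align
        ref_[Q.R.lo] = lowpt_edge_[e];
      }
      if (static_cast<int>(S_.size()) == stack_bottom_[ei]) break;
    }
    // merge conflicting return edges of earlier siblings into P.L
    while (!S_.empty() &&
           (conflicting(S_.back().L, ei) || conflicting(S_.back().R, ei))) {
      ConflictPair Q = S_.back();
      S_.pop_back();
      if (conflicting(Q.R, ei)) std::swap(Q.L, Q.R);
      if (conflicting(Q.R, ei)) return false;  // not planar
      if (P.R.lo != -1) ref_[P.R.lo] = Q.R.hi;
      if (Q.R.lo != -1) P.R.lo = Q.R.lo;
      if (P.L.empty())
        P.L = Q.L;
      else
        ref_[P.L.lo] = Q.L.hi;
      P.L.lo = Q.L.lo;
    }
    if (!(P.L.empty() && P.R.empty())) S_.push_back(P);
    return true;
  }

  void remove_back_edges(int e) {
    int u = esrc_[e];
    // drop entire conflict pairs returning to u
    while (!S_.empty() && lowest(S_.back()) == height_[u]) {
      ConflictPair P = S_.back();
      S_.pop_back();
      if (P.L.lo != -1) side_[P.L.lo] = -1;
    }
    if (!S_.empty()) {  // trim one more conflict pair
      ConflictPair P = S_.back();
      S_.pop_back();
      while (P.L.hi != -1 && edst_[P.L.hi] == u) P.L.hi = ref_[P.L.hi];
      if (P.L.hi == -1 && P.L.lo != -1) {  // just emptied
        ref_[P.L.lo] = P.R.lo;
        side_[P.L.lo] = -1;
        P.L.lo = -1;
      }
      while (P.R.hi != -1 && edst_[P.R.hi] == u) P.R.hi = ref_[P.R.hi];
      if (P.R.hi == -1 && P.R.lo != -1) {  // just emptied
        ref_[P.R.lo] = P.L.lo;
        side_[P.R.lo] = -1;
        P.R.lo = -1;
      }
      S_.push_back(P);
    }
    if (low_[e] < height_[u] && !S_.empty()) {  // e has return edge
      int hl = S_.back().L.hi, hr = S_.back().R.hi;
      if (hl != -1 && (hr == -1 || low_[hl] > low_[hr]))
        ref_[e] = hl;
      else
        ref_[e] = hr;
    }
  }
};

bool lr_planar(int n, const std::vector<std::pair<int, int> >& edges) {
  if (n <= 2 || edges.size() <= 8) {
    // fewer than 9 edges cannot contain a K5 or K3,3 subdivision
    bool simple_small = true;
    for (size_t i = 0; i < edges.size() && simple_small; ++i)
      if (edges[i].first == edges[i].second) simple_small = false;
    if (simple_small) return true;
  }
  LRPlanarity st(n, edges);
  return st.run();
}

std::vector<std::pair<int, int> > as_pairs(const Rcpp::IntegerMatrix& edges) {
  std::vector<std::pair<int, int> > out;
  out.reserve(edges.nrow());
  for (int i = 0; i < edges.nrow(); ++i)
    out.push_back(std::make_pair(edges(i, 0) - 1, edges(i, 1) - 1));
  return out;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".lr_is_planar")]]
bool lr_is_planar_cpp(int n, Rcpp::IntegerMatrix edges) {
  std::vector<std::pair<int, int> > e = as_pairs(edges);
  for (size_t i = 0; i < e.size(); ++i) {
    if (e[i].first < 0 || e[i].second < 0 || e[i].first >= n ||
        e[i].second >= n)
      Rcpp::stop("edge endpoint out of range");
    if (e[i].first == e[i].second) Rcpp::stop("self-loops are not allowed");
  }
  return lr_planar(n, e);
}

// Greedy PMFG selection: candidates arrive already ranked (decreasing weight,
// ties pre-broken); an edge is kept iff the kept set plus the edge stays
// planar; the scan stops once 3(n-2) edges are accepted.
//' @noRd
// [[Rcpp::export(name = ".pmfg_select")]]
Rcpp::LogicalVector pmfg_select_cpp(int n, Rcpp::IntegerMatrix candidates) {
  std::vector<std::pair<int, int> > cand = as_pairs(candidates);
  int target = 3 * (n - 2);
  std::vector<std::pair<int, int> > kept;
  kept.reserve(target);
  Rcpp::LogicalVector sel(cand.size(), false);
  for (size_t i = 0; i < cand.size(); ++i) {
    if (static_cast<int>(kept.size()) >= target) break;
    kept.push_back(cand[i]);
    if (kept.size() > 8 && !lr_planar(n, kept)) {
      kept.pop_back();
    } else {
      sel[i] = true;
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return sel;
}
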
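// Exact branch-and-bound search for the canonical (minimal) labeling.
//
// The canonical form of a molecular graph is the lexicographically smallest
// serialized identifier over all labelings that respect element grouping
// (labels ascending by atomic number). The serialized key is the flattened
// edge-tuple stream -- pairs (a, b), a < b, sorted by (a, b) -- compared
// first, then the node-feature stream as (label, feature-rank) pairs.
//
// Element blocks are assigned from the heaviest down; labels within a block
// ascending. Blocks whose members bond only to heavier elements ("deferred",
// hydrogens in practice) are never branched over: their labels appear in no
// other row of the stream, so once the scaffold is placed their optimal
// internal order is forced by sorting.
//
// Prunings (all exact):
//  * admissible optimistic bound on the leading tuple stream;
//  * twin candidates (precomputed: interchangeable by a transposition or
//    pendant-matching automorphism);
//  * orbit pruning: automorphisms discovered from equal-key leaves; a
//    candidate in the orbit of an explored sibling (under generators fixing
//    all assigned atoms) heads a mirror-image subtree;
//  * backjumping: when a new automorphism proves an ancestor choice
//    equivalent to one of its explored siblings, the search unwinds to it.

#include <Rcpp.h>
#include <algorithm>
#include <utility>
#include <vector>

using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;
using Rcpp::List;
using Rcpp::LogicalVector;
using std::vector;

namespace {

typedef std::pair<int, int> Pair;

struct Frame {
  vector<int> assigned;  // nodes assigned before this level
  vector<int> tried;     // candidates already handled at this level
  int v;                 // candidate currently being explored
};

struct Search {
  int n, nb, maxgens;
  vector<vector<int> > adj;      // 0-based node ids
  vector<int> bid;               // node -> element block (0-based)
  vector<int> bstart, bsize;     // block b owns labels bstart[b]+1 .. +bsize[b]
  vector<vector<int> > members;  // block -> nodes
  vector<bool> deferred;
  vector<int> seqpos;            // structural labels in assignment order
  vector<int> spos_sorted;
  vector<int> stable;            // WL cell per node (exploration order only)
  vector<int> featrank;          // 0 = no features; else 1-based rank
  vector<bool> twin;             // n*n interchangeability matrix
  vector<Pair> edges;            // 0-based node pairs

  vector<int> lab;  // node -> label (0 unassigned)
  vector<int> pos;  // label-1 -> node (-1 unassigned)

  bool has_best;
  vector<int> bestflat, bestfeat, bestlab;
  vector<vector<int> > gens;
  vector<Frame> stack;
  int abort_depth;
  long long nodes_visited;

  // scratch buffers, reused across the search to avoid re-allocation
  vector<vector<int> > freeb_buf;
  vector<int> cnt_buf, row_buf, queue_buf;
  vector<vector<int> > rows_buf;
  vector<Pair> pair_buf;
  vector<bool> inorb_buf;

  void free_labels(int b, vector<int>* out) const {
    out->clear();
    for (int a = bstart[b] + 1; a <= bstart[b] + bsize[b]; ++a)
      if (pos[a - 1] < 0) out->push_back(a);
  }

  // row of a deferred-block member: labels of its (heavier) neighbors,
  // unassigned ones optimistically taking the smallest free labels of
  // their own blocks
  void member_row(int v, const vector<vector<int> >& freeb,
                  vector<int>* row, vector<int>* cnt) const {
    row->clear();
    std::fill(cnt->begin(), cnt->end(), 0);
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int u = adj[v][i];
      if (lab[u] > 0) {
        row->push_back(lab[u]);
      } else {
        row->push_back(freeb[bid[u]][(*cnt)[bid[u]]++]);
      }
    }
    std::sort(row->begin(), row->end());
  }

  // joint optimistic parent labels for a deferred block whose members all
  // have degree <= 1 (the common hydrogen case). Distinct unassigned
  // parents must occupy distinct labels; the stream over the block's rows
  // is minimized by giving parents with more children the smaller free
  // labels of their own block -- a true lower bound, tighter than treating
  // each row independently.
  bool pendant_rows(int b, const vector<vector<int> >& freeb,
                    vector<vector<int> >* rows) {
    const vector<int>& mem = members[b];
    rows->assign(mem.size(), vector<int>());
    vector<int> parent(mem.size(), -1);
    for (size_t i = 0; i < mem.size(); ++i) {
      if (adj[mem[i]].size() > 1) return false;
      if (!adj[mem[i]].empty()) parent[i] = adj[mem[i]][0];
    }
    // children count per unassigned parent
    vector<Pair> unp;  // (-children, parent)
    vector<int> optlab(n, 0);
    for (size_t i = 0; i < mem.size(); ++i) {
      int p = parent[i];
      if (p >= 0 && lab[p] == 0 && optlab[p] == 0) {
        int ch = 0;
        for (size_t j = 0; j < mem.size(); ++j) {
          if (parent[j] == p) ++ch;
        }
        unp.push_back(Pair(-ch, p));
        optlab[p] = -1;
      }
    }
    std::sort(unp.begin(), unp.end());
    std::fill(cnt_buf.begin(), cnt_buf.end(), 0);
    for (size_t i = 0; i < unp.size(); ++i) {
      int p = unp[i].second;
      optlab[p] = freeb[bid[p]][cnt_buf[bid[p]]++];
    }
    for (size_t i = 0; i < mem.size(); ++i) {
      int p = parent[i];
      if (p < 0) continue;
      (*rows)[i].push_back(lab[p] > 0 ? lab[p] : optlab[p]);
    }
    return true;
  }

  // rows ordered as they appear in the stream: elementwise, a longer row
  // beating its own prefix (tuples (a, .) continue before row a+1 starts)
  static bool row_less(const vector<int>& x, const vector<int>& y) {
    size_t k = std::min(x.size(), y.size());
    for (size_t i = 0; i < k; ++i) {
      if (x[i] != y[i]) return x[i] < y[i];
    }
    return x.size() > y.size();
  }

  // optimistic lower bound on the leading tuple stream of any completion,
  // truncated at the first unassigned structural label
  void bound_flat(vector<int>* flat) {
    int astop = n + 1;
    for (size_t i = 0; i < spos_sorted.size(); ++i) {
      if (pos[spos_sorted[i] - 1] < 0) { astop = spos_sorted[i]; break; }
    }
    for (int b = 0; b < nb; ++b) free_labels(b, &freeb_buf[b]);
    vector<Pair>& P = pair_buf;
    P.clear();
    for (int v = 0; v < n; ++v) {
      int a = lab[v];
      if (a == 0 || a >= astop) continue;
      int used = 0;
      for (size_t i = 0; i < adj[v].size(); ++i) {
        int u = adj[v][i];
        if (lab[u] > a) {
          P.push_back(Pair(a, lab[u]));
        } else if (lab[u] == 0 && bid[u] == bid[v]) {
          P.push_back(Pair(a, freeb_buf[bid[v]][used++]));
        }
      }
    }
    for (int b = 0; b < nb; ++b) {
      if (!deferred[b] || bstart[b] + 1 >= astop) continue;
      if (!pendant_rows(b, freeb_buf, &rows_buf)) {
        rows_buf.resize(members[b].size());
        for (size_t i = 0; i < members[b].size(); ++i) {
          member_row(members[b][i], freeb_buf, &row_buf, &cnt_buf);
          rows_buf[i] = row_buf;
        }
      }
      std::sort(rows_buf.begin(), rows_buf.end(), row_less);
      for (size_t j = 0; j < rows_buf.size(); ++j) {
        for (size_t i = 0; i < rows_buf[j].size(); ++i) {
          P.push_back(Pair(bstart[b] + 1 + static_cast<int>(j), rows_buf[j][i]));
        }
      }
    }
    std::sort(P.begin(), P.end());
    flat->clear();
    flat->reserve(P.size() * 2);
    for (size_t i = 0; i < P.size(); ++i) {
      flat->push_back(P[i].first);
      flat->push_back(P[i].second);
    }
  }

  bool bound_exceeds_best(const vector<int>& flat) const {
    if (!has_best) return false;
    size_t k = std::min(flat.size(), bestflat.size());
    for (size_t i = 0; i < k; ++i) {
      if (flat[i] != bestflat[i]) return flat[i] > bestflat[i];
    }
    return false;
  }

  // complete labeling: deferred blocks filled by sorting exact member rows,
  // ties resolved feature-bearing members first by ascending feature rank
  void complete_labels(vector<int>* labels) {
    *labels = lab;
    vector<vector<int> >& freeb = freeb_buf;
    for (int b = 0; b < nb; ++b) free_labels(b, &freeb[b]);
    vector<int>& cnt = cnt_buf;
    vector<int> row;
    for (int b = 0; b < nb; ++b) {
      if (!deferred[b]) continue;
      const vector<int>& mem = members[b];
      vector<std::pair<vector<int>, std::pair<Pair, int> > > keyed(mem.size());
      for (size_t i = 0; i < mem.size(); ++i) {
        member_row(mem[i], freeb, &row, &cnt);
        int fr = featrank[mem[i]];
        keyed[i].first = row;
        // feature-bearing first (0 before 1), then rank, then node id for
        // determinism among exact ties
        keyed[i].second = std::make_pair(Pair(fr == 0 ? 1 : 0, fr), mem[i]);
      }
      vector<int> ord(mem.size());
      for (size_t i = 0; i < ord.size(); ++i) ord[i] = static_cast<int>(i);
      std::sort(ord.begin(), ord.end(), [&](int x, int y) {
        if (keyed[x].first != keyed[y].first)
          return row_less(keyed[x].first, keyed[y].first);
        return keyed[x].second < keyed[y].second;
      });
      for (size_t j = 0; j < ord.size(); ++j) {
        (*labels)[mem[ord[j]]] = bstart[b] + 1 + static_cast<int>(j);
      }
    }
  }

  void full_key(const vector<int>& labels, vector<int>* eflat,
                vector<int>* fflat) const {
    vector<Pair> P(edges.size());
    for (size_t i = 0; i < edges.size(); ++i) {
      int a = labels[edges[i].first], b = labels[edges[i].second];
      P[i] = Pair(std::min(a, b), std::max(a, b));
    }
    std::sort(P.begin(), P.end());
    eflat->clear();
    for (size_t i = 0; i < P.size(); ++i) {
      eflat->push_back(P[i].first);
      eflat->push_back(P[i].second);
    }
    vector<Pair> F;
    for (int v = 0; v < n; ++v) {
      if (featrank[v] > 0) F.push_back(Pair(labels[v], featrank[v]));
    }
    std::sort(F.begin(), F.end());
    fflat->clear();
    for (size_t i = 0; i < F.size(); ++i) {
      fflat->push_back(F[i].first);
      fflat->push_back(F[i].second);
    }
  }

  void leaf() {
    vector<int> labels, eflat, fflat;
    complete_labels(&labels);
    full_key(labels, &eflat, &fflat);
    if (!has_best || eflat < bestflat ||
        (eflat == bestflat && fflat < bestfeat)) {
      has_best = true;
      bestflat = eflat;
      bestfeat = fflat;
      bestlab = labels;
      return;
    }
    if (eflat != bestflat || fflat != bestfeat) return;
    // identical serialization: the permutation relating the labelings is an
    // automorphism of the graph (edges, elements and features preserved)
    vector<int> inv(n), sigma(n), sigma_inv(n);
    for (int v = 0; v < n; ++v) inv[labels[v] - 1] = v;
    bool ident = true;
    for (int v = 0; v < n; ++v) {
      sigma[v] = inv[bestlab[v] - 1];
      if (sigma[v] != v) ident = false;
    }
    if (ident || static_cast<int>(gens.size()) >= maxgens) return;
    for (int v = 0; v < n; ++v) sigma_inv[sigma[v]] = v;
    gens.push_back(sigma);
    gens.push_back(sigma_inv);
    // backjump: find the shallowest ancestor whose current choice is now
    // provably equivalent to an explored sibling
    for (size_t d = 0; d < stack.size(); ++d) {
      if (in_orbit(stack[d].v, stack[d].tried, stack[d].assigned)) {
        abort_depth = static_cast<int>(d);
        break;
      }
    }
  }

  bool fixes_all(const vector<int>& sg, const vector<int>& assigned) const {
    for (size_t i = 0; i < assigned.size(); ++i) {
      if (sg[assigned[i]] != assigned[i]) return false;
    }
    return true;
  }

  bool in_orbit(int v, const vector<int>& tried,
                const vector<int>& assigned) {
    if (tried.empty() || gens.empty()) return false;
    vector<const vector<int>*> fixing;
    for (size_t g = 0; g < gens.size(); ++g) {
      if (fixes_all(gens[g], assigned)) fixing.push_back(&gens[g]);
    }
    if (fixing.empty()) return false;
    inorb_buf.assign(n, false);
    vector<int>& queue = queue_buf;
    queue = tried;
    for (size_t i = 0; i < queue.size(); ++i) inorb_buf[queue[i]] = true;
    while (!queue.empty()) {
      int x = queue.back();
      queue.pop_back();
      for (size_t g = 0; g < fixing.size(); ++g) {
        int y = (*fixing[g])[x];
        if (!inorb_buf[y]) {
          if (y == v) return true;
          inorb_buf[y] = true;
          queue.push_back(y);
        }
      }
    }
    return false;
  }

  void dfs(int idx) {
    ++nodes_visited;
    if (idx == static_cast<int>(seqpos.size())) {
      leaf();
      return;
    }
    int a = seqpos[idx];
    int b = bid[0];  // recompute: block owning label a
    for (b = 0; b < nb; ++b) {
      if (a > bstart[b] && a <= bstart[b] + bsize[b]) break;
    }
    vector<int> cands;
    for (size_t i = 0; i < members[b].size(); ++i) {
      if (lab[members[b][i]] == 0) cands.push_back(members[b][i]);
    }
    vector<vector<int> > flats(cands.size());
    for (size_t i = 0; i < cands.size(); ++i) {
      lab[cands[i]] = a;
      pos[a - 1] = cands[i];
      bound_flat(&flats[i]);
      lab[cands[i]] = 0;
      pos[a - 1] = -1;
    }
    vector<int> ord(cands.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = static_cast<int>(i);
    if (cands.size() > 1) {
      // most promising first; WL cell then node id for determinism of the
      // exploration order (the minimum itself does not depend on it)
      std::sort(ord.begin(), ord.end(), [&](int x, int y) {
        if (flats[x] != flats[y]) return flats[x] < flats[y];
        if (stable[cands[x]] != stable[cands[y]])
          return stable[cands[x]] < stable[cands[y]];
        return cands[x] < cands[y];
      });
    }
    Frame fr;
    fr.v = -1;
    for (int v = 0; v < n; ++v) {
      if (lab[v] > 0) fr.assigned.push_back(v);
    }
    stack.push_back(fr);
    for (size_t i = 0; i < ord.size(); ++i) {
      int v = cands[ord[i]];
      Frame& self = stack[idx];
      self.v = v;
      bool skip = false;
      for (size_t w = 0; w < self.tried.size() && !skip; ++w) {
        if (twin[static_cast<size_t>(v) * n + self.tried[w]]) skip = true;
      }
      if (!skip && in_orbit(v, self.tried, self.assigned)) skip = true;
      if (!skip && bound_exceeds_best(flats[ord[i]])) skip = true;
      if (!skip) {
        lab[v] = a;
        pos[a - 1] = v;
        dfs(idx + 1);
        lab[v] = 0;
        pos[a - 1] = -1;
        if (abort_depth >= 0) {
          if (abort_depth < idx) {
            stack.pop_back();
            return;
          }
          abort_depth = -1;  // this subtree was the redundant one; move on
        }
      }
      stack[idx].tried.push_back(v);
    }
    stack.pop_back();
  }
};

}  // namespace

// [[Rcpp::export]]
List canonical_search_cpp(int n, List adjacency, IntegerVector bid,
                          IntegerVector bstart, IntegerVector bsize,
                          LogicalVector deferred, IntegerVector seqpos,
                          IntegerVector stable, IntegerVector featrank,
                          LogicalVector twin, IntegerMatrix edge_matrix,
                          int max_generators) {
  Search s;
  s.n = n;
  s.nb = bstart.size();
  s.maxgens = max_generators;
  s.adj.resize(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector av = adjacency[v];
    for (int i = 0; i < av.size(); ++i) s.adj[v].push_back(av[i] - 1);
  }
  s.bid.assign(bid.begin(), bid.end());
  for (size_t i = 0; i < s.bid.size(); ++i) s.bid[i] -= 1;
  s.bstart.assign(bstart.begin(), bstart.end());
  s.bsize.assign(bsize.begin(), bsize.end());
  s.members.resize(s.nb);
  for (int v = 0; v < n; ++v) s.members[s.bid[v]].push_back(v);
  s.deferred.assign(deferred.begin(), deferred.end());
  s.seqpos.assign(seqpos.begin(), seqpos.end());
  s.spos_sorted = s.seqpos;
  std::sort(s.spos_sorted.begin(), s.spos_sorted.end());
  s.stable.assign(stable.begin(), stable.end());
  s.featrank.assign(featrank.begin(), featrank.end());
  s.twin.assign(twin.begin(), twin.end());
  for (int i = 0; i < edge_matrix.nrow(); ++i) {
    s.edges.push_back(Pair(edge_matrix(i, 0) - 1, edge_matrix(i, 1) - 1));
  }
  s.lab.assign(n, 0);
  s.pos.assign(n, -1);
  s.freeb_buf.resize(s.nb);
  s.cnt_buf.assign(s.nb, 0);
  s.has_best = false;
  s.abort_depth = -1;
  s.nodes_visited = 0;
  s.dfs(0);
  IntegerVector labels(n);
  for (int v = 0; v < n; ++v) labels[v] = s.bestlab[v];
  return List::create(Rcpp::Named("labels") = labels,
                      Rcpp::Named("nodes") = static_cast<double>(s.nodes_visited),
                      Rcpp::Named("generators") = static_cast<int>(s.gens.size() / 2));
}
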
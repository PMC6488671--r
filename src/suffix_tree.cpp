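// Ukkonen's online suffix-tree construction plus the query walks the
// aligner needs: occurrence lookup, verbatim containment, and greedy
// maximal-exact-match coverage of a query string.
#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>

class SuffixTree {
public:
  std::string text;   // includes terminal sentinel
  int n;              // length of text (with sentinel)

  // node storage; node 0 unused, 1 == root
  std::vector<int> start_, end_, slink_, suffidx_;
  std::vector<std::map<char, int> > next_;

  SuffixTree(const std::string& t) : text(t), n((int)t.size()) {
    leaf_end_ = -1;
    new_node(-1, -1);            // dummy slot 0
    root_ = new_node(-1, -1);    // root
    active_node_ = root_;
    active_edge_ = -1;
    active_length_ = 0;
    remainder_ = 0;
    for (int i = 0; i < n; ++i) extend(i);
    set_suffix_indices(root_, 0);
  }

  int root() const { return root_; }

  int n_leaves() const {
    int c = 0;
    for (size_t v = 2; v < next_.size(); ++v)
      if (next_[v].empty()) ++c;
    return c;
  }

  // longest prefix of q[from..] that occurs in text (sentinel excluded by
  // construction: sentinel never equals a query character)
  int longest_match(const std::string& q, int from) const {
    int node = root_, len = 0;
    int i = from, qn = (int)q.size();
    while (i < qn) {
      std::map<char, int>::const_iterator it = next_[node].find(q[i]);
      if (it == next_[node].end()) break;
      int child = it->second;
      int e0 = start_[child], e1 = edge_end(child);
      int p = e0;
      while (p < e1 && i < qn && text[p] == q[i]) { ++p; ++i; ++len; }
      if (p < e1) break;   // fell off mid-edge
      node = child;
    }
    return len;
  }

  // all 0-based start positions of pattern in text (sentinel excluded)
  std::vector<int> occurrences(const std::string& pat) const {
    std::vector<int> out;
    int node = root_;
    int i = 0, pn = (int)pat.size();
    int child = -1;
    while (i < pn) {
      std::map<char, int>::const_iterator it = next_[node].find(pat[i]);
      if (it == next_[node].end()) return out;
      child = it->second;
      int e0 = start_[child], e1 = edge_end(child);
      int p = e0;
      while (p < e1 && i < pn) {
        if (text[p] != pat[i]) return out;
        ++p; ++i;
      }
      node = child;
    }
    collect_leaves(child == -1 ? root_ : child, out);
    // matches cannot overlap the sentinel because pattern chars never
    // equal it; still guard against pathological inputs
    std::vector<int> res;
    for (size_t j = 0; j < out.size(); ++j)
      if (out[j] + pn <= n - 1) res.push_back(out[j]);
    std::sort(res.begin(), res.end());
    return res;
  }

  bool contains(const std::string& pat) const {
    return longest_match(pat, 0) == (int)pat.size();
  }

  // greedy non-overlapping maximal-exact-match coverage of q, minimum
  // seed length w; returns (covered residues, number of seeds used)
  std::pair<long long, int> coverage(const std::string& q, int w) const {
    long long covered = 0;
    int mems = 0;
    int i = 0, qn = (int)q.size();
    while (i < qn) {
      int l = longest_match(q, i);
      if (l >= w) { covered += l; i += l; ++mems; }
      else ++i;
    }
    return std::make_pair(covered, mems);
  }

private:
  int root_, active_node_, active_edge_, active_length_, remainder_;
  int leaf_end_, last_new_node_;

  int new_node(int start, int end) {
    start_.push_back(start);
    end_.push_back(end);
    slink_.push_back(1);  // default suffix link to root
    suffidx_.push_back(-1);
    next_.push_back(std::map<char, int>());
    return (int)start_.size() - 1;
  }

  inline int edge_end(int v) const {
    return end_[v] == -1 ? leaf_end_ + 1 : end_[v];
  }
  inline int edge_length(int v) const { return edge_end(v) - start_[v]; }

  bool walk_down(int v) {
    if (active_length_ >= edge_length(v)) {
      active_edge_ += edge_length(v);
      active_length_ -= edge_length(v);
      active_node_ = v;
      return true;
    }
    return false;
  }

  void extend(int pos) {
    leaf_end_ = pos;
    ++remainder_;
    last_new_node_ = 0;
    while (remainder_ > 0) {
      if (active_length_ == 0) active_edge_ = pos;
      std::map<char, int>::iterator it =
        next_[active_node_].find(text[active_edge_]);
      if (it == next_[active_node_].end()) {
        next_[active_node_][text[active_edge_]] = new_node(pos, -1);
        if (last_new_node_) {
          slink_[last_new_node_] = active_node_;
          last_new_node_ = 0;
        }
      } else {
        int nxt = it->second;
        if (walk_down(nxt)) continue;
        if (text[start_[nxt] + active_length_] == text[pos]) {
          if (last_new_node_ && active_node_ != root_) {
            slink_[last_new_node_] = active_node_;
            last_new_node_ = 0;
          }
          ++active_length_;
          break;
        }
        // split the edge
        int split = new_node(start_[nxt], start_[nxt] + active_length_);
        next_[active_node_][text[active_edge_]] = split;
        next_[split][text[pos]] = new_node(pos, -1);
        start_[nxt] += active_length_;
        next_[split][text[start_[nxt]]] = nxt;
        if (last_new_node_) slink_[last_new_node_] = split;
        last_new_node_ = split;
      }
      --remainder_;
      if (active_node_ == root_ && active_length_ > 0) {
        --active_length_;
        active_edge_ = pos - remainder_ + 1;
      } else if (active_node_ != root_) {
        active_node_ = slink_[active_node_];
      }
    }
  }

  void set_suffix_indices(int v, int depth) {
    if (v != root_ && next_[v].empty()) {
      suffidx_[v] = n - depth;
      return;
    }
    for (std::map<char, int>::const_iterator it = next_[v].begin();
         it != next_[v].end(); ++it)
      set_suffix_indices(it->second, depth + edge_length(it->second));
  }

  void collect_leaves(int v, std::vector<int>& out) const {
    if (next_[v].empty()) {
      if (suffidx_[v] >= 0) out.push_back(suffidx_[v]);
      return;
    }
    for (std::map<char, int>::const_iterator it = next_[v].begin();
         it != next_[v].end(); ++it)
      collect_leaves(it->second, out);
  }
};

using namespace Rcpp;

// [[Rcpp::export]]
SEXP st_build_cpp(std::string text) {
  XPtr<SuffixTree> ptr(new SuffixTree(text), true);
  return ptr;
}

// [[Rcpp::export]]
int st_n_leaves_cpp(SEXP xp) {
  XPtr<SuffixTree> ptr(xp);
  return ptr->n_leaves();
}

// [[Rcpp::export]]
IntegerVector st_find_cpp(SEXP xp, std::string pattern) {
  XPtr<SuffixTree> ptr(xp);
  std::vector<int> occ = ptr->occurrences(pattern);
  return wrap(occ);
}

// [[Rcpp::export]]
bool st_contains_cpp(SEXP xp, std::string pattern) {
  XPtr<SuffixTree> ptr(xp);
  return ptr->contains(pattern);
}

// [[Rcpp::export]]
int st_longest_match_cpp(SEXP xp, std::string query, int from) {
  XPtr<SuffixTree> ptr(xp);
  return ptr->longest_match(query, from);
}

// [[Rcpp::export]]
NumericVector st_coverage_cpp(SEXP xp, std::string query, int min_seed) {
  XPtr<SuffixTree> ptr(xp);
  std::pair<long long, int> r = ptr->coverage(query, min_seed);
  return NumericVector::create((double)r.first, (double)r.second);
}
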
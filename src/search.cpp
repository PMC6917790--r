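// Multi-pattern search core: Aho-Corasick automaton over the 5-letter
// alphabet A,C,G,T,N (N in a reference never matches an oligo base unless a
// pattern itself carries N), Hamming-ball enumeration that gives the exact
// automaton k-mismatch capability, and an intentionally naive sliding-window
// scanner used as the testing oracle.

#include <Rcpp.h>
#include <array>
#include <functional>
#include <queue>
#include <string>
#include <vector>

using namespace Rcpp;

static const int ALPHA = 5; // A C G T N

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4; // N and anything else
  }
}

struct ACAutomaton {
  std::vector< std::array<int, ALPHA> > next;
  std::vector<int> fail;
  std::vector<int> dictlink;             // nearest suffix node with output
  std::vector< std::vector<int> > out;   // pattern ids (0-based) ending here
  std::vector<int> patlen;               // length per pattern id

  int new_node() {
    std::array<int, ALPHA> blank;
    blank.fill(-1);
    next.push_back(blank);
    fail.push_back(0);
    dictlink.push_back(-1);
    out.push_back(std::vector<int>());
    return (int)next.size() - 1;
  }
};

// [[Rcpp::export(name = ".cpp_ac_build")]]
SEXP cpp_ac_build(CharacterVector patterns) {
  if (patterns.size() == 0)
    stop("cannot build an automaton from an empty pattern list");
  ACAutomaton* ac = new ACAutomaton();
  ac->new_node(); // root = 0
  ac->patlen.resize(patterns.size());
  for (int id = 0; id < patterns.size(); ++id) {
    const char* p = CHAR(STRING_ELT(patterns, id));
    int node = 0;
    int len = 0;
    for (const char* q = p; *q; ++q, ++len) {
      int c = base_code(*q);
      if (ac->next[node][c] == -1) {
        int nn = ac->new_node();
        ac->next[node][c] = nn;
      }
      node = ac->next[node][c];
    }
    if (len == 0) { delete ac; stop("empty pattern at index %d", id + 1); }
    ac->patlen[id] = len;
    ac->out[node].push_back(id);
  }
  // BFS: failure links, goto completion, dict links
  std::queue<int> bfs;
  for (int c = 0; c < ALPHA; ++c) {
    int v = ac->next[0][c];
    if (v == -1) { ac->next[0][c] = 0; }
    else { ac->fail[v] = 0; bfs.push(v); }
  }
  while (!bfs.empty()) {
    int u = bfs.front(); bfs.pop();
    int f = ac->fail[u];
    ac->dictlink[u] = ac->out[f].empty() ? ac->dictlink[f] : f;
    for (int c = 0; c < ALPHA; ++c) {
      int v = ac->next[u][c];
      if (v == -1) {
        ac->next[u][c] = ac->next[f][c];
      } else {
        ac->fail[v] = ac->next[f][c];
        bfs.push(v);
      }
    }
  }
  XPtr<ACAutomaton> ptr(ac, true);
  ptr.attr("n_patterns") = (int)patterns.size();
  ptr.attr("n_nodes") = (int)ac->next.size();
  return ptr;
}

// [[Rcpp::export(name = ".cpp_ac_scan")]]
List cpp_ac_scan(SEXP autom, std::string text) {
  XPtr<ACAutomaton> ac(autom);
  std::vector<int> hit_pattern;
  std::vector<int> hit_end;
  int node = 0;
  const int n = (int)text.size();
  for (int i = 0; i < n; ++i) {
    node = ac->next[node][base_code(text[i])];
    for (int v = ac->out[node].empty() ? ac->dictlink[node] : node;
         v != -1; v = ac->dictlink[v]) {
      for (int id : ac->out[v]) {
        hit_pattern.push_back(id + 1); // 1-based pattern index
        hit_end.push_back(i + 1);      // 1-based end position
      }
    }
  }
  return List::create(_["pattern"] = wrap(hit_pattern),
                      _["end"] = wrap(hit_end));
}

// Enumerate every string at Hamming distance <= k from `pattern`.
// Substitution alphabet per position: the 3 other bases, plus N when
// include_n is true (so reference windows containing N, which always count
// as mismatched, are still recognized by the exact automaton).
// [[Rcpp::export(name = ".cpp_hamming_ball")]]
List cpp_hamming_ball(std::string pattern, int k, bool include_n,
                      double cap) {
  if (k < 0) stop("k must be >= 0");
  const R_xlen_t capn = (R_xlen_t)cap;
  const int L = (int)pattern.size();
  std::vector<std::string> out_str;
  std::vector<int> out_mm;
  std::string cur = pattern;
  const char bases4[4] = {'A', 'C', 'G', 'T'};
  std::function<void(int, int)> rec = [&](int pos, int used) {
    if ((R_xlen_t)out_str.size() > capn) return;
    if (pos == L) { out_str.push_back(cur); out_mm.push_back(used); return; }
    cur[pos] = pattern[pos];
    rec(pos + 1, used);
    if (used < k) {
      for (int b = 0; b < 4; ++b) {
        if (bases4[b] == pattern[pos]) continue;
        cur[pos] = bases4[b];
        rec(pos + 1, used + 1);
      }
      if (include_n && pattern[pos] != 'N') {
        cur[pos] = 'N';
        rec(pos + 1, used + 1);
      }
      cur[pos] = pattern[pos];
    }
  };
  rec(0, 0);
  if ((R_xlen_t)out_str.size() > capn)
    stop("Hamming ball of '%s' at k=%d exceeds the pattern cap; "
         "use a lower k or the brute-force method", pattern.c_str(), k);
  return List::create(_["sequence"] = wrap(out_str),
                      _["mismatches"] = wrap(out_mm));
}

// Fused k-mismatch search: inserts the Hamming ball of every pattern
// directly into the trie (no string materialization), completes the
// automaton, and scans every text in one call. Semantics identical to
// enumerating the ball and running the exact automaton.
// Flat-array trie (one malloc-free growth path per vector; outputs as an
// intrusive linked list, since almost all nodes have none).
struct FlatAC {
  std::vector<int> next;      // 5 slots per node
  std::vector<int> fail;
  std::vector<int> dictlink;
  std::vector<int> out_head;  // -1 or index into out_id/out_next
  std::vector<int> out_id;
  std::vector<int> out_next;

  int new_node() {
    next.insert(next.end(), ALPHA, -1);
    fail.push_back(0);
    dictlink.push_back(-1);
    out_head.push_back(-1);
    return (int)out_head.size() - 1;
  }
  void add_out(int node, int id) {
    out_id.push_back(id);
    out_next.push_back(out_head[node]);
    out_head[node] = (int)out_id.size() - 1;
  }
};

static void insert_ball(FlatAC& ac, const std::string& pat, int pos,
                        int node, int used, int k, bool include_n, int id) {
  const int L = (int)pat.size();
  if (pos == L) {
    ac.add_out(node, id);
    return;
  }
  int orig = base_code(pat[pos]);
  int nletters = include_n ? 5 : 4;
  for (int c = 0; c < nletters; ++c) {
    int nused = used + (c == orig ? 0 : 1);
    if (nused > k) continue;
    int child = ac.next[node * ALPHA + c];
    if (child == -1) {
      child = ac.new_node();
      ac.next[node * ALPHA + c] = child;
    }
    insert_ball(ac, pat, pos + 1, child, nused, k, include_n, id);
  }
}

// [[Rcpp::export(name = ".cpp_search_mm")]]
List cpp_search_mm(CharacterVector patterns, IntegerVector ks, bool include_n,
                   CharacterVector texts) {
  if (patterns.size() == 0) stop("empty pattern list");
  FlatAC ac;
  ac.new_node();
  for (int id = 0; id < patterns.size(); ++id) {
    std::string p = as<std::string>(patterns[id]);
    if (p.empty()) stop("empty pattern at index %d", id + 1);
    insert_ball(ac, p, 0, 0, 0, ks[id], include_n, id);
  }
  const int n_nodes = (int)ac.out_head.size();
  std::vector<int> bfs;
  bfs.reserve(n_nodes);
  for (int c = 0; c < ALPHA; ++c) {
    int v = ac.next[c];
    if (v == -1) ac.next[c] = 0;
    else { ac.fail[v] = 0; bfs.push_back(v); }
  }
  for (size_t qi = 0; qi < bfs.size(); ++qi) {
    int u = bfs[qi];
    int f = ac.fail[u];
    ac.dictlink[u] = (ac.out_head[f] != -1) ? f : ac.dictlink[f];
    for (int c = 0; c < ALPHA; ++c) {
      int v = ac.next[u * ALPHA + c];
      if (v == -1) ac.next[u * ALPHA + c] = ac.next[f * ALPHA + c];
      else { ac.fail[v] = ac.next[f * ALPHA + c]; bfs.push_back(v); }
    }
  }
  std::vector<int> m_pattern, m_end, m_text;
  for (int t = 0; t < texts.size(); ++t) {
    const char* txt = CHAR(STRING_ELT(texts, t));
    int node = 0;
    for (int i = 0; txt[i]; ++i) {
      node = ac.next[node * ALPHA + base_code(txt[i])];
      for (int v = (ac.out_head[node] != -1) ? node : ac.dictlink[node];
           v != -1; v = ac.dictlink[v]) {
        for (int e = ac.out_head[v]; e != -1; e = ac.out_next[e]) {
          m_pattern.push_back(ac.out_id[e] + 1);
          m_end.push_back(i + 1);
          m_text.push_back(t + 1);
        }
      }
    }
  }
  return List::create(_["pattern"] = wrap(m_pattern),
                      _["end"] = wrap(m_end),
                      _["text"] = wrap(m_text));
}

// Naive sliding-window Hamming scanner: the independent testing oracle.
// A column matches only when both characters are equal A/C/G/T; any N (or
// other character) on either side counts as a mismatch.
// [[Rcpp::export(name = ".cpp_brute_scan")]]
List cpp_brute_scan(std::string pattern, std::string text, int k) {
  const int L = (int)pattern.size();
  const int n = (int)text.size();
  std::vector<int> starts;
  std::vector<int> mms;
  for (int s = 0; s + L <= n; ++s) {
    int mm = 0;
    for (int j = 0; j < L; ++j) {
      char a = pattern[j], b = text[s + j];
      bool ok = (a == b) && (a == 'A' || a == 'C' || a == 'G' || a == 'T');
      if (!ok) {
        ++mm;
        if (mm > k) break;
      }
    }
    if (mm <= k) {
      starts.push_back(s + 1);
      mms.push_back(mm);
    }
  }
  return List::create(_["start"] = wrap(starts),
                      _["mismatches"] = wrap(mms));
}
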
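#include <Rcpp.h>
using namespace Rcpp;

// Overlap scan used by merge_pairs(): score candidate overlaps between the
// forward read and the reverse-complemented mate, longest first, and keep
// the one with the most matching bases among those whose mismatch fraction
// is admissible (ties resolved towards the longer overlap). The descending
// scan allows two prunings: an overlap of length o can never beat a best
// match count of best_m >= o, and a candidate dies as soon as its mismatch
// count exceeds both the admissible fraction and the count that could still
// improve on best_m.
static inline void best_overlap(const std::string &fwd, const std::string &rev_rc,
                                int min_overlap, double max_mismatch_frac,
                                int &best_o, int &best_m) {
  int nf = fwd.size(), nr = rev_rc.size();
  int max_o = std::min(nf, nr);
  best_o = 0;
  best_m = -1;
  for (int o = max_o; o >= min_overlap; --o) {
    if (o <= best_m) break;
    int lim_frac = (int)std::floor(max_mismatch_frac * o);
    int lim_beat = o - (best_m + 1);
    int lim = std::min(lim_frac, lim_beat);
    if (lim < 0) continue;
    const char *a = fwd.data() + (nf - o);
    const char *b = rev_rc.data();
    int mm = 0;
    bool ok = true;
    for (int i = 0; i < o; ++i) {
      if (a[i] != b[i] && ++mm > lim) { ok = false; break; }
    }
    if (ok) {
      best_m = o - mm;
      best_o = o;
    }
  }
}

// [[Rcpp::export(name = ".best_overlap_one")]]
IntegerVector best_overlap_one(std::string fwd, std::string rev_rc,
                               int min_overlap, double max_mismatch_frac) {
  int o, m;
  best_overlap(fwd, rev_rc, min_overlap, max_mismatch_frac, o, m);
  if (m < 0) return IntegerVector::create(0, 0);
  return IntegerVector::create(o, m);
}

// Full pair merging: overlap scan plus consensus. Disagreeing overlap bases
// resolve towards the higher quality (ties towards the forward read);
// overlap qualities take the per-position maximum. rev_rc / rev_qual_rev
// are the reverse-complemented mate and its reversed quality string.

// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector rev_rc,
                     CharacterVector fwd_qual, CharacterVector rev_qual_rev,
                     int min_overlap, double max_mismatch_frac) {
  int n = fwd.size();
  CharacterVector sequence(n), quality(n);
  IntegerVector overlap(n);
  for (int r = 0; r < n; ++r) {
    std::string f = as<std::string>(fwd[r]);
    std::string b = as<std::string>(rev_rc[r]);
    std::string fq = as<std::string>(fwd_qual[r]);
    std::string bq = as<std::string>(rev_qual_rev[r]);
    int o, m;
    best_overlap(f, b, min_overlap, max_mismatch_frac, o, m);
    if (m < 0) {
      sequence[r] = NA_STRING;
      quality[r] = NA_STRING;
      overlap[r] = 0;
      continue;
    }
    int nf = f.size(), nr = b.size();
    std::string seq = f.substr(0, nf - o);
    std::string qual = fq.substr(0, nf - o);
    for (int i = 0; i < o; ++i) {
      char cf = f[nf - o + i], cb = b[i];
      char qf = fq[nf - o + i], qb = bq[i];
      if (cf != cb && qb > qf) seq.push_back(cb); else seq.push_back(cf);
      qual.push_back(qf >= qb ? qf : qb);
    }
    seq += b.substr(o);
    qual += bq.substr(o);
    sequence[r] = seq;
    quality[r] = qual;
    overlap[r] = o;
  }
  return List::create(_["sequence"] = sequence, _["quality"] = quality,
                      _["overlap"] = overlap);
}

// Hamming distance with an early-exit cap; -1 when lengths differ.

// [[Rcpp::export(name = ".hamming_capped")]]
int hamming_capped(std::string a, std::string b, int cap) {
  if (a.size() != b.size()) return -1;
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i] && ++d > cap) return d;
  }
  return d;
}

// Shadow-artifact scan for one dereplicated group (sequences in descending
// count order). Entry i is a shadow when a surviving, >= (1/ratio)-fold more
// abundant entry j < i lies within max_mismatch substitutions.

// [[Rcpp::export(name = ".shadow_flags")]]
LogicalVector shadow_flags(CharacterVector seqs, NumericVector counts,
                           double ratio, int max_mismatch) {
  int n = seqs.size();
  LogicalVector flag(n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      if (flag[j]) continue;
      if (counts[i] > ratio * counts[j]) continue;
      if (s[i].size() != s[j].size()) continue;
      int d = 0;
      bool within = true;
      for (size_t k = 0; k < s[i].size(); ++k) {
        if (s[i][k] != s[j][k] && ++d > max_mismatch) { within = false; break; }
      }
      if (within) { flag[i] = true; break; }
    }
  }
  return flag;
}

static inline bool chimera_of(const std::string &child, const std::string &p1,
                              const std::string &p2) {
  int n = child.size(), n1 = p1.size(), n2 = p2.size();
  int pre = 0;
  int lim = std::min(n, n1);
  while (pre < lim && child[pre] == p1[pre]) ++pre;
  int suf = 0;
  int lim2 = std::min(n, n2);
  while (suf < lim2 && child[n - 1 - suf] == p2[n2 - 1 - suf]) ++suf;
  int k_lo = std::max(1, n - suf);
  int k_hi = std::min(pre, n - 1);
  return k_lo <= k_hi;
}

// [[Rcpp::export(name = ".is_chimera_of")]]
bool is_chimera_of(std::string child, std::string p1, std::string p2) {
  return chimera_of(child, p1, p2);
}

// Chimera scan for one group (descending count order, shadows already
// excluded via `alive`). A child is chimeric when it equals a prefix of one
// alive parent joined to a suffix of another at some internal breakpoint,
// both parents having >= parent_ratio times its count. Parents are capped
// at the max_parents most abundant qualifying entries (chimeras form from
// abundant templates). For each child the longest shared prefix/suffix with
// every parent is computed once; a breakpoint exists for parents (a, b)
// iff min(pre_a, n-1) + min(suf_b, n-1) >= n, which only needs the top-2
// parents by prefix and by suffix.

// [[Rcpp::export(name = ".chimera_flags")]]
LogicalVector chimera_flags(CharacterVector seqs, NumericVector counts,
                            LogicalVector alive, double parent_ratio,
                            int max_parents = 30) {
  int n = seqs.size();
  LogicalVector flag(n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    std::vector<int> par;
    for (int j = 0; j < n && (int)par.size() < max_parents; ++j) {
      if (j == i || !alive[j] || flag[j]) continue;
      if (counts[j] >= parent_ratio * counts[i] && s[j] != s[i]) par.push_back(j);
    }
    if (par.size() < 2) continue;
    int nc = s[i].size();
    // top-2 parents by capped prefix and by capped suffix
    int p1 = -1, p2 = -1, s1 = -1, s2 = -1; // indices into par
    std::vector<int> pre(par.size()), suf(par.size());
    for (size_t a = 0; a < par.size(); ++a) {
      const std::string &p = s[par[a]];
      int np = p.size();
      int q = 0, lim = std::min(nc, np);
      while (q < lim && s[i][q] == p[q]) ++q;
      pre[a] = std::min(q, nc - 1);
      q = 0;
      while (q < lim && s[i][nc - 1 - q] == p[np - 1 - q]) ++q;
      suf[a] = std::min(q, nc - 1);
      if (p1 < 0 || pre[a] > pre[p1]) { p2 = p1; p1 = a; }
      else if (p2 < 0 || pre[a] > pre[p2]) { p2 = a; }
      if (s1 < 0 || suf[a] > suf[s1]) { s2 = s1; s1 = a; }
      else if (s2 < 0 || suf[a] > suf[s2]) { s2 = a; }
    }
    bool hit = false;
    if (p1 != s1) {
      hit = pre[p1] + suf[s1] >= nc;
    } else {
      if (p2 >= 0 && pre[p2] + suf[s1] >= nc) hit = true;
      if (!hit && s2 >= 0 && pre[p1] + suf[s2] >= nc) hit = true;
    }
    if (hit) flag[i] = true;
  }
  return flag;
}

// Global alignment distance for unequal-length amino-acid sequences:
// maximise the alignment score (match +1, mismatch -1, gap -2); among
// co-optimal alignments minimise the number of substituted plus
// inserted/deleted positions, which is the reported distance.

// [[Rcpp::export(name = ".aa_align_distance")]]
int aa_align_distance(std::string a, std::string b) {
  int n = a.size(), m = b.size();
  std::vector<int> S_prev(m + 1), D_prev(m + 1), S_cur(m + 1), D_cur(m + 1);
  for (int j = 0; j <= m; ++j) { S_prev[j] = -2 * j; D_prev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    S_cur[0] = -2 * i; D_cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      bool match = a[i - 1] == b[j - 1];
      int sd = S_prev[j - 1] + (match ? 1 : -1);
      int dd = D_prev[j - 1] + (match ? 0 : 1);
      int su = S_prev[j] - 2, du = D_prev[j] + 1;
      int sl = S_cur[j - 1] - 2, dl = D_cur[j - 1] + 1;
      int S = sd, D = dd;
      if (su > S || (su == S && du < D)) { S = su; D = du; }
      if (sl > S || (sl == S && dl < D)) { S = sl; D = dl; }
      S_cur[j] = S; D_cur[j] = D;
    }
    std::swap(S_prev, S_cur);
    std::swap(D_prev, D_cur);
  }
  return D_prev[m];
}
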
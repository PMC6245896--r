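#include <Rcpp.h>
#include <array>
#include <string>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------
// Global alignment identity (clustering kernel)
//
// Needleman-Wunsch with match +1, mismatch -1, gap -1 (linear).  Among
// optimal-score alignments the one maximizing matches, then minimizing
// alignment length, is selected; this makes identity = matches / columns
// well defined without reference to traceback order.
// ---------------------------------------------------------------------

struct Cell { int score; int match; int len; };

static inline bool better(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.match != b.match) return a.match > b.match;
  return a.len < b.len;
}

// [[Rcpp::export]]
List cpp_nw_identity(std::string a, std::string b) {
  const int la = a.size(), lb = b.size();
  std::vector<Cell> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = {-j, 0, j};
  for (int i = 1; i <= la; ++i) {
    cur[0] = {-i, 0, i};
    for (int j = 1; j <= lb; ++j) {
      bool eq = a[i - 1] == b[j - 1];
      Cell diag = {prev[j - 1].score + (eq ? 1 : -1),
                   prev[j - 1].match + (eq ? 1 : 0), prev[j - 1].len + 1};
      Cell up   = {prev[j].score - 1, prev[j].match, prev[j].len + 1};
      Cell left = {cur[j - 1].score - 1, cur[j - 1].match, cur[j - 1].len + 1};
      Cell best = diag;
      if (better(up, best)) best = up;
      if (better(left, best)) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  const Cell &f = prev[lb];
  double id = f.len > 0 ? (double)f.match / f.len : 1.0;
  return List::create(_["score"] = f.score, _["matches"] = f.match,
                      _["aln_len"] = f.len, _["identity"] = id);
}

// ---------------------------------------------------------------------
// Smith-Waterman local alignment with affine gaps.
//
// Sequences arrive as 1-based integer codes indexing the substitution
// matrix.  A gap of length k costs gap_open + k * gap_extend.  Traceback
// ties prefer diagonal, then gap-in-subject, then gap-in-query, and the
// highest-scoring cell with the smallest (i, j) wins, so results are
// deterministic.
// ---------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sw_affine(IntegerVector q, IntegerVector s, NumericMatrix sm,
                   double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  const double NEG = -1e30;
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, NEG));
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open - gap_extend,
                         E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gap_open - gap_extend,
                         F[i - 1][j] - gap_extend);
      double diag = H[i - 1][j - 1] + sm(q[i - 1] - 1, s[j - 1] - 1);
      double h = diag;
      if (E[i][j] > h) h = E[i][j];
      if (F[i][j] > h) h = F[i][j];
      if (h < 0) h = 0;
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["matches"] = 0,
                        _["mismatches"] = 0, _["gaps"] = 0, _["aln_len"] = 0);
  // traceback
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (gap in query), 2 = F
  int matches = 0, mismatches = 0, gaps = 0, alen = 0;
  int qe = bi, se = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H[i][j] == 0) break;
      double diag = H[i - 1][j - 1] + sm(q[i - 1] - 1, s[j - 1] - 1);
      if (H[i][j] == diag) {
        if (q[i - 1] == s[j - 1]) ++matches; else ++mismatches;
        ++alen; --i; --j;
      } else if (H[i][j] == E[i][j]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++gaps; ++alen;
      if (E[i][j] == E[i][j - 1] - gap_extend) { --j; }
      else { --j; state = 0; }
    } else {
      ++gaps; ++alen;
      if (F[i][j] == F[i - 1][j] - gap_extend) { --i; }
      else { --i; state = 0; }
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = qe, _["s_start"] = j + 1,
                      _["s_end"] = se, _["matches"] = matches,
                      _["mismatches"] = mismatches, _["gaps"] = gaps,
                      _["aln_len"] = alen);
}

// ---------------------------------------------------------------------
// Greedy overlap-layout-consensus assembly.
//
// Overlaps are ungapped placements of contig B at a non-negative offset
// d inside/after contig A (same orientation after optional reverse
// complement): the shared span is min(la - d, lb) columns and must be at
// least min_ov long with identity >= min_id.  d = la - o recovers the
// classic suffix-prefix dovetail; d + lb <= la is containment (amplicon
// reads share their 5' start, so containment is the common case).  The
// pair with the most matching columns is merged first; the consensus is
// the per-column majority with ties kept at the earlier-created
// contig's base.
// ---------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; default: return 4;
  }
}
static const char BASES[5] = {'A', 'C', 'G', 'T', 'N'};

static std::string rc_string(const std::string &s) {
  std::string rc(s.rbegin(), s.rend());
  for (auto &ch : rc) {
    switch (ch) {
      case 'A': ch = 'T'; break; case 'T': ch = 'A'; break;
      case 'C': ch = 'G'; break; case 'G': ch = 'C'; break;
      default: break;
    }
  }
  return rc;
}

struct Contig {
  std::vector<std::array<int, 5>> prof;  // per-column base counts
  std::string cons;
  std::string cons_rc;    // cached reverse complement of cons
  int support;
  int created;            // creation order, for consensus tie-breaking
  std::vector<int> reads; // original read indices
  bool active;
};

static void flip_contig(Contig &c) {
  std::reverse(c.prof.begin(), c.prof.end());
  for (auto &col : c.prof) {
    std::swap(col[0], col[3]);  // A <-> T
    std::swap(col[1], col[2]);  // C <-> G
  }
  std::swap(c.cons, c.cons_rc);
}

struct Ov { int matches; int off; int len; int oi; int oj; };

// best placement of b at offset d >= 0 along a (fixed orientations)
static bool best_offset_overlap(const std::string &a, const std::string &b,
                                int min_ov, double min_id,
                                int &out_off, int &out_len,
                                int &out_matches) {
  const int la = a.size(), lb = b.size();
  bool found = false;
  int bm = -1, bo = 0, bl = 0;
  const int dmax = la - min_ov;
  for (int d = 0; d <= dmax; ++d) {
    const int o = std::min(la - d, lb);
    if (o < min_ov) break;
    const int allowed = (int)std::floor((1.0 - min_id) * o + 1e-9);
    int mm = 0;
    const char *pa = a.data() + d;
    bool ok = true;
    for (int k = 0; k < o; ++k) {
      if (pa[k] != b[k]) { if (++mm > allowed) { ok = false; break; } }
    }
    if (!ok) continue;
    const int matches = o - mm;
    if (matches > bm || (matches == bm && o > bl)) {
      bm = matches; bo = d; bl = o; found = true;
    }
  }
  out_off = bo; out_len = bl; out_matches = bm;
  return found;
}

// best overlap over orientation combinations for ordered pair (i left,
// j right).  Uses the cached reverse-complement strings; profiles are
// only flipped at merge time.
static bool best_overlap_pair(const Contig &ci, const Contig &cj,
                              bool both_orient, int min_ov, double min_id,
                              Ov &out) {
  bool found = false;
  Ov best = {-1, 0, 0, 0, 0};
  const int n_or = both_orient ? 2 : 1;
  for (int oi = 0; oi < n_or; ++oi) {
    const std::string &sa = (oi == 0) ? ci.cons : ci.cons_rc;
    for (int oj = 0; oj < n_or; ++oj) {
      const std::string &sb = (oj == 0) ? cj.cons : cj.cons_rc;
      int off, len, matches;
      if (best_offset_overlap(sa, sb, min_ov, min_id, off, len,
                              matches)) {
        if (matches > best.matches ||
            (matches == best.matches && len > best.len)) {
          best = {matches, off, len, oi, oj};
          found = true;
        }
      }
    }
  }
  if (found) out = best;
  return found;
}

// [[Rcpp::export]]
List cpp_assemble_olc(CharacterVector reads, int min_ov, double min_id,
                      bool both_orient) {
  const int n = reads.size();
  std::vector<Contig> nodes(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    nodes[i].cons = s;
    nodes[i].cons_rc = rc_string(s);
    nodes[i].prof.resize(s.size());
    for (size_t k = 0; k < s.size(); ++k) {
      nodes[i].prof[k].fill(0);
      nodes[i].prof[k][base_code(s[k])] = 1;
    }
    nodes[i].support = 1;
    nodes[i].created = i;
    nodes[i].reads.push_back(i);
    nodes[i].active = true;
  }
  // pairwise best overlaps (ordered pairs)
  std::vector<std::vector<Ov>> ov(n, std::vector<Ov>(n));
  std::vector<std::vector<char>> has(n, std::vector<char>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      Ov o;
      if (best_overlap_pair(nodes[i], nodes[j], both_orient, min_ov,
                            min_id, o)) { ov[i][j] = o; has[i][j] = 1; }
    }

  while (true) {
    // find globally best qualifying merge
    int bi = -1, bj = -1; Ov bo = {-1, 0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (!nodes[i].active) continue;
      for (int j = 0; j < n; ++j) {
        if (i == j || !nodes[j].active || !has[i][j]) continue;
        const Ov &o = ov[i][j];
        if (o.matches > bo.matches ||
            (o.matches == bo.matches && o.len > bo.len)) {
          bo = o; bi = i; bj = j;
        }
      }
    }
    if (bi < 0) break;
    // merge bj (right, at offset bo.off) into bi (left)
    Contig L = nodes[bi], R = nodes[bj];
    if (bo.oi == 1) flip_contig(L);
    if (bo.oj == 1) flip_contig(R);
    const int la = L.cons.size(), lb = R.cons.size();
    const int d = bo.off;
    const int newlen = std::max(la, d + lb);
    Contig M;
    M.support = L.support + R.support;
    M.created = std::min(L.created, R.created);
    M.reads = L.reads;
    M.reads.insert(M.reads.end(), R.reads.begin(), R.reads.end());
    M.active = true;
    M.prof.assign(newlen, {0, 0, 0, 0, 0});
    M.cons.assign(newlen, 'N');
    for (int k = 0; k < la; ++k) M.prof[k] = L.prof[k];
    for (int k = 0; k < lb; ++k)
      for (int z = 0; z < 5; ++z) M.prof[d + k][z] += R.prof[k][z];
    for (int p = 0; p < newlen; ++p) {
      const bool inL = p < la;
      const bool inR = p >= d && p < d + lb;
      if (inL && !inR) { M.cons[p] = L.cons[p]; continue; }
      if (inR && !inL) { M.cons[p] = R.cons[p - d]; continue; }
      // overlap column: majority; ties keep the earlier contig's base
      const char pref = (L.created <= R.created) ? L.cons[p]
                                                 : R.cons[p - d];
      int bestc = 0, bestv = -1;
      for (int z = 0; z < 5; ++z)
        if (M.prof[p][z] > bestv) { bestv = M.prof[p][z]; bestc = z; }
      M.cons[p] = (M.prof[p][base_code(pref)] == bestv) ? pref
                                                        : BASES[bestc];
    }
    M.cons_rc = rc_string(M.cons);
    nodes[bi] = M;
    nodes[bj].active = false;
    // refresh overlaps touching bi
    for (int k = 0; k < n; ++k) {
      if (k == bi || !nodes[k].active) continue;
      Ov o1, o2;
      has[bi][k] = best_overlap_pair(nodes[bi], nodes[k], both_orient,
                                     min_ov, min_id, o1) ? 1 : 0;
      if (has[bi][k]) ov[bi][k] = o1;
      has[k][bi] = best_overlap_pair(nodes[k], nodes[bi], both_orient,
                                     min_ov, min_id, o2) ? 1 : 0;
      if (has[k][bi]) ov[k][bi] = o2;
    }
  }
  // collect
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) if (nodes[i].active) keep.push_back(i);
  const int nc = keep.size();
  CharacterVector cons(nc);
  IntegerVector support(nc);
  List profiles(nc);
  IntegerVector assign(n);
  for (int c = 0; c < nc; ++c) {
    const Contig &nd = nodes[keep[c]];
    cons[c] = nd.cons;
    support[c] = nd.support;
    IntegerMatrix pm(5, nd.prof.size());
    for (size_t k = 0; k < nd.prof.size(); ++k)
      for (int z = 0; z < 5; ++z) pm(z, k) = nd.prof[k][z];
    profiles[c] = pm;
    for (int r : nd.reads) assign[r] = c + 1;
  }
  return List::create(_["consensus"] = cons, _["support"] = support,
                      _["profile"] = profiles, _["assignment"] = assign);
}

// ---------------------------------------------------------------------
// Semi-global (fit) alignment of a read inside a contig, unit costs.
// The read is aligned end-to-end; the contig contributes a free-ended
// window.  Returns the edit distance, the 1-based contig start, and a
// cover string giving, for each contig column in the aligned span, the
// read base placed there ('-' for a deletion; read insertions are
// skipped).  Ties prefer diagonal, then gap-in-contig, then
// gap-in-read, and the leftmost end column.
// ---------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_fit_align(std::string read, std::string contig) {
  const int n = read.size(), m = contig.size();
  std::vector<std::vector<int>> D(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) D[i][0] = i;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int diag = D[i - 1][j - 1] + (read[i - 1] == contig[j - 1] ? 0 : 1);
      int up = D[i - 1][j] + 1;     // read base consumed: insertion
      int left = D[i][j - 1] + 1;   // contig column skipped: deletion
      D[i][j] = std::min(diag, std::min(up, left));
    }
  int bj = 0, bd = D[n][0];
  for (int j = 1; j <= m; ++j)
    if (D[n][j] < bd) { bd = D[n][j]; bj = j; }
  // traceback
  std::string cover;
  int i = n, j = bj;
  while (i > 0 && j > 0) {
    int diag = D[i - 1][j - 1] + (read[i - 1] == contig[j - 1] ? 0 : 1);
    if (D[i][j] == diag) { cover.push_back(read[i - 1]); --i; --j; }
    else if (D[i][j] == D[i - 1][j] + 1) { --i; }
    else { cover.push_back('-'); --j; }
  }
  while (i > 0) { --i; }  // leading read overhang past contig start
  std::reverse(cover.begin(), cover.end());
  return List::create(_["edits"] = bd, _["c_start"] = j + 1,
                      _["c_end"] = bj, _["cover"] = cover);
}
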
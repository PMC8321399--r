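#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// base codes: A=0 C=1 G=2 T=3, anything else (N) = -1 (ineligible in k-mers)
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// bijective 64-bit mixer (splitmix64 finalizer); for k <= 31 the packed
// 2-bit k-mer fits in 62 bits, so equal hash values imply equal k-mers
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return x;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int L = (int) std::strlen(s);
    std::string r(L, 'N');
    for (int j = 0; j < L; ++j) r[L - 1 - j] = comp_base(s[j]);
    out[i] = r;
  }
  return out;
}

// best (smallest or largest) eligible k-mer of one strand; leftmost on ties.
// lexicographic or hashed ordering. Returns pos or -1.
static int scan_strand(const char* s, int L, int k, bool maximizer,
                       bool hashed, uint64_t seed) {
  if (L < k) return -1;
  int best = -1;
  if (hashed) {
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    uint64_t val = 0, best_hv = 0;
    int run = 0;
    for (int e = 0; e < L; ++e) {
      int c = base_code(s[e]);
      if (c < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t) c) & mask;
      if (++run >= k) {
        uint64_t hv = mix64(val ^ (seed * 0x9E3779B97F4A7C15ULL));
        int w = e - k + 1;
        if (best < 0 || (maximizer ? (hv > best_hv) : (hv < best_hv))) {
          best = w; best_hv = hv;
        }
      }
    }
  } else {
    // prefix counts of ineligible characters
    std::vector<int> inv(L + 1, 0);
    for (int i = 0; i < L; ++i) inv[i + 1] = inv[i] + (base_code(s[i]) < 0 ? 1 : 0);
    for (int w = 0; w + k <= L; ++w) {
      if (inv[w + k] != inv[w]) continue;
      if (best < 0) { best = w; continue; }
      int cmp = std::strncmp(s + w, s + best, k);
      if (maximizer ? (cmp > 0) : (cmp < 0)) best = w;
    }
  }
  return best;
}

// per-read selected k-minimizer (or k-maximizer) over both strands.
// strand tie on equal-ranked k-mers: forward preferred; within a strand the
// leftmost occurrence wins.
// Returns list(kmer, pos, strand): pos is 0-based within the oriented strand,
// strand 0 = forward, 1 = reverse complement; pos = -1 if no eligible window.
// [[Rcpp::export]]
List cpp_scan_minimizers(CharacterVector fwd, CharacterVector rcv, int k,
                         bool maximizer, bool both_strands,
                         bool hashed, double seed) {
  int n = fwd.size();
  IntegerVector pos(n), strand(n);
  CharacterVector kmer(n);
  uint64_t sd = (uint64_t) seed;
  for (int i = 0; i < n; ++i) {
    const char* f = CHAR(STRING_ELT(fwd, i));
    int L = (int) std::strlen(f);
    int pf = scan_strand(f, L, k, maximizer, hashed, sd);
    int pr = -1;
    const char* r = NULL;
    if (both_strands) {
      r = CHAR(STRING_ELT(rcv, i));
      pr = scan_strand(r, L, k, maximizer, hashed, sd);
    }
    int sel_strand = 0, sel_pos = pf;
    const char* sel_ptr = f;
    if (pf < 0 && pr >= 0) { sel_strand = 1; sel_pos = pr; sel_ptr = r; }
    else if (pf >= 0 && pr >= 0) {
      int cmp = std::strncmp(r + pr, f + pf, k);
      bool rc_wins = maximizer ? (cmp > 0) : (cmp < 0);
      if (rc_wins) { sel_strand = 1; sel_pos = pr; sel_ptr = r; }
    }
    if (sel_pos < 0) {
      pos[i] = -1; strand[i] = NA_INTEGER; kmer[i] = NA_STRING;
    } else {
      pos[i] = sel_pos; strand[i] = sel_strand;
      kmer[i] = std::string(sel_ptr + sel_pos, (size_t) k);
    }
  }
  return List::create(_["kmer"] = kmer, _["pos"] = pos, _["strand"] = strand);
}

// duplicate-detection key: canonical 31-minimizer block key, invariant under
// reverse complement. Tie chain: smaller k-mer, then smaller in-strand
// position, then lexicographically smaller oriented read.
// Returns list(key, orient) with orient 0 = forward, 1 = rc chosen as the
// read's canonical orientation.
// [[Rcpp::export]]
List cpp_dedup_keys(CharacterVector fwd, CharacterVector rcv, int k) {
  int n = fwd.size();
  CharacterVector key(n);
  IntegerVector orient(n);
  for (int i = 0; i < n; ++i) {
    const char* f = CHAR(STRING_ELT(fwd, i));
    const char* r = CHAR(STRING_ELT(rcv, i));
    int L = (int) std::strlen(f);
    int kk = k <= L ? k : L;
    int pf = scan_strand(f, L, kk, false, false, 0);
    int pr = scan_strand(r, L, kk, false, false, 0);
    int ori;
    if (pf < 0 && pr < 0) {
      // no eligible window at all: fall back to the canonical full sequence
      ori = (std::strcmp(f, r) <= 0) ? 0 : 1;
      key[i] = std::string("#") + (ori == 0 ? f : r);
      orient[i] = ori;
      continue;
    }
    if (pf < 0) ori = 1;
    else if (pr < 0) ori = 0;
    else {
      int cmp = std::strncmp(f + pf, r + pr, kk);
      if (cmp < 0) ori = 0;
      else if (cmp > 0) ori = 1;
      else if (pf < pr) ori = 0;
      else if (pr < pf) ori = 1;
      else ori = (std::strcmp(f, r) <= 0) ? 0 : 1;
    }
    const char* s = (ori == 0) ? f : r;
    int p = (ori == 0) ? pf : pr;
    key[i] = std::string(s + p, (size_t) kk) + "@" + std::to_string(p);
    orient[i] = ori;
  }
  return List::create(_["key"] = key, _["orient"] = orient);
}

struct EdgeAcc {
  std::vector<int> u, v, rel, mb, ob, weight;
  std::vector<int> rc;
};

// alignment of two oriented sequences with eb starting at sb (<= 0) relative
// to ea; returns mismatch count in the overlap or -1 if over budget
static inline int count_mismatches(const char* ea, int La, const char* eb,
                                   int Lb, int sb, int ov, int budget) {
  int mb = 0;
  for (int p = 0; p < ov; ++p) {
    if (ea[p] != eb[p - sb]) {
      if (++mb > budget) return -1;
    }
  }
  return mb;
}

// Candidate edges within blocks of one indexing round.
// Members are given as flat arrays; each block is members[start .. start+len),
// sorted by in-strand minimizer position ascending. Each member is compared
// with up to search_limit preceding members, aligning at the shared anchor.
// Edges are canonicalized to (u < v, u on forward strand); `rel` is the start
// of v's oriented sequence relative to u's.
// [[Rcpp::export]]
DataFrame cpp_scan_block_edges(CharacterVector fwd, CharacterVector rcv,
                               IntegerVector lens,
                               IntegerVector member_read,
                               IntegerVector member_pos,
                               IntegerVector member_strand,
                               IntegerVector block_start,
                               IntegerVector block_len,
                               int search_limit, int max_weight) {
  int nread = fwd.size();
  std::vector<const char*> pf(nread), pr(nread);
  for (int i = 0; i < nread; ++i) {
    pf[i] = CHAR(STRING_ELT(fwd, i));
    pr[i] = CHAR(STRING_ELT(rcv, i));
  }
  EdgeAcc acc;
  int nb = block_start.size();
  for (int b = 0; b < nb; ++b) {
    int st = block_start[b], sl = block_len[b];
    for (int j = 1; j < sl; ++j) {
      int lo = j - search_limit; if (lo < 0) lo = 0;
      int rj = member_read[st + j], pj = member_pos[st + j],
          tj = member_strand[st + j];
      const char* ej = tj ? pr[rj] : pf[rj];
      int Lj = lens[rj];
      for (int i = lo; i < j; ++i) {
        int ri = member_read[st + i];
        if (ri == rj) continue;
        int pi = member_pos[st + i], ti = member_strand[st + i];
        const char* ei = ti ? pr[ri] : pf[ri];
        int Li = lens[ri];
        // anchor alignment: e_i at 0, e_j at sb = pi - pj (<= 0, sorted)
        int sb = pi - pj;
        int ov = Li < (sb + Lj) ? Li : (sb + Lj);
        if (ov < 1) continue;
        // uncovered flanks of each read in this layout
        int h_i = (0 < -sb) ? 0 : 0;            // e_i head is never uncovered of itself
        // flanks of read i w.r.t. read j: i spans [0,Li), j spans [sb, sb+Lj)
        h_i = (sb > 0) ? sb : 0;                 // sb <= 0 so 0
        int t_i = Li - (sb + Lj); if (t_i < 0) t_i = 0;
        int h_j = 0 - sb; if (h_j < 0) h_j = 0;  // = -sb
        int t_j = (sb + Lj) - Li; if (t_j < 0) t_j = 0;
        bool same_span = (h_i == 0 && t_i == 0 && h_j == 0 && t_j == 0);
        if (!same_span) {
          // mutual decodability: each read must overhang on exactly one side
          if ((h_i > 0) + (t_i > 0) != 1) continue;
          if ((h_j > 0) + (t_j > 0) != 1) continue;
        }
        // canonical layout: u = min index, forward strand
        int a = ri, b2 = rj, sa = 0, sbb = sb, ta = ti, tb = tj;
        int uu, vv, su, sv, stru, strv;
        if (a < b2) { uu = a; su = sa; stru = ta; vv = b2; sv = sbb; strv = tb; }
        else        { uu = b2; su = sbb; stru = tb; vv = a; sv = sa; strv = ta; }
        if (stru) { // mirror so that u reads forward
          int nsu = -(su + lens[uu]);
          int nsv = -(sv + lens[vv]);
          su = nsu; sv = nsv;
        }
        int rel = sv - su;
        int ob = rel >= 0 ? rel : -rel;
        if (ob > max_weight) continue;
        int budget = (max_weight - ob) / 3;
        int mb = count_mismatches(ei, Li, ej, Lj, sb, ov, budget);
        if (mb < 0) continue;
        if (mb == 0 && same_span) continue;  // identical/rc-identical: deduped upstream
        acc.u.push_back(uu + 1);
        acc.v.push_back(vv + 1);
        acc.rc.push_back(ti != tj ? 1 : 0);
        acc.rel.push_back(rel);
        acc.mb.push_back(mb);
        acc.ob.push_back(ob);
        acc.weight.push_back(3 * mb + ob);
      }
    }
  }
  return DataFrame::create(_["u"] = acc.u, _["v"] = acc.v, _["rc"] = acc.rc,
                           _["rel"] = acc.rel, _["mb"] = acc.mb,
                           _["ob"] = acc.ob, _["weight"] = acc.weight);
}

// Exhaustive all-pairs, all-layouts, both-strand search for the
// weight-lightest alignment of every unordered pair. Used as the independent
// oracle for the heuristic edge search. Applies the same admissibility rules
// (single-flank decodability; weight = 3*mb + ob with ob taken in the
// canonical u-forward layout).
// [[Rcpp::export]]
DataFrame cpp_brute_best(CharacterVector fwd, CharacterVector rcv,
                         IntegerVector lens, int max_weight) {
  int n = fwd.size();
  std::vector<const char*> pf(n), pr(n);
  for (int i = 0; i < n; ++i) {
    pf[i] = CHAR(STRING_ELT(fwd, i));
    pr[i] = CHAR(STRING_ELT(rcv, i));
  }
  std::vector<int> U, V, W, REL, MB, RC;
  for (int u = 0; u < n; ++u) {
    int Lu = lens[u];
    for (int v = u + 1; v < n; ++v) {
      int Lv = lens[v];
      int best_w = max_weight + 1, best_rel = 0, best_mb = 0, best_rc = -1;
      for (int rc = 0; rc <= 1; ++rc) {
        const char* ev = rc ? pr[v] : pf[v];
        for (int rel = -(Lv - 1); rel <= Lu - 1; ++rel) {
          // u spans [0, Lu), v spans [rel, rel + Lv)
          int lo = rel > 0 ? rel : 0;
          int hi = Lu < (rel + Lv) ? Lu : (rel + Lv);
          int ov = hi - lo;
          if (ov < 1) continue;
          int h_u = 0 > rel ? 0 : rel;  // uncovered head of u = max(0, rel)
          h_u = rel > 0 ? rel : 0;
          int t_u = Lu - (rel + Lv); if (t_u < 0) t_u = 0;
          int h_v = -rel; if (h_v < 0) h_v = 0;
          int t_v = (rel + Lv) - Lu; if (t_v < 0) t_v = 0;
          bool same_span = (h_u == 0 && t_u == 0 && h_v == 0 && t_v == 0);
          if (!same_span) {
            if ((h_u > 0) + (t_u > 0) != 1) continue;
            if ((h_v > 0) + (t_v > 0) != 1) continue;
          }
          int ob = rel >= 0 ? rel : -rel;
          if (ob >= best_w) continue;
          int budget = (best_w - 1 - ob) / 3;
          int mb = 0; bool over = false;
          for (int p = lo; p < hi; ++p) {
            if (pf[u][p] != ev[p - rel]) { if (++mb > budget) { over = true; break; } }
          }
          if (over) continue;
          if (mb == 0 && same_span) continue;
          int w = 3 * mb + ob;
          if (w < best_w) {
            best_w = w; best_rel = rel; best_mb = mb; best_rc = rc;
          }
        }
      }
      if (best_rc >= 0 && best_w <= max_weight) {
        U.push_back(u + 1); V.push_back(v + 1); W.push_back(best_w);
        REL.push_back(best_rel); MB.push_back(best_mb); RC.push_back(best_rc);
      }
    }
  }
  return DataFrame::create(_["u"] = U, _["v"] = V, _["weight"] = W,
                           _["rel"] = REL, _["mb"] = MB, _["rc"] = RC);
}
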
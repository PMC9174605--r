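#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// Nucleotide encoding: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// Code 4 never matches anything, itself included.

static const int NCODE = 4;
static const int NEG_INF = -1000000000;

static inline int encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return NCODE;
  }
}

static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)encode_base(s[i]);
  return v;
}

static inline int subst_score(uint8_t a, uint8_t b, int reward, int penalty) {
  if (a == NCODE || b == NCODE) return penalty;
  return (a == b) ? reward : penalty;
}

// ---------------------------------------------------------------------------
// Low-complexity mask: for each sequence position p where a w-mer starts,
// compute the dinucleotide Shannon entropy over a fixed window anchored two
// bases upstream of the seed (clamped at the ends).  Seeds whose window
// entropy falls below the cutoff (bits) are skipped.
// ---------------------------------------------------------------------------
static std::vector<uint8_t> lowcomp_mask(const std::vector<uint8_t>& s, int w,
                                         int window, double min_entropy) {
  int n = (int)s.size();
  std::vector<uint8_t> mask(std::max(0, n - w + 1), 0);
  for (int p = 0; p < (int)mask.size(); ++p) {
    int lo = p - 2;
    if (lo < 0) lo = 0;
    int hi = lo + window;
    if (hi > n) { hi = n; lo = std::max(0, hi - window); }
    int counts[16] = {0};
    int tot = 0;
    for (int i = lo; i + 1 < hi; ++i) {
      if (s[i] == NCODE || s[i + 1] == NCODE) continue;
      counts[s[i] * 4 + s[i + 1]]++;
      tot++;
    }
    double H = 0.0;
    for (int k = 0; k < 16; ++k) {
      if (counts[k] > 0) {
        double f = (double)counts[k] / tot;
        H -= f * std::log2(f);
      }
    }
    if (tot == 0 || H < min_entropy) mask[p] = 1;
  }
  return mask;
}

// ---------------------------------------------------------------------------
// Affine-gap x-drop extension (one direction).
//
// Aligns A[0..alen) against B[0..blen) anchored at (0,0); the caller passes
// the sequence spans already oriented in the direction of extension (for
// leftward extension the spans are reversed).  Returns the best-scoring
// alignment endpoint over match-state cells, with traceback strings.
//
// States: M (ends in aligned pair), X (gap in B, consumes A), Y (gap in A,
// consumes B).  A gap of length k costs gopen + k * gext.  Cells whose best
// state score drops more than xdrop below the running best are pruned.
// ---------------------------------------------------------------------------
struct ExtResult {
  int score;            // best extension score (>= 0)
  int alen_used;        // characters of A consumed
  int blen_used;        // characters of B consumed
  std::string aln_a;    // alignment strings in extension direction
  std::string aln_b;
};

struct DpRow {
  int jlo;
  std::vector<int> M, X, Y;
  std::vector<uint8_t> tb;  // bits 0-1: M pred (0=M,1=X,2=Y); bit2: X pred ext; bit3: Y pred ext
};

static const char BASES[6] = "ACGTN";

// A and B point at the first character to consume; a_step/b_step are +1 for
// rightward extension and -1 for leftward (strided access avoids copying
// reversed prefixes for every seed).
static ExtResult xdrop_extend(const uint8_t* A, int alen, int a_step,
                              const uint8_t* B, int blen, int b_step,
                              int reward, int penalty, int gopen, int gext, int xdrop) {
  ExtResult res;
  res.score = 0; res.alen_used = 0; res.blen_used = 0;

  std::vector<DpRow> rows;
  int best = 0, besti = 0, bestj = 0;

  // Row 0: M(0,0)=0 and a horizontal gap run Y(0,j).
  {
    DpRow r; r.jlo = 0;
    r.M.push_back(0); r.X.push_back(NEG_INF); r.Y.push_back(NEG_INF); r.tb.push_back(0);
    for (int j = 1; j <= blen; ++j) {
      int y = (j == 1) ? -(gopen + gext) : r.Y[j - 1] - gext;
      if (y < best - xdrop) break;
      r.M.push_back(NEG_INF); r.X.push_back(NEG_INF); r.Y.push_back(y);
      r.tb.push_back(j == 1 ? 0 : 8);
    }
    rows.push_back(std::move(r));
  }

  for (int i = 1; i <= alen; ++i) {
    const DpRow& prev = rows.back();
    int pjlo = prev.jlo;
    int pjhi = prev.jlo + (int)prev.M.size() - 1;
    int jlo = pjlo;           // X from above keeps j; M needs j-1 >= pjlo
    int jhi = pjhi + 1;
    if (jhi > blen) jhi = blen;
    if (jlo > jhi) break;

    DpRow r; r.jlo = jlo;
    r.M.reserve(jhi - jlo + 2); r.X.reserve(jhi - jlo + 2);
    r.Y.reserve(jhi - jlo + 2); r.tb.reserve(jhi - jlo + 2);
    bool any_alive = false;

    for (int j = jlo; j <= jhi; ++j) {
      // predecessors from previous row
      int pM = NEG_INF, pX = NEG_INF, pY = NEG_INF;       // at (i-1, j)
      int dM = NEG_INF, dX = NEG_INF, dY = NEG_INF;       // at (i-1, j-1)
      int k = j - pjlo;
      if (k >= 0 && k < (int)prev.M.size()) { pM = prev.M[k]; pX = prev.X[k]; pY = prev.Y[k]; }
      int kd = j - 1 - pjlo;
      if (kd >= 0 && kd < (int)prev.M.size()) { dM = prev.M[kd]; dX = prev.X[kd]; dY = prev.Y[kd]; }

      uint8_t tb = 0;
      int x = NEG_INF;
      if (pM > NEG_INF / 2 || pX > NEG_INF / 2) {
        int xo = (pM > NEG_INF / 2) ? pM - gopen - gext : NEG_INF;
        int xe = (pX > NEG_INF / 2) ? pX - gext : NEG_INF;
        if (xe > xo) { x = xe; tb |= 4; } else x = xo;
      }

      int y = NEG_INF;
      if (!r.M.empty()) {  // (i, j-1) exists in this row
        int lM = r.M.back(), lY = r.Y.back();
        int yo = (lM > NEG_INF / 2) ? lM - gopen - gext : NEG_INF;
        int ye = (lY > NEG_INF / 2) ? lY - gext : NEG_INF;
        if (ye > yo) { y = ye; tb |= 8; } else y = yo;
      }

      int m = NEG_INF;
      if (j >= 1) {
        int dbest = dM; uint8_t mp = 0;
        if (dX > dbest) { dbest = dX; mp = 1; }
        if (dY > dbest) { dbest = dY; mp = 2; }
        if (dbest > NEG_INF / 2)
          m = dbest + subst_score(A[(i - 1) * a_step], B[(j - 1) * b_step],
                                  reward, penalty);
        tb |= mp;
      }

      int cell = std::max(m, std::max(x, y));
      if (cell < best - xdrop) { m = x = y = NEG_INF; }
      else any_alive = true;

      if (m > best) { best = m; besti = i; bestj = j; }
      r.M.push_back(m); r.X.push_back(x); r.Y.push_back(y); r.tb.push_back(tb);
    }

    // continue a horizontal gap run past jhi while it survives the x-drop
    int j = jhi + 1;
    while (j <= blen && !r.M.empty()) {
      int lM = r.M.back(), lY = r.Y.back();
      int yo = (lM > NEG_INF / 2) ? lM - gopen - gext : NEG_INF;
      int ye = (lY > NEG_INF / 2) ? lY - gext : NEG_INF;
      int y = std::max(yo, ye);
      if (y < best - xdrop) break;
      r.M.push_back(NEG_INF); r.X.push_back(NEG_INF); r.Y.push_back(y);
      r.tb.push_back((uint8_t)((ye > yo) ? 8 : 0));
      any_alive = true;
      ++j;
    }

    // trim dead edges
    int lead = 0, sz = (int)r.M.size();
    while (lead < sz && r.M[lead] <= NEG_INF / 2 && r.X[lead] <= NEG_INF / 2 && r.Y[lead] <= NEG_INF / 2)
      ++lead;
    int tail = sz;
    while (tail > lead && r.M[tail - 1] <= NEG_INF / 2 && r.X[tail - 1] <= NEG_INF / 2 && r.Y[tail - 1] <= NEG_INF / 2)
      --tail;
    if (!any_alive || tail <= lead) break;
    if (lead > 0 || tail < sz) {
      r.jlo += lead;
      r.M.assign(r.M.begin() + lead, r.M.begin() + tail);
      r.X.assign(r.X.begin() + lead, r.X.begin() + tail);
      r.Y.assign(r.Y.begin() + lead, r.Y.begin() + tail);
      r.tb.assign(r.tb.begin() + lead, r.tb.begin() + tail);
    }
    rows.push_back(std::move(r));
  }

  res.score = best;
  res.alen_used = besti;
  res.blen_used = bestj;
  if (best <= 0) { res.score = 0; res.alen_used = 0; res.blen_used = 0; return res; }

  // traceback from (besti, bestj), state M
  std::string sa, sb;
  int i = besti, j = bestj, state = 0;  // 0=M 1=X 2=Y
  while (i > 0 || j > 0) {
    if (i == 0 && j == 0) break;
    const DpRow& r = rows[i];
    int k = j - r.jlo;
    uint8_t tb = r.tb[k];
    if (state == 0) {
      sa.push_back(BASES[A[(i - 1) * a_step]]);
      sb.push_back(BASES[B[(j - 1) * b_step]]);
      state = tb & 3;
      --i; --j;
    } else if (state == 1) {  // X: gap in B, consume A
      sa.push_back(BASES[A[(i - 1) * a_step]]);
      sb.push_back('-');
      state = (tb & 4) ? 1 : 0;
      --i;
    } else {                  // Y: gap in A, consume B
      sa.push_back('-');
      sb.push_back(BASES[B[(j - 1) * b_step]]);
      state = (tb & 8) ? 2 : 0;
      --j;
    }
  }
  // built back-to-front relative to extension direction
  res.aln_a.assign(sa.rbegin(), sa.rend());
  res.aln_b.assign(sb.rbegin(), sb.rend());
  return res;
}

// allocation-free ungapped x-drop extension; returns score gained and
// characters consumed in one direction
static inline void ungapped_extend(const uint8_t* A, int alen, int a_step,
                                   const uint8_t* B, int blen, int b_step,
                                   int reward, int penalty, int xdrop,
                                   int* best_score, int* best_len) {
  int score = 0, best = 0, bl = 0;
  int n = std::min(alen, blen);
  for (int i = 0; i < n; ++i) {
    score += subst_score(A[i * a_step], B[i * b_step], reward, penalty);
    if (score > best) { best = score; bl = i + 1; }
    else if (score < best - xdrop) break;
  }
  *best_score = best;
  *best_len = bl;
}

// ---------------------------------------------------------------------------
// Full hit from one seed: leftward + seed + rightward extension.
// Two-stage strategy as in blastn: a cheap ungapped x-drop extension first;
// the gapped dynamic program runs only when the ungapped score reaches
// gap_trigger (pass a very negative trigger to force gapped extension).
// ---------------------------------------------------------------------------
struct Hit {
  int qs, qe, ss, se;   // 0-based half-open on the scanned sequences
  int score;
  std::string aq, as;
};

static Hit extend_from_seed(const std::vector<uint8_t>& Q, const std::vector<uint8_t>& S,
                            int qpos, int spos, int w,
                            int reward, int penalty, int gopen, int gext, int xdrop,
                            int gap_trigger, bool* gapped_run) {
  int ls, ll, rs, rl;
  ungapped_extend(qpos ? Q.data() + qpos - 1 : Q.data(), qpos, -1,
                  spos ? S.data() + spos - 1 : S.data(), spos, -1,
                  reward, penalty, xdrop, &ls, &ll);
  ungapped_extend(Q.data() + qpos + w, (int)Q.size() - qpos - w, +1,
                  S.data() + spos + w, (int)S.size() - spos - w, +1,
                  reward, penalty, xdrop, &rs, &rl);
  int ungapped_score = ls + w * reward + rs;
  if (ungapped_score < gap_trigger) {
    *gapped_run = false;
    Hit h;
    h.qs = qpos - ll; h.ss = spos - ll;
    h.qe = qpos + w + rl; h.se = spos + w + rl;
    h.score = ungapped_score;
    return h;  // alignment strings omitted: hit is below reporting range
  }
  *gapped_run = true;
  ExtResult left = xdrop_extend(qpos ? Q.data() + qpos - 1 : Q.data(), qpos, -1,
                                spos ? S.data() + spos - 1 : S.data(), spos, -1,
                                reward, penalty, gopen, gext, xdrop);
  ExtResult right = xdrop_extend(Q.data() + qpos + w, (int)Q.size() - qpos - w, +1,
                                 S.data() + spos + w, (int)S.size() - spos - w, +1,
                                 reward, penalty, gopen, gext, xdrop);
  Hit h;
  h.qs = qpos - left.alen_used;
  h.ss = spos - left.blen_used;
  h.qe = qpos + w + right.alen_used;
  h.se = spos + w + right.blen_used;
  h.score = left.score + w * reward + right.score;
  std::string seed_a, seed_b;
  for (int i = 0; i < w; ++i) { seed_a.push_back(BASES[Q[qpos + i]]); seed_b.push_back(BASES[S[spos + i]]); }
  std::string la(left.aln_a.rbegin(), left.aln_a.rend());
  std::string lb(left.aln_b.rbegin(), left.aln_b.rend());
  h.aq = la + seed_a + right.aln_a;
  h.as = lb + seed_b + right.aln_b;
  return h;
}

// [[Rcpp::export(name = ".Call_extend_seed")]]
List cpp_extend_seed(std::string qseq, std::string sseq, int qpos, int spos, int w,
                     int reward, int penalty, int gapopen, int gapextend, int xdrop) {
  std::vector<uint8_t> Q = encode_seq(qseq), S = encode_seq(sseq);
  if (qpos < 0 || spos < 0 || qpos + w > (int)Q.size() || spos + w > (int)S.size())
    stop("seed out of range");
  bool gapped_run = false;
  Hit h = extend_from_seed(Q, S, qpos, spos, w, reward, penalty, gapopen,
                           gapextend, xdrop, NEG_INF, &gapped_run);
  return List::create(_["q_start"] = h.qs, _["q_end"] = h.qe,
                      _["s_start"] = h.ss, _["s_end"] = h.se,
                      _["score"] = h.score,
                      _["aligned_q"] = h.aq, _["aligned_s"] = h.as);
}

// ---------------------------------------------------------------------------
// Seed scan over a sequence pair (one strand orientation).
//
// self_plus:  subject is the same molecule, same strand; only seeds with
//             spos > qpos are extended (skips the trivial diagonal and
//             collapses (q,s)/(s,q) mirrors).
// self_minus: subject is the reverse complement of the query (length L);
//             only seeds whose forward-strand subject start (L - spos - w)
//             is >= qpos are extended (mirror collapse).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".Call_scan_pair")]]
DataFrame cpp_scan_pair(std::string qseq, std::string sseq,
                        bool self_plus, bool self_minus,
                        int w, int reward, int penalty, int gapopen, int gapextend,
                        int xdrop, int min_score, int gap_trigger,
                        int lowcomp_window, double min_entropy) {
  std::vector<uint8_t> Q = encode_seq(qseq), S = encode_seq(sseq);
  int qn = (int)Q.size(), sn = (int)S.size();
  std::vector<int> out_qs, out_qe, out_ss, out_se, out_score;
  std::vector<std::string> out_aq, out_as;

  if (qn < w || sn < w)
    return DataFrame::create(_["q_start"] = out_qs, _["q_end"] = out_qe,
                             _["s_start"] = out_ss, _["s_end"] = out_se,
                             _["score"] = out_score,
                             _["aligned_q"] = out_aq, _["aligned_s"] = out_as,
                             _["stringsAsFactors"] = false);

  std::vector<uint8_t> qmask = lowcomp_mask(Q, w, lowcomp_window, min_entropy);
  std::vector<uint8_t> smask = (self_plus) ? qmask : lowcomp_mask(S, w, lowcomp_window, min_entropy);

  // hash subject w-mers
  int nbuckets = 1;
  for (int i = 0; i < w; ++i) nbuckets *= 4;
  std::vector<std::vector<int>> buckets(nbuckets);
  {
    int code = 0, valid = 0;
    for (int p = 0; p < sn; ++p) {
      if (S[p] == NCODE) { valid = 0; code = 0; continue; }
      code = ((code << 2) | S[p]) & (nbuckets - 1);
      if (++valid >= w) {
        int start = p - w + 1;
        if (!smask[start]) buckets[code].push_back(start);
      }
    }
  }

  // furthest q-end already extended, per diagonal (spos - qpos, offset by qn)
  std::vector<int> diag_end(qn + sn + 1, -1);

  int code = 0, valid = 0;
  for (int p = 0; p < qn; ++p) {
    if (Q[p] == NCODE) { valid = 0; code = 0; continue; }
    code = ((code << 2) | Q[p]) & (nbuckets - 1);
    if (++valid < w) continue;
    int qpos = p - w + 1;
    if (qmask[qpos]) continue;
    const std::vector<int>& bl = buckets[code];
    for (size_t bi = 0; bi < bl.size(); ++bi) {
      int spos = bl[bi];
      if (self_plus && spos <= qpos) continue;
      if (self_minus && (sn - spos - w) < qpos) continue;
      int diag = spos - qpos + qn;
      if (qpos < diag_end[diag]) continue;
      bool gapped_run = false;
      Hit h = extend_from_seed(Q, S, qpos, spos, w, reward, penalty,
                               gapopen, gapextend, xdrop,
                               std::min(gap_trigger, min_score), &gapped_run);
      // mark covered diagonals (start- and end-diagonal span of the hit)
      int d1 = h.ss - h.qs + qn, d2 = h.se - h.qe + qn;
      if (d1 > d2) std::swap(d1, d2);
      for (int d = d1; d <= d2; ++d)
        if (d >= 0 && d <= qn + sn && h.qe > diag_end[d]) diag_end[d] = h.qe;
      if (gapped_run && h.score >= min_score) {
        out_qs.push_back(h.qs); out_qe.push_back(h.qe);
        out_ss.push_back(h.ss); out_se.push_back(h.se);
        out_score.push_back(h.score);
        out_aq.push_back(h.aq); out_as.push_back(h.as);
      }
    }
  }

  return DataFrame::create(_["q_start"] = out_qs, _["q_end"] = out_qe,
                           _["s_start"] = out_ss, _["s_end"] = out_se,
                           _["score"] = out_score,
                           _["aligned_q"] = out_aq, _["aligned_s"] = out_as,
                           _["stringsAsFactors"] = false);
}
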
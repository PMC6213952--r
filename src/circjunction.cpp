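#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). The first gapped
// column of a run costs gap_open, each further column gap_extend. N never
// matches (scored as mismatch). Traceback is deterministic: the best cell is
// the first maximum in row-major order and ties within a cell prefer
// diagonal > up (gap in b) > left (gap in a), gap-open over gap-extend.

struct Scoring {
  int match, mismatch, gap_open, gap_extend;
};

struct AlnResult {
  int score = 0;
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  int mismatches = 0, gaps = 0, columns = 0;
  std::string al_a, al_b;
};

static inline bool base_eq(char x, char y) {
  return x == y && x != 'N' && y != 'N';
}

static AlnResult sw_align(const std::string &a, const std::string &b,
                          const Scoring &sc, bool build_strings) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  const int NEG = INT_MIN / 4;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  // cH: 0 stop, 1 diag, 2 up(E), 3 left(F); cE/cF: 1 open, 0 extend
  std::vector<unsigned char> cH((n + 1) * W, 0), cE((n + 1) * W, 0),
      cF((n + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int id = i * W + j;
      const int up_open = H[id - W] + sc.gap_open;
      const int up_ext = E[id - W] + sc.gap_extend;
      E[id] = std::max(up_open, up_ext);
      cE[id] = (up_open >= up_ext) ? 1 : 0;
      const int lf_open = H[id - 1] + sc.gap_open;
      const int lf_ext = F[id - 1] + sc.gap_extend;
      F[id] = std::max(lf_open, lf_ext);
      cF[id] = (lf_open >= lf_ext) ? 1 : 0;
      const int sub =
          base_eq(a[i - 1], b[j - 1]) ? sc.match : sc.mismatch;
      const int diag = H[id - W - 1] + sub;
      int h = 0;
      unsigned char c = 0;
      if (diag > h) { h = diag; c = 1; }
      if (E[id] > h) { h = E[id]; c = 2; }
      if (F[id] > h) { h = F[id]; c = 3; }
      H[id] = h;
      cH[id] = c;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  AlnResult res;
  if (best <= 0) return res;
  res.score = best;
  res.a_end = bi;
  res.b_end = bj;

  int i = bi, j = bj;
  std::string ra, rb;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    const int id = i * W + j;
    if (state == 0) {
      const unsigned char c = cH[id];
      if (c == 0) break;
      if (c == 1) {
        if (!base_eq(a[i - 1], b[j - 1])) res.mismatches++;
        res.columns++;
        if (build_strings) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
        --i; --j;
      } else if (c == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // gap in b, consume a
      res.gaps++;
      res.columns++;
      if (build_strings) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      const unsigned char c = cE[id];
      --i;
      if (c == 1) state = 0;
    } else { // gap in a, consume b
      res.gaps++;
      res.columns++;
      if (build_strings) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      const unsigned char c = cF[id];
      --j;
      if (c == 1) state = 0;
    }
  }
  res.a_start = i + 1;
  res.b_start = j + 1;
  if (build_strings) {
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    res.al_a = ra;
    res.al_b = rb;
  }
  return res;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  AlnResult r = sw_align(a, b, sc, true);
  return List::create(
      _["score"] = r.score, _["a_start"] = r.a_start, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end,
      _["mismatches"] = r.mismatches, _["gaps"] = r.gaps,
      _["columns"] = r.columns, _["aligned_a"] = r.al_a,
      _["aligned_b"] = r.al_b);
}

// Ungapped screen at clip-consistent offsets followed by the full DP.
// For a left-cluster read with clip boundary after position k1 and a
// right-cluster read with boundary after k2, two reads of the same junction
// overlap on the diagonal with offset k2 - k1; gapped alignments can shift
// this by at most max_gap columns. Pairs whose best ungapped diagonal within
// that band still shows more than max_mismatch + max_gap mismatches cannot
// pass the thresholds for substitution-only data and are rejected without
// the DP (see the methods vignette).
// [[Rcpp::export(name = ".batch_filter_cpp")]]
List batch_filter_cpp(CharacterVector seq_l, IntegerVector k1,
                      CharacterVector seq_r, IntegerVector k2,
                      IntegerVector il, IntegerVector ir, int match,
                      int mismatch, int gap_open, int gap_extend,
                      int max_mismatch, int max_gap, int min_overlap) {
  const int nl = seq_l.size(), nr = seq_r.size(), np = il.size();
  std::vector<std::string> L(nl), R(nr);
  for (int i = 0; i < nl; ++i) L[i] = as<std::string>(seq_l[i]);
  for (int i = 0; i < nr; ++i) R[i] = as<std::string>(seq_r[i]);
  Scoring sc{match, mismatch, gap_open, gap_extend};

  LogicalVector accept(np);
  IntegerVector score(np, NA_INTEGER), mism(np, NA_INTEGER),
      gaps(np, NA_INTEGER), cols(np, NA_INTEGER);

  for (int p = 0; p < np; ++p) {
    const std::string &A = L[il[p] - 1];
    const std::string &B = R[ir[p] - 1];
    const int kA = k1[il[p] - 1], kB = k2[ir[p] - 1];
    const int lenA = A.size(), lenB = B.size();
    const int mA = lenA - kA, mB = lenB - kB;
    const int c = std::min(kA, kB), d = std::min(mA, mB);
    accept[p] = false;
    if (c < 1 || d < 1 || c + d < min_overlap - max_gap) continue;

    int best_mm = INT_MAX;
    for (int s = -max_gap; s <= max_gap; ++s) {
      const int off = kB - kA + s;
      int p0 = std::max(1, 1 - off);
      int p1 = std::min(lenA, lenB - off);
      if (p1 - p0 + 1 < min_overlap - max_gap) continue;
      if (p0 > kA || p1 < kA + 1) continue; // must span the boundary
      int mm = 0;
      for (int q = p0; q <= p1 && mm <= max_mismatch + max_gap; ++q)
        if (!base_eq(A[q - 1], B[q + off - 1])) ++mm;
      if (mm < best_mm) best_mm = mm;
      if (best_mm == 0) break;
    }
    if (best_mm > max_mismatch + max_gap) continue;

    AlnResult r = sw_align(A, B, sc, false);
    score[p] = r.score;
    mism[p] = r.mismatches;
    gaps[p] = r.gaps;
    cols[p] = r.columns;
    const bool spans = r.score > 0 && r.a_start <= kA && r.a_end >= kA + 1 &&
                       r.b_start <= kB && r.b_end >= kB + 1;
    accept[p] = spans && r.columns >= min_overlap &&
                r.mismatches <= max_mismatch && r.gaps <= max_gap;
  }
  return List::create(_["accept"] = accept, _["score"] = score,
                      _["mismatches"] = mism, _["gaps"] = gaps,
                      _["columns"] = cols);
}

// Genomic pieces traversed by simulated reads of one transcript.
// Segments are the transcript's genomic intervals in splicing order; a
// circular transcript wraps at its total length. Returns one row per
// traversed piece with the read's row index, genomic interval, the read
// offset where the piece starts (0-based), its length, and a keep flag
// that drops pieces genomically contained in a longer piece of the same
// read (multiple wraps of a small circle collapse onto the full-circle
// middle segment).
// [[Rcpp::export(name = ".read_pieces_cpp")]]
DataFrame read_pieces_cpp(IntegerVector tstart, int read_len,
                          IntegerVector seg_start, IntegerVector seg_end,
                          bool circular) {
  const int ns = seg_start.size();
  std::vector<int> seg_len(ns), cum(ns + 1, 0);
  for (int s = 0; s < ns; ++s) {
    seg_len[s] = seg_end[s] - seg_start[s] + 1;
    cum[s + 1] = cum[s] + seg_len[s];
  }
  const int Ltot = cum[ns];
  std::vector<int> o_read, o_gs, o_ge, o_roff, o_len;
  std::vector<int> o_keep;

  for (int r = 0; r < tstart.size(); ++r) {
    int remaining = read_len;
    long tp = tstart[r]; // 1-based transcript coordinate
    int roff = 0;
    const size_t first_piece = o_read.size();
    while (remaining > 0) {
      long t0 = tp;
      if (circular) t0 = ((tp - 1) % Ltot) + 1;
      if (t0 > Ltot) break; // linear read runs off the transcript: clamp
      // locate segment containing t0
      int si = int(std::upper_bound(cum.begin(), cum.end(), t0 - 1) -
                   cum.begin()) - 1;
      const int within = int(t0 - 1 - cum[si]);
      int take = std::min(remaining, seg_len[si] - within);
      o_read.push_back(r + 1);
      o_gs.push_back(seg_start[si] + within);
      o_ge.push_back(seg_start[si] + within + take - 1);
      o_roff.push_back(roff);
      o_len.push_back(take);
      o_keep.push_back(1);
      tp += take;
      roff += take;
      remaining -= take;
    }
    // containment dedup within this read, longest pieces win
    const size_t last_piece = o_read.size();
    std::vector<size_t> idx;
    for (size_t q = first_piece; q < last_piece; ++q) idx.push_back(q);
    std::sort(idx.begin(), idx.end(), [&](size_t x, size_t y) {
      if (o_len[x] != o_len[y]) return o_len[x] > o_len[y];
      return o_roff[x] < o_roff[y];
    });
    std::vector<size_t> kept;
    for (size_t q : idx) {
      bool contained = false;
      for (size_t kq : kept)
        if (o_gs[kq] <= o_gs[q] && o_ge[kq] >= o_ge[q]) {
          contained = true;
          break;
        }
      if (contained)
        o_keep[q] = 0;
      else
        kept.push_back(q);
    }
  }
  return DataFrame::create(
      _["read_row"] = IntegerVector(o_read.begin(), o_read.end()),
      _["gstart"] = IntegerVector(o_gs.begin(), o_gs.end()),
      _["gend"] = IntegerVector(o_ge.begin(), o_ge.end()),
      _["roff"] = IntegerVector(o_roff.begin(), o_roff.end()),
      _["len"] = IntegerVector(o_len.begin(), o_len.end()),
      _["keep"] = IntegerVector(o_keep.begin(), o_keep.end()));
}
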
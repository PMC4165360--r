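#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Sequence characters are mapped to A=0, C=1, G=2, T=3, anything else
// (including N) = 4.  Code 4 contributes the column-minimum weight, so
// N-rich windows rarely clear a relative-score threshold.

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// Build a 5 x L scoring table from a 4 x L weight matrix: row 4 holds the
// per-column minimum (the N contribution).
static std::vector<double> scoreTable(const NumericMatrix& W) {
  int L = W.ncol();
  std::vector<double> tab(5 * L);
  for (int j = 0; j < L; ++j) {
    double mn = W(0, j);
    for (int b = 0; b < 4; ++b) {
      tab[b + 5 * j] = W(b, j);
      if (W(b, j) < mn) mn = W(b, j);
    }
    tab[4 + 5 * j] = mn;
  }
  return tab;
}

// Reverse-complement table: Wrc[b][j] = W[3-b][L-1-j].
static std::vector<double> rcTable(const NumericMatrix& W) {
  int L = W.ncol();
  std::vector<double> tab(5 * L);
  for (int j = 0; j < L; ++j) {
    int jj = L - 1 - j;
    double mn = W(0, jj);
    for (int b = 0; b < 4; ++b) {
      tab[b + 5 * j] = W(3 - b, jj);
      if (W(b, jj) < mn) mn = W(b, jj);
    }
    tab[4 + 5 * j] = mn;
  }
  return tab;
}

struct Hit {
  int start;      // 0-based window start
  int strand;     // 0 = '+', 1 = '-'
  double rel;
};

static void windowScores(const std::string& seq,
                         const std::vector<double>& fwd,
                         const std::vector<double>& rev,
                         int L, std::vector<double>& sF,
                         std::vector<double>& sR) {
  int n = (int) seq.size();
  int nw = n - L + 1;
  if (nw < 1) { sF.clear(); sR.clear(); return; }
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = baseCode(seq[i]);
  sF.assign(nw, 0.0);
  sR.assign(nw, 0.0);
  for (int s = 0; s < nw; ++s) {
    double a = 0.0, b = 0.0;
    for (int j = 0; j < L; ++j) {
      int c = code[s + j];
      a += fwd[c + 5 * j];
      b += rev[c + 5 * j];
    }
    sF[s] = a;
    sR[s] = b;
  }
}

// Scan sequences for all hits at or above `threshold` (relative score,
// 0-100), applying greedy overlap exclusion: hits retained in order of
// descending score (ties: leftmost, then '+' strand) such that retained
// hits overlap by at most `maxOverlap` bp.
// [[Rcpp::export]]
DataFrame cpp_scan_hits(CharacterVector seqs, NumericMatrix W,
                        double minScore, double maxScore,
                        double threshold, int maxOverlap) {
  int L = W.ncol();
  double span = maxScore - minScore;
  std::vector<double> fwd = scoreTable(W), rev = rcTable(W);
  std::vector<int> outSeq, outStart, outStrand;
  std::vector<double> outRel;
  std::vector<double> sF, sR;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string seq = as<std::string>(seqs[i]);
    windowScores(seq, fwd, rev, L, sF, sR);
    int nw = (int) sF.size();
    std::vector<Hit> cand;
    for (int s = 0; s < nw; ++s) {
      double rf = 100.0 * (sF[s] - minScore) / span;
      double rr = 100.0 * (sR[s] - minScore) / span;
      if (rf >= threshold) cand.push_back({s, 0, rf});
      if (rr >= threshold) cand.push_back({s, 1, rr});
    }
    // Rank on scores quantized at 1e-6 resolution so that mathematically
    // tied hits (e.g. a word and its own reverse complement, whose forward
    // and reverse score sums can differ in the last bit) resolve by the
    // documented leftmost/'+' tie-break rather than by summation order.
    std::stable_sort(cand.begin(), cand.end(), [](const Hit& a, const Hit& b) {
      long long qa = llround(a.rel * 1e6), qb = llround(b.rel * 1e6);
      if (qa != qb) return qa > qb;
      if (a.start != b.start) return a.start < b.start;
      return a.strand < b.strand;
    });
    std::vector<Hit> kept;
    for (const Hit& h : cand) {
      bool ok = true;
      for (const Hit& k : kept) {
        int d = h.start > k.start ? h.start - k.start : k.start - h.start;
        int ov = L - d;
        if (ov > maxOverlap) { ok = false; break; }
      }
      if (ok) kept.push_back(h);
    }
    std::sort(kept.begin(), kept.end(), [](const Hit& a, const Hit& b) {
      if (a.start != b.start) return a.start < b.start;
      return a.strand < b.strand;
    });
    for (const Hit& h : kept) {
      outSeq.push_back(i + 1);
      outStart.push_back(h.start);
      outStrand.push_back(h.strand);
      outRel.push_back(h.rel);
    }
  }
  int n = (int) outSeq.size();
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) strand[i] = outStrand[i] == 0 ? "+" : "-";
  return DataFrame::create(_["seq"] = outSeq, _["start"] = outStart,
                           _["strand"] = strand, _["rel_score"] = outRel,
                           _["stringsAsFactors"] = false);
}

// Best hit per sequence (highest relative score; ties resolved toward the
// window whose midpoint is closest to `center`, then leftmost, then '+').
// Sequences with no window at or above floorScore get has_hit = FALSE.
// [[Rcpp::export]]
DataFrame cpp_top_hits(CharacterVector seqs, NumericMatrix W,
                       double minScore, double maxScore,
                       double floorScore, int center) {
  int L = W.ncol();
  double span = maxScore - minScore;
  const double EPS = 1e-9;
  std::vector<double> fwd = scoreTable(W), rev = rcTable(W);
  int n = seqs.size();
  LogicalVector hasHit(n);
  IntegerVector start(n);
  CharacterVector strand(n);
  NumericVector rel(n);
  std::vector<double> sF, sR;
  int midOff = (L - 1) / 2;  // integer midpoint offset of a window
  for (int i = 0; i < n; ++i) {
    std::string seq = as<std::string>(seqs[i]);
    windowScores(seq, fwd, rev, L, sF, sR);
    int nw = (int) sF.size();
    bool found = false;
    double bestRel = 0.0;
    int bestStart = NA_INTEGER, bestStrand = 0, bestDist = 0;
    for (int s = 0; s < nw; ++s) {
      int dist = std::abs(s + midOff - center);
      for (int st = 0; st < 2; ++st) {
        double raw = st == 0 ? sF[s] : sR[s];
        double r = 100.0 * (raw - minScore) / span;
        if (r < floorScore) continue;
        bool take = false;
        if (!found || r > bestRel + EPS) {
          take = true;
        } else if (r > bestRel - EPS && dist < bestDist) {
          take = true;
        }
        if (take) {
          found = true;
          bestRel = r;
          bestStart = s;
          bestStrand = st;
          bestDist = dist;
        }
      }
    }
    hasHit[i] = found;
    if (found) {
      start[i] = bestStart;
      strand[i] = bestStrand == 0 ? "+" : "-";
      rel[i] = bestRel;
    } else {
      start[i] = NA_INTEGER;
      strand[i] = NA_STRING;
      rel[i] = NA_REAL;
    }
  }
  return DataFrame::create(_["has_hit"] = hasHit, _["start"] = start,
                           _["strand"] = strand, _["rel_score"] = rel,
                           _["stringsAsFactors"] = false);
}

// Per-sequence indicator of >=1 retained hit above threshold, plus the
// absolute distances |window midpoint - center| of all retained hits,
// pooled across sequences.  Used by the over-representation scores.
// [[Rcpp::export]]
List cpp_hit_summary(CharacterVector seqs, NumericMatrix W,
                     double minScore, double maxScore,
                     double threshold, int maxOverlap, int center) {
  DataFrame hits = cpp_scan_hits(seqs, W, minScore, maxScore, threshold,
                                 maxOverlap);
  IntegerVector hseq = hits["seq"];
  IntegerVector hstart = hits["start"];
  int L = W.ncol();
  int midOff = (L - 1) / 2;
  LogicalVector with(seqs.size());
  NumericVector dist(hseq.size());
  for (int i = 0; i < hseq.size(); ++i) {
    with[hseq[i] - 1] = true;
    dist[i] = std::abs(hstart[i] + midOff - center);
  }
  return List::create(_["with_hit"] = with, _["distances"] = dist);
}
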
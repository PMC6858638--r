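#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static inline char comp(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Substitution errors driven by per-base phred scores. When as_printed is
// true, 10^(-Q/10) is the probability of keeping the called base; otherwise
// it is the error probability (standard phred). N bases are replaced by a
// uniform random base before resampling.
// [[Rcpp::export]]
std::string cpp_inject_errors(std::string tmpl, IntegerVector quals,
                              bool as_printed) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  const int n = tmpl.size();
  if (n != quals.size()) stop("template/quality length mismatch");
  for (int i = 0; i < n; ++i) {
    char b = tmpl[i];
    if (b == 'N') b = BASES[(int)(unif_rand() * 4.0) % 4];
    double p = std::pow(10.0, -quals[i] / 10.0);
    double p_called = as_printed ? p : 1.0 - p;
    if (unif_rand() >= p_called) {
      // uniformly one of the three alternatives
      int k = (int)(unif_rand() * 3.0) % 3;
      for (int j = 0, seen = 0; j < 4; ++j) {
        if (BASES[j] == b) continue;
        if (seen++ == k) { tmpl[i] = BASES[j]; break; }
      }
    } else {
      tmpl[i] = b;
    }
  }
  return tmpl;
}

// Overlap merging of read pairs. For each pair, r2 is reverse-complemented
// (qualities reversed) and every overlap length in [min_overlap,
// min(len1, len2)] is scored by mismatch percentage; the minimum wins, ties
// to the longer overlap. Reject when best pct > p_max_diff (strict).
// Quality reconciliation: match -> max(q1, q2); mismatch -> base of the
// higher quality with quality |q1 - q2| (tie: r1's base, quality 0).
// [[Rcpp::export]]
List cpp_join_pairs(CharacterVector seq1, List qual1,
                    CharacterVector seq2, List qual2,
                    double p_max_diff, int min_overlap) {
  const int n = seq1.size();
  LogicalVector joined(n);
  IntegerVector overlap(n, NA_INTEGER), mism(n, NA_INTEGER);
  NumericVector pct(n, NA_REAL);
  CharacterVector mseq(n);
  List mqual(n);

  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(seq1[i]);
    std::string s2 = as<std::string>(seq2[i]);
    IntegerVector q1 = qual1[i];
    IntegerVector q2 = qual2[i];
    const int L1 = s1.size(), L2 = s2.size();
    // reverse complement r2, reverse its qualities
    std::string s2rc(L2, 'N');
    IntegerVector q2r(L2);
    for (int j = 0; j < L2; ++j) {
      s2rc[j] = comp(s2[L2 - 1 - j]);
      q2r[j] = q2[L2 - 1 - j];
    }
    const int maxov = std::min(L1, L2);
    int best_ov = -1, best_mm = 0;
    double best_pct = R_PosInf;
    for (int ov = min_overlap; ov <= maxov; ++ov) {
      int mm = 0;
      const int off = L1 - ov;  // r1 index where overlap starts
      for (int j = 0; j < ov; ++j) {
        if (s1[off + j] != s2rc[j]) ++mm;
      }
      double p = 100.0 * mm / ov;
      if (p < best_pct || (p == best_pct && ov > best_ov)) {
        best_pct = p; best_ov = ov; best_mm = mm;
      }
    }
    if (best_ov < 0 || best_pct > p_max_diff) {
      joined[i] = false;
      if (best_ov >= 0) { overlap[i] = best_ov; mism[i] = best_mm; pct[i] = best_pct; }
      continue;
    }
    joined[i] = true;
    overlap[i] = best_ov; mism[i] = best_mm; pct[i] = best_pct;
    const int off = L1 - best_ov;
    const int mlen = L1 + L2 - best_ov;
    std::string ms(mlen, 'N');
    IntegerVector mq(mlen);
    for (int j = 0; j < off; ++j) { ms[j] = s1[j]; mq[j] = q1[j]; }
    for (int j = 0; j < best_ov; ++j) {
      const char b1 = s1[off + j], b2 = s2rc[j];
      const int a = q1[off + j], b = q2r[j];
      if (b1 == b2) {
        ms[off + j] = b1;
        mq[off + j] = std::max(a, b);
      } else if (a == b) {
        ms[off + j] = b1;            // tie: keep r1's call
        mq[off + j] = 0;
      } else {
        ms[off + j] = (a > b) ? b1 : b2;
        mq[off + j] = std::abs(a - b);
      }
    }
    for (int j = best_ov; j < L2; ++j) {
      ms[L1 + j - best_ov] = s2rc[j];
      mq[L1 + j - best_ov] = q2r[j];
    }
    mseq[i] = ms;
    mqual[i] = mq;
  }
  return List::create(_["joined"] = joined, _["overlap"] = overlap,
                      _["mismatches"] = mism, _["pct"] = pct,
                      _["seq"] = mseq, _["qual"] = mqual);
}
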
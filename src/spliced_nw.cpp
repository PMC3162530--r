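#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Spliced Needleman-Wunsch over a protein query and a genomic target.
//
// State M[i][j] = minimal penalty of a parse of target prefix t[0..i-1]
// against query prefix q[0..j-1].  Moves into (i,j):
//   codon      (i-3, j-1) + match/mismatch penalty
//   insertion  (i,   j-1) + p_ins
//   gap        (i-3, j)   + p_gap
//   frameshift (i-1|i-2, j or j-1) + p_fs
//   intron closures via nine precomputed running minima ("intron variants"):
//     phase 0: V0[j]     = min over donors d <= i - lmin of
//                          M[d][j] + p_int + donor(t[d], t[d+1])
//     phase 1: V1[n][j]  = same with the codon's first nucleotide n = t[d]
//                          consumed before the intron; the match penalty is
//                          NOT yet included (the codon's tail is unknown
//                          until closure), frontier d <= i - lmin - 3
//     phase 2: V2[n][j]  = first two codon nucleotides consumed before the
//                          intron; match penalty already included, indexed
//                          by the hypothesised post-intron nucleotide n,
//                          frontier d <= i - lmin - 3
// Ties: candidates are evaluated in the order codon > intron(phase 0,1,2) >
// gap > insertion > frameshift and replaced only on strict improvement;
// running minima keep the earliest (leftmost) donor among equals.

static const double INF = 1e18;

// move codes for traceback
enum Move { M_START = 0, M_CODON, M_INT0, M_INT1, M_INT2, M_GAP, M_INS,
            M_FS1, M_FS2, M_FS1R, M_FS2R };

// [[Rcpp::export]]
List spliced_nw_cpp(IntegerVector tgt, IntegerVector qry,
                    IntegerVector codon_tab,
                    NumericMatrix donor_pen, NumericMatrix acceptor_pen,
                    double p_mis, double p_ins, double p_gap, double p_fs,
                    double p_int, int lmin, bool keep_matrix) {
  const int n = tgt.size(), m = qry.size();
  if ((double)(n + 1) * (m + 1) > 8e7)
    stop("alignment problem too large");
  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W, INF);
  std::vector<signed char> mv((size_t)(n + 1) * W, -1);
  std::vector<int> don((size_t)(n + 1) * W, -1);
  auto IDX = [&](int i, int j) { return (size_t)i * W + (size_t)j; };
  auto pmap = [&](int q, int a, int b, int c) -> double {
    int t = codon_tab[a * 25 + b * 5 + c];
    return (t == q && t != '*' && t != 'X') ? 0.0 : p_mis;
  };

  std::vector<double> V0(W, INF), V1(5 * W, INF), V2(5 * W, INF);
  std::vector<int> D0(W, -1), D1(5 * W, -1), D2(5 * W, -1);

  M[IDX(0, 0)] = 0.0;
  mv[IDX(0, 0)] = M_START;

  for (int i = 0; i <= n; ++i) {
    // advance intron frontiers: donor rows that become admissible at row i
    int d0 = i - lmin;               // in-frame intron donor
    if (d0 >= 0 && d0 + 1 < n) {
      double dp = p_int + donor_pen(tgt[d0], tgt[d0 + 1]);
      for (int j = 0; j <= m; ++j) {
        double b = M[IDX(d0, j)];
        if (b < INF / 2 && b + dp < V0[j]) { V0[j] = b + dp; D0[j] = d0; }
      }
    }
    int d12 = i - lmin - 3;          // codon-splitting intron donor
    if (d12 >= 0 && d12 + 3 < n) {
      int n1 = tgt[d12];
      double dp1 = p_int + donor_pen(tgt[d12 + 1], tgt[d12 + 2]);
      double dp2 = p_int + donor_pen(tgt[d12 + 2], tgt[d12 + 3]);
      for (int j = 0; j <= m; ++j) {
        double b = M[IDX(d12, j)];
        if (b >= INF / 2) continue;
        // phase 1: one codon nucleotide (n1) consumed before the intron
        double c1 = b + dp1;
        if (c1 < V1[(size_t)n1 * W + j]) {
          V1[(size_t)n1 * W + j] = c1; D1[(size_t)n1 * W + j] = d12;
        }
        // phase 2: two consumed; match penalty folded in, indexed by the
        // hypothesised nucleotide after the intron
        if (j < m) {
          for (int n3 = 0; n3 < 5; ++n3) {
            double c2 = b + dp2 + pmap(qry[j], tgt[d12], tgt[d12 + 1], n3);
            if (c2 < V2[(size_t)n3 * W + j]) {
              V2[(size_t)n3 * W + j] = c2; D2[(size_t)n3 * W + j] = d12;
            }
          }
        }
      }
    }

    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) continue;
      double best = INF; signed char bmv = -1; int bd = -1;
      // codon match/mismatch
      if (i >= 3 && j >= 1) {
        double c = M[IDX(i - 3, j - 1)];
        if (c < INF / 2) {
          c += pmap(qry[j - 1], tgt[i - 3], tgt[i - 2], tgt[i - 1]);
          if (c < best) { best = c; bmv = M_CODON; }
        }
      }
      // intron, phase 0: acceptor = t[i-2], t[i-1]
      if (i >= lmin && i >= 2 && V0[j] < INF / 2) {
        double c = V0[j] + acceptor_pen(tgt[i - 2], tgt[i - 1]);
        if (c < best) { best = c; bmv = M_INT0; bd = D0[j]; }
      }
      // intron, phase 1: codon = n1 | omega | t[i-2] t[i-1],
      // acceptor = t[i-4], t[i-3]
      if (j >= 1 && i >= 4) {
        double acc = acceptor_pen(tgt[i - 4], tgt[i - 3]);
        for (int n1 = 0; n1 < 5; ++n1) {
          double v = V1[(size_t)n1 * W + (j - 1)];
          if (v >= INF / 2) continue;
          double c = v + pmap(qry[j - 1], n1, tgt[i - 2], tgt[i - 1]) + acc;
          if (c < best) {
            best = c; bmv = M_INT1; bd = D1[(size_t)n1 * W + (j - 1)];
          }
        }
      }
      // intron, phase 2: codon tail = t[i-1], acceptor = t[i-3], t[i-2]
      if (j >= 1 && i >= 3) {
        int n3 = tgt[i - 1];
        double v = V2[(size_t)n3 * W + (j - 1)];
        if (v < INF / 2) {
          double c = v + acceptor_pen(tgt[i - 3], tgt[i - 2]);
          if (c < best) {
            best = c; bmv = M_INT2; bd = D2[(size_t)n3 * W + (j - 1)];
          }
        }
      }
      // gap (extra target codon)
      if (i >= 3) {
        double c = M[IDX(i - 3, j)];
        if (c < INF / 2 && c + p_gap < best) { best = c + p_gap; bmv = M_GAP; }
      }
      // insertion (extra query residue)
      if (j >= 1) {
        double c = M[IDX(i, j - 1)];
        if (c < INF / 2 && c + p_ins < best) { best = c + p_ins; bmv = M_INS; }
      }
      // frameshifts: 1-2 stray nucleotides, with or without a residue
      if (i >= 1) {
        double c = M[IDX(i - 1, j)];
        if (c < INF / 2 && c + p_fs < best) { best = c + p_fs; bmv = M_FS1; }
      }
      if (i >= 2) {
        double c = M[IDX(i - 2, j)];
        if (c < INF / 2 && c + p_fs < best) { best = c + p_fs; bmv = M_FS2; }
      }
      if (i >= 1 && j >= 1) {
        double c = M[IDX(i - 1, j - 1)];
        if (c < INF / 2 && c + p_fs < best) { best = c + p_fs; bmv = M_FS1R; }
      }
      if (i >= 2 && j >= 1) {
        double c = M[IDX(i - 2, j - 1)];
        if (c < INF / 2 && c + p_fs < best) { best = c + p_fs; bmv = M_FS2R; }
      }
      if (bmv >= 0) {
        M[IDX(i, j)] = best; mv[IDX(i, j)] = bmv; don[IDX(i, j)] = bd;
      }
    }
  }

  // traceback
  std::vector<int> cat, ifrom, ito, jfrom, jto, dpos;
  int i = n, j = m;
  while (!(i == 0 && j == 0)) {
    signed char k = mv[IDX(i, j)];
    if (k < 0) stop("internal error: no valid parse found");
    int pi = i, pj = j, d = don[IDX(i, j)];
    switch (k) {
      case M_CODON: pi = i - 3; pj = j - 1; break;
      case M_INT0:  pi = d;     pj = j;     break;
      case M_INT1:  pi = d;     pj = j - 1; break;
      case M_INT2:  pi = d;     pj = j - 1; break;
      case M_GAP:   pi = i - 3; pj = j;     break;
      case M_INS:   pi = i;     pj = j - 1; break;
      case M_FS1:   pi = i - 1; pj = j;     break;
      case M_FS2:   pi = i - 2; pj = j;     break;
      case M_FS1R:  pi = i - 1; pj = j - 1; break;
      case M_FS2R:  pi = i - 2; pj = j - 1; break;
      default: stop("internal error: bad move code");
    }
    cat.push_back(k); ifrom.push_back(pi); ito.push_back(i);
    jfrom.push_back(pj); jto.push_back(j); dpos.push_back(d);
    i = pi; j = pj;
  }
  std::reverse(cat.begin(), cat.end());
  std::reverse(ifrom.begin(), ifrom.end());
  std::reverse(ito.begin(), ito.end());
  std::reverse(jfrom.begin(), jfrom.end());
  std::reverse(jto.begin(), jto.end());
  std::reverse(dpos.begin(), dpos.end());

  List out = List::create(
    _["cost"] = (n == 0 && m == 0) ? 0.0 : M[IDX(n, m)],
    _["move"] = wrap(cat), _["ifrom"] = wrap(ifrom), _["ito"] = wrap(ito),
    _["jfrom"] = wrap(jfrom), _["jto"] = wrap(jto), _["donor"] = wrap(dpos));
  if (keep_matrix) {
    NumericMatrix Mout(n + 1, m + 1);
    for (int a = 0; a <= n; ++a)
      for (int b = 0; b <= m; ++b)
        Mout(a, b) = M[IDX(a, b)] < INF / 2 ? M[IDX(a, b)] : NA_REAL;
    out["matrix"] = Mout;
  }
  return out;
}
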
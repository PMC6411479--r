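// Viterbi and forward dynamic programming for profile HMMs.
//
// State layout per model column k = 0..M: match M_k (M_0 is the begin
// state), insert I_k, delete D_k (k >= 1). Transition matrix rows are
// k = 0..M with columns
//   0 tMM  M_k -> M_{k+1} (k = M: -> End)
//   1 tMI  M_k -> I_k
//   2 tMD  M_k -> D_{k+1} (invalid at k = M)
//   3 tIM  I_k -> M_{k+1} (k = M: -> End)
//   4 tII  I_k -> I_k
//   5 tID  I_k -> D_{k+1} (invalid at k = M)
//   6 tDM  D_k -> M_{k+1} (k = M: -> End)
//   7 tDD  D_k -> D_{k+1} (invalid at k = M)
//   8 tDI  D_k -> I_k
// All scores are log2; emissions arrive as log2-odds (or raw log2
// probabilities, the DP does not care). Local mode is uni-local: entry
// from the flank into any match state with log2(1/M), free exit from any
// match state, flanking residues at odds 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double ls2(double a, double b) {
  double hi = a > b ? a : b, lo = a > b ? b : a;
  if (hi == NEG_INF) return NEG_INF;
  double d = lo - hi;
  // 2^d below the double-precision noise floor of the sum; also covers -Inf
  if (d < -54.0) return hi;
  return hi + std::log1p(std::exp2(d)) / M_LN2;
}

static inline double max3(double a, double b, double c, int *arg) {
  double m = a; *arg = 0;
  if (b > m) { m = b; *arg = 1; }
  if (c > m) { m = c; *arg = 2; }
  return m;
}

// Forward or Viterbi score only (no traceback), rolling rows. Templated on
// the algorithm so the hot loop has no per-cell branching; raw
// column-major pointers avoid Rcpp accessor overhead.
template <bool VIT, bool LOCAL>
static double hmm_score_core(const NumericMatrix &mlo, const NumericVector &ilo,
                             const NumericMatrix &trans,
                             const IntegerVector &seq) {
  const int M = mlo.nrow(), L = seq.size();
  const int R = M + 1;
  const double *T = trans.begin();
  const double *tMM = T, *tMI = T + R, *tMD = T + 2 * R, *tIM = T + 3 * R,
               *tII = T + 4 * R, *tID = T + 5 * R, *tDM = T + 6 * R,
               *tDD = T + 7 * R, *tDI = T + 8 * R;
  const double *E = mlo.begin();  // column-major: E[x * M + (k-1)]
  const double lentry = -std::log2((double)M);
  std::vector<double> bufM(2 * R), bufI(2 * R), bufD(2 * R);
  double *pM = bufM.data(), *cM = bufM.data() + R;
  double *pI = bufI.data(), *cI = bufI.data() + R;
  double *pD = bufD.data(), *cD = bufD.data() + R;
  auto comb = [](double a, double b) {
    return VIT ? (a > b ? a : b) : ls2(a, b);
  };
  // batched log2-sum-exp: one log per cell instead of one per pairing
  auto comb3 = [](double a, double b, double c) {
    if (VIT) return std::max(a, std::max(b, c));
    double m = std::max(a, std::max(b, c));
    if (m == NEG_INF) return NEG_INF;
    return m + std::log(std::exp2(a - m) + std::exp2(b - m) +
                        std::exp2(c - m)) * M_LOG2E;
  };
  auto comb4 = [](double a, double b, double c, double d) {
    if (VIT) return std::max(std::max(a, b), std::max(c, d));
    double m = std::max(std::max(a, b), std::max(c, d));
    if (m == NEG_INF) return NEG_INF;
    return m + std::log(std::exp2(a - m) + std::exp2(b - m) +
                        std::exp2(c - m) + std::exp2(d - m)) * M_LOG2E;
  };
  for (int k = 0; k <= M; ++k) pM[k] = pI[k] = pD[k] = NEG_INF;
  if (!LOCAL) {
    pM[0] = 0.0;
    pD[1] = pM[0] + tMD[0];
    for (int k = 2; k <= M; ++k) pD[k] = pD[k - 1] + tDD[k - 1];
  }
  double local_acc = NEG_INF;
  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    const double ie = ilo[x];
    const double *ex = E + (size_t)x * M - 1;  // ex[k] = emission at col k
    cM[0] = NEG_INF;
    cD[0] = NEG_INF;
    double rowmax = NEG_INF;
    for (int k = 1; k <= M; ++k) {
      double best = LOCAL
        ? comb4(pM[k - 1] + tMM[k - 1], pI[k - 1] + tIM[k - 1],
                pD[k - 1] + tDM[k - 1], lentry)
        : comb3(pM[k - 1] + tMM[k - 1], pI[k - 1] + tIM[k - 1],
                pD[k - 1] + tDM[k - 1]);
      cM[k] = best + ex[k];
      if (LOCAL && cM[k] > rowmax) rowmax = cM[k];
    }
    cI[0] = comb(pM[0] + tMI[0], pI[0] + tII[0]) + ie;
    for (int k = 1; k <= M; ++k) {
      cI[k] = comb3(pM[k] + tMI[k], pI[k] + tII[k], pD[k] + tDI[k]) + ie;
    }
    cD[1] = comb(cM[0] + tMD[0], cI[0] + tID[0]);
    for (int k = 2; k <= M; ++k) {
      cD[k] = comb3(cM[k - 1] + tMD[k - 1], cI[k - 1] + tID[k - 1],
                    cD[k - 1] + tDD[k - 1]);
    }
    if (LOCAL) {
      if (VIT) {
        local_acc = std::max(local_acc, rowmax);
      } else if (rowmax > NEG_INF) {
        double s = 0.0;
        for (int k = 1; k <= M; ++k) s += std::exp2(cM[k] - rowmax);
        local_acc = ls2(local_acc, rowmax + std::log(s) * M_LOG2E);
      }
    }
    std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
  }
  if (LOCAL) return local_acc;
  return comb(pM[M] + tMM[M], comb(pI[M] + tIM[M], pD[M] + tDM[M]));
}

static double hmm_score_one(const NumericMatrix &mlo, const NumericVector &ilo,
                            const NumericMatrix &trans, const IntegerVector &seq,
                            int local, int viterbi) {
  if (viterbi) {
    return local ? hmm_score_core<true, true>(mlo, ilo, trans, seq)
                 : hmm_score_core<true, false>(mlo, ilo, trans, seq);
  }
  return local ? hmm_score_core<false, true>(mlo, ilo, trans, seq)
               : hmm_score_core<false, false>(mlo, ilo, trans, seq);
}

// [[Rcpp::export]]
double hmm_score(NumericMatrix mlo, NumericVector ilo, NumericMatrix trans,
                 IntegerVector seq, int local, int viterbi) {
  return hmm_score_one(mlo, ilo, trans, seq, local, viterbi);
}

// [[Rcpp::export]]
NumericVector hmm_score_many(NumericMatrix mlo, NumericVector ilo,
                             NumericMatrix trans, List seqs, int local,
                             int viterbi) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    IntegerVector s = seqs[j];
    out[j] = hmm_score_one(mlo, ilo, trans, s, local, viterbi);
  }
  return out;
}

// Viterbi with traceback. Returns score, the state path as a matrix with
// columns (state code 0=M/1=I/2=D, model column k, consumed-position i or 0),
// and the 0-based half-open interval of consumed residues.
// [[Rcpp::export]]
List hmm_viterbi_path(NumericMatrix mlo, NumericVector ilo, NumericMatrix trans,
                      IntegerVector seq, int local) {
  const int M = mlo.nrow(), L = seq.size();
  const double lentry = -std::log2((double)M);
  const int W = M + 1;
  const int R = M + 1;
  const double *T = trans.begin();
  const double *tMM = T, *tMI = T + R, *tMD = T + 2 * R, *tIM = T + 3 * R,
               *tII = T + 4 * R, *tID = T + 5 * R, *tDM = T + 6 * R,
               *tDD = T + 7 * R, *tDI = T + 8 * R;
  const double *E = mlo.begin();
  std::vector<double> vM((size_t)(L + 1) * W, NEG_INF),
                      vI((size_t)(L + 1) * W, NEG_INF),
                      vD((size_t)(L + 1) * W, NEG_INF);
  // backpointers: 0 from-M, 1 from-I, 2 from-D, 3 local-entry, -1 none
  std::vector<signed char> bM((size_t)(L + 1) * W, -1),
                           bI((size_t)(L + 1) * W, -1),
                           bD((size_t)(L + 1) * W, -1);
#define IX(i, k) ((size_t)(i) * W + (k))
  if (!local) {
    vM[IX(0, 0)] = 0.0;
    for (int k = 1; k <= M; ++k) {
      int arg;
      double fromM = vM[IX(0, k - 1)] + tMD[k - 1];
      double fromI = vI[IX(0, k - 1)] + tID[k - 1];
      double fromD = (k >= 2) ? vD[IX(0, k - 1)] + tDD[k - 1] : NEG_INF;
      vD[IX(0, k)] = max3(fromM, fromI, fromD, &arg);
      bD[IX(0, k)] = (signed char)arg;
    }
  }
  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    const double ie = ilo[x];
    const double *ex = E + (size_t)x * M - 1;
    double *vMp = &vM[IX(i - 1, 0)], *vIp = &vI[IX(i - 1, 0)],
           *vDp = &vD[IX(i - 1, 0)];
    double *vMc = &vM[IX(i, 0)], *vIc = &vI[IX(i, 0)], *vDc = &vD[IX(i, 0)];
    signed char *bMc = &bM[IX(i, 0)], *bIc = &bI[IX(i, 0)],
                *bDc = &bD[IX(i, 0)];
    for (int k = 1; k <= M; ++k) {
      int arg;
      double best = max3(vMp[k - 1] + tMM[k - 1], vIp[k - 1] + tIM[k - 1],
                         vDp[k - 1] + tDM[k - 1], &arg);
      if (local && lentry > best) { best = lentry; arg = 3; }
      vMc[k] = best + ex[k];
      bMc[k] = (signed char)arg;
    }
    for (int k = 0; k <= M; ++k) {
      int arg;
      double c = (k >= 1) ? vDp[k] + tDI[k] : NEG_INF;
      vIc[k] = max3(vMp[k] + tMI[k], vIp[k] + tII[k], c, &arg) + ie;
      bIc[k] = (signed char)arg;
    }
    for (int k = 1; k <= M; ++k) {
      int arg;
      double c = (k >= 2) ? vDc[k - 1] + tDD[k - 1] : NEG_INF;
      vDc[k] = max3(vMc[k - 1] + tMD[k - 1], vIc[k - 1] + tID[k - 1], c,
                    &arg);
      bDc[k] = (signed char)arg;
    }
  }
  double score = NEG_INF;
  int end_state = -1, end_i = -1, end_k = -1;
  if (local) {
    for (int i = 1; i <= L; ++i) {
      for (int k = 1; k <= M; ++k) {
        if (vM[IX(i, k)] > score) {
          score = vM[IX(i, k)]; end_state = 0; end_i = i; end_k = k;
        }
      }
    }
  } else {
    int arg;
    double a = vM[IX(L, M)] + trans(M, 0);
    double b = vI[IX(L, M)] + trans(M, 3);
    double c = vD[IX(L, M)] + trans(M, 6);
    score = max3(a, b, c, &arg);
    end_state = arg; end_i = L; end_k = M;
  }
  std::vector<int> st, col, pos;
  if (score > NEG_INF) {
    int s = end_state, i = end_i, k = end_k;
    while (true) {
      if (!local && s == 0 && k == 0) break; // glocal begin
      st.push_back(s); col.push_back(k); pos.push_back(s == 2 ? 0 : i);
      signed char bp;
      if (s == 0) bp = bM[IX(i, k)];
      else if (s == 1) bp = bI[IX(i, k)];
      else bp = bD[IX(i, k)];
      if (bp == 3) break; // local entry
      if (s == 0) { --i; --k; }
      else if (s == 1) { --i; }
      else { --k; }
      s = bp;
      if (i < 0 || k < 0) break;
    }
  }
  const int n = (int)st.size();
  IntegerMatrix path(n, 3);
  for (int j = 0; j < n; ++j) {
    path(j, 0) = st[n - 1 - j];
    path(j, 1) = col[n - 1 - j];
    path(j, 2) = pos[n - 1 - j];
  }
  int start0 = 0, end0 = L;
  if (local) {
    start0 = 0; end0 = 0;
    bool seen = false;
    for (int j = 0; j < n; ++j) {
      if (path(j, 0) != 2) { // consumed a residue
        if (!seen) { start0 = path(j, 2) - 1; seen = true; }
        end0 = path(j, 2);
      }
    }
    if (!seen) { start0 = 0; end0 = 0; }
  }
  return List::create(_["score"] = score, _["path"] = path,
                      _["start"] = start0, _["end"] = end0);
#undef IX
}
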
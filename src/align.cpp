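#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, three-state DP
// (M = aligned pair, IX = gap in reference / insertion in read,
// IY = gap in read / deletion from reference). A gap of length k costs
// gap_open + k * gap_extend. End gaps are penalised (true global
// alignment). Among co-optimal alignments the traceback prefers the M
// state on score ties, which places gaps at their leftmost co-optimal
// reference position. N scores 0 against anything (mismatch-neutral)
// and is never counted as a match.

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List align_affine_cpp(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = read.size(), m = ref.size();
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), IX((n + 1) * W, NEG),
      IY((n + 1) * W, NEG);
  // traceback: source state of each cell, 0=M 1=IX 2=IY, 9=none
  std::vector<unsigned char> pM((n + 1) * W, 9), pX((n + 1) * W, 9),
      pY((n + 1) * W, 9);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    IY[j] = gap_open + j * gap_extend;
    pY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    IX[i * W] = gap_open + i * gap_extend;
    pX[i * W] = (i == 1) ? 0 : 1;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M: from any state at (i-1, j-1); ties prefer M, then IY, then IX
      double best = M[d];
      unsigned char src = 0;
      if (IY[d] > best) { best = IY[d]; src = 2; }
      if (IX[d] > best) { best = IX[d]; src = 1; }
      M[c] = best + subscore(read[i - 1], ref[j - 1], match, mismatch);
      pM[c] = src;
      // IX (consume read): extend preferred on ties, then open from M
      double ext = IX[up] + gap_extend;
      double opn = M[up] + gap_open + gap_extend;
      double swc = IY[up] + gap_open + gap_extend;
      if (ext >= opn && ext >= swc) { IX[c] = ext; pX[c] = 1; }
      else if (opn >= swc) { IX[c] = opn; pX[c] = 0; }
      else { IX[c] = swc; pX[c] = 2; }
      // IY (consume ref)
      ext = IY[lf] + gap_extend;
      opn = M[lf] + gap_open + gap_extend;
      swc = IX[lf] + gap_open + gap_extend;
      if (ext >= opn && ext >= swc) { IY[c] = ext; pY[c] = 2; }
      else if (opn >= swc) { IY[c] = opn; pY[c] = 0; }
      else { IY[c] = swc; pY[c] = 1; }
    }
  }

  const int endc = n * W + m;
  int state;
  double score;
  // final state: prefer M, then IY, then IX on ties
  if (M[endc] >= IY[endc] && M[endc] >= IX[endc]) { state = 0; score = M[endc]; }
  else if (IY[endc] >= IX[endc]) { state = 2; score = IY[endc]; }
  else { state = 1; score = IX[endc]; }

  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      char a = read[i - 1], b = ref[j - 1];
      ops.push_back((a == b && a != 'N') ? 'M' : 'X');
      state = pM[c];
      --i; --j;
    } else if (state == 1) {
      ops.push_back('I');
      state = pX[c];
      --i;
    } else {
      ops.push_back('D');
      state = pY[c];
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = ops);
}
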
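#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Six-state spliced protein-to-genome DP.
//
// Genome rows i = 1..n (nucleotides), protein columns j = 1..m (residues).
// States: H (best), I (residue insertion), D (codon deletion),
// A/B/C (Phase-0/1/2 intron states).  Transitions:
//   I[i][j] = max(H[i][j-1]-q, I[i][j-1]) - e
//   D[i][j] = max(H[i-3][j]-q, D[i-3][j]) - e
//   A[i][j] = max(H[i-1][j]   - r - don(i),   A[i-1][j])   (intron starts at i)
//   B[i][j] = max(H[i-1][j-1] - r - don(i+1), B[i-1][j])   (codon base i, intron at i+1)
//   C[i][j] = max(H[i-1][j-1] - r - don(i+2), C[i-1][j])   (codon bases i,i+1)
//   H[i][j] = max(H[i-3][j-1] + s(i,j),
//                 H[i-1][j-1]-f, H[i-2][j-1]-f,   frameshift '$' (1/2-nt codon)
//                 H[i-1][j]-f,   H[i-2][j]-f,     frameshift '+' (1/2-nt insertion)
//                 I[i][j], D[i][j],
//                 A[i][j]   - acc(i),             intron ends at i
//                 B[i-3][j] - acc(i-2),           split codon bases i-1,i
//                 C[i-3][j] - acc(i-1))           split codon base i
// Phase-1/2 exits read the intron state three rows back so that every intron
// has length >= 1 nt and the split-codon geometry is valid.
// don(i): cost of an intron starting at genome position i (includes r? no, r added here).
// acc(i): cost of an intron ending at position i.
//
// With free_ends, H[i][0] = 0 for every i and the score is max_i H[i][m]
// (protein globally aligned, genome flanks free).  Otherwise H[.][0] is
// reachable only through deletions/frameshifts and the score is H[n][m].

static const int NEG = -(1 << 28);
static const int BIG = (1 << 26);

// op codes used in the traceback output
enum { OP_M = 1, OP_I, OP_D, OP_F, OP_G, OP_N, OP_U, OP_V };

struct Ops {
  std::vector<int> code, len;
  void push(int c, int l) {
    // merge only M/I/D runs: F/G/U/V ops each carry per-event semantics
    if (!code.empty() && code.back() == c && (c == OP_M || c == OP_I || c == OP_D))
      len.back() += l;
    else { code.push_back(c); len.push_back(l); }
  }
};

// [[Rcpp::export(name = ".spliced_dp_cpp")]]
List spliced_dp_cpp(IntegerVector tcode, IntegerVector pcode, IntegerMatrix smat,
                    int q, int e, int f, int r,
                    IntegerVector dcost, IntegerVector acost,
                    bool use_introns, bool free_ends) {
  const int n = tcode.size(), m = pcode.size();
  if (n < 1 || m < 1) stop("empty sequence");
  if ((double)(n + 1) * (m + 1) > 2.5e8) stop("DP window too large");

  const size_t W = (size_t)m + 1;
  std::vector<int> H[4], D[4], A[2], B[4], C[4], I(W);
  for (int t = 0; t < 4; ++t) { H[t].assign(W, NEG); D[t].assign(W, NEG); B[t].assign(W, NEG); C[t].assign(W, NEG); }
  A[0].assign(W, NEG); A[1].assign(W, NEG);

  std::vector<int8_t> tbH((size_t)(n + 1) * W, 0), tbI(tbH.size(), 0), tbD(tbH.size(), 0),
      tbA(tbH.size(), 0), tbB(tbH.size(), 0), tbC(tbH.size(), 0);
  auto TB = [&](std::vector<int8_t> &tb, int i, int j) -> int8_t & { return tb[(size_t)i * W + j]; };

  auto don = [&](int i) -> int { return (i >= 1 && i <= n) ? dcost[i - 1] : BIG; };
  auto acc = [&](int i) -> int { return (i >= 1 && i <= n) ? acost[i - 1] : BIG; };

  // row 0
  {
    std::vector<int> &h = H[0];
    h[0] = 0; TB(tbH, 0, 0) = 12;
    int Ip = NEG;
    for (int j = 1; j <= m; ++j) {
      int open = h[j - 1] - q, ext = Ip;
      int v; int8_t c;
      if (open >= ext) { v = open - e; c = 1; } else { v = ext - e; c = 2; }
      Ip = v; TB(tbI, 0, j) = c;
      h[j] = v; TB(tbH, 0, j) = 2;
    }
  }

  int best = NEG, best_i = -1;
  if (m >= 0) { best = H[0][m]; best_i = 0; }

  for (int i = 1; i <= n; ++i) {
    int cur = i & 3, p1 = (i - 1) & 3, p2 = (i - 2) & 3, p3 = (i - 3) & 3;
    int ap = (i - 1) & 1, ac_ = i & 1;
    std::vector<int> &h = H[cur], &hp1 = H[p1], &hp2 = H[p2], &hp3 = H[p3];
    std::vector<int> &d = D[cur], &dp3 = D[p3];
    std::vector<int> &a = A[ac_], &aprev = A[ap];
    std::vector<int> &b = B[cur], &bp1 = B[p1], &bp3 = B[p3];
    std::vector<int> &cc = C[cur], &cp1 = C[p1], &cp3 = C[p3];
    bool i3 = (i >= 3);
    int don_a = use_introns ? don(i) : BIG;
    int don_b = use_introns ? don(i + 1) : BIG;
    int don_c = use_introns ? don(i + 2) : BIG;
    int acc_a = use_introns ? acc(i) : BIG;
    int acc_b = use_introns ? acc(i - 2) : BIG;
    int acc_c = use_introns ? acc(i - 1) : BIG;
    int ti = tcode[i - 1];

    for (int j = 0; j <= m; ++j) {
      // I state (needs j >= 1; uses current row H[j-1] already computed)
      int Iv = NEG;
      if (j >= 1) {
        int open = h[j - 1] - q, ext = I[j - 1];
        if (open >= ext) { Iv = open - e; TB(tbI, i, j) = 1; }
        else            { Iv = ext - e;  TB(tbI, i, j) = 2; }
      }
      // D state
      int Dv = NEG;
      if (i3) {
        int open = hp3[j] - q, ext = dp3[j];
        if (open >= ext) { Dv = open - e; TB(tbD, i, j) = 1; }
        else            { Dv = ext - e;  TB(tbD, i, j) = 2; }
      }
      // A state: entry consumes base i as first intron base
      int Av = NEG;
      if (use_introns) {
        int entry = (hp1[j] > NEG / 2) ? hp1[j] - r - don_a : NEG;
        int ext = aprev[j];
        if (entry >= ext) { Av = entry; TB(tbA, i, j) = 1; }
        else              { Av = ext;   TB(tbA, i, j) = 2; }
      }
      // B state: entry consumes codon base i and residue j
      int Bv = NEG;
      if (use_introns) {
        int entry = (j >= 1 && hp1[j - 1] > NEG / 2) ? hp1[j - 1] - r - don_b : NEG;
        int ext = bp1[j];
        if (entry >= ext) { Bv = entry; TB(tbB, i, j) = 1; }
        else              { Bv = ext;   TB(tbB, i, j) = 2; }
      }
      // C state: entry consumes codon base i (base i+1 taken by first extension)
      int Cv = NEG;
      if (use_introns) {
        int entry = (j >= 1 && hp1[j - 1] > NEG / 2) ? hp1[j - 1] - r - don_c : NEG;
        int ext = cp1[j];
        if (entry >= ext) { Cv = entry; TB(tbC, i, j) = 1; }
        else              { Cv = ext;   TB(tbC, i, j) = 2; }
      }
      I[j] = Iv; d[j] = Dv; a[j] = Av; b[j] = Bv; cc[j] = Cv;

      // H state; candidate order fixes tie-breaking: match, frameshifts, indels, introns
      int Hv = NEG; int8_t Hc = 0;
      if (free_ends && j == 0) { Hv = 0; Hc = 11; }
      else {
        int v;
        if (i3 && j >= 1 && ti >= 0 && hp3[j - 1] > NEG / 2) {
          v = hp3[j - 1] + smat(ti, pcode[j - 1]);
          if (v > Hv) { Hv = v; Hc = 1; }
        }
        if (j >= 1 && hp1[j - 1] > NEG / 2) { v = hp1[j - 1] - f; if (v > Hv) { Hv = v; Hc = 4; } }
        if (j >= 1 && i >= 2 && hp2[j - 1] > NEG / 2) { v = hp2[j - 1] - f; if (v > Hv) { Hv = v; Hc = 5; } }
        if (hp1[j] > NEG / 2) { v = hp1[j] - f; if (v > Hv) { Hv = v; Hc = 6; } }
        if (i >= 2 && hp2[j] > NEG / 2) { v = hp2[j] - f; if (v > Hv) { Hv = v; Hc = 7; } }
        if (Iv > Hv) { Hv = Iv; Hc = 2; }
        if (Dv > Hv) { Hv = Dv; Hc = 3; }
        if (use_introns) {
          if (Av > NEG / 2) { v = Av - acc_a; if (v > Hv) { Hv = v; Hc = 8; } }
          if (i3 && bp3[j] > NEG / 2) { v = bp3[j] - acc_b; if (v > Hv) { Hv = v; Hc = 9; } }
          if (i3 && cp3[j] > NEG / 2) { v = cp3[j] - acc_c; if (v > Hv) { Hv = v; Hc = 10; } }
        }
      }
      h[j] = Hv; TB(tbH, i, j) = Hc;
    }
    if (free_ends && h[m] > best) { best = h[m]; best_i = i; }
  }

  int score, gi;
  if (free_ends) { score = best; gi = best_i; }
  else { score = H[n & 3][m]; gi = n; }
  if (score <= NEG / 2) stop("no feasible alignment");

  // traceback
  Ops ops;
  std::vector<int> istart, iend, iphase;
  int i = gi, j = m, gend = gi;
  bool done = false;
  while (!done) {
    int8_t c = TB(tbH, i, j);
    switch (c) {
    case 12: case 11: done = true; break;
    case 1: ops.push(OP_M, 1); i -= 3; j -= 1; break;
    case 4: ops.push(OP_F, 1); i -= 1; j -= 1; break;
    case 5: ops.push(OP_F, 2); i -= 2; j -= 1; break;
    case 6: ops.push(OP_G, 1); i -= 1; break;
    case 7: ops.push(OP_G, 2); i -= 2; break;
    case 2: { // insertion run
      int len = 0;
      for (;;) { int8_t ci = TB(tbI, i, j); ++len; --j; if (ci == 1) break; }
      ops.push(OP_I, len);
      break;
    }
    case 3: { // deletion run (codons)
      int len = 0;
      for (;;) { int8_t cd = TB(tbD, i, j); ++len; i -= 3; if (cd == 1) break; }
      ops.push(OP_D, len);
      break;
    }
    case 8: { // Phase-0 intron ending at i
      int i2 = i;
      while (TB(tbA, i2, j) == 2) --i2;   // entry row = first intron base
      ops.push(OP_N, i - i2 + 1);
      istart.push_back(i2); iend.push_back(i); iphase.push_back(0);
      i = i2 - 1;
      break;
    }
    case 9: { // Phase-1 intron: split codon base e | intron e+1..i-2 | bases i-1,i
      int e2 = i - 3;
      while (TB(tbB, e2, j) == 2) --e2;
      ops.push(OP_U, i - e2 + 1);
      istart.push_back(e2 + 1); iend.push_back(i - 2); iphase.push_back(1);
      i = e2 - 1; j -= 1;
      break;
    }
    case 10: { // Phase-2 intron: bases e,e+1 | intron e+2..i-1 | base i
      int e2 = i - 3;
      while (TB(tbC, e2, j) == 2) --e2;
      ops.push(OP_V, i - e2 + 1);
      istart.push_back(e2 + 2); iend.push_back(i - 1); iphase.push_back(2);
      i = e2 - 1; j -= 1;
      break;
    }
    default: stop("traceback error");
    }
  }
  int gstart = i + 1;

  int K = ops.code.size();
  IntegerMatrix opmat(K, 2);
  for (int t = 0; t < K; ++t) { opmat(t, 0) = ops.code[K - 1 - t]; opmat(t, 1) = ops.len[K - 1 - t]; }
  int NI = istart.size();
  IntegerMatrix intr(NI, 3);
  for (int t = 0; t < NI; ++t) {
    intr(t, 0) = istart[NI - 1 - t]; intr(t, 1) = iend[NI - 1 - t]; intr(t, 2) = iphase[NI - 1 - t];
  }
  return List::create(_["score"] = score, _["ops"] = opmat, _["introns"] = intr,
                      _["gstart"] = gstart, _["gend"] = gend);
}
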
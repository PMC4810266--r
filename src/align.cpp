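#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Traceback state codes
enum { ST_M = 0, ST_IX = 1, ST_IY = 2, ST_STOP = 3 };

// Build a 128x128 score lookup from a named substitution matrix.
static void build_lookup(const IntegerMatrix &sub, const CharacterVector &alpha,
                         int lut[128][128]) {
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) lut[i][j] = 0;
  int n = alpha.size();
  std::vector<char> ch(n);
  for (int i = 0; i < n; ++i) ch[i] = Rcpp::as<std::string>(alpha[i])[0];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      lut[(int)ch[i]][(int)ch[j]] = sub(i, j);
}

struct SWResult {
  int score, matches, aln_len, qstart, qend, sstart, send, gapopen, mismatch;
};

// Affine-gap local alignment, gap of length L costs open + L*extend.
// Deterministic: best cell = highest score, ties by smallest i then j;
// traceback prefers diagonal (M) over up (Ix) over left (Iy).
// DP rows are rolled (two rows live); the traceback matrix packs the three
// per-state predecessor codes into one byte per cell.
static SWResult sw_one(const std::string &a, const std::string &b,
                       const int lut[128][128], int open, int ext,
                       std::vector<int> &M0, std::vector<int> &M1,
                       std::vector<int> &Ix0, std::vector<int> &Ix1,
                       std::vector<int> &Iy1, std::vector<unsigned char> &tb) {
  const int m = a.size(), n = b.size();
  const int W = n + 1;
  const int NEG = -1000000000;
  const int oe = open + ext;
  if ((int)M0.size() < W) {
    M0.resize(W); M1.resize(W); Ix0.resize(W); Ix1.resize(W); Iy1.resize(W);
  }
  if (tb.size() < (size_t)(m + 1) * W) tb.resize((size_t)(m + 1) * W);
  std::fill(M0.begin(), M0.begin() + W, 0);
  std::fill(Ix0.begin(), Ix0.begin() + W, NEG);
  std::fill(Iy1.begin(), Iy1.begin() + W, NEG);  // virtual row 0 for Iy
  int best = 0, bi = 0, bj = 0;
  int *Mp = M0.data(), *Mc = M1.data();
  int *Ixp = Ix0.data(), *Ixc = Ix1.data();
  int *Iyc = Iy1.data();
  for (int i = 1; i <= m; ++i) {
    const int *lrow = lut[(int)(unsigned char)a[i - 1]];
    unsigned char *tbc = &tb[(size_t)i * W];
    Mc[0] = 0; Ixc[0] = NEG; Iyc[0] = NEG;
    int diagM = Mp[0], diagIx = Ixp[0], diagIy = NEG;
    for (int j = 1; j <= n; ++j) {
      // Ix: vertical gap (consumes a_i); branchless selects compile to cmov
      const int ixo = Mp[j] - oe, ixe = Ixp[j] - ext;
      const bool ix_ext = ixe > ixo;
      const int ixv = ix_ext ? ixe : ixo;
      const unsigned char ixs = ix_ext ? ST_IX : ST_M;
      // Iy: horizontal gap (consumes b_j)
      const int iyo = Mc[j - 1] - oe, iye = Iyc[j - 1] - ext;
      const bool iy_ext = iye > iyo;
      const int iyv = iy_ext ? iye : iyo;
      const unsigned char iys = iy_ext ? ST_IY : ST_M;
      // M: diagonal; predecessor preference M > Ix > Iy
      int pbest = diagM; unsigned char pst = ST_M;
      const bool t1 = diagIx > pbest;
      pbest = t1 ? diagIx : pbest; pst = t1 ? (unsigned char)ST_IX : pst;
      const bool t2 = diagIy > pbest;
      pbest = t2 ? diagIy : pbest; pst = t2 ? (unsigned char)ST_IY : pst;
      int v = pbest + lrow[(int)(unsigned char)b[j - 1]];
      const unsigned char mst = (v <= 0 || pbest <= 0) ? ST_STOP : pst;
      v = v > 0 ? v : 0;
      diagM = Mp[j]; diagIx = Ixp[j]; diagIy = Iyc[j];
      Mc[j] = v; Ixc[j] = ixv; Iyc[j] = iyv;
      tbc[j] = (unsigned char)(mst | (ixs << 2) | (iys << 4));
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Ixp, Ixc);
  }
  SWResult r; r.score = best;
  r.matches = 0; r.aln_len = 0; r.gapopen = 0; r.mismatch = 0;
  if (best == 0) { r.qstart = r.qend = r.sstart = r.send = 0; return r; }
  // traceback over the packed byte matrix
  int i = bi, j = bj; unsigned char st = ST_M;
  r.qend = bi; r.send = bj;
  while (true) {
    unsigned char code = tb[(size_t)i * W + j];
    if (st == ST_M) {
      unsigned char prev = code & 3;
      ++r.aln_len;
      if (a[i - 1] == b[j - 1]) ++r.matches; else ++r.mismatch;
      --i; --j;
      if (prev == ST_STOP) break;
      st = prev;
    } else if (st == ST_IX) {
      unsigned char prev = (code >> 2) & 3;
      ++r.aln_len;
      if (prev == ST_M) ++r.gapopen;
      --i; st = prev;
    } else { // ST_IY
      unsigned char prev = (code >> 4) & 3;
      ++r.aln_len;
      if (prev == ST_M) ++r.gapopen;
      --j; st = prev;
    }
  }
  r.qstart = i + 1; r.sstart = j + 1;
  return r;
}

//' @noRd
// [[Rcpp::export(name = ".sw_batch_cpp")]]
IntegerMatrix sw_batch_cpp(CharacterVector a, CharacterVector b,
                           IntegerMatrix sub, CharacterVector alphabet,
                           int gap_open, int gap_extend) {
  static int lut[128][128];
  build_lookup(sub, alphabet, lut);
  const int N = a.size();
  if (b.size() != N) stop("length mismatch");
  IntegerMatrix out(N, 9);
  std::vector<int> M0, M1, Ix0, Ix1, Iy1;
  std::vector<unsigned char> tb;
  for (int k = 0; k < N; ++k) {
    std::string sa = Rcpp::as<std::string>(a[k]);
    std::string sb = Rcpp::as<std::string>(b[k]);
    SWResult r = sw_one(sa, sb, lut, gap_open, gap_extend,
                        M0, M1, Ix0, Ix1, Iy1, tb);
    out(k, 0) = r.score; out(k, 1) = r.matches; out(k, 2) = r.aln_len;
    out(k, 3) = r.qstart; out(k, 4) = r.qend; out(k, 5) = r.sstart;
    out(k, 6) = r.send; out(k, 7) = r.gapopen; out(k, 8) = r.mismatch;
  }
  colnames(out) = CharacterVector::create(
      "score", "matches", "aln_len", "qstart", "qend", "sstart", "send",
      "gapopen", "mismatch");
  return out;
}

// Global (Needleman-Wunsch) affine-gap DP over a precomputed column-score
// matrix S (rows = columns of profile A, cols = columns of profile B).
// End gaps are charged. Returns aligned index vectors (0 = gap).
//' @noRd
// [[Rcpp::export(name = ".nw_profile_cpp")]]
List nw_profile_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int m = S.nrow(), n = S.ncol(), W = n + 1;
  const double NEG = -1e18;
  std::vector<double> M((size_t)(m + 1) * W, NEG), Ix((size_t)(m + 1) * W, NEG),
      Iy((size_t)(m + 1) * W, NEG);
  std::vector<unsigned char> tb((size_t)(m + 1) * W * 3, ST_STOP);
  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    size_t c = (size_t)i * W;
    Ix[c] = -gap_open - gap_extend * i;
    tb[c * 3 + ST_IX] = (i == 1) ? ST_M : ST_IX;
  }
  for (int j = 1; j <= n; ++j) {
    Iy[j] = -gap_open - gap_extend * j;
    tb[(size_t)j * 3 + ST_IY] = (j == 1) ? ST_M : ST_IY;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const size_t c = (size_t)i * W + j, d = (size_t)(i - 1) * W + (j - 1);
      const size_t up = (size_t)(i - 1) * W + j, lf = c - 1;
      double ixo = M[up] - gap_open - gap_extend, ixe = Ix[up] - gap_extend;
      if (ixo >= ixe) { Ix[c] = ixo; tb[c * 3 + ST_IX] = ST_M; }
      else            { Ix[c] = ixe; tb[c * 3 + ST_IX] = ST_IX; }
      double iyo = M[lf] - gap_open - gap_extend, iye = Iy[lf] - gap_extend;
      if (iyo >= iye) { Iy[c] = iyo; tb[c * 3 + ST_IY] = ST_M; }
      else            { Iy[c] = iye; tb[c * 3 + ST_IY] = ST_IY; }
      double pm = M[d], pix = Ix[d], piy = Iy[d];
      double pbest = pm; unsigned char pst = ST_M;
      if (pix > pbest) { pbest = pix; pst = ST_IX; }
      if (piy > pbest) { pbest = piy; pst = ST_IY; }
      M[c] = pbest + S(i - 1, j - 1);
      tb[c * 3 + ST_M] = pst;
    }
  }
  // choose best end state: M > Ix > Iy on ties
  size_t e = (size_t)m * W + n;
  unsigned char st = ST_M; double bestv = M[e];
  if (Ix[e] > bestv) { bestv = Ix[e]; st = ST_IX; }
  if (Iy[e] > bestv) { bestv = Iy[e]; st = ST_IY; }
  std::vector<int> ai, bi;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    unsigned char prev = tb[c * 3 + st];
    if (st == ST_M) { ai.push_back(i); bi.push_back(j); --i; --j; st = prev; }
    else if (st == ST_IX) { ai.push_back(i); bi.push_back(0); --i; st = prev; }
    else { ai.push_back(0); bi.push_back(j); --j; st = prev; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = bestv);
}
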
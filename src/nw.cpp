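#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment over A..Z-encoded residue strings.
//
// Gap model: the first residue of a gap run costs `gap_open`, every further
// residue `gap_extend` (both <= 0).  With gap_open == gap_extend the model is
// linear and a single-matrix DP is used; otherwise the three-state affine
// recurrence (M / Ix / Iy).  Traceback is byte-deterministic: ties prefer the
// diagonal move, then a gap in the second sequence ("up"), then a gap in the
// first ("left").

static const double NEG = -1e15;

struct AlnOut {
  double score;
  int matches;       // identical non-gap, non-X columns
  int aln_len;       // total columns
  int aligned_cols;  // columns with residues in both rows
  std::string aa, ab;
};

struct Workspace {
  std::vector<double> M, Ix, Iy;
  std::vector<unsigned char> pm, px, py;  // predecessor state per matrix
  std::vector<double> D;
  std::vector<unsigned char> P;
};

static inline bool is_match(char x, char y) {
  return x == y && x != 'X';
}

// linear gap penalty g per gap column
static void nw_linear(const std::string& a, const std::string& b,
                      const double* sub, double g, bool build,
                      Workspace& w, AlnOut& out) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t sz = (size_t)(n + 1) * (m + 1);
  if (w.D.size() < sz) { w.D.resize(sz); w.P.resize(sz); }
  double* D = w.D.data();
  unsigned char* P = w.P.data();
  const int W = m + 1;

  D[0] = 0; P[0] = 0;
  for (int j = 1; j <= m; ++j) { D[j] = j * g; P[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    D[(size_t)i * W] = i * g;
    P[(size_t)i * W] = 1;
    const int ai = a[i - 1] - 'A';
    const double* srow = sub + (size_t)ai * 26;
    const double* prev = D + (size_t)(i - 1) * W;
    double* cur = D + (size_t)i * W;
    unsigned char* pc = P + (size_t)i * W;
    for (int j = 1; j <= m; ++j) {
      const double d = prev[j - 1] + srow[b[j - 1] - 'A'];
      const double u = prev[j] + g;
      const double l = cur[j - 1] + g;
      if (d >= u && d >= l)      { cur[j] = d; pc[j] = 0; }
      else if (u >= l)           { cur[j] = u; pc[j] = 1; }
      else                       { cur[j] = l; pc[j] = 2; }
    }
  }
  out.score = D[(size_t)n * W + m];

  int i = n, j = m, matches = 0, cols = 0, both = 0;
  std::string ra, rb;
  if (build) { ra.reserve(n + m); rb.reserve(n + m); }
  while (i > 0 || j > 0) {
    const unsigned char p = P[(size_t)i * W + j];
    ++cols;
    if (p == 0) {
      if (is_match(a[i - 1], b[j - 1])) ++matches;
      ++both;
      if (build) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
      --i; --j;
    } else if (p == 1) {
      if (build) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i;
    } else {
      if (build) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j;
    }
  }
  out.matches = matches; out.aln_len = cols; out.aligned_cols = both;
  if (build) {
    out.aa.assign(ra.rbegin(), ra.rend());
    out.ab.assign(rb.rbegin(), rb.rend());
  }
}

// three-state affine recurrence; predecessor-state matrices drive traceback
static void nw_affine(const std::string& a, const std::string& b,
                      const double* sub, double go, double ge, bool build,
                      Workspace& w, AlnOut& out) {
  const int n = (int)a.size(), m = (int)b.size();
  const size_t sz = (size_t)(n + 1) * (m + 1);
  if (w.M.size() < sz) {
    w.M.resize(sz); w.Ix.resize(sz); w.Iy.resize(sz);
    w.pm.resize(sz); w.px.resize(sz); w.py.resize(sz);
  }
  double *M = w.M.data(), *Ix = w.Ix.data(), *Iy = w.Iy.data();
  unsigned char *pm = w.pm.data(), *px = w.px.data(), *py = w.py.data();
  const int W = m + 1;

  M[0] = 0; Ix[0] = NEG; Iy[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M[j] = NEG; Ix[j] = NEG;
    Iy[j] = go + (j - 1) * ge;
    py[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t)i * W, pr = r - W;
    M[r] = NEG; Iy[r] = NEG;
    Ix[r] = go + (i - 1) * ge;
    px[r] = (i == 1) ? 0 : 1;
    const int ai = a[i - 1] - 'A';
    const double* srow = sub + (size_t)ai * 26;
    for (int j = 1; j <= m; ++j) {
      // M: consume a[i-1] and b[j-1]
      double vm = M[pr + j - 1], vx = Ix[pr + j - 1], vy = Iy[pr + j - 1];
      unsigned char p = 0; double best = vm;
      if (vx > best) { best = vx; p = 1; }
      if (vy > best) { best = vy; p = 2; }
      M[r + j] = best + srow[b[j - 1] - 'A'];
      pm[r + j] = p;
      // Ix: gap in b, consume a[i-1]
      vm = M[pr + j] + go; vx = Ix[pr + j] + ge; vy = Iy[pr + j] + go;
      p = 0; best = vm;
      if (vx > best) { best = vx; p = 1; }
      if (vy > best) { best = vy; p = 2; }
      Ix[r + j] = best; px[r + j] = p;
      // Iy: gap in a, consume b[j-1]
      vm = M[r + j - 1] + go; vx = Ix[r + j - 1] + go; vy = Iy[r + j - 1] + ge;
      p = 0; best = vm;
      if (vx > best) { best = vx; p = 1; }
      if (vy > best) { best = vy; p = 2; }
      Iy[r + j] = best; py[r + j] = p;
    }
  }
  const size_t e = (size_t)n * W + m;
  unsigned char st = 0; double best = M[e];
  if (Ix[e] > best) { best = Ix[e]; st = 1; }
  if (Iy[e] > best) { best = Iy[e]; st = 2; }
  if (n == 0 && m == 0) { st = 0; best = 0; }
  out.score = best;

  int i = n, j = m, matches = 0, cols = 0, both = 0;
  std::string ra, rb;
  if (build) { ra.reserve(n + m); rb.reserve(n + m); }
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    ++cols;
    if (st == 0) {
      if (is_match(a[i - 1], b[j - 1])) ++matches;
      ++both;
      if (build) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
      st = pm[c]; --i; --j;
    } else if (st == 1) {
      if (build) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      st = px[c]; --i;
    } else {
      if (build) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      st = py[c]; --j;
    }
  }
  out.matches = matches; out.aln_len = cols; out.aligned_cols = both;
  if (build) {
    out.aa.assign(ra.rbegin(), ra.rend());
    out.ab.assign(rb.rbegin(), rb.rend());
  }
}

static void nw_dispatch(const std::string& a, const std::string& b,
                        const double* sub, double go, double ge, bool build,
                        Workspace& w, AlnOut& out) {
  if (go == ge) nw_linear(a, b, sub, go, build, w, out);
  else nw_affine(a, b, sub, go, ge, build, w, out);
}

static double identity_from(const AlnOut& o, int na, int nb, int mode) {
  int denom;
  if (mode == 1) denom = na < nb ? na : nb;        // shorter sequence
  else if (mode == 2) denom = o.aligned_cols;      // residue-residue columns
  else denom = o.aln_len;                          // full alignment length
  if (denom <= 0) return 0.0;
  return 100.0 * o.matches / denom;
}

// Alignments are computed in a canonical orientation (lexicographically
// smaller sequence first) so that the traceback — and hence the column
// counts behind percent identity — is invariant under swapping the
// inputs; the reported rows keep the caller's order.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  Workspace w;
  AlnOut out;
  const bool sw = b < a;
  nw_dispatch(sw ? b : a, sw ? a : b, REAL(sub), gap_open, gap_extend,
              true, w, out);
  if (sw) std::swap(out.aa, out.ab);
  return List::create(
    _["aligned_a"] = out.aa, _["aligned_b"] = out.ab,
    _["score"] = out.score, _["matches"] = out.matches,
    _["aln_len"] = out.aln_len, _["aligned_cols"] = out.aligned_cols);
}

// Batched identity over index pairs into a pool of sequences (1-based ia/ib).
// [[Rcpp::export]]
NumericVector nw_identity_pairs_cpp(CharacterVector seqs, IntegerVector ia,
                                    IntegerVector ib, NumericMatrix sub,
                                    double gap_open, double gap_extend,
                                    int denom_mode) {
  const int ns = seqs.size(), np = ia.size();
  if (ib.size() != np) stop("ia and ib must have equal length");
  std::vector<std::string> pool(ns);
  for (int k = 0; k < ns; ++k) pool[k] = as<std::string>(seqs[k]);
  Workspace w;
  AlnOut out;
  NumericVector res(np);
  const double* s = REAL(sub);
  for (int k = 0; k < np; ++k) {
    const int u = ia[k] - 1, v = ib[k] - 1;
    if (u < 0 || u >= ns || v < 0 || v >= ns) stop("pair index out of range");
    const std::string *pu = &pool[u], *pv = &pool[v];
    if (*pv < *pu) std::swap(pu, pv);  // canonical orientation (symmetry)
    nw_dispatch(*pu, *pv, s, gap_open, gap_extend, false, w, out);
    res[k] = identity_from(out, (int)pu->size(), (int)pv->size(),
                           denom_mode);
  }
  return res;
}

// Batched raw scores (used for score-level cross-checks).
// [[Rcpp::export]]
NumericVector nw_score_pairs_cpp(CharacterVector seqs, IntegerVector ia,
                                 IntegerVector ib, NumericMatrix sub,
                                 double gap_open, double gap_extend) {
  const int ns = seqs.size(), np = ia.size();
  std::vector<std::string> pool(ns);
  for (int k = 0; k < ns; ++k) pool[k] = as<std::string>(seqs[k]);
  Workspace w;
  AlnOut out;
  NumericVector res(np);
  const double* s = REAL(sub);
  for (int k = 0; k < np; ++k) {
    nw_dispatch(pool[ia[k] - 1], pool[ib[k] - 1], s, gap_open, gap_extend,
                false, w, out);
    res[k] = out.score;
  }
  return res;
}
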
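#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- k-mer encoding and hashing -------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;  // N or anything else
  }
}

// murmur3-style finalizer; keys are masked to 52 bits so they are exactly
// representable as doubles on the R side (joins on keys stay exact)
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 33;
  x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33;
  x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return x;
}
static const uint64_t KEY_MASK = (1ULL << 52) - 1;

// canonical key of one k-mer window: hash forward and reverse-complement
// 2-bit codes, keep the smaller; strand 0 when forward wins or ties
static inline bool canon_key(const char* s, int k, double& key, int& strand) {
  uint64_t fwd = 0, rc = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    fwd = (fwd << 2) | (uint64_t)c;
    rc |= ((uint64_t)(3 - c)) << (2 * i);
  }
  uint64_t hf = mix64(fwd) & KEY_MASK;
  uint64_t hr = mix64(rc) & KEY_MASK;
  if (hf <= hr) { key = (double)hf; strand = 0; }
  else          { key = (double)hr; strand = 1; }
  return true;
}

// [[Rcpp::export]]
SEXP canonical_kmer_cpp(std::string window) {
  int k = (int)window.size();
  double key; int strand;
  if (!canon_key(window.c_str(), k, key, strand)) return R_NilValue;
  return List::create(_["key"] = key, _["strand"] = strand);
}

// ---- minimizer scan --------------------------------------------------------

// closed-window minimizers: for every window of w consecutive k-mer start
// positions, emit all positions attaining the minimum key among valid
// (N-free) k-mers; duplicates across overlapping windows removed
// [[Rcpp::export]]
List minimizers_cpp(std::string seq, int k, int w) {
  int n = (int)seq.size();
  int nk = n - k + 1;
  std::vector<double> keys;
  std::vector<int> strands;
  std::vector<char> valid;
  if (nk < 1) {
    return List::create(_["key"] = NumericVector(0),
                        _["pos"] = IntegerVector(0),
                        _["strand"] = IntegerVector(0));
  }
  keys.resize(nk); strands.resize(nk); valid.resize(nk);
  const char* s = seq.c_str();
  for (int p = 0; p < nk; ++p) {
    double key; int strand;
    if (canon_key(s + p, k, key, strand)) {
      keys[p] = key; strands[p] = strand; valid[p] = 1;
    } else {
      valid[p] = 0;
    }
  }
  std::vector<char> emitted(nk, 0);
  int first_last = (nk <= w) ? 0 : (nk - w);   // last window start
  int wlen = (nk <= w) ? nk : w;               // short sequences: one window
  for (int i = 0; i <= first_last; ++i) {
    double mn = 0; bool seen = false;
    for (int j = i; j < i + wlen; ++j) {
      if (!valid[j]) continue;
      if (!seen || keys[j] < mn) { mn = keys[j]; seen = true; }
    }
    if (!seen) continue;
    for (int j = i; j < i + wlen; ++j)
      if (valid[j] && keys[j] == mn) emitted[j] = 1;
  }
  std::vector<double> okey; std::vector<int> opos, ostrand;
  for (int p = 0; p < nk; ++p) {
    if (emitted[p]) { okey.push_back(keys[p]); opos.push_back(p); ostrand.push_back(strands[p]); }
  }
  return List::create(_["key"] = wrap(okey),
                      _["pos"] = wrap(opos),
                      _["strand"] = wrap(ostrand));
}

// ---- chaining DP -----------------------------------------------------------

// anchors sorted by (tpos, qpos); all share one (seqid, strand).
// f(i) = max(span_i, max_{j in lookback window, feasible} f(j)
//            + min(dq, dt, span_i) - cost(j, i))
// cost = gap_scale * span_i * g + 0.5 * log2(g + 1), g = |dq - dt|.
// Predecessor ties resolved toward the largest j; a tie with the single-anchor
// base score keeps the base (pred 0). pred returned 1-based, 0 = chain start.
// [[Rcpp::export]]
List chain_dp_cpp(IntegerVector qpos, IntegerVector tpos, IntegerVector span,
                  int strand, double max_gap, double bw, double gap_scale,
                  int lookback) {
  int n = qpos.size();
  NumericVector f(n);
  IntegerVector pred(n);
  for (int i = 0; i < n; ++i) {
    double best = (double)span[i];
    int bp = 0;
    int j0 = i - lookback; if (j0 < 0) j0 = 0;
    for (int j = i - 1; j >= j0; --j) {
      double dt = (double)tpos[i] - (double)tpos[j];
      double dq = (strand == 0) ? ((double)qpos[i] - (double)qpos[j])
                                : ((double)qpos[j] - (double)qpos[i]);
      if (dt <= 0 || dq <= 0 || dq > max_gap || dt > max_gap) continue;
      double g = std::fabs(dq - dt);
      if (g > bw) continue;
      double gain = std::min(std::min(dq, dt), (double)span[i]);
      double cost = gap_scale * (double)span[i] * g + 0.5 * std::log2(g + 1.0);
      double cand = f[j] + gain - cost;
      if (cand > best) { best = cand; bp = j + 1; }
    }
    f[i] = best; pred[i] = bp;
  }
  return List::create(_["f"] = f, _["pred"] = pred);
}

// ---- affine-gap global alignment (Gotoh, banded) ---------------------------

// a = query, b = target. Ops: 0 = M (both), 1 = I (query only), 2 = D (target
// only). Cells with |i - j| > band are outside the band. Traceback tie order:
// diagonal (M) > deletion (D) > insertion (I), and M > D > I when choosing the
// predecessor state within a cell.
static const double NEG = -1e30;

// [[Rcpp::export]]
List affine_align_cpp(std::string a, std::string b, double match_s,
                      double mismatch_s, double gap_open, double gap_ext,
                      int band) {
  int la = (int)a.size(), lb = (int)b.size();
  if (std::abs(la - lb) > band) stop("band exceeded");
  if (la == 0 && lb == 0)
    return List::create(_["score"] = 0.0, _["ops"] = IntegerVector(0),
                        _["lens"] = IntegerVector(0));

  // rolling score rows; full byte traceback (2 bits per state):
  // predecessor state codes 0 = M, 1 = D(Ib), 2 = I(Ia)
  size_t ncell = (size_t)(la + 1) * (size_t)(lb + 1);
  std::vector<unsigned char> tb(ncell, 0);
  std::vector<double> pM(lb + 1, NEG), pI(lb + 1, NEG), pD(lb + 1, NEG);
  std::vector<double> cM(lb + 1), cI(lb + 1), cD(lb + 1);

  pM[0] = 0.0;
  for (int j = 1; j <= lb && j <= band; ++j) {
    pD[j] = -(gap_open + gap_ext * j);
    tb[j] = (unsigned char)(((j == 1 ? 0 : 1)) << 4);  // D-state pred
  }
  for (int i = 1; i <= la; ++i) {
    std::fill(cM.begin(), cM.end(), NEG);
    std::fill(cI.begin(), cI.end(), NEG);
    std::fill(cD.begin(), cD.end(), NEG);
    int jlo = i - band; if (jlo < 0) jlo = 0;
    int jhi = i + band; if (jhi > lb) jhi = lb;
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char t = 0;
      if (j > 0 && j - 1 >= (i - 1) - band) {  // diagonal inside previous band
        double s = (a[i - 1] == b[j - 1]) ? match_s : -mismatch_s;
        double m = pM[j - 1]; int mp = 0;
        if (pD[j - 1] > m) { m = pD[j - 1]; mp = 1; }
        if (pI[j - 1] > m) { m = pI[j - 1]; mp = 2; }
        if (m > NEG / 2) { cM[j] = m + s; t |= (unsigned char)mp; }
      }
      if (j <= (i - 1) + band) {  // vertical: consume a[i-1], op I
        double vM = pM[j] - (gap_open + gap_ext);
        double vD = pD[j] - (gap_open + gap_ext);
        double vI = pI[j] - gap_ext;
        double m = vM; int mp = 0;
        if (vD > m) { m = vD; mp = 1; }
        if (vI > m) { m = vI; mp = 2; }
        if (m > NEG / 2) { cI[j] = m; t |= (unsigned char)(mp << 2); }
      }
      if (j > 0) {  // horizontal: consume b[j-1], op D
        double hM = cM[j - 1] - (gap_open + gap_ext);
        double hI = cI[j - 1] - (gap_open + gap_ext);
        double hD = cD[j - 1] - gap_ext;
        double m = hM; int mp = 0;
        if (hD > m) { m = hD; mp = 1; }
        if (hI > m) { m = hI; mp = 2; }
        if (m > NEG / 2) { cD[j] = m; t |= (unsigned char)(mp << 4); }
      }
      tb[(size_t)i * (lb + 1) + j] = t;
    }
    std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
  }
  double sM = pM[lb], sI = pI[lb], sD = pD[lb];
  double score = sM; int state = 0;          // 0 = M, 1 = D, 2 = I
  if (sD > score) { score = sD; state = 1; }
  if (sI > score) { score = sI; state = 2; }
  if (score < NEG / 2) stop("band exceeded");

  // traceback
  std::vector<int> rops;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (lb + 1) + j];
    int prev;
    if (state == 0)      { rops.push_back(0); prev = t & 3;        --i; --j; }
    else if (state == 1) { rops.push_back(2); prev = (t >> 4) & 3; --j; }
    else                 { rops.push_back(1); prev = (t >> 2) & 3; --i; }
    state = prev;
  }
  // reverse + run-length encode
  std::vector<int> ops, lens;
  for (int p = (int)rops.size() - 1; p >= 0; --p) {
    int op = rops[p];
    if (!ops.empty() && ops.back() == op) lens.back()++;
    else { ops.push_back(op); lens.push_back(1); }
  }
  return List::create(_["score"] = score, _["ops"] = wrap(ops),
                      _["lens"] = wrap(lens));
}

// ---- interval tree (augmented treap) ---------------------------------------

struct ITNode {
  int s, e, payload;
  uint64_t pri;
  int l, r, maxe;
};

class ITree {
public:
  std::vector<ITNode> nodes;
  int root = -1;
  uint64_t counter = 0;

  int upd(int v) {
    int m = nodes[v].e;
    if (nodes[v].l >= 0 && nodes[nodes[v].l].maxe > m) m = nodes[nodes[v].l].maxe;
    if (nodes[v].r >= 0 && nodes[nodes[v].r].maxe > m) m = nodes[nodes[v].r].maxe;
    nodes[v].maxe = m;
    return v;
  }
  // split by start coordinate: keys < (s, tie) go left
  void split(int v, int s, int id, int& l, int& r) {
    if (v < 0) { l = r = -1; return; }
    bool goLeft = (nodes[v].s < s) || (nodes[v].s == s && v < id);
    if (goLeft) { split(nodes[v].r, s, id, nodes[v].r, r); l = upd(v); }
    else        { split(nodes[v].l, s, id, l, nodes[v].l); r = upd(v); }
  }
  int merge(int l, int r) {
    if (l < 0) return r;
    if (r < 0) return l;
    if (nodes[l].pri > nodes[r].pri) { nodes[l].r = merge(nodes[l].r, r); return upd(l); }
    else                             { nodes[r].l = merge(l, nodes[r].l); return upd(r); }
  }
  void insert(int s, int e, int payload) {
    int id = (int)nodes.size();
    ITNode nd; nd.s = s; nd.e = e; nd.payload = payload;
    nd.pri = mix64(++counter ^ 0x9e3779b97f4a7c15ULL);
    nd.l = nd.r = -1; nd.maxe = e;
    nodes.push_back(nd);
    int l, r;
    split(root, s, id, l, r);
    root = merge(merge(l, id), r);
  }
  void query(int v, int s, int e, std::vector<int>& out) const {
    if (v < 0) return;
    if (nodes[v].maxe <= s) return;          // nothing in subtree ends past s
    query(nodes[v].l, s, e, out);
    if (nodes[v].s < e && nodes[v].e > s) out.push_back(v);
    if (nodes[v].s < e) query(nodes[v].r, s, e, out);
  }
};

// [[Rcpp::export]]
SEXP it_new_cpp() {
  XPtr<ITree> p(new ITree(), true);
  return p;
}

// [[Rcpp::export]]
void it_insert_cpp(SEXP tree, IntegerVector s, IntegerVector e,
                   IntegerVector payload) {
  XPtr<ITree> p(tree);
  for (int i = 0; i < s.size(); ++i) p->insert(s[i], e[i], payload[i]);
}

// [[Rcpp::export]]
List it_query_cpp(SEXP tree, int s, int e) {
  XPtr<ITree> p(tree);
  std::vector<int> hits;
  p->query(p->root, s, e, hits);
  int n = (int)hits.size();
  IntegerVector os(n), oe(n), op(n);
  for (int i = 0; i < n; ++i) {
    os[i] = p->nodes[hits[i]].s;
    oe[i] = p->nodes[hits[i]].e;
    op[i] = p->nodes[hits[i]].payload;
  }
  return List::create(_["s"] = os, _["e"] = oe, _["payload"] = op);
}

// [[Rcpp::export]]
int it_size_cpp(SEXP tree) {
  XPtr<ITree> p(tree);
  return (int)p->nodes.size();
}

// ---- reverse complement ----------------------------------------------------

// [[Rcpp::export]]
std::string revcomp_cpp(std::string seq) {
  size_t n = seq.size();
  std::string out(n, 'N');
  for (size_t i = 0; i < n; ++i) {
    char c = seq[n - 1 - i];
    switch (c) {
    case 'A': out[i] = 'T'; break;
    case 'C': out[i] = 'G'; break;
    case 'G': out[i] = 'C'; break;
    case 'T': out[i] = 'A'; break;
    default:  out[i] = 'N';
    }
  }
  return out;
}

// ---- stable merge of sorted runs (for chunked parallel sort) ---------------

// keymat: n x m numeric key matrix (lexicographic order over columns).
// perm: 1-based permutation, concatenation of stably-sorted runs.
// runlen: lengths of the runs. Pairwise stable merges: on key ties the
// element from the left (earlier original positions) run wins.
// [[Rcpp::export]]
IntegerVector merge_sorted_runs_cpp(NumericMatrix keymat, IntegerVector perm,
                                    IntegerVector runlen) {
  int m = keymat.ncol();
  std::vector<std::vector<int>> runs;
  int off = 0;
  for (int r = 0; r < runlen.size(); ++r) {
    std::vector<int> run(runlen[r]);
    for (int i = 0; i < runlen[r]; ++i) run[i] = perm[off + i] - 1;
    off += runlen[r];
    runs.push_back(std::move(run));
  }
  auto lt = [&](int x, int y) {  // strict keymat[x] < keymat[y]
    for (int c = 0; c < m; ++c) {
      if (keymat(x, c) < keymat(y, c)) return true;
      if (keymat(x, c) > keymat(y, c)) return false;
    }
    return false;
  };
  while (runs.size() > 1) {
    std::vector<std::vector<int>> nxt;
    for (size_t r = 0; r + 1 < runs.size(); r += 2) {
      const std::vector<int>& A = runs[r];
      const std::vector<int>& B = runs[r + 1];
      std::vector<int> out; out.reserve(A.size() + B.size());
      size_t i = 0, j = 0;
      while (i < A.size() && j < B.size()) {
        if (lt(B[j], A[i])) out.push_back(B[j++]);   // left wins ties
        else out.push_back(A[i++]);
      }
      while (i < A.size()) out.push_back(A[i++]);
      while (j < B.size()) out.push_back(B[j++]);
      nxt.push_back(std::move(out));
    }
    if (runs.size() % 2 == 1) nxt.push_back(std::move(runs.back()));
    runs = std::move(nxt);
  }
  std::vector<int>& fin = runs[0];
  IntegerVector res((int)fin.size());
  for (size_t i = 0; i < fin.size(); ++i) res[i] = fin[i] + 1;
  return res;
}
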
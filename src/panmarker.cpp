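#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) returning the statistics of the
// optimal alignment. Among equal-score alignments the one with the most
// matches is preferred, then the one with the fewest columns; this makes
// the reported identity a deterministic function of the inputs.
//
// Gap convention: a gap run of length L costs gap_open + (L-1)*gap_extend,
// i.e. the first gapped column pays gap_open, each further column
// gap_extend. Costs are passed as positive numbers.

// The three DP objectives (score desc, matches desc, columns asc) are
// packed into one int64 so lexicographic comparison is a single integer
// max: value = score*2^44 + matches*2^22 + (LEN_BASE - columns).
// matches and the column field stay in [0, 2^22), so they never borrow
// into the score bits; sequences are capped well below that.

typedef int64_t cell_t;
static const cell_t S_UNIT = (cell_t)1 << 44;
static const cell_t M_UNIT = (cell_t)1 << 22;
static const cell_t LEN_BASE = ((cell_t)1 << 22) - 1;
static const cell_t NEG = INT64_MIN / 4;

// [[Rcpp::export(name = ".nw_align_stats")]]
List nw_align_stats(std::string a, std::string b,
                    int match = 1, int mismatch = -1,
                    int gap_open = 10, int gap_extend = 1) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if (n + m >= (1 << 21)) stop("sequences too long");

  const cell_t diag_match = (cell_t)match * S_UNIT + M_UNIT - 1;
  const cell_t diag_mismatch = (cell_t)mismatch * S_UNIT - 1;
  const cell_t open = (cell_t)gap_open * S_UNIT + 1;   // subtract, add column
  const cell_t extend = (cell_t)gap_extend * S_UNIT + 1;

  // rolling rows for states M (diagonal), X (gap in b, consumes a),
  // Y (gap in a, consumes b)
  std::vector<cell_t> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<cell_t> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  Mprev[0] = LEN_BASE;
  Xprev[0] = NEG;
  Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = LEN_BASE - (cell_t)j -
      ((cell_t)gap_open + (cell_t)(j - 1) * gap_extend) * S_UNIT;
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG;
    Ycur[0] = NEG;
    Xcur[0] = LEN_BASE - (cell_t)i -
      ((cell_t)gap_open + (cell_t)(i - 1) * gap_extend) * S_UNIT;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      cell_t d = std::max(Mprev[j - 1], std::max(Xprev[j - 1], Yprev[j - 1]));
      Mcur[j] = d + (ai == b[j - 1] ? diag_match : diag_mismatch);
      cell_t xo = std::max(Mprev[j], Yprev[j]) - open;
      cell_t xe = Xprev[j] - extend;
      Xcur[j] = xo > xe ? xo : xe;
      cell_t yo = std::max(Mcur[j - 1], Xcur[j - 1]) - open;
      cell_t ye = Ycur[j - 1] - extend;
      Ycur[j] = yo > ye ? yo : ye;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  cell_t r = std::max(Mprev[m], std::max(Xprev[m], Yprev[m]));
  int len = (int)(LEN_BASE - (r & (M_UNIT - 1)));
  int matches = (int)((r >> 22) & (M_UNIT - 1));
  int score = (int)(r >> 44); // arithmetic shift: lower fields are non-negative
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["alignment_length"] = len,
                      _["identity"] = (double)matches / (double)len);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Sorted unique 2-bit k-mer codes of a sequence; windows containing
// non-ACGT symbols are skipped. k must be <= 15.
// [[Rcpp::export(name = ".kmer_codes")]]
IntegerVector kmer_codes(std::string seq, int k = 8) {
  if (k < 1 || k > 15) stop("k must be in 1..15");
  int n = seq.size();
  std::vector<int> out;
  if (n < k) return IntegerVector(0);
  uint32_t mask = (1u << (2 * k)) - 1u;
  uint32_t code = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[i]);
    if (b < 0) {
      valid = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++valid >= k) out.push_back((int)code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return wrap(out);
}

// Number of k-mer codes shared by two sorted unique code vectors.
// [[Rcpp::export(name = ".shared_kmer_count")]]
int shared_kmer_count(IntegerVector a, IntegerVector b) {
  int i = 0, j = 0, n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// Batched variant: shared-code counts of one profile against a list.
// [[Rcpp::export(name = ".shared_kmer_counts")]]
IntegerVector shared_kmer_counts(IntegerVector a, List profs) {
  int np = profs.size();
  IntegerVector out(np);
  for (int p = 0; p < np; ++p) {
    IntegerVector b = profs[p];
    int i = 0, j = 0, n = 0;
    while (i < a.size() && j < b.size()) {
      if (a[i] < b[j]) ++i;
      else if (a[i] > b[j]) ++j;
      else { ++n; ++i; ++j; }
    }
    out[p] = n;
  }
  return out;
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// All binding sites of an oligo on a template, both strands, allowing up
// to max_mm substitutions per site but none in the 3'-terminal
// three_prime_exact bases. No indels. Returns a matrix with columns
// start (0-based, on the given template strand), strand (1 = oligo
// matches the template strand, -1 = oligo matches the reverse
// complement), mismatches.
// [[Rcpp::export(name = ".oligo_sites")]]
IntegerMatrix oligo_sites(std::string oligo, std::string tmpl,
                          int max_mm = 2, int three_prime_exact = 2) {
  int l = oligo.size(), L = tmpl.size();
  std::vector<int> starts, strands, mms;
  if (l == 0 || L < l) {
    IntegerMatrix out(0, 3);
    colnames(out) = CharacterVector::create("start", "strand", "mismatches");
    return out;
  }
  std::string rc(l, 'N');
  for (int i = 0; i < l; ++i) rc[i] = comp(oligo[l - 1 - i]);
  int tpe = std::min(three_prime_exact, l);
  for (int p = 0; p + l <= L; ++p) {
    // plus strand: oligo 5'->3' equals template[p..p+l); 3' end is the
    // last tpe oligo bases
    int mm = 0;
    bool ok = true;
    for (int i = 0; i < l; ++i) {
      if (oligo[i] != tmpl[p + i]) {
        if (i >= l - tpe) { ok = false; break; }
        if (++mm > max_mm) { ok = false; break; }
      }
    }
    if (ok) { starts.push_back(p); strands.push_back(1); mms.push_back(mm); }
    // minus strand: reverse complement of oligo appears at template[p..p+l);
    // the oligo 3' end maps to rc positions 0..tpe-1
    mm = 0;
    ok = true;
    for (int i = 0; i < l; ++i) {
      if (rc[i] != tmpl[p + i]) {
        if (i < tpe) { ok = false; break; }
        if (++mm > max_mm) { ok = false; break; }
      }
    }
    if (ok) { starts.push_back(p); strands.push_back(-1); mms.push_back(mm); }
  }
  int nh = starts.size();
  IntegerMatrix out(nh, 3);
  for (int i = 0; i < nh; ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = strands[i];
    out(i, 2) = mms[i];
  }
  colnames(out) = CharacterVector::create("start", "strand", "mismatches");
  return out;
}
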
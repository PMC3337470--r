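#include <Rcpp.h>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

// Gametes are stored as little-endian byte buffers interpreted as a
// sequence of 64-bit words, bit i of the logical allele string living in
// word i / 64 at in-word offset i % 64 (lowest bit first).  Trailing bits
// beyond n_sites are kept zero so whole-buffer comparisons are meaningful.

static const int WORD_BITS = 64;

static inline R_xlen_t n_words(int n_sites) {
  return (static_cast<R_xlen_t>(n_sites) + WORD_BITS - 1) / WORD_BITS;
}

// [[Rcpp::export(name = ".cpp_pack")]]
RawVector cpp_pack(IntegerVector bits) {
  int n = bits.size();
  RawVector out(n_words(n) * 8);
  uint64_t* w = reinterpret_cast<uint64_t*>(RAW(out));
  std::memset(w, 0, out.size());
  for (int i = 0; i < n; ++i) {
    int b = bits[i];
    if (b == NA_INTEGER || (b != 0 && b != 1))
      stop("allele at site %d is not 0/1", i + 1);
    if (b) w[i / WORD_BITS] |= (uint64_t{1} << (i % WORD_BITS));
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_unpack_region")]]
IntegerVector cpp_unpack_region(RawVector words, int n_sites, int lo, int hi) {
  // half-open [lo, hi), 0-based site indices
  if (lo < 0 || hi < lo || hi > n_sites)
    stop("region [%d,%d) out of range for %d sites", lo, hi, n_sites);
  const uint64_t* w = reinterpret_cast<const uint64_t*>(RAW(words));
  IntegerVector out(hi - lo);
  for (int i = lo; i < hi; ++i)
    out[i - lo] = (w[i / WORD_BITS] >> (i % WORD_BITS)) & 1;
  return out;
}

// Mosaic of a and b switching source at each breakpoint (0-based site
// index, strictly increasing, in (0, n_sites)).  Whole words are copied;
// only words straddling a breakpoint are merged at bit level, and the
// number of such bit-level merges is returned for instrumentation.
// [[Rcpp::export(name = ".cpp_recombine")]]
List cpp_recombine(RawVector a, RawVector b, int n_sites,
                   IntegerVector breakpoints, int start_with) {
  if (a.size() != b.size())
    stop("gamete length mismatch");
  R_xlen_t nw = n_words(n_sites);
  if (a.size() != nw * 8)
    stop("word buffer does not match n_sites");
  int nb = breakpoints.size();
  for (int k = 0; k < nb; ++k) {
    if (breakpoints[k] <= 0 || breakpoints[k] >= n_sites)
      stop("breakpoint %d outside (0, n_sites)", breakpoints[k]);
    if (k > 0 && breakpoints[k] <= breakpoints[k - 1])
      stop("breakpoints must be strictly increasing");
  }
  const uint64_t* src[2] = {
    reinterpret_cast<const uint64_t*>(RAW(a)),
    reinterpret_cast<const uint64_t*>(RAW(b))
  };
  RawVector outv(nw * 8);
  uint64_t* out = reinterpret_cast<uint64_t*>(RAW(outv));
  int cur = (start_with == 0) ? 0 : 1;
  int touched = 0;

  int seg_lo = 0;
  for (int k = 0; k <= nb; ++k) {
    int seg_hi = (k < nb) ? breakpoints[k] : n_sites;
    // word range fully inside the segment
    int w_lo = seg_lo / WORD_BITS, off_lo = seg_lo % WORD_BITS;
    int w_hi = seg_hi / WORD_BITS, off_hi = seg_hi % WORD_BITS;
    if (w_lo == w_hi) {
      if (seg_hi > seg_lo) {
        uint64_t mask = ((off_hi - off_lo == WORD_BITS)
                           ? ~uint64_t{0}
                           : (((uint64_t{1} << (off_hi - off_lo)) - 1) << off_lo));
        out[w_lo] = (out[w_lo] & ~mask) | (src[cur][w_lo] & mask);
        ++touched;
      }
    } else {
      if (off_lo != 0) {
        uint64_t mask = ~((uint64_t{1} << off_lo) - 1);
        out[w_lo] = (out[w_lo] & ~mask) | (src[cur][w_lo] & mask);
        ++touched;
        ++w_lo;
      }
      if (w_hi > w_lo)
        std::memcpy(out + w_lo, src[cur] + w_lo, (w_hi - w_lo) * 8);
      if (off_hi != 0) {
        uint64_t mask = (uint64_t{1} << off_hi) - 1;
        out[w_hi] = (out[w_hi] & ~mask) | (src[cur][w_hi] & mask);
        ++touched;
      }
    }
    cur = 1 - cur;
    seg_lo = seg_hi;
  }
  // zero trailing bits beyond n_sites
  int tail = n_sites % WORD_BITS;
  if (tail != 0 && nw > 0)
    out[nw - 1] &= (uint64_t{1} << tail) - 1;
  return List::create(_["words"] = outv, _["bit_words_touched"] = touched);
}

// Dosage (0/1/2) of two gametes at the given 0-based site indices.
// [[Rcpp::export(name = ".cpp_dosage")]]
IntegerVector cpp_dosage(RawVector pat, RawVector mat, int n_sites,
                         IntegerVector sites) {
  const uint64_t* p = reinterpret_cast<const uint64_t*>(RAW(pat));
  const uint64_t* m = reinterpret_cast<const uint64_t*>(RAW(mat));
  int ns = sites.size();
  IntegerVector out(ns);
  for (int j = 0; j < ns; ++j) {
    int i = sites[j];
    if (i < 0 || i >= n_sites) stop("site index %d out of range", i);
    out[j] = static_cast<int>((p[i / WORD_BITS] >> (i % WORD_BITS)) & 1)
           + static_cast<int>((m[i / WORD_BITS] >> (i % WORD_BITS)) & 1);
  }
  return out;
}

// Per-site counts of the 1 allele across a list of packed gametes.
// [[Rcpp::export(name = ".cpp_bit_counts")]]
IntegerVector cpp_bit_counts(List gametes, int n_sites) {
  IntegerVector out(n_sites);
  for (R_xlen_t g = 0; g < gametes.size(); ++g) {
    RawVector rv = gametes[g];
    if (rv.size() != n_words(n_sites) * 8)
      stop("gamete %d has wrong buffer size", (int)g + 1);
    const uint64_t* w = reinterpret_cast<const uint64_t*>(RAW(rv));
    for (int i = 0; i < n_sites; ++i)
      out[i] += (w[i / WORD_BITS] >> (i % WORD_BITS)) & 1;
  }
  return out;
}
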
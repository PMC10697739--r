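#include <Rcpp.h>
#include "wfa_internal.h"

using namespace Rcpp;

// Helpers converting between the R-side packed_dna list and wfa::Packed.
// 32-bit words travel as R integers (bit patterns reinterpreted).

static wfa::Packed packed_from_list(const List& x) {
  wfa::Packed p;
  p.len = as<int>(x["length"]);
  IntegerVector w = x["words"];
  p.words.resize((size_t)w.size());
  for (R_xlen_t i = 0; i < w.size(); ++i)
    p.words[(size_t)i] = (uint32_t)w[i];
  IntegerVector e = x["exceptions"];
  p.except_pos.assign(e.begin(), e.end());
  return p;
}

static List packed_to_list(const wfa::Packed& p) {
  IntegerVector w((R_xlen_t)p.words.size());
  for (size_t i = 0; i < p.words.size(); ++i)
    w[(R_xlen_t)i] = (int32_t)p.words[i];
  return List::create(_["length"] = p.len,
                      _["words"] = w,
                      _["exceptions"] = IntegerVector(p.except_pos.begin(),
                                                      p.except_pos.end()));
}

// [[Rcpp::export]]
List cpp_pack(std::string seq, bool lenient) {
  long err = -1;
  wfa::Packed p = wfa::pack(seq, lenient, &err);
  if (err >= 0)
    stop("unsupported character '%s' at position %d (expected A/C/G/T)",
         std::string(1, seq[(size_t)err]).c_str(), (int)err + 1);
  return packed_to_list(p);
}

// [[Rcpp::export]]
std::string cpp_unpack(List packed) {
  return wfa::unpack(packed_from_list(packed));
}

// [[Rcpp::export]]
int cpp_lcp(List a, List b, int i, int j) {
  wfa::Packed pa = packed_from_list(a), pb = packed_from_list(b);
  if (i < 0 || i > pa.len) stop("offset i = %d out of range [0, %d]", i, pa.len);
  if (j < 0 || j > pb.len) stop("offset j = %d out of range [0, %d]", j, pb.len);
  return wfa::lcp(pa, pb, i, j);
}

// Vectorised variant for large randomized equivalence checks.
// [[Rcpp::export]]
IntegerVector cpp_lcp_many(List a, List b, IntegerVector i, IntegerVector j) {
  if (i.size() != j.size()) stop("offset vectors must have equal length");
  wfa::Packed pa = packed_from_list(a), pb = packed_from_list(b);
  IntegerVector out(i.size());
  for (R_xlen_t r = 0; r < i.size(); ++r) {
    if (i[r] < 0 || i[r] > pa.len || j[r] < 0 || j[r] > pb.len)
      stop("offset out of range at instance %d", (int)r + 1);
    out[r] = wfa::lcp(pa, pb, i[r], j[r]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Backtrace store surface (the engine uses the same inline core)
// ---------------------------------------------------------------------------

typedef Rcpp::XPtr<wfa::BTBuffer> BufPtr;

// [[Rcpp::export]]
SEXP cpp_bt_buffer_new(double capacity) {
  size_t cap = R_FINITE(capacity) ? (size_t)capacity : (size_t)-1;
  return BufPtr(new wfa::BTBuffer(cap), true);
}

// [[Rcpp::export]]
double cpp_bt_buffer_size(SEXP buf) {
  BufPtr p(buf);
  return (double)p->blocks.size();
}

static wfa::BTHandle handle_from_list(const List& h) {
  wfa::BTHandle out;
  out.bits = (uint32_t)(int32_t)as<int>(h["bits"]);
  out.prev = (int32_t)as<int>(h["prev"]);
  out.count = (uint8_t)as<int>(h["count"]);
  return out;
}

static List handle_to_list(const wfa::BTHandle& h) {
  return List::create(_["bits"] = (int)(int32_t)h.bits,
                      _["count"] = (int)h.count,
                      _["prev"] = (int)h.prev);
}

// [[Rcpp::export]]
List cpp_bt_handle_new() {
  return handle_to_list(wfa::BTHandle());
}

// Copy-on-extend push: returns the extended handle, never mutates the input.
// overflow = TRUE signals buffer capacity exhaustion.
// [[Rcpp::export]]
List cpp_bt_push(List handle, int op, SEXP buf) {
  if (op < 1 || op > 3) stop("op code must be 1 (X), 2 (I) or 3 (D)");
  BufPtr p(buf);
  wfa::BTHandle h = handle_from_list(handle);
  bool ok = wfa::bt_push(h, op, *p);
  List out = handle_to_list(h);
  out["overflow"] = !ok;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_bt_traceback(SEXP buf, List handle) {
  BufPtr p(buf);
  std::vector<int> ops;
  try {
    ops = wfa::bt_traceback(*p, handle_from_list(handle));
  } catch (const std::runtime_error& e) {
    stop("%s", e.what());
  }
  return IntegerVector(ops.begin(), ops.end());
}

// [[Rcpp::export]]
std::string cpp_build_cigar(IntegerVector ops, std::string q, std::string t,
                            bool lenient) {
  long err = -1;
  wfa::Packed pq = wfa::pack(q, lenient, &err);
  if (err >= 0) stop("query: unsupported character at position %d", (int)err + 1);
  wfa::Packed pt = wfa::pack(t, lenient, &err);
  if (err >= 0) stop("text: unsupported character at position %d", (int)err + 1);
  std::vector<int> v(ops.begin(), ops.end());
  try {
    return wfa::build_cigar(v, pq, pt);
  } catch (const std::runtime_error& e) {
    stop("%s", e.what());
  }
}

// [[Rcpp::export]]
int cpp_bt_block_ops() { return wfa::BT_BLOCK_OPS; }

// [[Rcpp::export]]
int cpp_mpd(IntegerVector k, IntegerVector h, int n, int m) {
  if (k.size() == 0) stop("no non-NULL diagonals");
  int target = m - n;
  long best_d = 0;
  int best_k = 0;
  bool first = true;
  for (R_xlen_t r = 0; r < k.size(); ++r) {
    long d = (long)(m - h[r]) + (long)(n - (h[r] - k[r]));
    if (first || wfa::diag_better(d, k[r], best_d, best_k, target)) {
      best_d = d;
      best_k = k[r];
      first = false;
    }
  }
  return best_k;
}
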
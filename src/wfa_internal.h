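#ifndef WAVEALIGN_WFA_INTERNAL_H
#define WAVEALIGN_WFA_INTERNAL_H

#include <cstdint>
#include <cstdlib>
#include <vector>
#include <string>
#include <algorithm>
#include <stdexcept>

namespace wfa {

// ---------------------------------------------------------------------------
// 2-bit packed DNA
//
// Codes are the two distinguishing bits (positions 1-2) of the ASCII bytes:
//   A -> 00, C -> 01, G -> 11, T -> 10
// 16 bases per 32-bit word; base i occupies bits [2*(i%16), 2*(i%16)+1] of
// word i/16. One zero guard word is kept past the end so that unaligned
// 16-base fetches never read out of bounds; pad bits may spuriously match,
// which is neutralised by clamping every LCP to the remaining lengths.
// ---------------------------------------------------------------------------

struct Packed {
  int len = 0;
  std::vector<uint32_t> words;   // ceil(len/16) + 1 guard word
  std::vector<int> except_pos;   // sorted 0-based positions that never match
};

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 3;
    case 'T': return 2;
    default:  return -1;
  }
}

inline char code_base(int code) {
  static const char tab[4] = {'A', 'C', 'T', 'G'};  // index = code
  return tab[code & 3];
}

// err: on failure (strict mode, unsupported char) set to 0-based offending
// position and an empty Packed is returned.
inline Packed pack(const std::string& seq, bool lenient, long* err_pos) {
  Packed p;
  *err_pos = -1;
  p.len = (int)seq.size();
  p.words.assign((size_t)(p.len + 15) / 16 + 1, 0u);
  for (int i = 0; i < p.len; ++i) {
    char c = seq[(size_t)i];
    if (c >= 'a' && c <= 'z') c = (char)(c - 'a' + 'A');
    int code = base_code(c);
    if (code < 0) {
      if (!lenient) {
        *err_pos = i;
        return Packed();
      }
      p.except_pos.push_back(i);  // always compares as mismatch
      code = 0;
    }
    p.words[(size_t)(i >> 4)] |= ((uint32_t)code) << ((i & 15) << 1);
  }
  return p;
}

inline std::string unpack(const Packed& p) {
  std::string s((size_t)p.len, 'A');
  for (int i = 0; i < p.len; ++i) {
    int code = (int)((p.words[(size_t)(i >> 4)] >> ((i & 15) << 1)) & 3u);
    s[(size_t)i] = code_base(code);
  }
  for (size_t e = 0; e < p.except_pos.size(); ++e)
    s[(size_t)p.except_pos[e]] = 'N';
  return s;
}

// 16 bases starting at base position pos (possibly unaligned).
inline uint32_t fetch16(const Packed& p, int pos) {
  int w = pos >> 4;
  int r = (pos & 15) << 1;
  uint32_t lo = p.words[(size_t)w] >> r;
  uint32_t hi = r ? (p.words[(size_t)w + 1] << (32 - r)) : 0u;
  return lo | hi;
}

// First exception position >= from, as a cap on comparable length.
inline int except_cap(const Packed& p, int from) {
  if (p.except_pos.empty()) return p.len;
  std::vector<int>::const_iterator it =
      std::lower_bound(p.except_pos.begin(), p.except_pos.end(), from);
  return (it == p.except_pos.end()) ? p.len : *it;
}

// Longest common prefix of a[i..] and b[j..], compared 16 bases per 32-bit
// XOR; the mismatch offset inside a word is the lowest set bit pair.
inline int lcp(const Packed& a, const Packed& b, int i, int j) {
  int maxl = std::min(a.len - i, b.len - j);
  if (maxl <= 0) return 0;
  if (!a.except_pos.empty()) maxl = std::min(maxl, except_cap(a, i) - i);
  if (!b.except_pos.empty()) maxl = std::min(maxl, except_cap(b, j) - j);
  if (maxl <= 0) return 0;
  int l = 0;
  while (l < maxl) {
    uint32_t x = fetch16(a, i + l) ^ fetch16(b, j + l);
    if (x) {
      l += __builtin_ctz(x) >> 1;
      break;
    }
    l += 16;
  }
  return std::min(l, maxl);
}

// ---------------------------------------------------------------------------
// Succinct piggybacked backtrace
//
// Edit operations (match runs are never stored) are appended as 2-bit codes
// into a 32-bit BT-block (16 ops per block). A full block is offloaded to the
// append-only BT-buffer and the live handle keeps the index of its newest
// offloaded block, chaining blocks backwards. Handles are small values copied
// on inheritance, so two diagonals may share a frozen offloaded prefix but
// never mutate it.
// ---------------------------------------------------------------------------

// Code 0 is the gap-close marker: the engine emits it when a gap run wins
// the match-wavefront merge, delimiting gap runs so that the match re-fill
// in build_cigar() can tell "gap continues" from "gap closed, matches, new
// gap" (the edit codes alone are ambiguous between the two).
enum BtOp { OP_CLOSE = 0, OP_X = 1, OP_I = 2, OP_D = 3 };

struct BTHandle {
  uint32_t bits = 0;
  int32_t prev = -1;   // index of newest offloaded block, -1 = chain start
  uint8_t count = 0;   // ops used in the active block, 0..16
};

struct BTBlock {
  uint32_t bits;
  int32_t prev;
};

const int BT_BLOCK_OPS = 16;  // 32 bits / 2 bits per op

struct BTBuffer {
  std::vector<BTBlock> blocks;
  size_t capacity;
  BTBuffer(size_t cap = (size_t)-1) : capacity(cap) {}
};

// Returns false when the buffer capacity is exhausted (typed overflow,
// consumed by the batch runner's rescue path).
inline bool bt_push(BTHandle& h, int op, BTBuffer& buf) {
  if (h.count == BT_BLOCK_OPS) {
    if (buf.blocks.size() >= buf.capacity) return false;
    BTBlock blk;
    blk.bits = h.bits;
    blk.prev = h.prev;
    buf.blocks.push_back(blk);
    h.prev = (int32_t)buf.blocks.size() - 1;
    h.bits = 0;
    h.count = 0;
  }
  h.bits |= ((uint32_t)op) << (2 * h.count);
  h.count++;
  return true;
}

// All edit ops in emission (alignment) order.
inline std::vector<int> bt_traceback(const BTBuffer& buf, const BTHandle& h) {
  std::vector<int32_t> chain;
  int32_t p = h.prev;
  while (p != -1) {
    if (p < 0 || p >= (int32_t)buf.blocks.size())
      throw std::runtime_error("backtrace chain refers to a block outside the buffer");
    chain.push_back(p);
    p = buf.blocks[(size_t)p].prev;
  }
  std::reverse(chain.begin(), chain.end());
  std::vector<int> ops;
  ops.reserve(chain.size() * BT_BLOCK_OPS + h.count);
  for (size_t c = 0; c < chain.size(); ++c) {
    uint32_t bits = buf.blocks[(size_t)chain[c]].bits;
    for (int t = 0; t < BT_BLOCK_OPS; ++t)
      ops.push_back((int)((bits >> (2 * t)) & 3u));
  }
  for (int t = 0; t < h.count; ++t)
    ops.push_back((int)((h.bits >> (2 * t)) & 3u));
  return ops;
}

// Re-fill match runs between edit ops with LCP() and emit a run-length CIGAR
// over {M, X, I, D}. Ops must consume the sequences exactly.
// Convention: h indexes the text, v = h - k the query; X consumes one of
// each, I consumes one text character, D one query character.
inline std::string build_cigar(const std::vector<int>& ops,
                               const Packed& q, const Packed& t) {
  int n = q.len, m = t.len;
  int v = 0, h = 0;
  std::string out;
  char run_op = 0;
  long run_len = 0;
  char buf[32];
  // emit helper (run-length merge)
  struct Emit {
    std::string* out;
    char* run_op;
    long* run_len;
    char* buf;
    void operator()(char op, long len) {
      if (len <= 0) return;
      if (op == *run_op) {
        *run_len += len;
      } else {
        flush();
        *run_op = op;
        *run_len = len;
      }
    }
    void flush() {
      if (*run_len > 0) {
        int w = snprintf(buf, 32, "%ld%c", *run_len, *run_op);
        out->append(buf, (size_t)w);
      }
      *run_len = 0;
      *run_op = 0;
    }
  } emit = {&out, &run_op, &run_len, buf};

  // Match runs are re-filled with LCP() only outside gap runs; consecutive
  // identical gap codes continue one run until a close marker (or a
  // different code) ends it.
  int state = OP_CLOSE;  // OP_CLOSE = "in match context"
  for (size_t idx = 0; idx < ops.size(); ++idx) {
    switch (ops[idx]) {
      case OP_CLOSE: {
        int l = lcp(q, t, v, h);
        emit('M', l); v += l; h += l;
        state = OP_CLOSE;
        break;
      }
      case OP_X: {
        int l = lcp(q, t, v, h);
        emit('M', l); v += l; h += l;
        if (v >= n || h >= m)
          throw std::runtime_error("backtrace ops inconsistent with sequences (mismatch past end)");
        emit('X', 1); v++; h++;
        state = OP_CLOSE;
        break;
      }
      case OP_I: {
        if (state != OP_I) {
          int l = lcp(q, t, v, h);
          emit('M', l); v += l; h += l;
        }
        if (h >= m)
          throw std::runtime_error("backtrace ops inconsistent with sequences (insertion past text end)");
        emit('I', 1); h++;
        state = OP_I;
        break;
      }
      case OP_D: {
        if (state != OP_D) {
          int l = lcp(q, t, v, h);
          emit('M', l); v += l; h += l;
        }
        if (v >= n)
          throw std::runtime_error("backtrace ops inconsistent with sequences (deletion past query end)");
        emit('D', 1); v++;
        state = OP_D;
        break;
      }
      default:
        throw std::runtime_error("invalid backtrace operation code");
    }
  }
  {
    int l = lcp(q, t, v, h);
    emit('M', l); v += l; h += l;
  }
  if (v != n || h != m)
    throw std::runtime_error("backtrace ops do not consume the sequences exactly");
  emit.flush();
  return out;
}

// Most-promising-diagonal comparator: smaller remaining distance to the
// bottom-right cell wins; ties resolved toward the target diagonal m-n, then
// smaller |k|, then smaller k (fully deterministic).
inline bool diag_better(long d, int k, long best_d, int best_k, int target) {
  if (d != best_d) return d < best_d;
  long a = std::labs((long)k - target), b = std::labs((long)best_k - target);
  if (a != b) return a < b;
  if (std::abs(k) != std::abs(best_k)) return std::abs(k) < std::abs(best_k);
  return k < best_k;
}

}  // namespace wfa

#endif
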
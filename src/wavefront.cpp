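#include <Rcpp.h>
#include <climits>
#include "wfa_internal.h"

using namespace Rcpp;

// Gap-affine wavefront aligner. Offsets h count consumed text characters,
// v = h - k consumed query characters; the target cell is h = m on diagonal
// k = m - n. NULL offsets are an absorbing minimal integer so that invalid
// operands lose every max in the recurrences.

namespace {

const int32_t WF_NULL = INT32_MIN / 2;

struct WFront {
  int s = -1;                 // score held by this ring slot (-1 = unused)
  int lo = 0, hi = -1;        // inclusive diagonal range; empty when hi < lo
  std::vector<int32_t> M, I, D;
  std::vector<wfa::BTHandle> Mh, Ih, Dh;

  bool empty() const { return hi < lo; }

  void reset(int score, int lo_, int hi_, bool bt) {
    s = score;
    lo = lo_;
    hi = hi_;
    size_t w = (hi >= lo) ? (size_t)(hi - lo + 1) : 0;
    M.assign(w, WF_NULL);
    I.assign(w, WF_NULL);
    D.assign(w, WF_NULL);
    if (bt) {
      Mh.assign(w, wfa::BTHandle());
      Ih.assign(w, wfa::BTHandle());
      Dh.assign(w, wfa::BTHandle());
    } else {
      Mh.clear(); Ih.clear(); Dh.clear();
    }
  }
  void mark_empty() { hi = lo - 1; }
};

inline int32_t getM(const WFront* w, int k) {
  return (w && k >= w->lo && k <= w->hi) ? w->M[(size_t)(k - w->lo)] : WF_NULL;
}
inline int32_t getI(const WFront* w, int k) {
  return (w && k >= w->lo && k <= w->hi) ? w->I[(size_t)(k - w->lo)] : WF_NULL;
}
inline int32_t getD(const WFront* w, int k) {
  return (w && k >= w->lo && k <= w->hi) ? w->D[(size_t)(k - w->lo)] : WF_NULL;
}

struct Ring {
  std::vector<WFront> slots;
  explicit Ring(int size) : slots((size_t)size) {}
  WFront& at(int s) { return slots[(size_t)(s % (int)slots.size())]; }
  const WFront* get(int s) const {
    if (s < 0) return 0;
    const WFront& w = slots[(size_t)(s % (int)slots.size())];
    return (w.s == s && !w.empty()) ? &w : 0;
  }
};

struct Stats {
  long long wavefronts = 0;        // wavefronts computed (incl. empty)
  long long offsets_allocated = 0; // 3 * width summed over wavefronts
  long long max_width = 0;
  long long bt_blocks = 0;         // blocks offloaded to the BT-buffer
  long long bt_ops = 0;            // edit ops piggybacked
  long long max_score = -1;        // highest score whose wavefront was computed
};

List finish(std::string status, int score, SEXP cigar, const Stats& st) {
  return List::create(
      _["status"] = status,
      _["score"] = (score < 0) ? NA_INTEGER : score,
      _["cigar"] = cigar,
      _["stats"] = List::create(
          _["wavefronts"] = (double)st.wavefronts,
          _["offsets_allocated"] = (double)st.offsets_allocated,
          _["max_width"] = (double)st.max_width,
          _["bt_blocks"] = (double)st.bt_blocks,
          _["bt_ops"] = (double)st.bt_ops,
          _["max_score_reached"] = (double)st.max_score));
}

}  // namespace

// [[Rcpp::export]]
List cpp_wf_align(std::string q, std::string t, int x, int o, int e,
                  bool want_cigar, double max_score, bool banded, int beta,
                  int lam, bool center_target, bool lenient,
                  double bt_capacity) {
  if (x <= 0 || e <= 0 || o < 0)
    stop("penalties must satisfy x > 0, o >= 0, e > 0");
  long err = -1;
  wfa::Packed pq = wfa::pack(q, lenient, &err);
  if (err >= 0)
    stop("query: unsupported character '%s' at position %d",
         std::string(1, q[(size_t)err]).c_str(), (int)err + 1);
  wfa::Packed pt = wfa::pack(t, lenient, &err);
  if (err >= 0)
    stop("text: unsupported character '%s' at position %d",
         std::string(1, t[(size_t)err]).c_str(), (int)err + 1);

  const int n = pq.len, m = pt.len;
  Stats st;

  // Degenerate lengths short-circuit to the closed-form gap cost.
  if (n == 0 || m == 0) {
    int score = 0;
    std::string cig;
    if (m > 0) { score = o + m * e; cig = std::to_string(m) + "I"; }
    else if (n > 0) { score = o + n * e; cig = std::to_string(n) + "D"; }
    if (max_score >= 0 && R_FINITE(max_score) && score > (double)max_score)
      return finish("budget_exceeded", -1, R_NilValue, st);
    st.max_score = score;
    return finish(banded ? "approximate" : "exact", score,
                  want_cigar ? (SEXP)wrap(cig) : R_NilValue, st);
  }

  long long budget = (max_score >= 0 && R_FINITE(max_score))
                         ? (long long)max_score : LLONG_MAX;
  const int L = std::max(x, o + e);  // deepest lookback of Eq. recurrences
  Ring ring(L + 1);
  wfa::BTBuffer buf(R_FINITE(bt_capacity) ? (size_t)bt_capacity : (size_t)-1);

  const int target_k = m - n;
  int half = banded ? (beta - 1) / 2 : 0;
  int center = banded ? (center_target ? target_k : 0) : 0;
  int last_m_score = 0;  // newest score whose extended M has a non-NULL entry
  int consecutive_empty = 0;

  // Bootstrap: X(0,0) = 0, stored in M pending extension.
  {
    WFront& w0 = ring.at(0);
    w0.reset(0, 0, 0, want_cigar);
    w0.M[0] = 0 + wfa::lcp(pq, pt, 0, 0);
    st.wavefronts = 1;
    st.offsets_allocated = 3;
    st.max_width = 1;
    st.max_score = 0;
    if (target_k == 0 && w0.M[0] == m)
      return finish(banded ? "approximate" : "exact", 0,
                    want_cigar ? (SEXP)wrap(wfa::build_cigar(
                        std::vector<int>(), pq, pt)) : R_NilValue, st);
  }

  for (int s = 1;; ++s) {
    if ((long long)s > budget)
      return finish("budget_exceeded", -1, R_NilValue, st);

    if (banded && lam > 0 && s % lam == 0) {
      // Recenter the band on the most promising diagonal of the newest
      // wavefront that still has match-component progress.
      const WFront* w = ring.get(last_m_score);
      if (w) {
        long best_d = 0; int best_k = 0; bool first = true;
        for (int k = w->lo; k <= w->hi; ++k) {
          int32_t h = w->M[(size_t)(k - w->lo)];
          if (h == WF_NULL) continue;
          long d = (long)(m - h) + (long)(n - (h - k));
          if (first || wfa::diag_better(d, k, best_d, best_k, target_k)) {
            best_d = d; best_k = k; first = false;
          }
        }
        if (!first) center = best_k;
      }
    }

    const WFront* wx = ring.get(s - x);
    const WFront* we = ring.get(s - e);
    const WFront* woe = ring.get(s - o - e);

    int lo = INT_MAX, hi = INT_MIN;
    if (wx) { lo = std::min(lo, wx->lo); hi = std::max(hi, wx->hi); }
    if (we) { lo = std::min(lo, we->lo); hi = std::max(hi, we->hi); }
    if (woe) { lo = std::min(lo, woe->lo); hi = std::max(hi, woe->hi); }

    WFront& w = ring.at(s);
    if (lo == INT_MAX) {
      w.reset(s, 0, -1, false);
      st.wavefronts++;
      st.max_score = s;
      if (++consecutive_empty > L)
        return banded ? finish("band_collapse", -1, R_NilValue, st)
                      : (stop("exact wavefront progression stalled"), List());
      continue;
    }
    lo = std::max(lo - 1, -n);
    hi = std::min(hi + 1, m);
    if (banded) {
      lo = std::max(lo, center - half);
      hi = std::min(hi, center + half);
    }
    st.wavefronts++;
    st.max_score = s;
    if (hi < lo) {
      w.reset(s, 0, -1, false);
      if (++consecutive_empty > L)
        return banded ? finish("band_collapse", -1, R_NilValue, st)
                      : (stop("exact wavefront progression stalled"), List());
      continue;
    }

    w.reset(s, lo, hi, want_cigar);
    st.offsets_allocated += 3LL * (hi - lo + 1);
    st.max_width = std::max(st.max_width, (long long)(hi - lo + 1));

    bool any = false;
    bool overflow = false;
    for (int k = lo; k <= hi; ++k) {
      size_t idx = (size_t)(k - lo);

      // Insertion component (consumes text; diagonal k-1 -> k).
      int32_t iopen = getM(woe, k - 1);
      int32_t iext = getI(we, k - 1);
      int32_t iv = WF_NULL;
      int isrc = 0;  // 1 = open (from M), 2 = extend (from I); ties extend,
                     // keeping gap runs contiguous
      if (iext != WF_NULL) { iv = iext + 1; isrc = 2; }
      if (iopen != WF_NULL && iopen + 1 > iv) { iv = iopen + 1; isrc = 1; }
      if (iv != WF_NULL) {
        int32_t vv = iv - k;
        if (iv < 0 || iv > m || vv < 0 || vv > n) { iv = WF_NULL; isrc = 0; }
      }
      if (iv != WF_NULL) {
        w.I[idx] = iv;
        if (want_cigar) {
          wfa::BTHandle hdl = (isrc == 1) ? woe->Mh[(size_t)(k - 1 - woe->lo)]
                                          : we->Ih[(size_t)(k - 1 - we->lo)];
          if (!wfa::bt_push(hdl, wfa::OP_I, buf)) { overflow = true; break; }
          st.bt_ops++;
          w.Ih[idx] = hdl;
        }
      }

      // Deletion component (consumes query; diagonal k+1 -> k).
      int32_t dopen = getM(woe, k + 1);
      int32_t dext = getD(we, k + 1);
      int32_t dv = WF_NULL;
      int dsrc = 0;
      if (dext != WF_NULL) { dv = dext; dsrc = 2; }
      if (dopen != WF_NULL && dopen > dv) { dv = dopen; dsrc = 1; }
      if (dv != WF_NULL) {
        int32_t vv = dv - k;
        if (dv < 0 || dv > m || vv < 0 || vv > n) { dv = WF_NULL; dsrc = 0; }
      }
      if (dv != WF_NULL) {
        w.D[idx] = dv;
        if (want_cigar) {
          wfa::BTHandle hdl = (dsrc == 1) ? woe->Mh[(size_t)(k + 1 - woe->lo)]
                                          : we->Dh[(size_t)(k + 1 - we->lo)];
          if (!wfa::bt_push(hdl, wfa::OP_D, buf)) { overflow = true; break; }
          st.bt_ops++;
          w.Dh[idx] = hdl;
        }
      }

      // Mismatch candidate and the transient X max (tie preference X > I > D).
      int32_t xm = getM(wx, k);
      int32_t xv = WF_NULL;
      if (xm != WF_NULL) {
        xv = xm + 1;
        int32_t vv = xv - k;
        if (xv < 0 || xv > m || vv < 0 || vv > n) xv = WF_NULL;
      }
      int32_t mv = WF_NULL;
      int msrc = 0;  // 1 = X, 2 = I, 3 = D
      if (xv != WF_NULL) { mv = xv; msrc = 1; }
      if (w.I[idx] != WF_NULL && w.I[idx] > mv) { mv = w.I[idx]; msrc = 2; }
      if (w.D[idx] != WF_NULL && w.D[idx] > mv) { mv = w.D[idx]; msrc = 3; }
      if (mv != WF_NULL) {
        if (want_cigar) {
          if (msrc == 1) {
            wfa::BTHandle hdl = wx->Mh[(size_t)(k - wx->lo)];
            if (!wfa::bt_push(hdl, wfa::OP_X, buf)) { overflow = true; break; }
            st.bt_ops++;
            w.Mh[idx] = hdl;
          } else {
            // A gap run enters the match wavefront: delimit it with the
            // close marker so the CIGAR re-fill knows the run ended here.
            wfa::BTHandle hdl = (msrc == 2) ? w.Ih[idx] : w.Dh[idx];
            if (!wfa::bt_push(hdl, wfa::OP_CLOSE, buf)) { overflow = true; break; }
            st.bt_ops++;
            w.Mh[idx] = hdl;
          }
        }
        // Extend along the diagonal with free matches.
        w.M[idx] = mv + wfa::lcp(pq, pt, mv - k, mv);
        any = true;
      }
      if (w.I[idx] != WF_NULL || w.D[idx] != WF_NULL) any = true;
    }
    st.bt_blocks = (long long)buf.blocks.size();
    if (overflow) return finish("bt_overflow", -1, R_NilValue, st);

    if (!any) {
      w.mark_empty();
      if (++consecutive_empty > L)
        return banded ? finish("band_collapse", -1, R_NilValue, st)
                      : (stop("exact wavefront progression stalled"), List());
      continue;
    }
    consecutive_empty = 0;

    bool m_alive = false;
    for (int k = w.lo; k <= w.hi && !m_alive; ++k)
      if (w.M[(size_t)(k - w.lo)] != WF_NULL) m_alive = true;
    if (m_alive) last_m_score = s;

    if (target_k >= w.lo && target_k <= w.hi &&
        w.M[(size_t)(target_k - w.lo)] == m) {
      SEXP cig = R_NilValue;
      if (want_cigar) {
        std::vector<int> ops =
            wfa::bt_traceback(buf, w.Mh[(size_t)(target_k - w.lo)]);
        try {
          cig = wrap(wfa::build_cigar(ops, pq, pt));
        } catch (const std::runtime_error& ex) {
          stop("%s", ex.what());
        }
      }
      return finish(banded ? "approximate" : "exact", s, cig, st);
    }
  }
}
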
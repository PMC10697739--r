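#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Classical three-matrix gap-affine dynamic programming (Gotoh), used as the
// independent reference aligner. Deliberately shares no code with the
// wavefront engine: plain character comparison, full (n+1) x (m+1) matrices,
// standard traceback. Minimisation with match = 0, mismatch = x, gap of
// length l = o + l*e.
//
// Conventions mirror the engine's CIGAR dialect: i indexes the query, j the
// text; I consumes one text character, D one query character.

// [[Rcpp::export]]
List cpp_gotoh(std::string q, std::string t, int x, int o, int e,
               bool want_cigar) {
  if (x <= 0 || e <= 0 || o < 0)
    stop("penalties must satisfy x > 0, o >= 0, e > 0");
  const long n = (long)q.size(), m = (long)t.size();
  if ((double)(n + 1) * (double)(m + 1) > 1e8)
    stop("sequences too long for the quadratic reference aligner");
  for (long i = 0; i < n; ++i)
    if (q[(size_t)i] >= 'a' && q[(size_t)i] <= 'z') q[(size_t)i] -= 32;
  for (long j = 0; j < m; ++j)
    if (t[(size_t)j] >= 'a' && t[(size_t)j] <= 'z') t[(size_t)j] -= 32;

  const int INF = INT_MAX / 4;
  const size_t W = (size_t)(m + 1);
  std::vector<int> H((size_t)(n + 1) * W), E(H.size()), F(H.size());

  H[0] = 0; E[0] = INF; F[0] = INF;
  for (long j = 1; j <= m; ++j) {
    E[(size_t)j] = o + (int)j * e;   // leading gap consuming text
    H[(size_t)j] = E[(size_t)j];
    F[(size_t)j] = INF;
  }
  for (long i = 1; i <= n; ++i) {
    size_t r = (size_t)i * W;
    F[r] = o + (int)i * e;           // leading gap consuming query
    H[r] = F[r];
    E[r] = INF;
    for (long j = 1; j <= m; ++j) {
      size_t c = r + (size_t)j;
      E[c] = std::min(H[c - 1] + o + e, E[c - 1] + e);
      F[c] = std::min(H[c - W] + o + e, F[c - W] + e);
      int sub = (q[(size_t)(i - 1)] == t[(size_t)(j - 1)]) ? 0 : x;
      H[c] = std::min(H[c - W - 1] + sub, std::min(E[c], F[c]));
    }
  }
  int score = H[(size_t)n * W + (size_t)m];

  if (!want_cigar)
    return List::create(_["score"] = score, _["cigar"] = R_NilValue);

  // Traceback; prefers the diagonal, then text gaps, then query gaps, and
  // closes gaps as early as possible -- one deterministic co-optimal path.
  std::string rev;
  long i = n, j = m;
  char state = 'H';
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + (size_t)j;
    if (state == 'H') {
      if (i > 0 && j > 0) {
        int sub = (q[(size_t)(i - 1)] == t[(size_t)(j - 1)]) ? 0 : x;
        if (H[c] == H[c - W - 1] + sub) {
          rev.push_back(sub ? 'X' : 'M');
          --i; --j;
          continue;
        }
      }
      state = (j > 0 && H[c] == E[c]) ? 'E' : 'F';
      continue;
    }
    if (state == 'E') {
      rev.push_back('I');
      state = (E[c] == H[c - 1] + o + e) ? 'H' : 'E';
      --j;
    } else {  // 'F'
      rev.push_back('D');
      state = (F[c] == H[c - W] + o + e) ? 'H' : 'F';
      --i;
    }
  }

  // Run-length encode the reversed operation string.
  std::string cig;
  char buf[32];
  for (size_t p = rev.size(); p > 0;) {
    char op = rev[p - 1];
    long len = 0;
    while (p > 0 && rev[p - 1] == op) { --p; ++len; }
    int w = snprintf(buf, 32, "%ld%c", len, op);
    cig.append(buf, (size_t)w);
  }
  return List::create(_["score"] = score, _["cigar"] = cig);
}
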
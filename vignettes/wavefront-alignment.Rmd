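---
title: "Wavefront alignment in wavealign: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavefront alignment in wavealign: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavealign)
```

## The alignment model

`wavealign` computes *global* pairwise alignment of DNA sequences under a
gap-affine score: matches are free, a mismatch costs `x`, and a gap of length
`l` costs `g(l) = o + l * e`. All penalties are positive integers (the
gap-open `o` may be zero), and alignment is a minimisation: the optimal score
of identical sequences is 0.

The classical way to solve this model is full dynamic programming over an
`(n+1) x (m+1)` matrix (Gotoh's three-matrix algorithm), which costs `O(nm)`
time and memory regardless of how similar the sequences are. The wavefront
algorithm exploits similarity instead. Writing `h` for the number of text
characters consumed and `v = h - k` for query characters on diagonal `k`, it
tracks, for each score `s`, the *furthest-reaching point* on every diagonal,
split into three components: `M` (partial alignments ending in a match run),
`I` (ending in a text-consuming gap), and `D` (ending in a query-consuming
gap). A wavefront at score `s` is assembled from the wavefronts at scores
`s - x`, `s - e`, and `s - o - e`:

* `I[s,k] = max(M[s-o-e, k-1] + 1, I[s-e, k-1] + 1)` — gap open or extend;
* `D[s,k] = max(M[s-o-e, k+1],     D[s-e, k+1])`;
* the transient mismatch candidate `X[s,k] = M[s-x, k] + 1` competes with
  `I[s,k]` and `D[s,k]` for the new `M[s,k]`, which is then *extended* for
  free along its diagonal by the length of the longest common prefix (LCP)
  of the two remaining suffixes.

Starting from the single point `(0, 0)` at score 0, scores increase one unit
at a time until the `M` component reaches the bottom-right cell: offset
`h = m` on the target diagonal `k = m - n`. Time is proportional to the
total wavefront area, `O(ns + s^2)` in the worst case, and the full-history
memory bound is `3 (s+1)^2` offsets (`estimate_memory()`); for similar
sequences `s` is small and the method is far cheaper than full DP.

Because each diagonal of a wavefront depends only on *previous* wavefronts,
all diagonals of one score are computed independently in a tight loop — the
same per-diagonal independence that makes the method a good fit for SIMD and
many-core hardware. This implementation keeps that contract (the kernel is a
data-parallel loop over diagonals) but runs it sequentially in compiled code.

## Match extension over packed sequences

LCP computation dominates running time, so sequences are packed to 2 bits
per base before alignment. The codes are the two distinguishing bits of the
ASCII bytes — `A = 00`, `C = 01`, `G = 11`, `T = 10` — with 16 bases per
32-bit word. An LCP call XORs 16-base blocks and locates the first mismatch
from the lowest set bit pair, so extension costs one machine word comparison
per 16 matching bases. Tail padding past the end of a sequence is neutral
because every result is clamped to the remaining lengths.

Input handling is strict by default: any character outside `A/C/G/T`
(after upper-casing) is an error naming the offending position. In lenient
mode such positions are recorded in a per-sequence exception list and
*always* compare as mismatches — including against another ambiguous base —
which is the conservative reading when the true base is unknown. The
reference behaviour of every bit-level operation is the plain per-character
comparison, and the test suite holds the packed path to it exactly.

## Succinct piggybacked backtrace

Recovering a CIGAR normally requires keeping all wavefronts back to score 0
(the `12 (s+1)^2`-byte bound above). Instead, each wavefront entry carries a
small *backtrace handle*: a 32-bit bitmap holding up to 16 two-bit edit
codes plus the index of its predecessor block. When a transition wins a
maximum, the corresponding code is appended to a copy of the winner's handle
(`X` for the mismatch branch, `I`/`D` for gap branches); full blocks are
offloaded to an append-only global buffer and chained by index. Matches are
never stored — they are recomputed with the same LCP function when the CIGAR
is rebuilt. Amortised storage is 4 bits per wavefront entry (64 bits per
16-entry block), an 8-fold reduction over 4-byte raw offsets, and only a
ring of the most recent `max(x, o + e) + 1` wavefronts is retained.

One refinement proved necessary. A chain of plain edit codes is ambiguous:
`[I, I]` cannot distinguish *one gap of length 2* from *gap, matches, gap*,
and a greedy LCP re-fill can slide gaps sideways, splitting runs (which
changes the affine cost) or over-consuming a sequence. The fourth 2-bit
code, otherwise unused, therefore serves as a **gap-close marker**: it is
appended whenever a gap component wins the `M` merge. CIGAR reconstruction
is then a small state machine that inserts match runs only outside gap runs.
With this marker, re-scoring every reconstructed CIGAR reproduces the
engine's score exactly across the full randomized suite.

Tie-breaks are fixed for determinism: in the `M` merge the preference order
is mismatch > insertion > deletion; within a gap component, extension is
preferred over opening (keeping gap runs contiguous). Offsets that would
leave the matrix (`h > m` or `v > n`) are set to NULL — a reserved minimal
integer that loses every maximum — and empty sequences short-circuit to the
closed-form gap cost without entering the wavefront loop.

## The adaptive banded heuristic

For applications that tolerate approximation, `band_config(beta, lam)`
clamps every wavefront to a window of at most `beta` diagonals. The window
starts centered on the main diagonal (option: on the target diagonal
`m - n`, useful for very different lengths) and every `lam` score steps is
re-centered on the *most promising diagonal* — the one minimising the
remaining distance to the bottom-right corner,
`d(k) = (m - h) + (n - (h - k))`, with ties resolved toward the target
diagonal and then toward smaller `|k|`. Diagonals that leave the window are
dropped and never revived, so banding only removes paths: the reported score
is always an upper bound on the exact score, and if the whole window goes
NULL the aligner returns a typed `band_collapse` outcome instead of a score.

Defaults are `beta = 1025` and `lam = 100`. The original GPU formulation
derives `beta` from on-chip memory capacity, which has no host-side
equivalent; a width in the low thousands keeps banded scores exact on the
long noisy simulated pairs used in validation, and re-center periods up to
100 behave equivalently in accuracy (asserted in the test suite at
`lam` in {10, 50, 100}). Two regimes are worth distinguishing:

* with a *static* window (re-centering never triggered), `beta >= 2s* + 1`
  guarantees the window never truncates any wavefront, so banded equals
  exact — the suite asserts this;
* with re-centering, the window tracks the most promising partial alignment
  and can in principle drift away from the optimal path even when `beta` is
  large, so equality is expected rather than guaranteed; in practice the
  validation runs report 100% score equality at `beta = 2049, lam = 100` on
  10 kb pairs at 5% error.

## Batch alignment, budgeting, and rescue

`align_batch()` mirrors how aligner pools budget memory up front. Each pair
gets a score budget from an assumed maximum error rate (default 10% of the
longer sequence):

```
budget = ceil(rate * max(n, m)) * max(x, o + e) + [n != m] * (o + |n - m| * e)
```

i.e. the worst-case cost of that many single-character edits plus one gap
covering any length difference — deliberately conservative, so a pair whose
true score is within the budget is never cut off. Pairs that exceed their
budget (or collapse their band, or overflow a bounded backtrace buffer) are
re-run by the unbounded exact aligner and marked `rescued`; in exact mode
every final score is therefore optimal regardless of budgeting. Alignment
is deterministic and free of randomness, so results are identical for any
worker count; workers simply fork over pairs. Per-pair input errors are
reported in the result table rather than aborting the batch.

## The simulator and what it does (not) emulate

`simulate_pairs()` reproduces the standard benchmark protocol for wavefront
aligners: uniform random texts of a chosen length, and queries derived by
injecting `round(error_rate * length)` edits at uniform positions with a
configurable mismatch/insertion/deletion mix (default 1/3 each). Mismatch
and deletion positions are sampled without replacement and substitutions
always change the base, so the nominal count is realised; an optional
Poisson mode draws per-pair counts around the same mean for "average error"
semantics. Validation uses the three scales of that protocol — 150, 1000,
and 10 000 bases at 2-10% error.

What the generator does *not* emulate: real base composition and repeats
(uniform i.i.d. bases make LCPs short and spurious matches rare), clustered
or bursty errors, sequencing-quality profiles, and true read/reference pairs
obtained by mapping. Passing the simulated suites therefore demonstrates
algorithmic correctness (scores equal full-DP optima; CIGARs re-score
exactly) and the expected behaviour of the heuristics at realistic error
rates, but not recall on any particular instrument's data. Note also that
an inserted base adjacent to a deletion can occasionally cancel part of its
effect, so the *realised* edit distance of a pair can be slightly below the
injected count recorded in its id; bounds in the tests use the injected
count as an upper bound, which remains valid.

## Validation scales and numerical choices

The test suite validates, among others: exact scores and re-scored CIGARs
against an independently implemented full-DP (Gotoh) aligner on 500
randomized pairs of 10-200 bases at 0-20% error over the penalty grid
{(4,6,2), (1,0,1), (2,3,1), (5,2,4)} — the Gotoh aligner itself is checked
against exhaustive path enumeration on sequences of up to 6 bases; the
bit-parallel LCP against per-character comparison on 10 000 random suffix
pairs; banded conservativeness and the untruncated-band equality on the same
distribution; band-score equality on 10 pairs of 10 000 bases at 5% error
(`beta = 2049`, `lam = 100`); and full rescue of a 200-pair batch of
1000-base pairs in which 5% of pairs carry 30% error against a 10% budget.
These sizes keep the whole suite under half a minute on one core while
exercising every score regime the package targets; `scripts/acceptance.R`
re-runs the long-pair band experiment from scratch for any seed.

Remaining fixed choices: NULL offsets are `INT32_MIN / 2` (absorbing under
`+1` without overflow); 32-bit offsets limit sequences to well beyond any
read length in practice; the quadratic reference aligner refuses problems
over `1e8` cells; the CIGAR dialect keeps `M` (match) distinct from `X`
(mismatch), with `cigar_samlike()` collapsing them when a SAM-style string
is wanted. `I` consumes one *text* character and `D` one *query* character,
matching the `(h, v)` coordinate convention above.

## Known limitations

* Global alignment only — no local, semi-global, or ends-free modes.
* Single-piece affine penalties only (no two-piece or convex gap models).
* The exact engine's memory for the backtrace buffer grows with the
  wavefront area; distance mode avoids it entirely, and `O(s)`-memory
  bidirectional variants are out of scope.
* The banded heuristic offers no approximation-error guarantee; its typed
  `band_collapse` outcome (and the batch rescue path) is the safety net.
```{r example}
pr <- simulate_pairs(1, 1000, 0.05, seed = 11)
a <- wfa_align(pr$query, pr$text)
a
storage_audit(a)$run$bytes_succinct
```
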
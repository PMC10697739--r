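#' Adaptive band configuration for the heuristic aligner
#'
#' The heuristic keeps a fixed-size wavefront of `beta` diagonals. The window
#' starts centered on the main diagonal (or on the target diagonal `m - n`
#' with `center = "target"`, useful for very different lengths) and every
#' `lam` score steps is re-centered on the most promising diagonal -- the one
#' closest to the bottom-right cell of the DP matrix. Diagonals that leave
#' the window are dropped and never revived, so the reported score is an
#' upper bound on the exact score.
#'
#' Defaults `beta = 1025`, `lam = 100`: band widths in the low thousands
#' retain exact results on long noisy sequences, and re-center periods up to
#' 100 perform equivalently in accuracy.
#'
#' @param beta Band width in diagonals; odd integer `>= 1`.
#' @param lam Re-center period in score steps; integer `>= 1`.
#' @param center Initial window center: `"main"` (diagonal 0) or `"target"`
#'   (diagonal `m - n`).
#'
#' @return An object of class `"wfa_band_config"`.
#' @examples
#' wfa_align("GATTACA", "GACTACA", band = band_config(beta = 5, lam = 2))
#' @export
band_config <- function(beta = 1025L, lam = 100L, center = c("main", "target")) {
  beta <- as.integer(beta); lam <- as.integer(lam)
  center <- match.arg(center)
  if (length(beta) != 1L || is.na(beta) || beta < 1L || beta %% 2L == 0L)
    stop("`beta` must be a single odd integer >= 1")
  if (length(lam) != 1L || is.na(lam) || lam < 1L)
    stop("`lam` must be a single integer >= 1")
  structure(list(beta = beta, lam = lam, center = center),
            class = "wfa_band_config")
}

#' @export
print.wfa_band_config <- function(x, ...) {
  cat(sprintf("adaptive band: beta = %d diagonals, recenter every %d steps (start: %s diagonal)\n",
              x$beta, x$lam, x$center))
  invisible(x)
}

#' Most promising diagonal of a wavefront
#'
#' Given the non-NULL match-component offsets of a wavefront, returns the
#' diagonal whose furthest-reaching point is closest to the bottom-right cell
#' of the DP matrix, i.e. the `k` minimising the remaining distance
#' `d(k) = (m - h) + (n - (h - k))`. Ties are resolved toward the target
#' diagonal `m - n`, then toward smaller `|k|`. This is the re-centering rule
#' used by the banded aligner.
#'
#' @param offsets Integer vector of furthest-reaching text offsets `h`,
#'   named by diagonal `k` (or accompanied by `k`); `NA` entries (NULL
#'   diagonals) are ignored.
#' @param n,m Query and text lengths.
#' @param k Optional integer vector of diagonals, if `offsets` is unnamed.
#'
#' @return The most promising diagonal `k*` (integer).
#' @examples
#' most_promising_diagonal(c(`-1` = 3, `0` = 5, `1` = 4), n = 10, m = 10)
#' @export
most_promising_diagonal <- function(offsets, n, m, k = NULL) {
  if (is.null(k)) {
    if (is.null(names(offsets)))
      stop("`offsets` must be named by diagonal, or `k` supplied")
    k <- as.integer(names(offsets))
  }
  keep <- !is.na(offsets)
  if (!any(keep))
    stop(band_collapse_condition("wavefront has no non-NULL offsets"))
  cpp_mpd(as.integer(k[keep]), as.integer(offsets[keep]),
          as.integer(n), as.integer(m))
}

band_collapse_condition <- function(msg) {
  structure(class = c("wfa_band_collapse", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
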
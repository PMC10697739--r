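#' Gap-affine penalty set
#'
#' Scoring parameters for minimisation-based gap-affine alignment: matches
#' cost 0, a mismatch costs `x`, and a gap of length `l` costs
#' `g(l) = o + l * e` (every gap pays the opening penalty `o` once plus `e`
#' per gapped character). All penalties are integers.
#'
#' The defaults `x = 4, o = 6, e = 2` are the affine set commonly used by
#' wavefront-based aligners.
#'
#' @param x Mismatch cost, integer `> 0`.
#' @param o Gap-open cost, integer `>= 0`.
#' @param e Gap-extension cost, integer `> 0`.
#'
#' @return An object of class `"wfa_penalties"`: a list with elements
#'   `x`, `o`, `e`.
#' @examples
#' p <- wfa_penalties()
#' gap_cost(p, 3)  # 6 + 3 * 2 = 12
#' @export
wfa_penalties <- function(x = 4L, o = 6L, e = 2L) {
  x <- as.integer(x); o <- as.integer(o); e <- as.integer(e)
  if (length(x) != 1L || is.na(x) || x <= 0L)
    stop("mismatch cost `x` must be a single integer > 0")
  if (length(o) != 1L || is.na(o) || o < 0L)
    stop("gap-open cost `o` must be a single integer >= 0")
  if (length(e) != 1L || is.na(e) || e <= 0L)
    stop("gap-extension cost `e` must be a single integer > 0")
  structure(list(x = x, o = o, e = e), class = "wfa_penalties")
}

#' Cost of a gap of given length
#'
#' @param penalties A [wfa_penalties()] object.
#' @param l Gap length(s), integer `>= 1`.
#' @return `o + l * e`, vectorised over `l`.
#' @export
gap_cost <- function(penalties, l) {
  stopifnot(inherits(penalties, "wfa_penalties"), all(l >= 1))
  penalties$o + as.integer(l) * penalties$e
}

#' @export
print.wfa_penalties <- function(x, ...) {
  cat(sprintf("gap-affine penalties: mismatch x = %d, gap g(l) = %d + l * %d\n",
              x$x, x$o, x$e))
  invisible(x)
}

as_penalties <- function(p) {
  if (inherits(p, "wfa_penalties")) return(p)
  if (is.numeric(p) && length(p) == 3L) return(wfa_penalties(p[1], p[2], p[3]))
  stop("`penalties` must be a wfa_penalties object or a numeric vector (x, o, e)")
}
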
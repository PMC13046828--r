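#' Circular morph-wheel descriptor
#'
#' The identity space of the adjustment task is a closed wheel of face
#' morphs interpolated between three anchor identities. With 46
#' intermediates per segment the wheel holds 3 + 3 * 46 = 141 morphs,
#' indexed 0..140; all stimulus and response arithmetic is modulo the
#' wheel size.
#'
#' @param n_points Number of morphs on the wheel. Must be odd so that no
#'   pair of indices is exactly antipodal (which would make the sign of
#'   the minimal displacement ambiguous).
#' @param n_anchors Number of anchor identities (equally spaced).
#' @return An object of class `morph_wheel` with fields `n_points` and
#'   `anchor_indices`.
#' @examples
#' w <- morph_wheel()
#' w$anchor_indices # 0, 47, 94
#' @export
morph_wheel <- function(n_points = 141L, n_anchors = 3L) {
  n_points <- as.integer(n_points)
  n_anchors <- as.integer(n_anchors)
  if (n_points < 3L || n_points %% 2L == 0L)
    stop("`n_points` must be odd and >= 3 (even wheels have antipodal ties)")
  if (n_points %% n_anchors != 0L)
    stop("anchors must be equally spaced: `n_points` not divisible by `n_anchors`")
  structure(
    list(n_points = n_points,
         anchor_indices = as.integer((0:(n_anchors - 1L)) * (n_points / n_anchors))),
    class = "morph_wheel")
}

#' @export
print.morph_wheel <- function(x, ...) {
  cat("<morph_wheel> ", x$n_points, " morphs, anchors at ",
      paste(x$anchor_indices, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Minimal signed circular distance between wheel indices
#'
#' Returns the signed displacement from `b` to `a` along the shorter arc,
#' in morph steps. Positive values are clockwise (increasing index modulo
#' the wheel size), negative counterclockwise. For an odd wheel the
#' shorter arc is unique and `|delta| <= floor(n/2)`.
#'
#' @param a,b Wheel indices in `0..n-1` (vectorised, recycled).
#' @param n Wheel size (odd integer), or a [morph_wheel()].
#' @return Integer vector of signed distances in `[-(n-1)/2, (n-1)/2]`.
#' @examples
#' signed_circular_distance(140, 0)  # -1: one step counterclockwise
#' signed_circular_distance(70, 0)   # +70
#' @export
signed_circular_distance <- function(a, b, n = 141L) {
  if (inherits(n, "morph_wheel")) n <- n$n_points
  n <- as.integer(n)
  if (n %% 2L == 0L)
    stop("even wheel size is unsupported: antipodal displacement has no sign")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("wheel indices must be finite")
  a <- as.integer(a); b <- as.integer(b)
  if (any(a < 0L | a >= n) || any(b < 0L | b >= n))
    stop("wheel index out of range [0, ", n - 1L, "]")
  half <- n %/% 2L
  as.integer((a - b + half) %% n - half)
}

#' Signed adjustment error of a reproduced morph
#'
#' The adjustment error is the minimal signed circular distance from the
#' target to the response: 0 when the reproduced face is the target,
#' positive when the response lies clockwise of the target.
#'
#' @inheritParams signed_circular_distance
#' @param response,target Wheel indices.
#' @return Signed error in morph steps.
#' @export
adjustment_error <- function(response, target, n = 141L) {
  signed_circular_distance(response, target, n)
}

#' Distance-bin assignment for inducer-target separations
#'
#' Absolute separations of 1--23 morph steps are `close`, 24--46 `middle`
#' and 47--69 `far`; zero separations (no direction information) and
#' separations of 70 or more steps (trimmed so the three bins hold equally
#' many distances) are `excluded`.
#'
#' @param delta Signed distances in morph steps.
#' @return Factor with levels `close`, `middle`, `far`, `excluded`.
#' @export
assign_distance_bin <- function(delta) {
  a <- abs(delta)
  lab <- ifelse(a >= 1 & a <= 23, "close",
         ifelse(a >= 24 & a <= 46, "middle",
         ifelse(a >= 47 & a <= 69, "far", "excluded")))
  factor(lab, levels = c("close", "middle", "far", "excluded"))
}
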
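#' Wrap angles to the axial range [-90, 90)
#'
#' Orientations of line-like structures are axial: a line at \eqn{\theta} is
#' the same line at \eqn{\theta + 180}. All orientations in this package are
#' reported in degrees in the half-open interval \[-90, 90), measured
#' counterclockwise from the +x (column) axis with the image origin at the
#' top-left.
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped to \[-90, 90).
#' @export
#' @examples
#' wrap_axial(c(90, 180, -95, 270))
wrap_axial <- function(a) {
  ((a + 90) %% 180) - 90
}

#' Axial angular difference
#'
#' Smallest difference between two orientations defined modulo 180 degrees,
#' i.e. \eqn{\min_k |a - b + 180k|}. Always in \[0, 90\].
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return numeric vector of differences in degrees, in \[0, 90\].
#' @export
#' @examples
#' axial_difference(80, -80)  # 20: 180-degree periodicity
#' axial_difference(0, 90)    # 90: maximal axial separation
axial_difference <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}

# Counterclockwise (visual) 90-degree rotation of an image matrix [row, col].
# A structure at axial angle theta maps to theta + 90 (wrapped).
rot90_ccw <- function(m) {
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}
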
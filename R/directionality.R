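#' Directionality histogram from the Fourier power spectrum
#'
#' The image is mean-subtracted, windowed with a 2D Hann window, and its
#' power spectrum is computed. Every spatial-frequency sample outside a
#' low-frequency exclusion disc contributes its power to the orientation bin
#' of the *structure* it encodes: spectral energy of a structure at angle
#' \eqn{\theta} lies perpendicular to \eqn{\theta}, so the 90-degree rotation
#' is applied inside the histogram and bins report structure orientation
#' directly, comparable with [frangi_vesselness()] orientations.
#'
#' @param image 2D numeric matrix; must not be constant.
#' @param n_bins number of uniform bins covering \[-90, 90) (>= 6).
#' @param exclusion_radius frequency-sample radius excluded around DC.
#' @return An object of class `directionality_histogram`: list with
#'   `bin_centers_deg`, `mass` (sums to 1), `n_bins`.
#' @export
directionality_histogram <- function(image, n_bins = 90,
                                     exclusion_radius = 3) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (n_bins < 6) stop("n_bins must be >= 6")
  if (diff(range(image)) == 0) {
    stop("degenerate input: constant image has no directionality")
  }
  nr <- nrow(image); nc <- ncol(image)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  w <- outer(hann(nr), hann(nc))
  p <- Mod(stats::fft((image - mean(image)) * w))^2

  fy <- ifelse(seq_len(nr) - 1 > nr / 2, seq_len(nr) - 1 - nr, seq_len(nr) - 1)
  fx <- ifelse(seq_len(nc) - 1 > nc / 2, seq_len(nc) - 1 - nc, seq_len(nc) - 1)
  fyg <- matrix(fy, nr, nc)
  fxg <- matrix(fx, nr, nc, byrow = TRUE)
  keep <- fyg^2 + fxg^2 > exclusion_radius^2
  if (!any(keep) || sum(p[keep]) == 0) {
    stop("degenerate input: no spectral power outside the exclusion disc")
  }
  # y (row) axis points down; structure angle = spectral angle + 90
  ang <- wrap_axial(atan2(-fyg[keep], fxg[keep]) * 180 / pi + 90)
  width <- 180 / n_bins
  # bins centred on -90 + (i-1)*width so that 0 (the common near-horizontal
  # reference) is a bin centre; the first bin wraps across the axial seam
  idx <- (floor((ang + 90 + width / 2) / width) %% n_bins) + 1
  mass <- vapply(seq_len(n_bins),
                 function(i) sum(p[keep][idx == i]), numeric(1))
  mass <- mass / sum(mass)
  structure(
    list(
      bin_centers_deg = -90 + (seq_len(n_bins) - 1) * width,
      mass = mass, n_bins = n_bins
    ),
    class = "directionality_histogram"
  )
}

#' @export
print.directionality_histogram <- function(x, ...) {
  cat(sprintf(
    "directionality_histogram: %d bins, modal bin at %.1f deg (mass %.3f)\n",
    x$n_bins, x$bin_centers_deg[which.max(x$mass)], max(x$mass)
  ))
  invisible(x)
}

#' Alignment percentage from a directionality histogram
#'
#' Percentage of histogram mass in bins whose centre lies within
#' `cutoff_deg` (axially) of the pattern direction — the Fourier-spectrum
#' counterpart of [alignment_fraction()].
#'
#' @param hist a `directionality_histogram`.
#' @param pattern_angle_deg reference direction in degrees.
#' @param cutoff_deg half-width of the alignment band, in (0, 90).
#' @return percentage in \[0, 100\].
#' @export
histogram_alignment <- function(hist, pattern_angle_deg, cutoff_deg = 30) {
  stopifnot(inherits(hist, "directionality_histogram"))
  if (cutoff_deg <= 0 || cutoff_deg >= 90) {
    stop("cutoff_deg must be in (0, 90)")
  }
  sel <- axial_difference(hist$bin_centers_deg, pattern_angle_deg) < cutoff_deg
  100 * sum(hist$mass[sel])
}
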
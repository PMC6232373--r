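#' Parse a nanogroove substrate name
#'
#' Substrates are named `DxxxLyyy`, where the D-value is the pattern period
#' in nm (one groove + ridge repeat) and the L-value the ridge width in nm;
#' e.g. `D450L180` is a 450 nm period with 180 nm ridges. Flat control
#' substrates are named `FLAT_PDMS` or `FLAT_PS` (any `FLAT`-prefixed name is
#' accepted) and carry no groove dimensions.
#'
#' @param name substrate name string.
#' @return list with `flat` (logical) and, for grooved substrates,
#'   `period_nm` and `ridge_nm` integers.
#' @export
#' @examples
#' parse_pattern_name("D450L180")
#' parse_pattern_name("FLAT_PDMS")
parse_pattern_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  if (grepl("^FLAT([_-][A-Za-z0-9]+)?$", name, ignore.case = TRUE)) {
    return(list(flat = TRUE, name = name))
  }
  m <- regmatches(name, regexec("^D([0-9]+)L([0-9]+)$", name))[[1]]
  if (length(m) != 3) {
    stop(sprintf(
      "malformed substrate name '%s': expected D<period_nm>L<ridge_nm> (e.g. D450L180) or FLAT_<material>",
      name
    ))
  }
  list(flat = FALSE, name = name,
       period_nm = as.integer(m[2]), ridge_nm = as.integer(m[3]))
}

#' Derived groove metrics
#'
#' Groove width is the pattern period minus the ridge width; the ridge-width
#' to period ratio L/D summarizes how much of each repeat is ridge.
#'
#' @param period_nm pattern period D in nm.
#' @param ridge_nm ridge width L in nm; must satisfy 0 < L < D.
#' @return list with `groove_nm` and `ridge_period_ratio`.
#' @export
#' @examples
#' derive_pattern_metrics(450, 180)  # groove 270 nm, ratio 0.4
derive_pattern_metrics <- function(period_nm, ridge_nm) {
  if (!(period_nm > 0 && ridge_nm > 0 && ridge_nm < period_nm)) {
    stop("require 0 < ridge_nm < period_nm")
  }
  list(groove_nm = period_nm - ridge_nm,
       ridge_period_ratio = ridge_nm / period_nm)
}

#' Substrate pattern specification
#'
#' Bundles the parsed name, derived metrics and the measured pattern angle.
#' Flat substrates always carry an (arbitrary) pattern angle of 0 degrees:
#' no actual guidance direction exists, and 0 makes the isotropic alignment
#' expectation of 33.3% directly comparable across substrates.
#'
#' @param name substrate name (see [parse_pattern_name()]).
#' @param pattern_angle_deg measured groove direction in \[-90, 90); ignored
#'   (forced to 0) for flat substrates.
#' @return object of class `pattern_spec`.
#' @export
pattern_spec <- function(name, pattern_angle_deg = NA_real_) {
  p <- parse_pattern_name(name)
  if (p$flat) {
    p$pattern_angle_deg <- 0
  } else {
    if (is.na(pattern_angle_deg)) {
      stop("grooved substrates require a measured pattern_angle_deg")
    }
    if (pattern_angle_deg < -90 || pattern_angle_deg >= 90) {
      stop("pattern_angle_deg must lie in [-90, 90)")
    }
    p <- c(p, derive_pattern_metrics(p$period_nm, p$ridge_nm))
    p$pattern_angle_deg <- pattern_angle_deg
  }
  structure(p, class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  if (x$flat) {
    cat(sprintf("pattern_spec: %s (flat control, angle 0 deg)\n", x$name))
  } else {
    cat(sprintf(
      "pattern_spec: %s  period %d nm, ridge %d nm, groove %d nm, L/D %.3g, angle %.2f deg\n",
      x$name, x$period_nm, x$ridge_nm, x$groove_nm, x$ridge_period_ratio,
      x$pattern_angle_deg
    ))
  }
  invisible(x)
}

#' Estimate the groove direction from a reference image
#'
#' The groove direction of each substrate is measured from a reference image
#' showing the pattern edge. The dominant orientation is taken from the
#' modal bin of the Fourier directionality histogram, refined by parabolic
#' interpolation of the three bins around the mode (circular neighbours). If
#' the peak mass is below `dominance` times the uniform bin mass the image
#' has no dominant direction and an error asks for a manual angle instead.
#'
#' @param reference_image 2D numeric matrix containing a dominant straight
#'   edge or stripe.
#' @param n_bins histogram bins (1-degree bins by default: finer than the
#'   2-degree screening default, since this estimate anchors every alignment
#'   measurement of a substrate).
#' @param dominance required ratio of peak mass to the uniform level.
#' @return estimated angle in degrees, in \[-90, 90).
#' @export
estimate_pattern_angle <- function(reference_image, n_bins = 180,
                                   dominance = 2) {
  h <- directionality_histogram(reference_image, n_bins = n_bins)
  k <- which.max(h$mass)
  if (h$mass[k] < dominance / n_bins) {
    stop(sprintf(
      "no dominant direction (peak mass %.4f < %g x uniform level); supply a manual pattern angle",
      h$mass[k], dominance
    ))
  }
  width <- 180 / n_bins
  left <- h$mass[if (k == 1) n_bins else k - 1]
  right <- h$mass[if (k == n_bins) 1 else k + 1]
  denom <- left - 2 * h$mass[k] + right
  delta <- if (denom == 0) 0 else 0.5 * (left - right) / denom
  wrap_axial(h$bin_centers_deg[k] + delta * width)
}
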
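# Gaussian derivative kernels sampled on an integer grid, truncated at 4*sigma.
gauss_kernel_1d <- function(sigma, order = 0) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    # zero-sum corrected so a constant image has an exactly null response
    "2" = {
      k <- (x^2 - sigma^2) / sigma^4 * g
      k - sum(k) * g
    },
    stop("unsupported derivative order")
  )
}

# 2D separable filtering with replicated borders; kern[row, col] offsets.
filter_sep <- function(img, krow, kcol) {
  EBImage::filter2(img, outer(krow, kcol), boundary = "replicate")
}

#' Multiscale Frangi vesselness with per-pixel ridge orientation
#'
#' Computes, at each scale \eqn{\sigma}, the \eqn{\sigma^2}-normalized Hessian
#' of the Gaussian-smoothed image, its eigenvalues ordered by magnitude
#' \eqn{|\lambda_1| \le |\lambda_2|}, and the 2D vesselness
#' \deqn{V = \exp(-R_B^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2)),}
#' with blobness ratio \eqn{R_B = \lambda_1/\lambda_2} and structureness
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}. For bright ridges on a dark
#' background, \eqn{V = 0} wherever \eqn{\lambda_2 > 0}. The per-pixel
#' response is the maximum over scales; the orientation is the axial angle of
#' the eigenvector belonging to \eqn{\lambda_1} (the along-ridge direction) at
#' the maximizing scale.
#'
#' @param image 2D numeric matrix of finite intensities.
#' @param scales numeric vector of Gaussian scales \eqn{\sigma} in pixels.
#' @param beta blobness sensitivity \eqn{\beta} (> 0).
#' @param c structureness sensitivity; `NULL` (default) uses half the maximum
#'   structureness \eqn{S} observed at each scale (adaptive, per Frangi's
#'   suggestion).
#' @param dark_ridges if `TRUE`, detect dark ridges on a bright background
#'   (inverts the eigenvalue sign convention).
#' @return An object of class `orientation_field`: a list with matrices
#'   `vesselness` (in \[0, 1\]), `orientation_deg` (axial, `NA` where no ridge
#'   direction is defined), `scale_of_max`, plus the call parameters.
#' @export
frangi_vesselness <- function(image, scales = c(1, 1.5, 2, 3), beta = 0.5,
                              c = NULL, dark_ridges = FALSE) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (length(scales) < 1 || any(scales <= 0)) stop("scales must be positive")
  if (beta <= 0) stop("beta must be > 0")
  if (!is.null(c) && c <= 0) stop("c must be > 0")
  if (dark_ridges) image <- -image

  best_v <- matrix(0, nrow(image), ncol(image))
  best_theta <- matrix(NA_real_, nrow(image), ncol(image))
  best_scale <- matrix(NA_real_, nrow(image), ncol(image))

  for (sigma in scales) {
    g0 <- gauss_kernel_1d(sigma, 0)
    g1 <- gauss_kernel_1d(sigma, 1)
    g2 <- gauss_kernel_1d(sigma, 2)
    # x = column axis, y = row axis (down); gamma = 2 scale normalization
    hxx <- sigma^2 * filter_sep(image, g0, g2)
    hyy <- sigma^2 * filter_sep(image, g2, g0)
    hxy <- sigma^2 * filter_sep(image, g1, g1)

    m <- (hxx + hyy) / 2
    disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    e_hi <- m + disc
    e_lo <- m - disc
    swap <- abs(e_hi) >= abs(e_lo)
    l2 <- ifelse(swap, e_hi, e_lo)  # larger magnitude: across-ridge
    l1 <- ifelse(swap, e_lo, e_hi)  # smaller magnitude: along-ridge

    s <- sqrt(l1^2 + l2^2)
    # the adaptive c is scale-free; structureness below the floating-point
    # noise of the convolutions carries no structure (flat image -> 0)
    s[s < 1e-8 * max(1, max(abs(image)))] <- 0
    cc <- if (is.null(c)) max(s) / 2 else c
    if (cc <= 0) next
    v <- matrix(0, nrow(image), ncol(image))
    ok <- l2 < 0 & s > 0
    if (any(ok)) {
      rb2 <- (l1[ok] / l2[ok])^2
      v[ok] <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s[ok]^2 / (2 * cc^2)))
    }
    # degenerate eigenvalues carry no ridge direction
    v[disc == 0] <- 0

    upd <- v > best_v
    if (any(upd)) {
      # eigenvector of l1: (hxy, l1 - hxx), falling back to the other row of
      # (H - l1 I) when that expression vanishes
      vx <- hxy[upd]
      vy <- l1[upd] - hxx[upd]
      tiny <- abs(vx) + abs(vy) < 1e-12 * pmax(abs(l2[upd]), 1e-300)
      if (any(tiny)) {
        vx[tiny] <- (l1[upd] - hyy[upd])[tiny]
        vy[tiny] <- hxy[upd][tiny]
      }
      # y axis points down in image coordinates; negate for CCW-from-+x angles
      theta <- wrap_axial(atan2(-vy, vx) * 180 / pi)
      best_v[upd] <- v[upd]
      best_theta[upd] <- theta
      best_scale[upd] <- sigma
    }
  }

  structure(
    list(
      vesselness = best_v,
      orientation_deg = best_theta,
      scale_of_max = best_scale,
      scales = scales, beta = beta, c = c, dark_ridges = dark_ridges
    ),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf(
    "orientation_field: %d x %d px, scales {%s}, %d px with vesselness > 0\n",
    nrow(x$vesselness), ncol(x$vesselness),
    paste(x$scales, collapse = ", "), sum(x$vesselness > 0)
  ))
  invisible(x)
}

#' Fraction of neurite pixels aligned with the pattern direction
#'
#' The alignment statistic: among supra-threshold vesselness pixels (the
#' support), the percentage whose axial orientation differs from the pattern
#' angle by less than `cutoff_deg`. The comparison is strict (< 30 degrees by
#' default). Under an isotropic orientation distribution the expected value is
#' 100 * 60/180 = 33.3%.
#'
#' @param field an `orientation_field` from [frangi_vesselness()].
#' @param pattern_angle_deg reference (groove) direction in degrees.
#' @param threshold vesselness cutoff in (0, 1) defining the support.
#' @param restrict_mask optional logical matrix; support is intersected with it.
#' @param cutoff_deg half-width of the alignment band, in (0, 90).
#' @return An object of class `alignment_result`: list with `percent_aligned`
#'   (`NA` and `undefined = TRUE` when the support is empty),
#'   `n_support_pixels`, `pattern_angle_deg`, `cutoff_deg`.
#' @export
alignment_fraction <- function(field, pattern_angle_deg, threshold = 0.15,
                               restrict_mask = NULL, cutoff_deg = 30) {
  stopifnot(inherits(field, "orientation_field"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (cutoff_deg <= 0 || cutoff_deg >= 90) {
    stop("cutoff_deg must be in (0, 90)")
  }
  support <- field$vesselness > threshold & !is.na(field$orientation_deg)
  if (!is.null(restrict_mask)) {
    restrict_mask <- as.matrix(restrict_mask) != 0
    stopifnot(identical(dim(restrict_mask), dim(support)))
    support <- support & restrict_mask
  }
  n <- sum(support)
  pct <- if (n == 0) NA_real_ else {
    100 * mean(axial_difference(field$orientation_deg[support],
                                pattern_angle_deg) < cutoff_deg)
  }
  structure(
    list(
      percent_aligned = pct, n_support_pixels = n,
      pattern_angle_deg = wrap_axial(pattern_angle_deg),
      cutoff_deg = cutoff_deg, undefined = n == 0
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  if (x$undefined) {
    cat("alignment_result: undefined (empty support)\n")
  } else {
    cat(sprintf(
      "alignment_result: %.1f%% of %d px within %g deg of %g deg\n",
      x$percent_aligned, x$n_support_pixels, x$cutoff_deg, x$pattern_angle_deg
    ))
  }
  invisible(x)
}
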
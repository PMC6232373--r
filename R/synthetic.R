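#' Scene specification for the synthetic culture generator
#'
#' Describes one synthetic field of view emulating 10x epifluorescence images
#' of a sparse differentiated neuronal culture: blob-like somata with nuclei,
#' thin curvilinear neurites whose orientations follow a mixture of an
#' isotropic component and a component concentrated around the groove
#' direction, optional single-level branching, and Poisson + Gaussian noise
#' over an uneven-free constant background offset.
#'
#' @param image_shape integer (rows, cols) in pixels.
#' @param pixel_size_um micrometres per pixel (default 0.65, plausible for a
#'   10x objective).
#' @param n_cells number of somata to place (>= 0).
#' @param soma_radius_um mean and sd of the soma radius, micrometres.
#' @param neurites_per_cell_probs probability vector over 0, 1, 2, 3+ neurites
#'   per cell (must sum to 1; the 3+ class generates exactly 3).
#' @param neurite_length_um mean and sd of neurite arc length, micrometres.
#' @param branch_prob probability that a neurite carries one side branch.
#' @param pattern_angle_deg groove direction in \[-90, 90).
#' @param aligned_fraction probability that a neurite orientation is drawn
#'   from the concentrated (pattern-aligned) mixture component.
#' @param concentration_deg sd (degrees) of the concentrated angular
#'   component.
#' @param curvature_step_deg maximal per-step heading change of the
#'   bounded-turn random walk tracing each neurite.
#' @param background_level constant background intensity (photon units).
#' @param signal_level peak signal scale (photon units).
#' @param noise_gain Poisson gain (counts per photon unit).
#' @param read_noise_sd sd of additive Gaussian read noise.
#' @return validated list of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(512, 512),
                       pixel_size_um = 0.65,
                       n_cells = 10,
                       soma_radius_um = c(mean = 7.5, sd = 1.5),
                       neurites_per_cell_probs = c(0.5, 0.25, 0.15, 0.1),
                       neurite_length_um = c(mean = 45, sd = 12),
                       branch_prob = 0.2,
                       pattern_angle_deg = 0,
                       aligned_fraction = 0,
                       concentration_deg = 10,
                       curvature_step_deg = 5,
                       background_level = 50,
                       signal_level = 400,
                       noise_gain = 1,
                       read_noise_sd = 2) {
  soma_radius_um <- stats::setNames(as.numeric(soma_radius_um),
                                    c("mean", "sd"))
  neurite_length_um <- stats::setNames(as.numeric(neurite_length_um),
                                       c("mean", "sd"))
  spec <- list(
    image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
    n_cells = as.integer(n_cells), soma_radius_um = soma_radius_um,
    neurites_per_cell_probs = neurites_per_cell_probs,
    neurite_length_um = neurite_length_um, branch_prob = branch_prob,
    pattern_angle_deg = pattern_angle_deg,
    aligned_fraction = aligned_fraction,
    concentration_deg = concentration_deg,
    curvature_step_deg = curvature_step_deg,
    background_level = background_level, signal_level = signal_level,
    noise_gain = noise_gain, read_noise_sd = read_noise_sd
  )
  with(spec, {
    stopifnot(
      length(image_shape) == 2, all(image_shape >= 8),
      pixel_size_um > 0, n_cells >= 0,
      length(neurites_per_cell_probs) == 4,
      all(neurites_per_cell_probs >= 0), all(neurites_per_cell_probs <= 1),
      abs(sum(neurites_per_cell_probs) - 1) < 1e-9,
      branch_prob >= 0, branch_prob <= 1,
      aligned_fraction >= 0, aligned_fraction <= 1,
      pattern_angle_deg >= -90, pattern_angle_deg < 90,
      concentration_deg > 0, curvature_step_deg >= 0,
      background_level >= 0, signal_level > 0, noise_gain > 0,
      read_noise_sd >= 0
    )
  })
  structure(spec, class = "scene_spec")
}

#' Sample axial orientations from the aligned/isotropic mixture
#'
#' With probability `aligned_fraction` an angle is drawn from a wrapped
#' normal (axial, 180-degree periodic) around the pattern angle with sd
#' `concentration_deg`; otherwise uniformly on \[-90, 90).
#'
#' @param n number of angles (>= 0).
#' @param aligned_fraction mixture weight of the concentrated component.
#' @param pattern_angle_deg centre of the concentrated component.
#' @param concentration_deg sd of the concentrated component (> 0).
#' @param seed optional integer; when given, sampling is reproducible.
#' @return numeric vector of axial angles in \[-90, 90).
#' @export
sample_orientations <- function(n, aligned_fraction, pattern_angle_deg,
                                concentration_deg, seed = NULL) {
  if (length(n) != 1 || n < 0) stop("n must be a nonnegative count")
  stopifnot(aligned_fraction >= 0, aligned_fraction <= 1,
            concentration_deg > 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  aligned <- stats::runif(n) < aligned_fraction
  out <- stats::runif(n, -90, 90)
  if (any(aligned)) {
    out[aligned] <- wrap_axial(stats::rnorm(sum(aligned), pattern_angle_deg,
                                            concentration_deg))
  }
  out
}

#' Multi-channel image container
#'
#' One field of view: nuclei, F-actin and beta-tubulin intensity rasters of
#' identical shape plus the pixel calibration.
#'
#' @param nuclei,actin,tubulin 2D numeric matrices, same shape, finite, >= 0.
#' @param pixel_size_um micrometres per pixel.
#' @return object of class `channel_stack`.
#' @export
channel_stack <- function(nuclei, actin, tubulin, pixel_size_um) {
  nuclei <- as.matrix(nuclei); actin <- as.matrix(actin)
  tubulin <- as.matrix(tubulin)
  stopifnot(
    identical(dim(nuclei), dim(actin)), identical(dim(nuclei), dim(tubulin)),
    all(is.finite(nuclei)), all(is.finite(actin)), all(is.finite(tubulin)),
    min(nuclei, actin, tubulin) >= 0, pixel_size_um > 0
  )
  structure(list(nuclei = nuclei, actin = actin, tubulin = tubulin,
                 pixel_size_um = pixel_size_um),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("channel_stack: %d x %d px (%.3g um/px), channels nuclei/actin/tubulin\n",
              nrow(x$nuclei), ncol(x$nuclei), x$pixel_size_um))
  invisible(x)
}

# Bounded-turn polyline from a start point: the heading wiggles around the
# target direction as a mean-reverting (AR(1)) process with per-step
# innovations bounded by curvature_step_deg, so the chord angle stays close
# to the requested orientation while the path is visibly curved. Truncated
# at a border margin so the rendered structure and the ground truth agree.
# Returns an n x 2 matrix of (row, col) positions at sub-pixel step 0.5 px.
walk_polyline <- function(start_rc, heading_deg, length_px,
                          curvature_step_deg, shape, margin = 2,
                          step_px = 0.5, reversion = 0.95) {
  n_steps <- max(1L, ceiling(length_px / step_px))
  dev <- numeric(n_steps)
  if (curvature_step_deg > 0) {
    eps <- stats::runif(n_steps, -curvature_step_deg, curvature_step_deg)
    for (t in seq_len(n_steps)) {
      dev[t] <- reversion * (if (t == 1) 0 else dev[t - 1]) + eps[t]
    }
  }
  h <- (heading_deg + dev) * pi / 180
  dr <- -sin(h) * step_px   # image rows grow downward
  dc <- cos(h) * step_px
  r <- start_rc[1] + c(0, cumsum(dr))
  c_ <- start_rc[2] + c(0, cumsum(dc))
  inside <- r >= 1 + margin & r <= shape[1] - margin &
    c_ >= 1 + margin & c_ <= shape[2] - margin
  cut <- which(!inside)
  keep <- if (length(cut)) seq_len(max(1L, cut[1] - 1L)) else seq_along(r)
  cbind(row = r[keep], col = c_[keep])
}

polyline_arc_px <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
}

polyline_chord_angle <- function(p) {
  dr <- p[nrow(p), 1] - p[1, 1]
  dc <- p[nrow(p), 2] - p[1, 2]
  if (dr == 0 && dc == 0) return(NA_real_)
  wrap_axial(atan2(-dr, dc) * 180 / pi)
}

# Stamp sub-pixel polyline points into an amplitude raster (bilinear weight
# deposition, so rendering is rotation-invariant with no staircase bias) and
# blur once, producing constant-width Gaussian-profile ridges.
render_polylines <- function(polys, shape, ridge_sigma_px = 0.9,
                             amplitude = 1, step_px = 0.5) {
  img <- matrix(0, shape[1], shape[2])
  pts <- do.call(rbind, polys)
  if (!is.null(pts) && nrow(pts)) {
    r <- pts[, 1]; c_ <- pts[, 2]
    r0 <- floor(r); c0 <- floor(c_)
    fr <- r - r0; fc <- c_ - c0
    rows <- c(r0, r0 + 1, r0, r0 + 1)
    cols <- c(c0, c0, c0 + 1, c0 + 1)
    w <- amplitude * step_px *
      c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
    ok <- rows >= 1 & rows <= shape[1] & cols >= 1 & cols <= shape[2]
    idx <- rows[ok] + (cols[ok] - 1) * shape[1]
    acc <- rowsum(w[ok], idx)
    img[as.integer(rownames(acc))] <- acc[, 1]
  }
  if (ridge_sigma_px > 0) {
    img <- EBImage::gblur(img, sigma = ridge_sigma_px)
  }
  img
}

# Additive Gaussian blob on a local window (used for somata and nuclei).
add_blob <- function(img, centre_rc, sigma_px, amplitude) {
  r0 <- centre_rc[1]; c0 <- centre_rc[2]
  half <- ceiling(4 * sigma_px)
  rr <- max(1, floor(r0 - half)):min(nrow(img), ceiling(r0 + half))
  cc <- max(1, floor(c0 - half)):min(ncol(img), ceiling(c0 + half))
  if (!length(rr) || !length(cc)) return(img)
  g <- outer(exp(-(rr - r0)^2 / (2 * sigma_px^2)),
             exp(-(cc - c0)^2 / (2 * sigma_px^2)))
  img[rr, cc] <- img[rr, cc] + amplitude * g
  img
}

apply_noise <- function(signal, background_level, signal_level, noise_gain,
                        read_noise_sd) {
  lambda <- (background_level + signal_level * signal) / noise_gain
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow(lambda)) *
    noise_gain
  if (read_noise_sd > 0) {
    counts <- counts + matrix(stats::rnorm(length(counts), 0, read_noise_sd),
                              nrow(counts))
  }
  pmax(counts, 0)
}

# Grow one neurite (primary path plus at most one side branch).
grow_neurite <- function(start_rc, chord_dir_deg, spec, shape) {
  len_px <- max(5, stats::rnorm(1, spec$neurite_length_um["mean"],
                                spec$neurite_length_um["sd"])) /
    spec$pixel_size_um
  primary <- walk_polyline(start_rc, chord_dir_deg, len_px,
                           spec$curvature_step_deg, shape)
  polys <- list(primary)
  n_branch <- 0L
  if (nrow(primary) > 10 && stats::runif(1) < spec$branch_prob) {
    at <- sample(seq(floor(0.3 * nrow(primary)),
                     ceiling(0.7 * nrow(primary))), 1)
    seg <- primary[max(1, at - 2):at, , drop = FALSE]
    local_heading <- atan2(-(seg[nrow(seg), 1] - seg[1, 1]),
                           seg[nrow(seg), 2] - seg[1, 2]) * 180 / pi
    turn <- sample(c(-1, 1), 1) * stats::runif(1, 25, 50)
    blen <- stats::runif(1, 0.3, 0.6) * len_px
    branch <- walk_polyline(primary[at, ], local_heading + turn, blen,
                            spec$curvature_step_deg, shape)
    if (nrow(branch) > 6) {
      polys <- c(polys, list(branch))
      n_branch <- 1L
    }
  }
  list(polys = polys, primary = primary, branch_count = n_branch)
}

#' Generate one synthetic culture image with ground truth
#'
#' Renders the three channels (nuclei: Gaussian blobs at soma centroids;
#' tubulin: somata plus neurites as ~2-4 px wide Gaussian-profile curvilinear
#' ridges; actin: somata plus attenuated neurites), applies Poisson then
#' Gaussian noise last, and returns the complete ground truth used by the
#' parameter-recovery tests.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; generation is byte-reproducible for a fixed
#'   (spec, seed).
#' @return list with `stack` (a [channel_stack()]) and `truth`, a list with
#'   `cells` (data frame: cell_id, row, col, radius_px), `neurites` (data
#'   frame: neurite_id, cell_id, chord_angle_deg, arc_length_um,
#'   chord_length_um, branch_count), `polylines` (list of (row, col)
#'   matrices, primary path per neurite), `pattern_angle_deg` and
#'   `true_aligned_fraction` (fraction of neurites whose chord angle is
#'   within 30 degrees of the pattern angle; `NA` when there are none).
#' @export
generate_culture_image <- function(spec, seed) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  shape <- spec$image_shape
  rad_px <- spec$soma_radius_um / spec$pixel_size_um

  # -- place somata: sparse culture, no overlapping cell bodies
  centres <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  min_sep <- 2.3 * rad_px["mean"]
  margin <- rad_px["mean"] + 10
  if (2 * margin >= min(shape)) {
    if (spec$n_cells > 0) {
      stop(sprintf(
        "image %d x %d too small to place a soma of mean radius %.1f px with margin",
        shape[1], shape[2], rad_px["mean"]))
    }
  }
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in 1:300) {
      p <- c(stats::runif(1, margin, shape[1] - margin),
             stats::runif(1, margin, shape[2] - margin))
      if (nrow(centres) == 0 ||
          min(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2)) >
            min_sep) {
        centres <- rbind(centres, p)
        radii <- c(radii, max(2, stats::rnorm(1, rad_px["mean"],
                                              rad_px["sd"])))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "image %d x %d too small to place %d non-overlapping somata (placed %d)",
        shape[1], shape[2], spec$n_cells, nrow(centres)))
    }
  }

  # -- neurites per cell from the 0/1/2/3+ distribution
  neurite_polys <- list()
  nrec <- list()
  primaries <- list()
  nid <- 0L
  n_per_cell <- if (spec$n_cells > 0) {
    sample(0:3, spec$n_cells, replace = TRUE,
           prob = spec$neurites_per_cell_probs)
  } else integer(0)
  for (ci in seq_len(spec$n_cells)) {
    k <- n_per_cell[ci]
    if (k == 0) next
    thetas <- sample_orientations(k, spec$aligned_fraction,
                                  spec$pattern_angle_deg,
                                  spec$concentration_deg)
    # departure side (+/- 180, leaving the axial orientation untouched):
    # spread departure points around the soma so distinct neurites do not
    # sprout from the same boundary point
    signs <- sample(c(0, 180), k, replace = TRUE)
    if (k > 1) {
      circ_d <- function(a, b) {
        d <- abs((a - b) %% 360)
        pmin(d, 360 - d)
      }
      chosen <- thetas[1] + signs[1]
      for (j in 2:k) {
        cand <- thetas[j] + c(0, 180)
        sep <- vapply(cand, function(a) min(circ_d(a, chosen)), numeric(1))
        pick <- if (abs(diff(sep)) < 1e-9) (signs[j] / 180) + 1 else {
          which.max(sep)
        }
        signs[j] <- c(0, 180)[pick]
        chosen <- c(chosen, thetas[j] + signs[j])
      }
    }
    for (ni in seq_len(k)) {
      theta <- thetas[ni]
      dir_deg <- theta + signs[ni]
      start <- c(centres[ci, 1] - radii[ci] * sin(dir_deg * pi / 180),
                 centres[ci, 2] + radii[ci] * cos(dir_deg * pi / 180))
      g <- grow_neurite(start, dir_deg, spec, shape)
      if (nrow(g$primary) < 4) next
      nid <- nid + 1L
      neurite_polys <- c(neurite_polys, g$polys)
      primaries[[nid]] <- g$primary
      nrec[[nid]] <- data.frame(
        neurite_id = nid, cell_id = ci,
        chord_angle_deg = polyline_chord_angle(g$primary),
        arc_length_um = polyline_arc_px(g$primary) * spec$pixel_size_um,
        chord_length_um = sqrt(sum((g$primary[nrow(g$primary), ] -
                                      g$primary[1, ])^2)) *
          spec$pixel_size_um,
        branch_count = g$branch_count
      )
    }
  }
  neurites <- if (length(nrec)) do.call(rbind, nrec) else data.frame(
    neurite_id = integer(0), cell_id = integer(0),
    chord_angle_deg = numeric(0), arc_length_um = numeric(0),
    chord_length_um = numeric(0), branch_count = integer(0))

  # -- render channels; noise applied last
  ridge <- render_polylines(neurite_polys, shape)
  soma <- matrix(0, shape[1], shape[2])
  nuc <- matrix(0, shape[1], shape[2])
  for (ci in seq_len(nrow(centres))) {
    soma <- add_blob(soma, centres[ci, ], 0.65 * radii[ci], 1)
    nuc <- add_blob(nuc, centres[ci, ], 0.45 * radii[ci], 1)
  }
  stack <- channel_stack(
    nuclei = apply_noise(nuc, spec$background_level, spec$signal_level,
                         spec$noise_gain, spec$read_noise_sd),
    actin = apply_noise(pmin(soma + 0.4 * ridge, 1.5), spec$background_level,
                        spec$signal_level, spec$noise_gain,
                        spec$read_noise_sd),
    tubulin = apply_noise(pmin(0.9 * soma + ridge, 1.5),
                          spec$background_level, spec$signal_level,
                          spec$noise_gain, spec$read_noise_sd),
    pixel_size_um = spec$pixel_size_um
  )

  truth <- list(
    cells = data.frame(cell_id = seq_len(nrow(centres)),
                       row = centres[, 1], col = centres[, 2],
                       radius_px = radii, row.names = NULL),
    neurites = neurites,
    polylines = primaries,
    pattern_angle_deg = spec$pattern_angle_deg,
    true_aligned_fraction = if (nrow(neurites)) {
      mean(axial_difference(neurites$chord_angle_deg,
                            spec$pattern_angle_deg) < 30)
    } else NA_real_
  )
  list(stack = stack, truth = truth)
}

#' Generate a neurite-only raster of straight-or-curved ridges
#'
#' Renders `n_neurites` Gaussian-profile ridges with given (or sampled)
#' chord orientations on a zero background — the synthetic counterpart of a
#' neurite-only image after soma and background subtraction. Used by the
#' alignment-calibration batteries.
#'
#' @param n_neurites number of neurites.
#' @param shape image shape (rows, cols).
#' @param angles optional vector of axial angles; when `NULL`, sampled via
#'   [sample_orientations()] with the mixture parameters below.
#' @param aligned_fraction,pattern_angle_deg,concentration_deg mixture
#'   parameters used when `angles` is `NULL`.
#' @param length_um mean and sd of neurite length, micrometres.
#' @param pixel_size_um micrometres per pixel.
#' @param curvature_step_deg per-step heading jitter (0 = straight).
#' @param seed integer seed.
#' @return list with `image` (clean intensity raster) and `truth` data frame
#'   (chord_angle_deg, arc_length_um per neurite).
#' @export
generate_neurite_field <- function(n_neurites, shape = c(512, 512),
                                   angles = NULL, aligned_fraction = 0,
                                   pattern_angle_deg = 0,
                                   concentration_deg = 10,
                                   length_um = c(mean = 45, sd = 10),
                                   pixel_size_um = 0.65,
                                   curvature_step_deg = 0, seed = 1) {
  length_um <- stats::setNames(as.numeric(length_um), c("mean", "sd"))
  set.seed(seed)
  if (is.null(angles)) {
    angles <- sample_orientations(n_neurites, aligned_fraction,
                                  pattern_angle_deg, concentration_deg)
  }
  stopifnot(length(angles) == n_neurites)
  polys <- vector("list", n_neurites)
  rec <- vector("list", n_neurites)
  for (i in seq_len(n_neurites)) {
    len_px <- max(5, stats::rnorm(1, length_um["mean"], length_um["sd"])) /
      pixel_size_um
    start <- c(stats::runif(1, 3, shape[1] - 3),
               stats::runif(1, 3, shape[2] - 3))
    dir_deg <- angles[i] + sample(c(0, 180), 1)
    p <- walk_polyline(start, dir_deg, len_px, curvature_step_deg, shape)
    polys[[i]] <- p
    rec[[i]] <- data.frame(chord_angle_deg = polyline_chord_angle(p),
                           arc_length_um = polyline_arc_px(p) * pixel_size_um)
  }
  list(image = render_polylines(polys, shape), truth = do.call(rbind, rec))
}

#' Generate a reference edge image for pattern-angle estimation
#'
#' Renders a high-contrast set of parallel stripes at the requested angle
#' over a noisy background, emulating the phase-contrast reference image of
#' the pattern edge from which the groove direction is measured.
#'
#' @param angle_deg stripe direction in \[-90, 90).
#' @param shape image shape (rows, cols).
#' @param seed integer seed.
#' @param n_stripes number of parallel stripes.
#' @param spacing_px stripe spacing, pixels.
#' @param width_px Gaussian half-width of each stripe, pixels.
#' @return 2D intensity matrix.
#' @export
generate_reference_edge_image <- function(angle_deg, shape = c(512, 512),
                                          seed = 1, n_stripes = 11,
                                          spacing_px = 16, width_px = 1.5) {
  if (angle_deg < -90 || angle_deg >= 90) {
    stop("angle_deg must lie in the axial range [-90, 90)")
  }
  stopifnot(length(shape) == 2, all(shape >= 32))
  set.seed(seed)
  rc <- (shape[1] + 1) / 2
  cc <- (shape[2] + 1) / 2
  th <- angle_deg * pi / 180
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  # signed distance perpendicular to a line at angle_deg through the centre
  d <- (c_ - cc) * sin(th) + (r - rc) * cos(th)
  sig <- matrix(0, shape[1], shape[2])
  offs <- (seq_len(n_stripes) - (n_stripes + 1) / 2) * spacing_px
  for (o in offs) sig <- sig + exp(-(d - o)^2 / (2 * width_px^2))
  apply_noise(pmin(sig, 1), background_level = 50, signal_level = 400,
              noise_gain = 1, read_noise_sd = 2)
}
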
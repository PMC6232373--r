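#' Detection parameter set
#'
#' All detection stages are driven by explicit parameters with documented
#' defaults, so that an otherwise wizard-tuned proprietary stage is fully
#' reproducible. Lengths are in micrometres and converted with the stack's
#' pixel calibration.
#'
#' @param nucleus_blur_sigma Gaussian sigma (px) smoothing the nuclei channel
#'   before thresholding.
#' @param min_nucleus_area_px minimum seed area; smaller specks are dropped.
#' @param soma_blur_sigma sigma (px) smoothing the combined actin/tubulin
#'   body image; large enough to suppress thin neurites.
#' @param soma_exclusion_px dilation (px) of the soma mask excluded from the
#'   neurite skeleton.
#' @param frangi_scales vesselness scales (px) for ridge enhancement.
#' @param hysteresis_low,hysteresis_high vesselness hysteresis pair: weak
#'   pixels survive only in components containing a strong pixel.
#' @param prune_len_um skeleton spurs shorter than this are removed.
#' @param attachment_radius_um a skeleton component must approach a soma
#'   within this distance to be linked to it.
#' @param min_neurite_len_um traced neurites shorter than this are dropped
#'   (counted in the QC log).
#' @param vesselness_threshold support threshold for the alignment statistic.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(nucleus_blur_sigma = 2,
                             min_nucleus_area_px = 12,
                             soma_blur_sigma = 4,
                             soma_exclusion_px = 2,
                             frangi_scales = c(1, 1.5, 2),
                             hysteresis_low = 0.05,
                             hysteresis_high = 0.25,
                             prune_len_um = 5,
                             attachment_radius_um = 6,
                             min_neurite_len_um = 10,
                             vesselness_threshold = 0.15) {
  p <- as.list(environment())
  stopifnot(p$hysteresis_low > 0, p$hysteresis_high >= p$hysteresis_low,
            p$hysteresis_high < 1, all(p$frangi_scales > 0),
            p$vesselness_threshold > 0, p$vesselness_threshold < 1)
  structure(p, class = "detection_params")
}

norm01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Segment somata from the nuclei and cytoskeletal channels
#'
#' Nuclei seed the detection: the smoothed nuclei channel is Otsu-thresholded
#' and labelled; the soma extent is grown from those seeds over a body mask
#' derived from the (heavily smoothed) actin + tubulin channels by
#' Voronoi-based propagation, which splits touching somata between their
#' seeds.
#'
#' @param stack a [channel_stack()].
#' @param params a [detection_params()].
#' @return list with `labels` (integer matrix, 0 = background, labels dense
#'   1..K) and `cells` (data frame of cell stubs: cell_id, row, col,
#'   area_px).
#' @export
segment_somata <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "channel_stack"))
  nuc <- norm01(stack$nuclei)
  if (diff(range(stack$nuclei)) == 0) {
    warning("nuclei channel is constant; no cells detected")
    return(list(labels = matrix(0L, nrow(nuc), ncol(nuc)),
                cells = data.frame(cell_id = integer(0), row = numeric(0),
                                   col = numeric(0), area_px = integer(0))))
  }
  nuc_raw_s <- EBImage::gblur(stack$nuclei, params$nucleus_blur_sigma)
  nuc_s <- EBImage::gblur(nuc, params$nucleus_blur_sigma)
  th <- EBImage::otsu(EBImage::Image(norm01(nuc_s)))
  seeds <- EBImage::bwlabel(norm01(nuc_s) > th)
  # drop speck seeds and seeds indistinguishable from background noise
  sig_floor <- stats::median(nuc_raw_s) + 5 * stats::mad(nuc_raw_s)
  tab <- tabulate(seeds[seeds > 0])
  peaks <- vapply(seq_along(tab), function(k)
    max(nuc_raw_s[seeds == k]), numeric(1))
  bad <- which(tab < params$min_nucleus_area_px | peaks < sig_floor)
  if (length(bad)) seeds[seeds %in% bad] <- 0L

  body <- norm01(EBImage::gblur(norm01(stack$actin) + norm01(stack$tubulin),
                                params$soma_blur_sigma))
  bth <- EBImage::otsu(EBImage::Image(body))
  mask <- body > bth | seeds > 0
  labels <- EBImage::imageData(EBImage::propagate(EBImage::Image(body),
                                                  seeds, mask = mask))
  # relabel densely 1..K
  labels <- matrix(as.integer(labels), nrow(nuc))
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  remap <- integer(max(c(0L, ids)))
  remap[ids] <- seq_along(ids)
  labels[labels > 0] <- remap[labels[labels > 0]]

  cells <- if (length(ids)) {
    px <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[px]
    data.frame(
      cell_id = seq_along(ids),
      row = as.numeric(tapply(px[, 1], lab, mean)),
      col = as.numeric(tapply(px[, 2], lab, mean)),
      area_px = as.integer(tabulate(lab, length(ids)))
    )
  } else {
    data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
               area_px = integer(0))
  }
  list(labels = labels, cells = cells)
}

#' Detect the neurite skeleton
#'
#' Ridge-enhances the tubulin channel with multiscale vesselness, applies a
#' hysteresis threshold (weak components are kept only when they contain a
#' strong pixel), skeletonizes, and prunes short spurs. Soma interiors
#' (dilated by `soma_exclusion_px`) are excluded.
#'
#' @param stack a [channel_stack()].
#' @param soma_labels label matrix from [segment_somata()].
#' @param params a [detection_params()].
#' @return logical single-pixel-wide skeleton matrix (empty is valid).
#' @export
detect_neurites <- function(stack, soma_labels, params = detection_params()) {
  stopifnot(inherits(stack, "channel_stack"),
            identical(dim(soma_labels), dim(stack$tubulin)))
  # high-pass the tubulin channel first: soma bodies and uneven background
  # are broad structures whose intensity slope otherwise defeats the ridge
  # filter where neurites leave the cell body
  resid <- stack$tubulin - EBImage::gblur(stack$tubulin,
                                          2 * params$soma_blur_sigma)
  hp <- pmax(resid, 0)
  vf <- frangi_vesselness(norm01(hp), scales = params$frangi_scales)
  v <- vf$vesselness
  soma_mask <- dilate_mask(soma_labels > 0, params$soma_exclusion_px)
  v[soma_mask] <- 0

  # ridges must also rise above the image's own noise floor, so that a
  # background-only image yields an empty skeleton despite the scale-free
  # vesselness normalization
  noise_floor <- 4 * stats::mad(resid)
  weak <- v > params$hysteresis_low & hp > noise_floor
  if (!any(weak)) return(matrix(FALSE, nrow(v), ncol(v)))
  comp <- EBImage::bwlabel(weak)
  strong_ids <- unique(comp[v > params$hysteresis_high])
  strong_ids <- strong_ids[strong_ids > 0]
  mask <- matrix(comp %in% strong_ids, nrow(v))
  if (!any(mask)) return(matrix(FALSE, nrow(v), ncol(v)))
  skel <- thin_mask(mask)
  skel[soma_mask] <- FALSE
  prune_skeleton(skel, params$prune_len_um / stack$pixel_size_um)
}

dilate_mask <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask != 0)
  k <- EBImage::makeBrush(2 * ceiling(radius_px) + 1, shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask != 0), k)) > 0
}

# Grow soma labels outward by `radius` 8-connected steps; ties between
# neighbouring labels resolve to the lower cell_id (deterministic).
grow_labels <- function(labels, radius) {
  lab <- labels
  offs <- zs_offsets
  for (step in seq_len(radius)) {
    prop <- matrix(Inf, nrow(lab), ncol(lab))
    for (o in offs) {
      s <- shift_mat(lab, o[1], o[2])
      cand <- s > 0 & lab == 0L
      prop[cand] <- pmin(prop[cand], s[cand])
    }
    new <- is.finite(prop)
    if (!any(new)) break
    lab[new] <- as.integer(prop[new])
  }
  lab
}

#' Trace the skeleton into neurites and link them to cells
#'
#' The skeleton is decomposed into connected components; each component is
#' attached to the soma (or somata) it approaches within the attachment
#' radius. Every distinct soma contact point roots one neurite tree: pixels
#' of the component are assigned to the nearest root (geodesically), the
#' neurite's polyline is the longest root-to-tip path, its length is the
#' 8-connected geodesic (diagonal steps sqrt(2)) times the pixel size, and
#' branch points are junction-pixel clusters of the tree. Components
#' touching no soma are discarded and counted in the QC summary; ambiguous
#' pixels go to the lower cell_id.
#'
#' @param skeleton logical skeleton matrix from [detect_neurites()].
#' @param soma_labels label matrix from [segment_somata()].
#' @param pixel_size_um micrometres per pixel.
#' @param params a [detection_params()].
#' @return list with `neurites` (data frame: neurite_id, cell_id, length_um,
#'   chord_angle_deg, branch_count), `cells` (data frame: cell_id, polarity
#'   in none/unipolar/bipolar/multipolar, n_neurites,
#'   has_branched_neurite), `polylines` (list of (row, col) matrices) and
#'   `qc` (counts of discarded components/stubs).
#' @export
trace_and_link <- function(skeleton, soma_labels, pixel_size_um,
                           params = detection_params()) {
  if (!identical(dim(skeleton), dim(soma_labels))) {
    stop("skeleton and soma label matrices must share their shape")
  }
  n_cells <- max(0L, max(soma_labels))
  empty_cells <- data.frame(
    cell_id = seq_len(n_cells), polarity = rep("none", n_cells),
    n_neurites = integer(n_cells),
    has_branched_neurite = logical(n_cells),
    stringsAsFactors = FALSE)
  empty <- list(
    neurites = data.frame(neurite_id = integer(0), cell_id = integer(0),
                          length_um = numeric(0),
                          chord_angle_deg = numeric(0),
                          branch_count = integer(0)),
    cells = empty_cells, polylines = list(),
    qc = c(discarded_components = 0L, discarded_stubs = 0L))
  if (!any(skeleton)) return(empty)

  radius_px <- ceiling(params$attachment_radius_um / pixel_size_um)
  grown <- grow_labels(soma_labels, radius_px)
  soma_px <- lapply(seq_len(n_cells), function(k)
    which(soma_labels == k, arr.ind = TRUE))
  sg <- resolve_crossings(skeleton_graph(skeleton))
  comp <- igraph::components(sg$g)
  contact_lab <- grown[sg$px]

  nrecs <- list()
  polylines <- list()
  discarded <- 0L
  stubs <- 0L
  nid <- 0L
  min_len_px <- params$min_neurite_len_um / pixel_size_um

  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    if (length(vids) < 4) next   # isolated remnants of cut junctions
    labs <- contact_lab[vids]
    if (all(labs == 0L)) {
      discarded <- discarded + 1L
      next
    }
    sub <- igraph::induced_subgraph(sg$g, vids)
    zone_px <- radius_px + params$soma_exclusion_px + 2
    pass_gap_px <- params$soma_exclusion_px + 2

    # contact pixels cluster into roots: connected runs of same-label
    # contact pixels within the component; each root remembers how closely
    # its cluster actually approaches the soma
    contact_v <- which(labs > 0L)
    csub <- igraph::induced_subgraph(sub, contact_v)
    ccomp <- igraph::components(csub)
    roots <- integer(0); root_cell <- integer(0); root_gap <- numeric(0)
    for (k in seq_len(ccomp$no)) {
      members <- contact_v[ccomp$membership == k]
      cell <- min(labs[members])          # tie -> lower cell_id
      mpx <- sg$px[vids[members], , drop = FALSE]
      spx <- soma_px[[cell]]
      gap <- if (nrow(spx)) {
        min(vapply(seq_len(nrow(mpx)), function(m)
          min(sqrt((spx[, 1] - mpx[m, 1])^2 + (spx[, 2] - mpx[m, 2])^2)),
          numeric(1)))
      } else Inf
      roots <- c(roots, members[1])
      root_cell <- c(root_cell, cell)
      root_gap <- c(root_gap, gap)
    }

    # decompose repeatedly: a "contact" whose cluster never closely touches
    # the soma and whose assigned skeleton runs straight through the
    # neighbourhood (exactly two near-opposite arms) is a passing neurite,
    # not an attachment; its root is dropped and its pixels reassigned
    arms_info <- NULL
    repeat {
      d <- igraph::distances(sub, v = seq_along(vids), to = roots)
      assign_root <- apply(d, 1, which.min)  # ties -> first (lower index)
      arms_info <- vector("list", length(roots))
      drop <- logical(length(roots))
      for (ri in seq_along(roots)) {
        mine <- which(assign_root == ri)
        if (length(mine) < 2) next
        tree <- igraph::induced_subgraph(sub, mine)
        dd <- igraph::distances(tree, v = match(roots[ri], mine))[1, ]
        dd[!is.finite(dd)] <- -1
        outside <- which(dd > zone_px)
        if (!length(outside)) next
        arms <- igraph::induced_subgraph(tree, outside)
        acomp <- igraph::components(arms)
        entries <- vapply(seq_len(acomp$no), function(ai) {
          av <- which(acomp$membership == ai)
          av[which.min(dd[outside[av]])]
        }, integer(1))
        arms_info[[ri]] <- list(mine = mine, outside = outside,
                                acomp = acomp, entries = entries, dd = dd,
                                arms = arms)
        if (root_gap[ri] > pass_gap_px && acomp$no == 2) {
          rp <- sg$px[vids[roots[ri]], ]
          dirs <- vapply(1:2, function(ai) {
            v <- sg$px[vids[mine[outside[entries[ai]]]], ] - rp
            v / max(sqrt(sum(v^2)), 1e-9)
          }, numeric(2))
          if (sum(dirs[, 1] * dirs[, 2]) < cos(150 * pi / 180)) {
            drop[ri] <- TRUE
          }
        }
      }
      if (!any(drop)) break
      keep <- !drop
      roots <- roots[keep]; root_cell <- root_cell[keep]
      root_gap <- root_gap[keep]
      if (!length(roots)) break
    }
    if (!length(roots)) { discarded <- discarded + 1L; next }

    for (ri in seq_along(roots)) {
      info <- arms_info[[ri]]
      if (is.null(info)) { stubs <- stubs + 1L; next }
      sp_cell <- soma_px[[root_cell[ri]]]
      for (ai in seq_len(info$acomp$no)) {
        av <- which(info$acomp$membership == ai)
        entry <- info$entries[ai]
        arm <- igraph::induced_subgraph(info$arms, av)
        ad <- igraph::distances(arm, v = match(entry, av))[1, ]
        ad[!is.finite(ad)] <- -1
        # the neurite runs from the soma boundary: its measured length is
        # the arm geodesic plus the straight gap back to the soma itself
        ep <- sg$px[vids[info$mine[info$outside[entry]]], ]
        gap_ep <- if (nrow(sp_cell)) {
          min(sqrt((sp_cell[, 1] - ep[1])^2 + (sp_cell[, 2] - ep[2])^2))
        } else 0
        if (max(ad) + gap_ep < min_len_px) { stubs <- stubs + 1L; next }
        tip <- which.max(ad)
        spth <- igraph::shortest_paths(arm, from = match(entry, av),
                                       to = tip)
        path_v <- as.integer(spth$vpath[[1]])
        poly <- sg$px[vids[info$mine[info$outside[av[path_v]]]], ,
                      drop = FALSE]
        degs <- igraph::degree(arm)
        jv <- which(degs >= 3)
        branch_count <- if (length(jv)) {
          igraph::components(igraph::induced_subgraph(arm, jv))$no
        } else 0L
        nid <- nid + 1L
        polylines[[nid]] <- poly
        nrecs[[nid]] <- data.frame(
          neurite_id = nid, cell_id = root_cell[ri],
          length_um = (max(ad) + gap_ep) * pixel_size_um,
          chord_angle_deg = polyline_chord_angle(poly),
          branch_count = as.integer(branch_count))
      }
    }
  }

  neurites <- if (length(nrecs)) do.call(rbind, nrecs) else empty$neurites
  cells <- empty_cells
  if (nrow(neurites) && n_cells > 0) {
    cnt <- tabulate(neurites$cell_id, n_cells)
    cells$n_neurites <- cnt
    cells$polarity <- ifelse(cnt == 0, "none",
                      ifelse(cnt == 1, "unipolar",
                      ifelse(cnt == 2, "bipolar", "multipolar")))
    br <- tapply(neurites$branch_count, neurites$cell_id, function(x)
      any(x > 0))
    cells$has_branched_neurite <- FALSE
    cells$has_branched_neurite[as.integer(names(br))] <- as.logical(br)
  }
  list(neurites = neurites, cells = cells, polylines = polylines,
       qc = c(discarded_components = discarded, discarded_stubs = stubs))
}

#' Neurite-only intensity image
#'
#' Retains tubulin intensities (background-subtracted) only on the dilated
#' skeleton support; soma pixels and background are zeroed. This raster is
#' the sole input to the vesselness and Fourier alignment pathways in
#' neurite-only mode.
#'
#' @param stack a [channel_stack()].
#' @param soma_labels label matrix from [segment_somata()].
#' @param skeleton logical skeleton from [detect_neurites()].
#' @param dilate_px support half-width around the skeleton.
#' @param feather_px Gaussian taper of the support edge; a hard mask edge
#'   would inject spurious perpendicular-oriented power into the Fourier
#'   pathway (0 disables).
#' @return intensity matrix, zero outside the (feathered) neurite support.
#' @export
neurite_only_image <- function(stack, soma_labels, skeleton, dilate_px = 2,
                               feather_px = 1.5) {
  stopifnot(identical(dim(stack$tubulin), dim(soma_labels)),
            identical(dim(stack$tubulin), dim(skeleton)))
  support <- dilate_mask(skeleton, dilate_px) & soma_labels == 0
  bg <- stats::median(stack$tubulin)
  out <- pmax(stack$tubulin - bg, 0)
  if (feather_px > 0) {
    # taper inward: intensities ramp down toward the support edge, but the
    # nonzero set stays inside the dilated-skeleton support
    soft <- EBImage::gblur(matrix(as.numeric(support), nrow(support)),
                           feather_px)
    out <- out * soft
  }
  out[!support] <- 0
  out
}

#' Summarize one image into a screening record
#'
#' Collapses the per-cell and per-neurite records of one field of view into
#' the per-image variable vector consumed by the statistics layer. The mean
#' neurite length is undefined (reported `NA`) when no neurite was detected.
#'
#' @param cells cell data frame from [trace_and_link()].
#' @param neurites neurite data frame from [trace_and_link()].
#' @param image_id image identifier.
#' @param pattern_name substrate name.
#' @return one-row data frame of class `screening_record` with columns
#'   image_id, pattern_name, n_cells, n_cells_with_neurites, n_neurites,
#'   mean_neurite_length_um, n_unipolar, n_bipolar, n_multipolar,
#'   branched_unipolar, branched_bipolar, branched_multipolar, and alignment
#'   columns (`NA` until filled by the alignment stage).
#' @export
summarize_image <- function(cells, neurites, image_id, pattern_name) {
  if (nrow(neurites) && !all(neurites$cell_id %in% cells$cell_id)) {
    stop("inconsistent records: neurite references a missing cell_id")
  }
  pol <- factor(cells$polarity,
                levels = c("none", "unipolar", "bipolar", "multipolar"))
  tab <- table(pol)
  branched <- vapply(c("unipolar", "bipolar", "multipolar"), function(p)
    sum(cells$has_branched_neurite[cells$polarity == p]), integer(1))
  rec <- data.frame(
    image_id = image_id, pattern_name = pattern_name,
    n_cells = nrow(cells),
    n_cells_with_neurites = sum(cells$polarity != "none"),
    n_neurites = nrow(neurites),
    mean_neurite_length_um = if (nrow(neurites)) {
      mean(neurites$length_um)
    } else NA_real_,
    n_unipolar = as.integer(tab["unipolar"]),
    n_bipolar = as.integer(tab["bipolar"]),
    n_multipolar = as.integer(tab["multipolar"]),
    branched_unipolar = branched[["unipolar"]],
    branched_bipolar = branched[["bipolar"]],
    branched_multipolar = branched[["multipolar"]],
    alignment_vesselness = NA_real_, alignment_fft = NA_real_,
    alignment_chord = NA_real_,
    stringsAsFactors = FALSE
  )
  stopifnot(
    rec$n_cells_with_neurites <= rec$n_cells,
    rec$n_unipolar + rec$n_bipolar + rec$n_multipolar ==
      rec$n_cells_with_neurites,
    rec$n_neurites >= rec$n_cells_with_neurites
  )
  class(rec) <- c("screening_record", class(rec))
  rec
}
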
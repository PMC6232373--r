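#' Per-neurite chord alignment (the manual-measurement analogue)
#'
#' The manual protocol draws a straight line from the start to the end of
#' each neurite and counts the neurite as aligned when that chord's axial
#' angle is within the cutoff of the pattern direction. This statistic is
#' per-neurite, not per-pixel, and serves as the independent cross-check of
#' the vesselness and Fourier pathways.
#'
#' @param neurites data frame with a `chord_angle_deg` column (e.g. from
#'   [trace_and_link()] or a ground-truth table).
#' @param pattern_angle_deg pattern direction in degrees.
#' @param cutoff_deg half-width of the alignment band, in (0, 90).
#' @return list with `percent_aligned` (`NA` + `undefined = TRUE` for an
#'   empty list), `n_neurites`.
#' @export
manual_chord_alignment <- function(neurites, pattern_angle_deg,
                                   cutoff_deg = 30) {
  if (cutoff_deg <= 0 || cutoff_deg >= 90) {
    stop("cutoff_deg must be in (0, 90)")
  }
  ang <- neurites$chord_angle_deg
  ang <- ang[is.finite(ang)]
  if (!length(ang)) {
    return(list(percent_aligned = NA_real_, n_neurites = 0L,
                undefined = TRUE))
  }
  list(
    percent_aligned =
      100 * mean(axial_difference(ang, pattern_angle_deg) < cutoff_deg),
    n_neurites = length(ang), undefined = FALSE
  )
}

#' Run configuration
#'
#' Single configuration object for a batch run; serializable to YAML and
#' round-trippable, so every parameter of an analysis is on record.
#'
#' @param manifest path to the manifest CSV (columns image_id, path,
#'   pattern_name, and either pattern_angle_deg or reference_path), or a
#'   data frame with those columns.
#' @param output_dir directory for tables and the QC log.
#' @param detection a [detection_params()] list.
#' @param cutoff_deg alignment band half-width (degrees).
#' @param fft_bins directionality histogram bins.
#' @param aggregation test unit for the statistics layer: "image" (each
#'   image is one observation) or "substrate" (per-substrate medians).
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(manifest, output_dir = ".",
                       detection = detection_params(), cutoff_deg = 30,
                       fft_bins = 90, aggregation = c("image", "substrate"),
                       seed = 1) {
  aggregation <- match.arg(aggregation)
  stopifnot(cutoff_deg > 0, cutoff_deg < 90, fft_bins >= 6)
  structure(list(manifest = manifest, output_dir = output_dir,
                 detection = detection, cutoff_deg = cutoff_deg,
                 fft_bins = fft_bins, aggregation = aggregation,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()] (for writing).
#' @param path YAML file path.
#' @return [read_run_config()] returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$detection <- unclass(x$detection)
  if (is.data.frame(x$manifest)) {
    stop("only file-backed manifests can be serialized to YAML")
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  det <- do.call(detection_params, lapply(x$detection, function(v)
    if (is.list(v)) unlist(v) else v))
  run_config(manifest = x$manifest, output_dir = x$output_dir,
             detection = det, cutoff_deg = x$cutoff_deg,
             fft_bins = x$fft_bins, aggregation = x$aggregation,
             seed = x$seed)
}

#' Screen a single field of view
#'
#' The complete per-image pipeline: soma segmentation, neurite skeleton
#' detection, tracing and linking, neurite-only image construction, then
#' the three alignment measurements side by side — per-pixel vesselness
#' orientation, Fourier directionality, and the per-neurite chord statistic.
#'
#' @param stack a [channel_stack()].
#' @param pattern_angle_deg pattern direction for this substrate.
#' @param image_id,pattern_name identifiers copied into the record.
#' @param params a [detection_params()].
#' @param cutoff_deg alignment band half-width.
#' @param fft_bins directionality histogram bins.
#' @return list with `record` (one screening-record row), `cells`,
#'   `neurites`, `skeleton`, `neurite_only`, `qc`.
#' @export
screen_image <- function(stack, pattern_angle_deg, image_id = "img",
                         pattern_name = "FLAT_PDMS",
                         params = detection_params(), cutoff_deg = 30,
                         fft_bins = 90) {
  seg <- segment_somata(stack, params)
  skel <- detect_neurites(stack, seg$labels, params)
  tr <- trace_and_link(skel, seg$labels, stack$pixel_size_um, params)
  nonly <- neurite_only_image(stack, seg$labels, skel)

  rec <- summarize_image(tr$cells, tr$neurites, image_id, pattern_name)
  if (any(nonly > 0)) {
    vf <- frangi_vesselness(norm01(nonly), scales = params$frangi_scales)
    av <- alignment_fraction(vf, pattern_angle_deg,
                             threshold = params$vesselness_threshold,
                             cutoff_deg = cutoff_deg)
    rec$alignment_vesselness <- av$percent_aligned
    hist <- tryCatch(directionality_histogram(nonly, n_bins = fft_bins),
                     error = function(e) NULL)
    if (!is.null(hist)) {
      rec$alignment_fft <- histogram_alignment(hist, pattern_angle_deg,
                                               cutoff_deg = cutoff_deg)
    }
  }
  ch <- manual_chord_alignment(tr$neurites, pattern_angle_deg,
                               cutoff_deg = cutoff_deg)
  rec$alignment_chord <- ch$percent_aligned
  list(record = rec, cells = tr$cells, neurites = tr$neurites,
       skeleton = skel, neurite_only = nonly, qc = tr$qc)
}

#' Run a manifest-driven batch
#'
#' Processes every manifest row with [screen_image()], derives the screening
#' variables, runs the statistics layer per variable, and writes the record
#' table, the variable table, the per-variable statistics and a QC log to
#' the output directory. Per-image failures are isolated and logged; they
#' never abort the batch. Deterministic for a fixed (config, seed).
#'
#' @param config a [run_config()]. The manifest must give, per image:
#'   `image_id`, `path` (TIFF readable by [read_channel_stack()]),
#'   `pattern_name`, and either `pattern_angle_deg` (manual, takes
#'   precedence) or `reference_path` (angle estimated with
#'   [estimate_pattern_angle()]). Flat substrates need neither.
#' @return list with `records` (data frame), `variables`, `stats` (named
#'   list of [stats_report()]s for variables with >= 2 substrates), `qc`
#'   (character vector of log lines).
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  man <- config$manifest
  if (!is.data.frame(man)) man <- utils::read.csv(man,
                                                  stringsAsFactors = FALSE)
  req <- c("image_id", "path", "pattern_name")
  if (!all(req %in% names(man))) {
    stop(sprintf("manifest must contain columns: %s",
                 paste(req, collapse = ", ")))
  }
  set.seed(config$seed)
  qc <- character(0)

  # resolve one pattern angle per substrate before any processing starts
  angles <- list()
  for (nm in unique(man$pattern_name)) {
    p <- parse_pattern_name(nm)
    rows <- man[man$pattern_name == nm, , drop = FALSE]
    manual <- if ("pattern_angle_deg" %in% names(rows)) {
      rows$pattern_angle_deg[is.finite(rows$pattern_angle_deg)]
    } else numeric(0)
    if (p$flat) {
      angles[[nm]] <- 0
    } else if (length(manual)) {
      angles[[nm]] <- manual[1]
    } else if ("reference_path" %in% names(rows) &&
               any(nzchar(rows$reference_path) &
                     !is.na(rows$reference_path))) {
      ref <- rows$reference_path[nzchar(rows$reference_path) &
                                   !is.na(rows$reference_path)][1]
      img <- tiff::readTIFF(ref)
      if (length(dim(img)) == 3) img <- img[, , 1]
      angles[[nm]] <- estimate_pattern_angle(img)
      qc <- c(qc, sprintf("substrate %s: angle %.2f deg estimated from %s",
                          nm, angles[[nm]], ref))
    } else {
      stop(sprintf(
        "configuration error: grooved substrate %s has neither a manual pattern_angle_deg nor a reference_path",
        nm))
    }
  }

  recs <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    res <- tryCatch({
      stack <- read_channel_stack(row$path)
      screen_image(stack, angles[[row$pattern_name]],
                   image_id = row$image_id, pattern_name = row$pattern_name,
                   params = config$detection, cutoff_deg = config$cutoff_deg,
                   fft_bins = config$fft_bins)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      qc <- c(qc, sprintf("image %s FAILED: %s", row$image_id,
                          conditionMessage(res)))
      next
    }
    qc <- c(qc, sprintf(
      "image %s: %d cells, %d neurites, %d unattached components, %d stubs discarded",
      row$image_id, res$record$n_cells, res$record$n_neurites,
      res$qc["discarded_components"], res$qc["discarded_stubs"]))
    recs[[length(recs) + 1]] <- res$record
  }
  if (!length(recs)) stop("no image in the manifest could be processed")
  records <- do.call(rbind, recs)

  dv <- derive_screening_variables(records)
  variables <- dv$variables
  if (config$aggregation == "substrate") {
    agg <- stats::aggregate(value ~ pattern_name + variable, variables,
                            stats::median, na.action = stats::na.omit)
    agg$image_id <- agg$pattern_name
    variables <- agg[, c("image_id", "pattern_name", "variable", "value")]
  }
  stats_out <- list()
  for (v in unique(variables$variable)) {
    g <- group_variable(variables, v)
    g <- g[lengths(g) >= 1]
    if (length(g) >= 2 && sum(lengths(g)) >= 5) {
      stats_out[[v]] <- tryCatch(stats_report(g),
                                 error = function(e) NULL)
    }
  }
  stats_out <- Filter(Negate(is.null), stats_out)

  if (!is.null(config$output_dir) && nzchar(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records,
                     file.path(config$output_dir, "screening_records.csv"),
                     row.names = FALSE)
    utils::write.csv(variables,
                     file.path(config$output_dir, "screening_variables.csv"),
                     row.names = FALSE)
    writeLines(qc, file.path(config$output_dir, "qc_log.txt"))
    if (length(stats_out)) {
      tab <- do.call(rbind, lapply(names(stats_out), function(v) {
        d <- stats_out[[v]]$dunn
        d$variable <- v
        d
      }))
      utils::write.csv(tab, file.path(config$output_dir, "dunn_posthoc.csv"),
                       row.names = FALSE)
    }
  }
  list(records = records, variables = variables, stats = stats_out, qc = qc)
}
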
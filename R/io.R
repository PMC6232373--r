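# TIFF channel-stack reading and writing.
#
# Stacks are written as 3-page 16-bit TIFFs (nuclei, actin, tubulin) with a
# JSON sidecar (<path>.json) recording the pixel size, the channel order and
# the intensity scale used for the 16-bit quantization.

#' Write a channel stack as a multi-page 16-bit TIFF
#'
#' @param stack a [channel_stack()].
#' @param path output TIFF path; a `<path>.json` sidecar is written too.
#' @param max_intensity intensity mapped to the top of the 16-bit range;
#'   defaults to the stack maximum.
#' @return `path`, invisibly.
#' @export
write_channel_stack <- function(stack, path, max_intensity = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  chans <- list(nuclei = stack$nuclei, actin = stack$actin,
                tubulin = stack$tubulin)
  if (is.null(max_intensity)) {
    max_intensity <- max(1, vapply(chans, max, numeric(1)))
  }
  pages <- lapply(chans, function(m) pmin(pmax(m / max_intensity, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         channels = names(chans), max_intensity = max_intensity),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a channel stack written by [write_channel_stack()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must be present unless
#'   `pixel_size_um` is supplied.
#' @param pixel_size_um overrides the sidecar calibration.
#' @return a [channel_stack()].
#' @export
read_channel_stack <- function(path, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3) {
    stop(sprintf("expected a 3-page TIFF (nuclei, actin, tubulin), got %d",
                 length(pages)))
  }
  side <- paste0(path, ".json")
  max_intensity <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$max_intensity)) max_intensity <- meta$max_intensity
  }
  if (is.null(pixel_size_um)) {
    stop("pixel_size_um not given and no JSON sidecar found")
  }
  channel_stack(pages[[1]] * max_intensity, pages[[2]] * max_intensity,
                pages[[3]] * max_intensity, pixel_size_um)
}

#' Write the ground truth of a synthetic scene
#'
#' One CSV row per neurite plus a JSON sidecar with the scene parameters and
#' seed, so a synthetic battery on disk is self-describing.
#'
#' @param truth ground-truth list from [generate_culture_image()].
#' @param spec the [scene_spec()] used.
#' @param seed the seed used.
#' @param csv_path output CSV path (JSON sidecar at `<csv_path>.json`).
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(truth, spec, seed, csv_path) {
  utils::write.csv(truth$neurites, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(spec), seed = seed,
         pattern_angle_deg = truth$pattern_angle_deg,
         true_aligned_fraction = truth$true_aligned_fraction,
         cells = truth$cells),
    paste0(csv_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
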
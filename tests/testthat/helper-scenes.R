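# Shared fixtures, built in code at test time.

# Analytic Gaussian-profile ridge at a given axial angle through the image
# centre: the closed-form intensity used as the independent oracle for the
# vesselness filter (no rendering involved).
analytic_ridge <- function(theta_deg, shape = c(128, 128), width = 1.5,
                           amplitude = 1) {
  th <- theta_deg * pi / 180
  rc <- (shape[1] + 1) / 2
  cc <- (shape[2] + 1) / 2
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- (c_ - cc) * sin(th) + (r - rc) * cos(th)
  list(image = amplitude * exp(-d^2 / (2 * width^2)), dist = d)
}

# Isotropic Gaussian blob of matched peak contrast.
analytic_blob <- function(shape = c(128, 128), width = 1.5, amplitude = 1) {
  rc <- (shape[1] + 1) / 2
  cc <- (shape[2] + 1) / 2
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  amplitude * exp(-((r - rc)^2 + (c_ - cc)^2) / (2 * width^2))
}

# A small culture scene shared by detection tests.
default_test_scene <- function(seed, n_cells = 5,
                               probs = c(0.2, 0.3, 0.3, 0.2), ...) {
  generate_culture_image(
    scene_spec(n_cells = n_cells, image_shape = c(384, 384),
               neurites_per_cell_probs = probs, ...),
    seed = seed)
}

# Match each true cell to the nearest detected cell (within tol px);
# returns data frame with true and detected neurite counts.
match_cells <- function(truth, seg, traced, tol = 5) {
  out <- NULL
  for (i in seq_len(nrow(truth$cells))) {
    d2 <- (seg$cells$row - truth$cells$row[i])^2 +
      (seg$cells$col - truth$cells$col[i])^2
    if (!length(d2)) next
    j <- which.min(d2)
    if (d2[j] < tol^2) {
      out <- rbind(out, data.frame(
        true_k = sum(truth$neurites$cell_id == i),
        det_k = traced$cells$n_neurites[j]))
    }
  }
  out
}

polarity_class <- function(k) {
  c("none", "unipolar", "bipolar", "multipolar")[pmin(k, 3) + 1]
}
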
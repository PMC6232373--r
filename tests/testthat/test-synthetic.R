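test_that("orientation sampling honours the mixture contract", {
  # degenerate mixture: everything concentrated at the pattern angle
  a <- sample_orientations(200, 1, 12, 1e-6, seed = 1)
  expect_true(all(abs(a - 12) < 1e-3))
  # pure isotropic component: 60/180 of the mass within any +-30 band
  u <- sample_orientations(1e5, 0, 0, 5, seed = 2)
  expect_true(all(u >= -90 & u < 90))
  expect_equal(mean(axial_difference(u, 0) < 30), 1 / 3, tolerance = 0.02)
  expect_equal(mean(axial_difference(u, 57) < 30), 1 / 3, tolerance = 0.02)
  # determinism and argument checking
  expect_identical(sample_orientations(50, .5, 10, 5, seed = 7),
                   sample_orientations(50, .5, 10, 5, seed = 7))
  expect_error(sample_orientations(-1, .5, 0, 5), "nonnegative")
  expect_identical(sample_orientations(0, .5, 0, 5, seed = 1), numeric(0))
})

test_that("empirical chord-angle distribution matches the requested mixture", {
  f <- 0.7; conc <- 5
  spec <- scene_spec(n_cells = 12, aligned_fraction = f,
                     concentration_deg = conc,
                     neurites_per_cell_probs = c(0, 0.2, 0.4, 0.4))
  chords <- unlist(lapply(1:8, function(s)
    generate_culture_image(spec, seed = s)$truth$neurites$chord_angle_deg))
  # closed-form mixture expectation of the +-30 band occupancy
  p_c <- mean(abs(wrap_axial(rnorm(1e5, 0, conc))) < 30)
  expected <- f * p_c + (1 - f) / 3
  expect_equal(mean(axial_difference(chords, 0) < 30), expected,
               tolerance = 0.08)
})

test_that("culture generation is deterministic and truth-consistent", {
  spec <- scene_spec(n_cells = 6, image_shape = c(256, 256))
  a <- generate_culture_image(spec, seed = 3)
  b <- generate_culture_image(spec, seed = 3)
  expect_identical(a$stack$tubulin, b$stack$tubulin)
  expect_identical(a$truth$neurites, b$truth$neurites)
  # every neurite references an existing cell; arc >= chord
  tr <- a$truth
  expect_true(all(tr$neurites$cell_id %in% tr$cells$cell_id))
  expect_true(all(tr$neurites$arc_length_um >=
                    tr$neurites$chord_length_um - 1e-9))
  expect_true(is.na(tr$true_aligned_fraction) ||
                (tr$true_aligned_fraction >= 0 &
                   tr$true_aligned_fraction <= 1))
})

test_that("degenerate scenes behave per contract", {
  # no cells: background + noise only, empty truth
  empty <- generate_culture_image(scene_spec(n_cells = 0,
                                             image_shape = c(64, 64)),
                                  seed = 1)
  expect_equal(nrow(empty$truth$cells), 0)
  expect_equal(nrow(empty$truth$neurites), 0)
  expect_true(all(dim(empty$stack$nuclei) == c(64, 64)))
  # forced neurite count: probability mass all on two neurites
  two <- generate_culture_image(
    scene_spec(n_cells = 4, image_shape = c(384, 384),
               neurites_per_cell_probs = c(0, 0, 1, 0)),
    seed = 2)
  counts <- table(factor(two$truth$neurites$cell_id, levels = 1:4))
  expect_true(all(counts == 2))
  # image too small for a soma
  expect_error(
    generate_culture_image(scene_spec(n_cells = 1, image_shape = c(16, 16)),
                           seed = 1),
    "too small")
})

test_that("reference edge images are reproducible and angle-validated", {
  expect_error(generate_reference_edge_image(180, c(64, 64)), "axial")
  expect_error(generate_reference_edge_image(90, c(64, 64)), "axial")
  a <- generate_reference_edge_image(7, c(128, 128), seed = 5)
  b <- generate_reference_edge_image(7, c(128, 128), seed = 5)
  expect_identical(a, b)
})

test_that("channel stacks round-trip through 16-bit TIFF", {
  gi <- generate_culture_image(scene_spec(n_cells = 3,
                                          image_shape = c(128, 128)),
                               seed = 9)
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_channel_stack(gi$stack, path)
  back <- read_channel_stack(path)
  expect_equal(back$pixel_size_um, gi$stack$pixel_size_um)
  expect_equal(dim(back$tubulin), dim(gi$stack$tubulin))
  # 16-bit quantization error only
  scale <- max(1, max(gi$stack$nuclei, gi$stack$actin, gi$stack$tubulin))
  expect_lt(max(abs(back$tubulin - gi$stack$tubulin)), scale / 65535 * 1.01)
})
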
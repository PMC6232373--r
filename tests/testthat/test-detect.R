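test_that("well-separated somata are segmented with accurate centroids", {
  gi <- default_test_scene(seed = 11)
  seg <- segment_somata(gi$stack)
  expect_equal(nrow(seg$cells), nrow(gi$truth$cells))
  expect_setequal(sort(unique(as.vector(seg$labels[seg$labels > 0]))),
                  seq_len(nrow(seg$cells)))
  for (i in seq_len(nrow(gi$truth$cells))) {
    d <- sqrt(min((seg$cells$row - gi$truth$cells$row[i])^2 +
                    (seg$cells$col - gi$truth$cells$col[i])^2))
    expect_lt(d, 3)
  }
})

test_that("background-only images yield no cells and empty skeleton", {
  gi <- generate_culture_image(scene_spec(n_cells = 0,
                                          image_shape = c(128, 128)),
                               seed = 2)
  seg <- suppressWarnings(segment_somata(gi$stack))
  expect_equal(nrow(seg$cells), 0)
  skel <- detect_neurites(gi$stack, seg$labels)
  # noise may leave a few isolated supra-threshold specks at most
  expect_lt(sum(skel), 20)
  tr <- trace_and_link(skel, seg$labels, gi$stack$pixel_size_um)
  expect_equal(nrow(tr$neurites), 0)
})

test_that("skeleton covers the true neurite paths", {
  gi <- default_test_scene(seed = 11, probs = c(0, 0.5, 0.5, 0))
  seg <- segment_somata(gi$stack)
  skel <- detect_neurites(gi$stack, seg$labels)
  # every ground-truth polyline pixel (away from the soma) should have a
  # skeleton pixel within 3 px
  sk_px <- which(skel, arr.ind = TRUE)
  covered <- 0; total <- 0
  for (k in seq_along(gi$truth$polylines)) {
    p <- gi$truth$polylines[[k]]
    cell <- gi$truth$neurites$cell_id[k]
    ctr <- gi$truth$cells[cell, ]
    away <- sqrt((p[, 1] - ctr$row)^2 + (p[, 2] - ctr$col)^2) >
      ctr$radius_px + 6
    p <- p[away, , drop = FALSE]
    if (!nrow(p)) next
    for (m in seq_len(nrow(p))) {
      total <- total + 1
      if (min((sk_px[, 1] - p[m, 1])^2 + (sk_px[, 2] - p[m, 2])^2) <= 9) {
        covered <- covered + 1
      }
    }
  }
  expect_gt(covered / total, 0.8)
})

test_that("raising the hysteresis threshold never lengthens the skeleton", {
  gi <- default_test_scene(seed = 5)
  seg <- segment_somata(gi$stack)
  lens <- vapply(c(0.15, 0.25, 0.4, 0.6), function(hi) {
    sum(detect_neurites(gi$stack, seg$labels,
                        detection_params(hysteresis_high = hi)))
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("tracing recovers polarity, lengths and branches", {
  gi <- default_test_scene(seed = 11)
  seg <- segment_somata(gi$stack)
  skel <- detect_neurites(gi$stack, seg$labels)
  tr <- trace_and_link(skel, seg$labels, gi$stack$pixel_size_um)
  # polarity invariant: class matches neurite count
  with(tr$cells, {
    expect_true(all(polarity[n_neurites == 0] == "none"))
    expect_true(all(polarity[n_neurites == 1] == "unipolar"))
    expect_true(all(polarity[n_neurites == 2] == "bipolar"))
    expect_true(all(polarity[n_neurites > 2] == "multipolar"))
  })
  # per-image mean length within 15% of truth on this scene
  expect_lt(abs(mean(tr$neurites$length_um) /
                  mean(gi$truth$neurites$arc_length_um) - 1), 0.15)
  # branched cells are flagged
  br_cells <- unique(tr$neurites$cell_id[tr$neurites$branch_count > 0])
  expect_true(all(tr$cells$has_branched_neurite[br_cells]))
  expect_error(trace_and_link(skel[1:10, 1:10], seg$labels,
                              gi$stack$pixel_size_um), "shape")
})

test_that("an empty skeleton leaves every cell with polarity none", {
  gi <- default_test_scene(seed = 11)
  seg <- segment_somata(gi$stack)
  empty <- matrix(FALSE, nrow(seg$labels), ncol(seg$labels))
  tr <- trace_and_link(empty, seg$labels, gi$stack$pixel_size_um)
  expect_equal(nrow(tr$neurites), 0)
  expect_true(all(tr$cells$polarity == "none"))
})

test_that("neurite-only images honour the masking contract", {
  gi <- default_test_scene(seed = 7)
  seg <- segment_somata(gi$stack)
  skel <- detect_neurites(gi$stack, seg$labels)
  nonly <- neurite_only_image(gi$stack, seg$labels, skel)
  # soma pixels exactly zero
  expect_true(all(nonly[seg$labels > 0] == 0))
  # nonzero support within the dilated skeleton support
  supp <- neuritescreen:::dilate_mask(skel, 2)
  expect_true(all(nonly[!supp] == 0))
  # all-background scene gives an all-zero raster
  bg <- generate_culture_image(scene_spec(n_cells = 0,
                                          image_shape = c(96, 96)), seed = 1)
  sb <- suppressWarnings(segment_somata(bg$stack))
  zero <- neurite_only_image(bg$stack, sb$labels,
                             matrix(FALSE, 96, 96))
  expect_true(all(zero == 0))
})

test_that("screening records satisfy their count identities", {
  gi <- default_test_scene(seed = 13)
  seg <- segment_somata(gi$stack)
  skel <- detect_neurites(gi$stack, seg$labels)
  tr <- trace_and_link(skel, seg$labels, gi$stack$pixel_size_um)
  rec <- summarize_image(tr$cells, tr$neurites, "img13", "D450L180")
  expect_lte(rec$n_cells_with_neurites, rec$n_cells)
  expect_equal(rec$n_unipolar + rec$n_bipolar + rec$n_multipolar,
               rec$n_cells_with_neurites)
  expect_gte(rec$n_neurites, rec$n_cells_with_neurites)
  # zero neurites: mean length missing, not zero
  rec0 <- summarize_image(
    data.frame(cell_id = 1:2, polarity = "none", n_neurites = 0,
               has_branched_neurite = FALSE),
    tr$neurites[0, ], "empty", "FLAT_PDMS")
  expect_true(is.na(rec0$mean_neurite_length_um))
  expect_error(
    summarize_image(tr$cells[0, ], tr$neurites, "bad", "FLAT_PDMS"),
    "missing cell_id")
})

test_that("crossing neurites are separated by angular continuity", {
  # two straight ridges crossing at the image centre: the skeleton graph
  # must split into two strands, not one four-armed blob
  a <- analytic_ridge(20, shape = c(96, 96), width = 1.2)$image
  b <- analytic_ridge(-50, shape = c(96, 96), width = 1.2)$image
  m <- pmax(a, b) > 0.4
  sk <- neuritescreen:::thin_mask(m)
  sg <- neuritescreen:::skeleton_graph(sk)
  res <- neuritescreen:::resolve_crossings(sg)
  comp <- igraph::components(res$g)
  big <- sum(comp$csize >= 10)
  expect_equal(big, 2)
})
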
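# Independent brute-force oracles used throughout this file: every statistic
# is recomputed from first principles (explicit rank formulas) and the
# package implementation must agree to near machine precision.

kw_brute <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(groups), function(i)
      sum(r[idx == i])^2 / sum(idx == i), numeric(1))) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

dunn_brute <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pr <- utils::combn(length(groups), 2)
  vapply(seq_len(ncol(pr)), function(k) {
    i <- pr[1, k]; j <- pr[2, k]
    (mean(r[idx == i]) - mean(r[idx == j])) /
      sqrt((n * (n + 1) / 12 - tie_term) *
             (1 / sum(idx == i) + 1 / sum(idx == j)))
  }, numeric(1))
}

spearman_brute <- function(x, y) cor(rank(x), rank(y))

quartiles_brute <- function(v) {
  # type-7 linear interpolation written out explicitly
  s <- sort(v); n <- length(s)
  one <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  c(one(.5), one(.25), one(.75))
}

test_that("Kruskal-Wallis matches the rank-sum formula", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(g)
  expect_equal(res$H, 7.2, tolerance = 1e-12)
  expect_equal(res$H, kw_brute(g), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # identical groups: H = 0
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(same)$H, 0, tolerance = 1e-12)
  # tie-corrected case against the oracle
  set.seed(3)
  gt <- list(sample(1:4, 8, TRUE), sample(1:4, 6, TRUE),
             sample(1:4, 7, TRUE))
  expect_equal(kruskal_wallis(gt)$H, kw_brute(gt), tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:5)), "2 groups")
})

test_that("rank statistics are invariant under monotone transforms and relabeling", {
  set.seed(9)
  g <- list(rnorm(8), rnorm(6, 1), rnorm(7, 2))
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, exp))$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(lapply(g, function(v) 3 * v - 10))$H, h0,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(rev(g))$H, h0, tolerance = 1e-12)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(spearman_cor(exp(x), y)$r, spearman_cor(x, y)$r,
               tolerance = 1e-12)
})

test_that("Dunn z matches brute force and adjustment never lowers p", {
  set.seed(4)
  g <- list(a = rnorm(6), b = rnorm(7, 1.5), c = sample(1:3, 6, TRUE))
  d <- dunns_posthoc(g)
  expect_equal(d$z, dunn_brute(g), tolerance = 1e-12)
  expect_true(all(d$p_adjusted >= d$p_value - 1e-15))
  expect_true(all(d$p_adjusted <= 1))
  # identical groups: nothing significant
  same <- dunns_posthoc(list(1:6, 1:6, 1:6))
  expect_false(any(same$significant))
  # none adjustment leaves p untouched
  dn <- dunns_posthoc(g, method = "none")
  expect_equal(dn$p_adjusted, dn$p_value)
})

test_that("Spearman handles ties, direction and the Fisher interval", {
  x <- 1:10
  expect_equal(spearman_cor(x, 2 * x + 3)$r, 1)
  expect_equal(spearman_cor(x, -x^3)$r, -1)
  set.seed(5)
  xt <- sample(1:4, 12, TRUE); yt <- sample(1:5, 12, TRUE)
  res <- spearman_cor(xt, yt)
  expect_equal(res$r, spearman_brute(xt, yt), tolerance = 1e-12)
  # agreement with the t-approximation p of the reference implementation
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman",
                                   exact = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
  expect_true(res$conf_int[1] <= res$r && res$r <= res$conf_int[2])
  expect_error(spearman_cor(1:5, 1:6), "equal length")
})

test_that("median and IQR follow the declared interpolation rule", {
  expect_equal(unname(summarize_median_iqr(c(1, 2, 3, 4, 5))["median"]), 3)
  expect_equal(unname(summarize_median_iqr(7)), c(7, 7, 7))
  set.seed(8)
  for (n in c(4, 9, 20)) {
    v <- rnorm(n)
    expect_equal(unname(summarize_median_iqr(v)), quartiles_brute(v),
                 tolerance = 1e-12)
  }
  expect_error(summarize_median_iqr(numeric(0)), "n >= 1")
})

test_that("Lilliefors test calibrates against its Monte-Carlo null", {
  set.seed(10)
  normal <- rnorm(500)
  res <- lilliefors_test(normal, n_mc = 2000)
  expect_gt(res$p_value, 0.05)
  uniform <- runif(500)
  expect_lt(lilliefors_test(uniform, n_mc = 2000)$p_value, 0.01)
  expect_error(lilliefors_test(rep(1, 10)), "constant")
  expect_error(lilliefors_test(c(1, 2)), "n >= 4")
  # D statistic agrees with the reference implementation
  d_ref <- nortest::lillie.test(normal)$statistic
  expect_equal(res$statistic, unname(d_ref), tolerance = 1e-12)
})

test_that("derived screening variables follow the missing-value policy", {
  rec <- rbind(
    summarize_image(
      data.frame(cell_id = 1:10,
                 polarity = c(rep("unipolar", 4), "bipolar",
                              rep("none", 5)),
                 n_neurites = c(rep(1, 4), 2, rep(0, 5)),
                 has_branched_neurite = c(TRUE, rep(FALSE, 9))),
      data.frame(neurite_id = 1:6, cell_id = c(1:4, 5, 5),
                 length_um = seq(20, 45, 5), chord_angle_deg = 0,
                 branch_count = c(1, 0, 0, 0, 0, 0)),
      "imgA", "D450L180"),
    summarize_image(
      data.frame(cell_id = 1:3, polarity = c("bipolar", "none", "none"),
                 n_neurites = c(2, 0, 0),
                 has_branched_neurite = FALSE),
      data.frame(neurite_id = 1:2, cell_id = c(1, 1),
                 length_um = c(30, 40), chord_angle_deg = 0,
                 branch_count = 0),
      "imgB", "FLAT_PDMS"))
  dv <- derive_screening_variables(rec)
  v <- dv$variables
  get <- function(img, var) v$value[v$image_id == img & v$variable == var]
  expect_equal(get("imgA", "b_over_u"), 0.25)
  expect_equal(get("imgA", "m_over_u"), 0)
  expect_equal(get("imgA", "differentiated_fraction"), 0.5)
  expect_equal(get("imgA", "branched_fraction_unipolar"), 0.25)
  # no unipolar cells: ratios missing, never infinite
  expect_true(is.na(get("imgB", "b_over_u")))
  expect_true(is.na(get("imgB", "m_over_u")))
  expect_equal(get("imgB", "differentiated_fraction"), 1 / 3)
  groups <- group_variable(v, "differentiated_fraction")
  expect_named(groups, c("D450L180", "FLAT_PDMS"))
})

test_that("zero-cell images are excluded with a QC count", {
  rec <- summarize_image(
    data.frame(cell_id = integer(0), polarity = character(0),
               n_neurites = integer(0), has_branched_neurite = logical(0)),
    data.frame(neurite_id = integer(0), cell_id = integer(0),
               length_um = numeric(0), chord_angle_deg = numeric(0),
               branch_count = integer(0)),
    "empty", "FLAT_PS")
  dv <- derive_screening_variables(rec)
  expect_equal(nrow(dv$variables), 0)
  expect_equal(unname(dv$qc["excluded_zero_cell_images"]), 1L)
})

test_that("stats_report assembles groupwise summaries", {
  set.seed(12)
  g <- list(A = rnorm(8), B = rnorm(8, 2), C = rnorm(8))
  rep <- stats_report(g, lilliefors_n_mc = 500)
  expect_s3_class(rep, "stats_report")
  expect_equal(nrow(rep$per_group), 3)
  expect_equal(nrow(rep$dunn), 3)
  expect_true(all(rep$per_group$q1 <= rep$per_group$median))
  expect_true(all(rep$per_group$median <= rep$per_group$q3))
  expect_output(print(rep), "Kruskal-Wallis")
})
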
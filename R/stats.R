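#' Lilliefors normality test with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov distance between the empirical distribution and a
#' normal with mean and sd estimated from the same sample. Because the
#' parameters are estimated, the plain KS null does not apply; the p-value
#' is calibrated by simulating the null distribution of the statistic
#' (standard-normal samples of the same size, statistic recomputed with
#' re-estimated parameters) with a fixed internal seed, so no critical-value
#' table is involved.
#'
#' @param values numeric sample, n >= 4, nonzero variance.
#' @param n_mc number of Monte-Carlo null replicates (>= 10000 by default).
#' @param mc_seed internal seed for the null simulation (fixed for
#'   reproducibility; does not touch the caller's RNG stream).
#' @return list with `statistic` (D) and `p_value`.
#' @export
lilliefors_test <- function(values, n_mc = 10000, mc_seed = 20260923) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("lilliefors_test requires n >= 4 finite values")
  if (stats::sd(values) == 0) {
    stop("degenerate input: constant sample has no normality test")
  }
  d_obs <- lillie_stat(values)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mc_seed)
  d_null <- vapply(seq_len(n_mc), function(i) {
    lillie_stat(stats::rnorm(n))
  }, numeric(1))
  list(statistic = d_obs, p_value = (1 + sum(d_null >= d_obs)) / (1 + n_mc))
}

lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction, p-value from the chi-square
#' approximation with k - 1 degrees of freedom (delegated to
#' [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 numeric samples, total n >= 5.
#' @return list with `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("kruskal_wallis requires a list of >= 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) < 1)) {
    stop("every group needs at least one value")
  }
  if (sum(lengths(groups)) < 5) stop("total sample size must be >= 5")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post hoc pairwise comparisons
#'
#' For every pair of groups, the Dunn z statistic from pooled tie-corrected
#' mean ranks,
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)},}
#' with tie term \eqn{T = \sum (t^3 - t) / (12 (N - 1))}. Two-sided p-values
#' are multiplicity-adjusted (Bonferroni over all pairs by default;
#' configurable through [stats::p.adjust()] methods).
#'
#' @param groups list of >= 2 numeric samples (named or indexed).
#' @param alpha significance level for the flags.
#' @param method multiplicity adjustment: "bonferroni" (default), "holm" or
#'   "none".
#' @return data frame with group_i, group_j, z, p_value, p_adjusted,
#'   significant.
#' @export
dunns_posthoc <- function(groups, alpha = 0.05, method = "bonferroni") {
  method <- match.arg(method, c("bonferroni", "holm", "none"))
  if (!is.list(groups) || length(groups) < 2) {
    stop("dunns_posthoc requires a list of >= 2 groups")
  }
  nm <- if (is.null(names(groups))) as.character(seq_along(groups)) else {
    names(groups)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)                      # average ranks under ties
  n_tot <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  rbar <- tapply(r, g, mean)
  ns <- lengths(groups)
  pairs <- utils::combn(length(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / ns[i] + 1 / ns[j]))
    (rbar[i] - rbar[j]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p, method = if (method == "none") "none" else {
    method
  })
  data.frame(
    group_i = nm[pairs[1, ]], group_j = nm[pairs[2, ]],
    z = as.numeric(z), p_value = as.numeric(p),
    p_adjusted = as.numeric(p_adj),
    significant = as.numeric(p_adj) < alpha,
    stringsAsFactors = FALSE
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks under ties; two-tailed p-value from
#' the t approximation with n - 2 degrees of freedom, plus an optional
#' confidence interval through the Fisher z transform (99% by default,
#' matching a screening threshold of P < 0.01).
#'
#' @param x,y numeric samples of equal length, n >= 4.
#' @param conf_level confidence level for the Fisher-transform interval.
#' @return list with `r`, `p_value`, `n`, `conf_int`.
#' @export
spearman_cor <- function(x, y, conf_level = 0.99) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_cor requires n >= 4 complete pairs")
  r <- stats::cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  ci <- if (abs(r) < 1 && n > 3) {
    zr <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    tanh(c(zr - q * se, zr + q * se))
  } else c(NA_real_, NA_real_)
  list(r = r, p_value = p, n = n, conf_int = ci)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7, the documented rule used throughout).
#'
#' @param values numeric sample, n >= 1.
#' @return named vector (median, q1, q3).
#' @export
summarize_median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("summarize_median_iqr requires n >= 1")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Derive the screening variables from per-image records
#'
#' Per image: the bipolar/unipolar and multipolar/unipolar polarity ratios
#' (undefined when there is no unipolar cell — reported missing, never
#' infinite), the branching fraction per polarity class, the differentiated
#' fraction (cells with at least one neurite over all cells), the mean
#' neurite length and the three alignment percentages. Images with zero
#' cells are excluded and counted.
#'
#' @param records data frame of screening records (rows from
#'   [summarize_image()]).
#' @return list with `variables`, a long data frame (image_id, pattern_name,
#'   variable, value), and `qc` (count of excluded zero-cell images and of
#'   missing ratios).
#' @export
derive_screening_variables <- function(records) {
  stopifnot(is.data.frame(records))
  excluded <- sum(records$n_cells == 0)
  rec <- records[records$n_cells > 0, , drop = FALSE]
  per_image <- lapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    u <- r$n_unipolar; b <- r$n_bipolar; m <- r$n_multipolar
    vals <- c(
      b_over_u = if (u > 0) b / u else NA_real_,
      m_over_u = if (u > 0) m / u else NA_real_,
      branched_fraction_unipolar = if (u > 0) r$branched_unipolar / u else
        NA_real_,
      branched_fraction_bipolar = if (b > 0) r$branched_bipolar / b else
        NA_real_,
      branched_fraction_multipolar = if (m > 0) r$branched_multipolar / m
        else NA_real_,
      differentiated_fraction = r$n_cells_with_neurites / r$n_cells,
      mean_neurite_length_um = r$mean_neurite_length_um,
      alignment_vesselness = r$alignment_vesselness,
      alignment_fft = r$alignment_fft,
      alignment_chord = r$alignment_chord
    )
    data.frame(image_id = r$image_id, pattern_name = r$pattern_name,
               variable = names(vals), value = unname(vals),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  variables <- if (length(per_image)) do.call(rbind, per_image) else {
    data.frame(image_id = character(0), pattern_name = character(0),
               variable = character(0), value = numeric(0))
  }
  list(variables = variables,
       qc = c(excluded_zero_cell_images = excluded,
              missing_values = sum(is.na(variables$value))))
}

#' Grouped values of one screening variable
#'
#' @param variables long data frame from [derive_screening_variables()].
#' @param variable variable name to extract.
#' @return named list: substrate -> numeric vector of per-image values
#'   (missing values dropped).
#' @export
group_variable <- function(variables, variable) {
  v <- variables[variables$variable == variable & !is.na(variables$value), ]
  split(v$value, v$pattern_name)
}

#' Full nonparametric statistics report for one variable
#'
#' Per-group Lilliefors normality, medians with IQR, the Kruskal-Wallis
#' omnibus test and Dunn's post hoc pairwise table.
#'
#' @param groups named list: substrate -> per-image values.
#' @param alpha significance level for the Dunn flags.
#' @param lilliefors_n_mc Monte-Carlo replicates for the normality p-values.
#' @return list of class `stats_report` with `per_group` (data frame:
#'   group, n, median, q1, q3, lilliefors_D, lilliefors_p),
#'   `kruskal_wallis`, `dunn`.
#' @export
stats_report <- function(groups, alpha = 0.05, lilliefors_n_mc = 10000) {
  stopifnot(is.list(groups), length(groups) >= 2)
  per_group <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    mi <- summarize_median_iqr(v)
    lf <- if (length(v) >= 4 && stats::sd(v) > 0) {
      lilliefors_test(v, n_mc = lilliefors_n_mc)
    } else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(group = nm, n = length(v), median = mi["median"],
               q1 = mi["q1"], q3 = mi["q3"],
               lilliefors_D = lf$statistic, lilliefors_p = lf$p_value,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(
    list(per_group = per_group,
         kruskal_wallis = kruskal_wallis(groups),
         dunn = dunns_posthoc(groups, alpha = alpha)),
    class = "stats_report"
  )
}

#' @export
print.stats_report <- function(x, ...) {
  cat("stats_report\n")
  print(x$per_group, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$kruskal_wallis$H, x$kruskal_wallis$df,
              x$kruskal_wallis$p_value))
  sig <- x$dunn[x$dunn$significant, , drop = FALSE]
  cat(sprintf("Dunn post hoc: %d/%d significant pairs\n",
              nrow(sig), nrow(x$dunn)))
  invisible(x)
}
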
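#' Agreement metrics between two aligned angle signals
#'
#' Computes the agreement battery on one aligned pair: MAE, RMSE, R-squared,
#' Spearman rank correlation, and the mean and (population) sd of the
#' per-sample differences (test - reference).
#'
#' Two R-squared readings exist in the validation literature: the squared
#' Pearson correlation between test and reference (reported here by
#' default — it measures whether the two systems follow the same trend, and
#' is the reading compatible with reporting R-squared near 1 alongside a
#' several-degree MAE) and the identity-line variant
#' `1 - SS(test - ref) / SS(ref - mean(ref))`, which also penalizes bias.
#'
#' @param pair A tibble with `reference` and `test` columns (degrees), e.g.
#'   from [aligned_pair()].
#' @param r2 `"correlation"` (default) or `"identity"`.
#' @return A one-row tibble: `mae`, `rmse`, `r2`, `spearman`, `mean_diff`,
#'   `sd_diff`, `n`, plus `angle`/`arm` and meta columns when the pair
#'   carries them.
#' @examples
#' p <- tibble::tibble(reference = c(0, 10, 20, 30), test = c(1, 12, 18, 33))
#' agreement_metrics(p)
#' @export
agreement_metrics <- function(pair, r2 = c("correlation", "identity")) {
  r2 <- match.arg(r2)
  stopifnot(all(c("reference", "test") %in% names(pair)), nrow(pair) > 0)
  ref <- pair$reference
  test <- pair$test
  d <- test - ref
  constant <- sd_pop(ref) == 0 || sd_pop(test) == 0
  if (constant) {
    warning("constant series: correlation-based metrics undefined, reported as NA")
    r2_val <- NA_real_
    rho <- NA_real_
  } else {
    r2_val <- if (r2 == "correlation") {
      cor(test, ref)^2
    } else {
      1 - sum(d^2) / sum((ref - mean(ref))^2)
    }
    rho <- cor(test, ref, method = "spearman")
  }
  meta <- attr(pair, "meta")
  tibble(
    angle = attr(pair, "angle") %||% NA_character_,
    arm = attr(pair, "arm") %||% NA_character_,
    subject = meta$subject_id %||% NA_character_,
    exercise = meta$exercise %||% NA_character_,
    distance = meta$distance %||% NA_real_,
    mae = mean(abs(d)), rmse = sqrt(mean(d^2)),
    r2 = r2_val, spearman = rho,
    mean_diff = mean(d), sd_diff = sd_pop(d), n = length(d)
  )
}

#' Bland-Altman difference-plot data
#'
#' Per-sample method difference (test - reference) against the best estimate
#' of the true value (the mean of the two methods), with the mean-difference
#' line and mean +/- sd lines used in the difference plots.
#'
#' @inheritParams agreement_metrics
#' @return A list with `points` (tibble `x`, `diff`), `mean_line`,
#'   `upper_line`, `lower_line` (degrees; population sd).
#' @export
difference_plot_data <- function(pair) {
  stopifnot(all(c("reference", "test") %in% names(pair)), nrow(pair) > 0)
  d <- pair$test - pair$reference
  m <- mean(d)
  s <- sd_pop(d)
  list(
    points = tibble(x = (pair$test + pair$reference) / 2, diff = d),
    mean_line = m, upper_line = m + s, lower_line = m - s
  )
}

new_stat_test_report <- function(test_name, statistic, p_value, groups,
                                 posthoc = NULL) {
  structure(
    list(test_name = test_name, statistic = unname(statistic),
         p_value = unname(p_value), groups = groups, posthoc = posthoc),
    class = "stat_test_report"
  )
}

#' @exportS3Method base::print
print.stat_test_report <- function(x, ...) {
  cat(sprintf("<stat_test_report> %s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc (Bonferroni-corrected):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Test for a camera-distance effect (Friedman + post-hoc)
#'
#' Friedman's nonparametric test across the three camera-distance
#' conditions on matched units (by default one summary value per subject
#' and distance, e.g. per-trial MAE), followed by post-hoc pairwise
#' Wilcoxon signed-rank tests with Bonferroni correction.
#'
#' @param values_by_distance A matrix or data frame with one column per
#'   distance condition and one row per matched unit (>= 3 units), or a
#'   named list of equal-length numeric vectors.
#' @return A `stat_test_report` with `test_name = "friedman"` and a
#'   `posthoc` tibble of pairwise Wilcoxon results.
#' @examples
#' m <- cbind(`2` = c(4, 5, 6, 7), `2.5` = c(5, 6, 7, 8), `3.5` = c(7, 8, 9, 10))
#' distance_effect_test(m)
#' @export
distance_effect_test <- function(values_by_distance) {
  if (is.list(values_by_distance) && !is.data.frame(values_by_distance)) {
    lens <- lengths(values_by_distance)
    if (length(unique(lens)) != 1) {
      stop("matched design required: unequal unit counts per distance", call. = FALSE)
    }
    values_by_distance <- do.call(cbind, values_by_distance)
  }
  m <- as.matrix(values_by_distance)
  if (anyNA(m)) stop("matched design required: missing values", call. = FALSE)
  if (nrow(m) < 3) stop("need >= 3 matched units", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  if (all(m == m[, 1])) {
    # every unit identical across conditions: no effect by definition
    ft <- list(statistic = 0, p.value = 1)
  } else {
    ft <- friedman.test(m)
  }
  combos <- utils::combn(ncol(m), 2)
  posthoc <- dplyr::bind_rows(lapply(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]
    j <- combos[2, k]
    wt <- arm_difference_test(m[, i], m[, j], exact = FALSE)
    tibble(group1 = colnames(m)[i], group2 = colnames(m)[j],
           statistic = wt$statistic, p_raw = wt$p_value)
  }))
  posthoc$p_adj <- pmin(1, posthoc$p_raw * nrow(posthoc)) # Bonferroni
  new_stat_test_report("friedman", ft$statistic, ft$p.value,
                       groups = colnames(m), posthoc = posthoc)
}

#' Test for a left-right arm difference (Wilcoxon signed rank)
#'
#' Paired Wilcoxon signed-rank test between matched samples of the two
#' arms' shoulder angles. All-zero differences are a degenerate case
#' reported with p = 1 rather than an error.
#'
#' @param x,y Matched numeric samples (e.g. alpha_L and alpha_R summaries).
#' @param exact Passed to [stats::wilcox.test()]; `NULL` (default) uses the
#'   exact distribution for small tie-free samples.
#' @return A `stat_test_report` with `test_name = "wilcoxon_signed_rank"`.
#' @export
arm_difference_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (all(x - y == 0)) {
    return(new_stat_test_report("wilcoxon_signed_rank", statistic = 0,
                                p_value = 1, groups = c("L", "R")))
  }
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact))
  new_stat_test_report("wilcoxon_signed_rank", wt$statistic, wt$p.value,
                       groups = c("L", "R"))
}

#' Normality tests on an error sample
#'
#' Shapiro-Wilk and Kolmogorov-Smirnov tests of the between-system errors.
#' The KS test uses the sample's own mean and sd (moment estimates), which
#' makes it conservative; it is included because it is the second standard
#' member of the normality battery. Shapiro-Wilk is evaluated on a
#' deterministic evenly-spaced subsample when n exceeds its 5000-sample
#' limit. A constant sample is a defined failure: both reports carry NA with
#' a warning.
#'
#' @param errors Numeric sample of errors (n >= 3).
#' @return A list of two `stat_test_report`s: `shapiro_wilk` and
#'   `kolmogorov_smirnov`.
#' @export
normality_tests <- function(errors) {
  stopifnot(length(errors) >= 3)
  if (sd_pop(errors) == 0) {
    warning("constant error sample: normality tests undefined, reported as NA")
    return(list(
      shapiro_wilk = new_stat_test_report("shapiro_wilk", NA_real_, NA_real_, "errors"),
      kolmogorov_smirnov = new_stat_test_report("kolmogorov_smirnov", NA_real_,
                                                NA_real_, "errors")
    ))
  }
  sw_sample <- if (length(errors) > 5000) {
    errors[round(seq(1, length(errors), length.out = 5000))]
  } else {
    errors
  }
  sw <- shapiro.test(sw_sample)
  ks <- suppressWarnings(ks.test(errors, "pnorm", mean(errors), sd(errors)))
  list(
    shapiro_wilk = new_stat_test_report("shapiro_wilk", sw$statistic, sw$p.value,
                                        "errors"),
    kolmogorov_smirnov = new_stat_test_report("kolmogorov_smirnov", ks$statistic,
                                              ks$p.value, "errors")
  )
}

#' Histogram counts of an angle signal
#'
#' Bins angle samples over \[0, 180\] degrees at a fixed bin width; counts
#' always sum to the sample size.
#'
#' @param x An `angle_series` (use `angle` to pick the signal) or a numeric
#'   vector of angles in degrees.
#' @param bin_width Bin width in degrees (> 0).
#' @param angle Which angle to bin when `x` is an `angle_series`.
#' @return A tibble with `bin_left`, `bin_right` and `count`.
#' @export
histogram_data <- function(x, bin_width = 5, angle = c("alpha", "beta", "gamma")) {
  if (inherits(x, "angle_series")) {
    angle <- match.arg(angle)
    x <- x$samples[[angle]]
  }
  stopifnot(is.numeric(x), length(x) > 0)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  if (any(x < 0 | x > 180)) stop("angles must lie in [0, 180] degrees", call. = FALSE)
  breaks <- unique(c(seq(0, 180, by = bin_width), 180))
  h <- hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE, right = FALSE)
  # `right = FALSE` leaves x == 180 outside the last [a, 180) bin; hist()
  # still counts it in the top bin via include.lowest on reversed intervals,
  # so re-check conservation defensively.
  counts <- h$counts
  if (sum(counts) != length(x)) counts[length(counts)] <- counts[length(counts)] +
      (length(x) - sum(counts))
  tibble(bin_left = head(breaks, -1), bin_right = breaks[-1], count = counts)
}

#' Aggregate per-trial metric reports into a summary table
#'
#' Collapses a table of per-trial [agreement_metrics()] rows into grouped
#' mean +/- sd cells (population sd across subjects), the format used for
#' cohort agreement tables.
#'
#' @param reports A tibble of metric rows (one per trial/subject).
#' @param grouping Character vector of grouping columns present in
#'   `reports` (default `c("angle", "arm", "distance")`).
#' @param metrics Metric columns to aggregate.
#' @return A tibble with one row per group and `<metric>_mean` /
#'   `<metric>_sd` columns plus `n_trials`.
#' @export
aggregate_report <- function(reports,
                             grouping = c("angle", "arm", "distance"),
                             metrics = c("mae", "rmse", "r2", "spearman")) {
  stopifnot(all(grouping %in% names(reports)))
  metrics <- intersect(metrics, names(reports))
  out <- reports |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd_pop(.x))),
      n_trials = dplyr::n(), .groups = "drop"
    )
  if (nrow(out) == 0) warning("no non-empty groups to aggregate")
  out
}
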
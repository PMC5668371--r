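#' Cortical layer assignment from recording depth
#'
#' Maps depth below the pial surface to cortical layers I, II-III, IV, V,
#' VI using half-open intervals `[lo, hi)`; the deepest boundary is closed
#' so the full `[0, 1500]` micrometre range is covered.
#'
#' @param depth_um recording depth(s) in micrometres.
#' @param boundaries a tibble with columns `layer`, `lo`, `hi` (see
#'   `default_layer_boundaries()`).
#' @return character vector of layer labels.
#' @export
#' @examples
#' assign_layer(c(0, 500, 1500))
assign_layer <- function(depth_um, boundaries = default_layer_boundaries()) {
  lo_all <- min(boundaries$lo)
  hi_all <- max(boundaries$hi)
  if (any(!is.finite(depth_um)) ||
    any(depth_um < lo_all) || any(depth_um > hi_all)) {
    abort(
      sprintf("Depth must lie within [%g, %g] um.", lo_all, hi_all),
      class = "agingV1_invalid_argument"
    )
  }
  vapply(depth_um, function(d) {
    hit <- which(
      (d >= boundaries$lo & d < boundaries$hi) |
        (d == hi_all & boundaries$hi == hi_all)
    )
    boundaries$layer[hit[1]]
  }, character(1))
}

#' @rdname assign_layer
#' @export
default_layer_boundaries <- function() {
  tibble(
    layer = c("I", "II-III", "IV", "V", "VI"),
    lo = c(0, 100, 500, 700, 1100),
    hi = c(100, 500, 700, 1100, 1500)
  )
}

#' Bin specifications for response-metric distributions
#'
#' A bin specification partitions the value range into labelled intervals
#' with explicit edge inclusivity, matching the study's printed bins (e.g.
#' OSI: `<= 0.4`, `0.4-0.65` open, `>= 0.65`). `default_bin_specs()`
#' returns the specs for OSI, DSI, OR, AR, SA and SNR; where the printed
#' text leaves a boundary unassigned (AR exactly 30, SNR exactly 10) the
#' value goes to the upper bin.
#'
#' @param name metric name.
#' @param bins tibble with columns `bin`, `lower`, `upper`, `lower_closed`,
#'   `upper_closed`; bins must be ordered and partition the range (adjacent
#'   edges shared with complementary inclusivity).
#' @return an object of class `bin_spec`.
#' @export
bin_spec <- function(name, bins) {
  stopifnot(all(c("bin", "lower", "upper", "lower_closed", "upper_closed")
  %in% names(bins)))
  n <- nrow(bins)
  if (any(bins$lower >= bins$upper)) {
    abort("Each bin must have lower < upper.",
      class = "agingV1_invalid_argument"
    )
  }
  if (n > 1) {
    touching <- bins$upper[-n] == bins$lower[-1]
    complementary <- xor(bins$upper_closed[-n], bins$lower_closed[-1])
    if (!all(touching & complementary)) {
      abort("Bins must partition the range without gaps or overlaps.",
        class = "agingV1_invalid_argument"
      )
    }
  }
  structure(list(name = name, bins = bins), class = "bin_spec")
}

#' @rdname bin_spec
#' @export
default_bin_specs <- function() {
  mk <- function(name, labels, lower, upper, lc, uc) {
    bin_spec(name, tibble(
      bin = labels, lower = lower, upper = upper,
      lower_closed = lc, upper_closed = uc
    ))
  }
  list(
    osi = mk(
      "osi", c("<=0.4", "0.4-0.65", ">=0.65"),
      c(-Inf, 0.4, 0.65), c(0.4, 0.65, Inf),
      c(FALSE, FALSE, TRUE), c(TRUE, FALSE, FALSE)
    ),
    dsi = mk(
      "dsi", c("<=0.4", "0.4-0.6", ">=0.6"),
      c(-Inf, 0.4, 0.6), c(0.4, 0.6, Inf),
      c(FALSE, FALSE, TRUE), c(TRUE, FALSE, FALSE)
    ),
    or = mk(
      "or", c("<=60", ">60"),
      c(-Inf, 60), c(60, Inf),
      c(FALSE, FALSE), c(TRUE, FALSE)
    ),
    ar = mk(
      "ar", c("<30", ">=30"),
      c(-Inf, 30), c(30, Inf),
      c(FALSE, TRUE), c(FALSE, FALSE)
    ),
    sa = mk(
      "sa", c("<5", "5-10", ">10"),
      c(-Inf, 5, 10), c(5, 10, Inf),
      c(FALSE, TRUE, FALSE), c(FALSE, TRUE, FALSE)
    ),
    snr = mk(
      "snr", c("<10", ">=10"),
      c(-Inf, 10), c(10, Inf),
      c(FALSE, TRUE), c(FALSE, FALSE)
    )
  )
}

#' Bin a metric's values into a printed-style distribution
#'
#' Assigns every value to exactly one bin of a [bin_spec()] and reports
#' counts and percentages (percent = 100 * count / n, rounded to 1
#' decimal). `NA` values are dropped with a warning; a non-missing value
#' that falls outside all bins is an error.
#'
#' @param values numeric vector.
#' @param spec a [bin_spec()].
#' @return tibble with columns `metric`, `bin`, `count`, `percent`.
#' @export
bin_distribution <- function(values, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  if (anyNA(values)) {
    warn(sprintf(
      "Dropping %d missing value(s) before binning.", sum(is.na(values))
    ))
    values <- values[!is.na(values)]
  }
  bins <- spec$bins
  assign_bin <- function(v) {
    in_bin <- (v > bins$lower | (bins$lower_closed & v == bins$lower)) &
      (v < bins$upper | (bins$upper_closed & v == bins$upper))
    hit <- which(in_bin)
    if (length(hit) != 1) {
      abort(sprintf("Value %g falls in %d bins of spec '%s'.",
        v, length(hit), spec$name
      ), class = "agingV1_invalid_argument")
    }
    hit
  }
  idx <- vapply(values, assign_bin, integer(1))
  counts <- tabulate(idx, nbins = nrow(bins))
  tibble(
    metric = spec$name,
    bin = bins$bin,
    count = counts,
    percent = round(100 * counts / length(values), 1)
  )
}

#' Pearson chi-square test on a contingency table
#'
#' The Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (rows - 1)(cols - 1)` and an upper-tail chi-square p-value (no
#' continuity correction), as used for the study's distribution
#' comparisons.
#'
#' @param table a numeric matrix (or data frame) of non-negative integer
#'   counts; rows are groups, columns are bins.
#' @return one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_test(rbind(c(10, 20), c(20, 10)))
chi_square_test <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    abort("Counts must be non-negative integers.",
      class = "agingV1_invalid_argument"
    )
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Contingency table has a zero marginal.",
      class = "agingV1_invalid_argument"
    )
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value)
  )
}

#' Two-sample t-test (Welch or pooled, one- or two-tailed)
#'
#' Wraps the standard two-sample t-test. With `tails = 1` the one-tailed
#' p-value equals half the two-tailed p when the observed effect lies in
#' the hypothesized direction (and its complement otherwise); by default
#' the hypothesized direction is the observed one.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param tails 1 or 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param alternative for `tails = 1`: `"greater"` means the mean of `a`
#'   is hypothesized larger than the mean of `b`; `"less"` the reverse;
#'   `"observed"` (default) uses the direction of the observed difference.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `tails`, `variant`.
#' @export
t_test_groups <- function(a, b, tails = 2,
                          variant = c("welch", "pooled"),
                          alternative = c("observed", "greater", "less")) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  stopifnot(tails %in% c(1, 2), length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- mean(a) == mean(b)
    return(tibble(
      statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
      df = length(a) + length(b) - 2,
      p_value = if (equal) 1 else 0,
      mean_a = mean(a), mean_b = mean(b), tails = tails, variant = variant
    ))
  }
  alt <- if (tails == 2) {
    "two.sided"
  } else if (alternative == "observed") {
    if (mean(a) >= mean(b)) "greater" else "less"
  } else {
    alternative
  }
  res <- stats::t.test(a, b, alternative = alt, var.equal = variant == "pooled")
  tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    mean_a = mean(a), mean_b = mean(b), tails = tails, variant = variant
  )
}

#' Balanced fixed-effects two-way ANOVA with interaction
#'
#' The study's design for per-AOI histology measures: two crossed fixed
#' factors (age group and cortical layer) with equal cell counts. The
#' design must be balanced — unbalanced input is rejected rather than
#' silently re-weighted. A second factor with a single level degrades
#' gracefully to one-way ANOVA on the first factor; data with no variance
#' report F = 0.
#'
#' @param data a data frame of observations.
#' @param value name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns (e.g. `"group"`
#'   and `"layer"`).
#' @return tibble with one row per effect (`factor_a`, `factor_b`,
#'   interaction): `effect`, `df1`, `df2`, `statistic`, `p_value`.
#' @export
two_way_anova <- function(data, value, factor_a, factor_b) {
  stopifnot(all(c(value, factor_a, factor_b) %in% names(data)))
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (nlevels(fa) < 2) {
    abort("The first factor needs at least two levels.",
      class = "agingV1_invalid_argument"
    )
  }
  cell_counts <- table(fa, fb)
  if (any(cell_counts == 0)) {
    abort("Empty design cell; a balanced design is required.",
      class = "agingV1_invalid_argument"
    )
  }
  if (length(unique(as.vector(cell_counts))) != 1) {
    abort("Unbalanced design; equal cell counts are required.",
      class = "agingV1_invalid_argument"
    )
  }
  df <- data.frame(y = data[[value]], A = fa, B = fb)
  # a one-level second factor reduces to one-way ANOVA on the first factor
  if (nlevels(fb) == 1) {
    if (stats::var(df$y) == 0) {
      return(tibble(
        effect = factor_a, df1 = nlevels(fa) - 1,
        df2 = nrow(df) - nlevels(fa), statistic = 0, p_value = 1
      ))
    }
    fit1 <- stats::aov(y ~ A, data = df)
    tab1 <- summary(fit1)[[1]]
    rn1 <- trimws(rownames(tab1))
    return(tibble(
      effect = factor_a,
      df1 = tab1[match("A", rn1), "Df"],
      df2 = tab1[match("Residuals", rn1), "Df"],
      statistic = tab1[match("A", rn1), "F value"],
      p_value = tab1[match("A", rn1), "Pr(>F)"]
    ))
  }
  # degenerate data (all observations equal): no variance to apportion
  if (stats::var(df$y) == 0) {
    a <- nlevels(fa)
    b <- nlevels(fb)
    return(tibble(
      effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
      df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
      df2 = rep(nrow(df) - a * b, 3),
      statistic = rep(0, 3), p_value = rep(1, 3)
    ))
  }
  fit <- stats::aov(y ~ A * B, data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  rows <- match(c("A", "B", "A:B"), rn)
  df2 <- tab[match("Residuals", rn), "Df"]
  tibble(
    effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
    df1 = tab[rows, "Df"],
    df2 = rep(df2, 3),
    statistic = tab[rows, "F value"],
    p_value = tab[rows, "Pr(>F)"]
  )
}

#' Signed percent change between two group means
#'
#' `100 * (comparison - reference) / reference`, rounded to the requested
#' number of decimals (the study reports 1 decimal, except nearest-integer
#' for the spontaneous-activity change).
#'
#' @param reference_mean baseline mean (non-zero).
#' @param comparison_mean comparison mean.
#' @param decimals decimals to round to (default 1).
#' @return signed percent change (numeric, vectorized).
#' @export
#' @examples
#' percent_change(47.1, 99.1) # +110.4
percent_change <- function(reference_mean, comparison_mean, decimals = 1) {
  if (any(reference_mean == 0)) {
    abort("`reference_mean` must be non-zero.",
      class = "agingV1_invalid_argument"
    )
  }
  round(100 * (comparison_mean - reference_mean) / reference_mean, decimals)
}

#' Group summary (mean, sample SD, n) of a metric
#'
#' Flagged/missing entries are excluded from `n`. A single defined record
#' reports SD 0 with a warning.
#'
#' @param records data frame of per-neuron (or per-AOI) records.
#' @param metric name of the numeric column to summarize.
#' @param group optional name of a grouping column; if given, one row per
#'   group is returned.
#' @return tibble with columns `metric`, (`group`,) `mean`, `sd`, `n`.
#' @export
summarize_group <- function(records, metric, group = NULL) {
  stopifnot(metric %in% names(records))
  one <- function(values) {
    values <- values[!is.na(values)]
    if (!length(values)) {
      abort(sprintf("No defined values for metric '%s'.", metric),
        class = "agingV1_invalid_argument"
      )
    }
    s <- if (length(values) == 1) {
      warn("Single record; SD reported as 0.")
      0
    } else {
      stats::sd(values)
    }
    tibble(metric = metric, mean = mean(values), sd = s, n = length(values))
  }
  if (is.null(group)) {
    return(one(records[[metric]]))
  }
  stopifnot(group %in% names(records))
  records |>
    dplyr::group_by(.g = .data[[group]]) |>
    dplyr::group_modify(~ one(.x[[metric]])) |>
    dplyr::ungroup() |>
    dplyr::rename(!!group := ".g") |>
    dplyr::select("metric", dplyr::all_of(group), "mean", "sd", "n")
}
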
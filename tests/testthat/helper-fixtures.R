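# shared fixtures built in code at test time

# noiseless tuning curve from known model parameters (response scale)
make_test_curve <- function(a0 = 0, a1 = 1, a2 = 0.3, theta0 = 90,
                            sigma = 16, sa = 0.5,
                            directions = seq(0, 345, by = 15)) {
  curve <- tibble::tibble(
    direction_deg = directions,
    mean_response = double_gaussian(directions, a0, a1, a2, theta0, sigma),
    sd_response = 0,
    n_reps = 5L
  )
  attr(curve, "sa") <- sa
  class(curve) <- c("tuning_curve", class(curve))
  curve
}

# one-row ground-truth neuron without going through a preset
make_test_neuron <- function(a1 = 50, a2 = 10, theta0 = 30, sigma = 30,
                             sa = 3, m = 0.2, id = "n1") {
  tibble::tibble(
    neuron_id = id, group = "test",
    a0_true = 0, a1_true = a1, a2_true = a2,
    theta0_true = theta0, sigma_true = sigma, sa_true = sa,
    or_true = a1 + a2 * exp(-180^2 / (2 * sigma^2)),
    osi_true = NA_real_, dsi_true = NA_real_,
    modulation_depth = m,
    cell_class_true = if (m > 1) "simple" else "complex",
    depth_um = 600
  )
}

# hand-written Pearson chi-square, the independent oracle
pearson_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# from-scratch balanced two-way ANOVA sum-of-squares decomposition
anova_ss_oracle <- function(y, a, b) {
  a <- factor(a)
  b <- factor(b)
  n <- length(y)
  gm <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  r <- n / (nlevels(a) * nlevels(b)) # reps per cell (balanced)
  ss_a <- r * nlevels(b) * sum((ma - gm)^2)
  ss_b <- r * nlevels(a) * sum((mb - gm)^2)
  cell_means <- mab[interaction(a, b)]
  ss_ab <- r * sum((tapply(y, interaction(a, b), mean) -
    rep(ma, times = nlevels(b)) -
    mb[rep(seq_len(nlevels(b)), each = nlevels(a))] + gm)^2)
  ss_res <- sum((y - cell_means)^2)
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_res <- n - nlevels(a) * nlevels(b)
  ms_res <- ss_res / df_res
  list(
    f_a = (ss_a / df_a) / ms_res,
    f_b = (ss_b / df_b) / ms_res,
    f_ab = (ss_ab / df_ab) / ms_res
  )
}
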
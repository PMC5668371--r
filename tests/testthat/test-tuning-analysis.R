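test_that("tuning curves average trials and validate their design", {
  proto <- stimulus_protocol(n_reps = 5)
  # constant evoked rate: flat curve, zero SDs
  flat <- tidyr::expand_grid(
    neuron_id = "n1", direction_deg = proto$directions, rep = 1:5
  ) |>
    dplyr::mutate(raw_rate = 12, prestim_rate = 2, evoked_rate = 10)
  curve <- build_tuning_curve(flat)
  expect_true(all(curve$mean_response == 10))
  expect_true(all(curve$sd_response == 0))
  expect_equal(attr(curve, "sa"), 2)
  # hand-built 2-rep table: means equal hand averages
  two_rep <- tidyr::expand_grid(
    direction_deg = proto$directions, rep = 1:2
  ) |>
    dplyr::mutate(
      evoked_rate = rep + direction_deg / 100,
      prestim_rate = 1, raw_rate = evoked_rate + 1
    )
  expect_warning(c2 <- build_tuning_curve(two_rep), "4-6")
  expect_equal(c2$mean_response, 1.5 + proto$directions / 100)
  # duplicated (direction, rep) rows are an integrity error
  expect_error(
    build_tuning_curve(dplyr::bind_rows(flat, flat[1, ])),
    class = "agingV1_invalid_argument"
  )
  # missing directions are listed
  expect_error(
    build_tuning_curve(dplyr::filter(flat, direction_deg != 45)),
    "45",
    class = "agingV1_invalid_argument"
  )
})

test_that("noiseless model curves are refit to their parameters", {
  curve <- make_test_curve(a0 = 0.02, a1 = 1, a2 = 0.3, theta0 = 97, sigma = 16)
  fit <- fit_double_gaussian(curve)
  expect_true(fit$accepted)
  scale <- fit$scale
  expect_lt(abs(fit$a0 * scale - 0.02), 1e-3)
  expect_lt(abs(fit$a1 * scale - 1), 1e-3)
  expect_lt(abs(fit$a2 * scale - 0.3), 1e-3)
  expect_lt(abs(wrap_angle(fit$theta0_deg - 97)), 1e-3)
  expect_lt(abs(fit$sigma_deg - 16), 1e-3)
  expect_lt(fit$mse, 1e-6)
  # at wider widths the fixed-baseline rule leaves a small, bounded bias
  wide <- make_test_curve(a0 = 0, a1 = 1, a2 = 0.3, theta0 = 90, sigma = 25)
  fw <- fit_double_gaussian(wide)
  expect_true(fw$accepted)
  expect_lt(abs(wrap_angle(fw$theta0_deg - 90)), 0.1)
  expect_lt(abs(fw$a1 * fw$scale - 1), 5e-3)
  expect_lt(abs(fw$a2 * fw$scale - 0.3), 5e-3)
  expect_lt(abs(fw$sigma_deg - 25), 0.2)
  expect_lt(fw$mse, 1e-5)
})

test_that("degenerate curves are flagged, never fit", {
  flat <- make_test_curve(a1 = 0, a2 = 0, a0 = 0.4)
  expect_false(fit_double_gaussian(flat)$accepted)
  zero <- make_test_curve(a0 = 0, a1 = 0, a2 = 0)
  f0 <- fit_double_gaussian(zero)
  expect_false(f0$accepted)
  expect_equal(f0$a1, 0)
  expect_equal(f0$a2, 0)
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_double_gaussian(make_test_curve())
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "unit") %in% names(td)))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$accepted)
})

test_that("selectivity indices implement the normalized difference", {
  # construct a fit whose R_opt is 100 and null response 30, R_spon 3.4
  curve <- make_test_curve(
    a0 = 0, a1 = 100, a2 = 30, theta0 = 90, sigma = 18, sa = 3.4
  )
  fit <- fit_double_gaussian(curve)
  idx <- selectivity_indices(fit, curve)
  expect_false(idx$flagged)
  # cross-lobe leakage at sigma = 18 is < 1e-10, so the hand value holds
  expect_equal(idx$dsi, (100 - 30) / (100 - 3.4), tolerance = 1e-3)
  # symmetric lobes: DSI = 0
  sym <- make_test_curve(a1 = 50, a2 = 50, theta0 = 45, sigma = 20, sa = 1)
  idx_sym <- selectivity_indices(fit_double_gaussian(sym), sym)
  expect_equal(idx_sym$dsi, 0, tolerance = 1e-6)
  # null below spontaneous produces a raw index above 1; clipped to 1
  clip_curve <- make_test_curve(
    a1 = 40, a2 = 0, theta0 = 0, sigma = 15, sa = 5
  )
  idx_clip <- selectivity_indices(fit_double_gaussian(clip_curve), clip_curve)
  expect_equal(idx_clip$dsi, 1)
  raw <- selectivity_indices(
    fit_double_gaussian(clip_curve), clip_curve,
    clip = FALSE
  )
  expect_gt(raw$dsi, 1)
  # optimum at or below the spontaneous rate: undefined, flagged
  weak <- make_test_curve(a1 = 2, a2 = 0, theta0 = 0, sigma = 15, sa = 10)
  expect_true(selectivity_indices(fit_double_gaussian(weak), weak)$flagged)
})

test_that("response metrics apply the 1 spike/s SNR floor", {
  curve <- make_test_curve(a1 = 20, a2 = 0, theta0 = 0, sigma = 15, sa = 0.5)
  m <- response_metrics(curve)
  expect_equal(m$or_, 20)
  expect_equal(m$snr, 20)
  # flat curve: OR equals AR
  flat <- make_test_curve(a0 = 0.7, a1 = 0, a2 = 0, sa = 2)
  mf <- response_metrics(flat)
  expect_equal(mf$or_, mf$ar)
  # toy curve: hand-computed max and mean
  toy <- make_test_curve(a1 = 0, a2 = 0, sa = 2)
  toy$mean_response <- seq(10, 240, by = 10)
  mt <- response_metrics(toy)
  expect_equal(mt$or_, 240)
  expect_equal(mt$ar, mean(seq(10, 240, by = 10)))
  expect_equal(mt$snr, 240 / 2)
})

test_that("indices and fit error are invariant to response rescaling", {
  base <- make_test_curve(
    a0 = 0.05, a1 = 1, a2 = 0.25, theta0 = 130, sigma = 20, sa = 2
  )
  scaled <- base
  scaled$mean_response <- base$mean_response * 7
  attr(scaled, "sa") <- 2 * 7
  f1 <- fit_double_gaussian(base)
  f2 <- fit_double_gaussian(scaled)
  expect_equal(f1$mse, f2$mse, tolerance = 1e-8)
  i1 <- selectivity_indices(f1, base)
  i2 <- selectivity_indices(f2, scaled)
  expect_equal(i1$osi, i2$osi, tolerance = 1e-6)
  expect_equal(i1$dsi, i2$dsi, tolerance = 1e-6)
  # SNR is scale-free once both rates are above the 1 spike/s floor
  expect_equal(
    response_metrics(base)$snr, response_metrics(scaled)$snr,
    tolerance = 1e-10
  )
})

test_that("growing the null lobe weakly decreases the direction index", {
  dsi_for_a2 <- function(a2) {
    analytic_indices(a1 = 60, a2 = a2, sigma_deg = 25, sa = 3)$dsi
  }
  vals <- vapply(seq(0, 60, by = 5), dsi_for_a2, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("a neuron with known analytic indices is recovered end to end", {
  # preset with zero SDs pins the analytic OSI at 0.80 exactly
  preset <- group_preset(
    name = "probe",
    osi_mean = 0.80, osi_sd = 0, dsi_mean = 0.5, dsi_sd = 0,
    or_mean = 80, or_sd = 0, sa_mean = 2, sa_sd = 0,
    simple_fraction = 0, n_neurons = 1
  )
  pop <- make_population(preset, seed = 5)
  expect_equal(pop$osi_true, 0.80)
  proto <- stimulus_protocol(n_reps = 6)
  sp <- simulate_trials(pop[1, ], proto, seed = 6)
  rec <- analyze_neuron(sp, proto, depth_um = pop$depth_um)
  expect_true(rec$fit_accepted)
  expect_lt(abs(rec$osi - 0.80), 0.05)
  expect_lt(abs(rec$dsi - 0.50), 0.05)
})

test_that("a neuron without evoked drive yields no indices", {
  proto <- stimulus_protocol(n_reps = 5)
  silent <- make_test_neuron(a1 = 0, a2 = 0, sa = 5, m = 0)
  sp <- simulate_trials(silent, proto, seed = 8)
  rec <- analyze_neuron(sp, proto, depth_um = 300)
  expect_true(is.na(rec$osi) && is.na(rec$dsi))
  expect_true(!rec$fit_accepted || rec$index_flagged)
  # spontaneous metrics survive the exclusion
  expect_gt(rec$sa, 0)
})

test_that("batch analysis is reproducible and carries layer labels", {
  pop <- make_population(young_preset(n_neurons = 4), seed = 10)
  proto <- stimulus_protocol(n_reps = 5)
  r1 <- analyze_population(pop, proto, seed = 20)
  r2 <- analyze_population(pop, proto, seed = 20)
  expect_identical(r1, r2)
  expect_true(all(r1$layer %in% c("I", "II-III", "IV", "V", "VI")))
  expect_identical(r1$layer, assign_layer(r1$depth_um))
})
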
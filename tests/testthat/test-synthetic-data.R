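test_that("population generation handles empty and invalid sizes", {
  expect_equal(nrow(make_population(young_preset(n_neurons = 0), seed = 1)), 0)
  expect_error(young_preset(n_neurons = -1), class = "agingV1_invalid_argument")
})

test_that("population generation is a pure function of (preset, seed)", {
  a <- make_population(old_preset(n_neurons = 25), seed = 99)
  b <- make_population(old_preset(n_neurons = 25), seed = 99)
  expect_identical(a, b)
  c <- make_population(old_preset(n_neurons = 25), seed = 100)
  expect_false(identical(a$theta0_true, c$theta0_true))
})

test_that("ground-truth draws are calibrated against analytic moments", {
  pop <- make_population(young_preset(n_neurons = 10000), seed = 1)
  # analytic OSI of the noiseless curves tracks the truncated-normal mean
  target_osi <- trunc_norm_mean(0.71, 0.18, 0, 1)
  expect_lt(abs(mean(pop$osi_true) - target_osi), 0.02)
  target_dsi <- trunc_norm_mean(0.48, 0.25, 0, 1)
  se_dsi <- sd(pop$dsi_true) / sqrt(nrow(pop))
  expect_lt(abs(mean(pop$dsi_true) - target_dsi), 3 * se_dsi + 0.005)
  # spontaneous activity: truncated normal for the young preset
  target_sa <- trunc_norm_mean(3.4, 2.6, 0, Inf)
  se_sa <- sd(pop$sa_true) / sqrt(nrow(pop))
  expect_lt(abs(mean(pop$sa_true) - target_sa), 3 * se_sa + 0.02)
  # old preset: lognormal SA moment-matched to the published moments
  pop_old <- make_population(old_preset(n_neurons = 5000), seed = 2)
  se_old <- sd(pop_old$sa_true) / sqrt(nrow(pop_old))
  expect_lt(abs(mean(pop_old$sa_true) - 24.7), 3 * se_old)
})

test_that("ground truth respects its structural invariants", {
  pop <- make_population(old_preset(n_neurons = 300), seed = 5)
  expect_true(all(pop$a1_true >= pop$a2_true))
  expect_true(all(pop$a2_true >= 0))
  expect_true(all(pop$sigma_true > 0))
  expect_true(all(pop$sa_true >= 0))
  expect_true(all(pop$osi_true >= 0 & pop$osi_true <= 1))
  expect_true(all(pop$dsi_true >= 0 & pop$dsi_true <= 1))
  expect_true(all(pop$depth_um >= 0 & pop$depth_um <= 1500))
  # the solver's curves reproduce the drawn indices exactly
  ai <- analytic_indices(pop$a1_true, pop$a2_true, pop$sigma_true, pop$sa_true)
  expect_lt(max(abs(ai$osi - pop$osi_true)), 1e-8)
  expect_lt(max(abs(ai$dsi - pop$dsi_true)), 1e-8)
})

test_that("trial simulation matches Poisson count statistics", {
  proto <- stimulus_protocol(
    stim_duration_s = 1, prestim_duration_s = 1, n_reps = 5
  )
  # zero-rate neuron emits no spikes at all
  silent <- make_test_neuron(a1 = 0, a2 = 0, sa = 0)
  expect_equal(nrow(simulate_trials(silent, proto, seed = 1)), 0)
  # untuned neuron at 5 spikes/s: 120 x 1 s stim epochs ~ Poisson(600)
  flat <- make_test_neuron(a1 = 0, a2 = 0, sa = 5, m = 0)
  sp <- simulate_trials(flat, proto, seed = 2)
  n_stim <- sum(sp$epoch == "stim")
  expect_lt(abs(n_stim - 600), 3 * sqrt(600))
  # determinism
  expect_identical(sp, simulate_trials(flat, proto, seed = 2))
})

test_that("trial rates are unbiased for homogeneous Poisson input", {
  proto <- stimulus_protocol()
  flat <- make_test_neuron(a1 = 0, a2 = 0, sa = 8, m = 0)
  sp <- simulate_trials(flat, proto, seed = 3)
  rates <- trial_rates(sp, proto)
  # 120 trials x 3 s: SE of the mean raw rate = sqrt(lambda / total time)
  se <- sqrt(8 / (nrow(rates) * proto$stim_duration_s))
  expect_lt(abs(mean(rates$raw_rate) - 8), 3 * se)
})

test_that("voltage synthesis plants recoverable templates", {
  # zero noise, zero spikes: an all-zero trace
  tr0 <- synthesize_voltage(numeric(0), duration_s = 0.1, noise_sd = 0)
  expect_true(all(tr0$samples == 0))
  # same seed, same trace
  planted <- c(0.11, 0.25, 0.42, 0.55, 0.61, 0.70, 0.78, 0.83, 0.91, 0.97)
  tr1 <- synthesize_voltage(planted, 1, amplitude = 1, noise_sd = 0.1, seed = 7)
  tr2 <- synthesize_voltage(planted, 1, amplitude = 1, noise_sd = 0.1, seed = 7)
  expect_identical(tr1$samples, tr2$samples)
  expect_error(
    synthesize_voltage(c(0.5, 2), duration_s = 1),
    class = "agingV1_invalid_argument"
  )
})

test_that("cell maps are Poisson-calibrated and keep planted truth", {
  expect_equal(
    nrow(make_cell_map(
      cell_map_spec(neun_density = 0, n_aois = 5), seed = 1
    )$cells),
    0
  )
  # published layer IV young density over 200 AOIs of 0.05 mm^2
  spec <- cell_map_spec(
    layer = "IV", neun_density = 17882, gaba_fraction = 0.168,
    aoi_area_mm2 = 0.05, n_aois = 200
  )
  map <- make_cell_map(spec, seed = 11)
  counts <- cell_map_counts(map)
  expect_equal(nrow(counts), 200)
  se <- sqrt(894.1 / 200) # Poisson mean = var
  expect_lt(abs(mean(counts$neun_count) - 894.1), 3 * se)
  # gaba_fraction = 1 double-labels every cell
  all_gaba <- make_cell_map(
    cell_map_spec(neun_density = 2000, gaba_fraction = 1, n_aois = 3),
    seed = 2
  )
  expect_true(all(all_gaba$cells$gaba))
})

test_that("blot lanes are lognormal with the requested moments", {
  spec0 <- tibble::tibble(
    group = "g", target_mean = 0.6, target_sd = 0,
    gapdh_mean = 1.2, gapdh_sd = 0
  )
  lanes0 <- make_blot_lanes(spec0, 4, seed = 1)
  expect_true(all(lanes0$target_od == 0.6))
  expect_true(all(lanes0$ratio == 0.5))
  # ratio calibrated to the published GAD67/GAPDH mean
  s <- blot_spec_for_ratio(0.872, 0.03, gapdh_cv = 0.02)
  lanes <- make_blot_lanes(
    tibble::tibble(
      group = "young", target_mean = s$target_mean, target_sd = s$target_sd,
      gapdh_mean = s$gapdh_mean, gapdh_sd = s$gapdh_sd
    ),
    1000,
    seed = 5
  )
  expect_lt(abs(mean(lanes$ratio) - 0.872), 0.01)
  expect_identical(lanes, make_blot_lanes(
    tibble::tibble(
      group = "young", target_mean = s$target_mean, target_sd = s$target_sd,
      gapdh_mean = s$gapdh_mean, gapdh_sd = s$gapdh_sd
    ),
    1000,
    seed = 5
  ))
  expect_error(
    make_blot_lanes(spec0, 0, seed = 1),
    class = "agingV1_invalid_argument"
  )
})

test_that("image rendering is seeded and respects an empty map", {
  empty <- make_cell_map(
    cell_map_spec(neun_density = 0, aoi_area_mm2 = 0.0025, n_aois = 1),
    seed = 1
  )
  img0 <- render_image(empty, noise_sd = 0, background = 0.07)
  expect_true(all(img0$neun == 0.07))
  map <- make_cell_map(
    cell_map_spec(neun_density = 300, aoi_area_mm2 = 0.0025, n_aois = 1),
    seed = 3
  )
  i1 <- render_image(map, seed = 9)
  i2 <- render_image(map, seed = 9)
  expect_identical(i1$neun, i2$neun)
  expect_identical(i1$gaba, i2$gaba)
})
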
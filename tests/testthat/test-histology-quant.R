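test_that("segmentation finds planted blobs and applies the area filter", {
  blank <- matrix(0, 60, 60)
  expect_equal(nrow(segment_cells(blank)), 0)
  # 20 well-separated blobs on a 200x200 um field
  grid <- tidyr::expand_grid(gx = seq(20, 180, by = 40), gy = seq(25, 185, by = 40))
  grid <- grid[1:20, ]
  map <- structure(
    list(
      cells = tibble::tibble(
        aoi = 1L, x_um = grid$gx, y_um = grid$gy,
        gaba = rep(c(TRUE, FALSE), 10)
      ),
      spec = cell_map_spec(neun_density = 500, aoi_area_mm2 = 0.04, n_aois = 1),
      aoi_side_um = 200
    ),
    class = "cell_map"
  )
  img <- render_image(map, blob_sigma_um = 2.5, noise_sd = 0.01, seed = 3)
  seg <- segment_cells(
    img$neun,
    intensity_threshold = 0.3, area_min_um2 = 5, area_max_um2 = 500
  )
  expect_equal(nrow(seg), 20)
  # centroids within one pixel of planted positions
  matches <- match_double_label(seg, map$cells, max_dist_um = 2)
  expect_equal(nrow(matches), 20)
  expect_lt(max(matches$dist_um), 1)
  # an object below the minimum area is excluded
  tiny <- matrix(0, 40, 40)
  tiny[5, 5] <- 1 # 1 px = 1 um^2
  tiny[20:24, 20:24] <- 1 # 25 um^2
  seg2 <- segment_cells(tiny,
    intensity_threshold = 0.5,
    area_min_um2 = 5, area_max_um2 = 100
  )
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$area_um2, 25)
})

test_that("double-label matching is greedy, capped and one-to-one", {
  pts <- tibble::tibble(x_um = c(1, 10, 20), y_um = c(1, 10, 20))
  all_m <- match_double_label(pts, pts)
  expect_equal(nrow(all_m), 3)
  expect_true(all(all_m$dist_um == 0))
  far <- tibble::tibble(x_um = c(100, 200), y_um = c(100, 200))
  expect_equal(nrow(match_double_label(pts, far)), 0)
  # planted 30% double labelling recovered as the matched fraction
  spec <- cell_map_spec(
    neun_density = 8000, gaba_fraction = 0.3, aoi_area_mm2 = 0.05, n_aois = 10
  )
  map <- make_cell_map(spec, seed = 4)
  n <- nrow(map$cells)
  matched <- match_double_label(
    map$cells, dplyr::filter(map$cells, gaba),
    max_dist_um = 0.1
  )
  frac <- nrow(matched) / n
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("AOI counting follows the inclusive-edge rule exactly", {
  pts <- tibble::tibble(
    x_um = runif(50, 0, 100), y_um = runif(50, 0, 100)
  )
  res <- count_aoi(pts, list(x_um = 0, y_um = 0, w_um = 100, h_um = 100))
  expect_equal(res$count, 50)
  expect_equal(res$density, 50 / 0.01)
  empty <- count_aoi(pts, list(x_um = 500, y_um = 500, w_um = 10, h_um = 10))
  expect_equal(empty$count, 0)
  expect_equal(empty$density, 0)
  # a centroid on a shared edge belongs to exactly one of two tiles
  edge <- tibble::tibble(x_um = 50, y_um = 10)
  left <- count_aoi(edge, list(x_um = 0, y_um = 0, w_um = 50, h_um = 100))
  right <- count_aoi(edge, list(x_um = 50, y_um = 0, w_um = 50, h_um = 100))
  expect_equal(left$count + right$count, 1)
  expect_equal(right$count, 1) # left edge inclusive
  expect_error(
    count_aoi(pts, list(x_um = 0, y_um = 0, w_um = 0, h_um = 10)),
    class = "agingV1_invalid_argument"
  )
})

test_that("density is additive over a partition of an AOI", {
  map <- make_cell_map(
    cell_map_spec(neun_density = 10000, aoi_area_mm2 = 0.04, n_aois = 1),
    seed = 9
  )
  side <- map$aoi_side_um
  whole <- count_aoi(map$cells, list(x_um = 0, y_um = 0, w_um = side, h_um = side))
  quadrants <- purrr::map_dfr(
    list(c(0, 0), c(side / 2, 0), c(0, side / 2), c(side / 2, side / 2)),
    ~ count_aoi(map$cells, list(
      x_um = .x[1], y_um = .x[2], w_um = side / 2, h_um = side / 2
    ))
  )
  expect_equal(sum(quadrants$count), whole$count)
  # densities area-weight back to the whole-AOI density
  expect_equal(
    sum(quadrants$density * quadrants$area_mm2) / whole$area_mm2,
    whole$density
  )
})

test_that("the layer table summarizes per-AOI densities and proportions", {
  # identical AOIs: zero SDs, exact proportions
  counts <- tidyr::expand_grid(
    group = c("young", "old"), layer = c("IV", "V"), aoi = 1:5
  ) |>
    dplyr::mutate(
      neun_count = 100, gaba_count = dplyr::if_else(group == "young", 17L, 5L),
      area_mm2 = 0.05
    )
  tab <- layer_density_table(counts)
  expect_true(all(tab$neun_density_sd == 0))
  expect_equal(
    tab$proportion_mean[tab$group == "young"], c(17, 17)
  )
  expect_true(all(tab$proportion_mean <= 100))
  # zero-NeuN AOIs are excluded with a warning
  counts0 <- dplyr::mutate(
    counts,
    neun_count = dplyr::if_else(aoi == 1 & group == "old", 0L, 100L),
    gaba_count = dplyr::if_else(aoi == 1 & group == "old", 0L, gaba_count)
  )
  expect_warning(tab0 <- layer_density_table(counts0), "zero NeuN")
  expect_equal(tab0$n_aois[tab0$group == "old"], c(4, 4))
  # GABA exceeding NeuN violates the subset invariant
  expect_error(
    layer_density_table(dplyr::mutate(counts, gaba_count = 200L)),
    class = "agingV1_invalid_argument"
  )
})

test_that("simulated histology recovers its planted parameters", {
  params <- tibble::tibble(
    group = c("young", "old"), layer = "IV",
    neun_density = c(17882, 17401), gaba_fraction = c(0.168, 0.051)
  )
  counts <- simulate_histology(params, seed = 6, n_aois = 61)
  tab <- layer_density_table(counts)
  y <- dplyr::filter(tab, group == "young")
  se_density <- y$neun_density_sd / sqrt(y$n_aois)
  expect_lt(abs(y$neun_density_mean - 17882), 3 * se_density)
  se_prop <- y$proportion_sd / sqrt(y$n_aois)
  expect_lt(abs(y$proportion_mean - 16.8), 3 * se_prop + 0.1)
})

test_that("fluorescence intensity subtracts background and averages AOIs", {
  uniform <- matrix(0.5, 100, 100)
  out <- fluorescence_intensity(
    uniform,
    background_mode = "constant", background = 0
  )
  expect_equal(out$mean_intensity, 0.5)
  expect_equal(out$n_aois, 30)
  # planted square patches of known intensity on a known background
  img <- matrix(0.1, 200, 200)
  aois <- tibble::tibble(
    x_um = seq(5, 180, length.out = 30) |> round(),
    y_um = rep(seq(10, 180, by = 34), 5)[1:30],
    w_um = 10, h_um = 10
  )
  for (i in seq_len(nrow(aois))) {
    ii <- (aois$x_um[i] + 1):(aois$x_um[i] + 10)
    jj <- (aois$y_um[i] + 1):(aois$y_um[i] + 10)
    img[ii, jj] <- 0.7
  }
  res <- fluorescence_intensity(img, aois = aois)
  expect_lt(abs(res$mean_intensity - 0.6), 0.01)
  expect_lt(abs(res$background - 0.1), 1e-6)
  # background at signal level: zero intensity with a warning
  expect_warning(
    flat <- fluorescence_intensity(
      matrix(0.2, 50, 50),
      background_mode = "constant", background = 0.5
    ),
    "Background"
  )
  expect_equal(flat$mean_intensity, 0)
})

test_that("blot normalization divides by the in-lane loading control", {
  lanes <- tibble::tibble(target_od = c(1, 0.6), gapdh_od = c(1, 1.2))
  expect_equal(blot_od_ratio(lanes), c(1, 0.5))
  expect_error(
    blot_od_ratio(tibble::tibble(target_od = 0, gapdh_od = 1)),
    class = "agingV1_invalid_argument"
  )
})
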
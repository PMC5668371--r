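#' Generate a synthetic double-labelled cell map
#'
#' Plants NeuN+ cell centroids as a homogeneous spatial Poisson process at
#' the specified density over each square AOI and marks each cell GABA+
#' independently with the specified probability. The planted truth (every
#' centroid and its label) is the returned object.
#'
#' @param spec a [cell_map_spec()].
#' @param seed integer seed.
#' @return an object of class `cell_map`: list with `cells` (tibble: `aoi`,
#'   `x_um`, `y_um`, `gaba`), `spec`, and `aoi_side_um`.
#' @export
#' @examples
#' map <- make_cell_map(cell_map_spec(n_aois = 3), seed = 1)
#' nrow(map$cells)
make_cell_map <- function(spec, seed) {
  stopifnot(inherits(spec, "cell_map_spec"))
  side_um <- sqrt(spec$aoi_area_mm2) * 1000
  cells <- with_seed(seed, {
    purrr::map_dfr(seq_len(spec$n_aois), function(i) {
      n <- rpois(1, spec$neun_density * spec$aoi_area_mm2)
      tibble(
        aoi = i,
        x_um = runif(n, 0, side_um),
        y_um = runif(n, 0, side_um),
        gaba = runif(n) < spec$gaba_fraction
      )
    })
  })
  structure(
    list(cells = cells, spec = spec, aoi_side_um = side_um),
    class = "cell_map"
  )
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf(
    "<cell_map layer %s> %d cells (%d GABA+) in %d AOIs of %.3f mm^2\n",
    x$spec$layer, nrow(x$cells), sum(x$cells$gaba),
    x$spec$n_aois, x$spec$aoi_area_mm2
  ))
  invisible(x)
}

#' Render a two-channel image of one AOI of a cell map
#'
#' Each cell becomes a Gaussian blob in the NeuN channel; GABA+ cells are
#' also rendered in the GABA channel. Channels are co-registered on the
#' same pixel grid; background and Gaussian noise are added. A blob whose
#' SD is below half a pixel is emitted as a single-pixel impulse.
#'
#' @param map a [make_cell_map()] object.
#' @param aoi which AOI to render.
#' @param pixel_size_um pixel pitch in micrometres.
#' @param blob_sigma_um blob SD in micrometres.
#' @param intensity peak blob intensity (per channel, length 1 or 2).
#' @param background constant background level.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed for the noise.
#' @return an object of class `cell_image`: list with `neun` and `gaba`
#'   matrices (x by y), `pixel_size_um`, and the planted `cells` tibble.
#' @export
render_image <- function(map, aoi = 1, pixel_size_um = 1,
                         blob_sigma_um = 3, intensity = 0.8,
                         background = 0.05, noise_sd = 0.02, seed = 1) {
  stopifnot(inherits(map, "cell_map"), pixel_size_um > 0)
  n_px <- max(1L, round(map$aoi_side_um / pixel_size_um))
  intensity <- rep(intensity, length.out = 2)
  cells <- dplyr::filter(map$cells, .data$aoi == !!aoi)

  blob_into <- function(img, x, y, peak) {
    if (blob_sigma_um < pixel_size_um / 2) {
      i <- min(max(floor(x / pixel_size_um) + 1, 1), n_px)
      j <- min(max(floor(y / pixel_size_um) + 1, 1), n_px)
      img[i, j] <- img[i, j] + peak
      return(img)
    }
    half <- ceiling(4 * blob_sigma_um / pixel_size_um)
    ci <- floor(x / pixel_size_um) + 1
    cj <- floor(y / pixel_size_um) + 1
    ii <- max(1, ci - half):min(n_px, ci + half)
    jj <- max(1, cj - half):min(n_px, cj + half)
    px <- (ii - 0.5) * pixel_size_um
    py <- (jj - 0.5) * pixel_size_um
    g <- outer(
      exp(-(px - x)^2 / (2 * blob_sigma_um^2)),
      exp(-(py - y)^2 / (2 * blob_sigma_um^2))
    )
    img[ii, jj] <- img[ii, jj] + peak * g
    img
  }

  neun <- matrix(background, n_px, n_px)
  gaba <- matrix(background, n_px, n_px)
  for (r in seq_len(nrow(cells))) {
    neun <- blob_into(neun, cells$x_um[r], cells$y_um[r], intensity[1])
    if (cells$gaba[r]) {
      gaba <- blob_into(gaba, cells$x_um[r], cells$y_um[r], intensity[2])
    }
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(2 * n_px * n_px, 0, noise_sd))
    neun <- neun + matrix(noise[seq_len(n_px^2)], n_px, n_px)
    gaba <- gaba + matrix(noise[n_px^2 + seq_len(n_px^2)], n_px, n_px)
  }
  structure(
    list(
      neun = pmin(pmax(neun, 0), 1), gaba = pmin(pmax(gaba, 0), 1),
      pixel_size_um = pixel_size_um, cells = cells
    ),
    class = "cell_image"
  )
}

#' Segment cells in one image channel
#'
#' Thresholds the calibrated channel, labels connected components, and
#' filters them by area, mirroring the area-filtration and
#' colour-segmentation counting workflow. Centroids are reported in
#' micrometres.
#'
#' @param channel numeric matrix (one image channel, values in `[0, 1]`).
#' @param pixel_size_um pixel pitch in micrometres.
#' @param intensity_threshold pixels strictly above this value are
#'   foreground.
#' @param area_min_um2,area_max_um2 object area bounds in square
#'   micrometres.
#' @return tibble of detected objects: `object`, `x_um`, `y_um`,
#'   `area_um2`, `mean_intensity`.
#' @export
segment_cells <- function(channel, pixel_size_um = 1,
                          intensity_threshold = 0.3,
                          area_min_um2 = 5, area_max_um2 = 1e4) {
  stopifnot(is.matrix(channel), pixel_size_um > 0)
  empty <- tibble(
    object = integer(), x_um = numeric(), y_um = numeric(),
    area_um2 = numeric(), mean_intensity = numeric()
  )
  mask <- channel > intensity_threshold
  if (!any(mask)) {
    return(empty)
  }
  if (all(mask)) {
    warn("Entire channel is above threshold; segmentation is degenerate.")
  }
  lbl <- EBImage::bwlabel(mask)
  idx <- which(lbl > 0)
  labs <- lbl[idx]
  rows <- (idx - 1) %% nrow(channel) + 1
  cols <- (idx - 1) %/% nrow(channel) + 1
  px_area <- pixel_size_um^2
  out <- tibble(
    lab = labs,
    x = (rows - 0.5) * pixel_size_um,
    y = (cols - 0.5) * pixel_size_um,
    val = channel[idx]
  ) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      x_um = mean(.data$x),
      y_um = mean(.data$y),
      area_um2 = dplyr::n() * px_area,
      mean_intensity = mean(.data$val),
      .groups = "drop"
    ) |>
    dplyr::filter(
      .data$area_um2 >= area_min_um2, .data$area_um2 <= area_max_um2
    ) |>
    dplyr::mutate(object = dplyr::row_number()) |>
    dplyr::select("object", "x_um", "y_um", "area_um2", "mean_intensity")
  out
}

#' Match objects across two channels (double labelling)
#'
#' Greedy nearest-neighbour matching of centroids under a distance cap:
#' the globally closest pair is matched first, each object at most once.
#' Used to decide which NeuN+ somata are also GABA+.
#'
#' @param objects_a,objects_b tibbles with `x_um`, `y_um` columns in the
#'   same coordinate frame.
#' @param max_dist_um matching distance cap in micrometres (default 5).
#' @return tibble of matches: `index_a`, `index_b`, `dist_um`.
#' @export
match_double_label <- function(objects_a, objects_b, max_dist_um = 5) {
  na <- nrow(objects_a)
  nb <- nrow(objects_b)
  if (na == 0 || nb == 0) {
    return(tibble(index_a = integer(), index_b = integer(), dist_um = numeric()))
  }
  d <- sqrt(
    outer(objects_a$x_um, objects_b$x_um, "-")^2 +
      outer(objects_a$y_um, objects_b$y_um, "-")^2
  )
  d[d > max_dist_um] <- Inf
  matches <- list()
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    matches[[length(matches) + 1]] <- tibble(
      index_a = k[1], index_b = k[2], dist_um = d[k[1], k[2]]
    )
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  dplyr::bind_rows(matches)
}

#' Count centroids inside an AOI and derive a density
#'
#' The boundary rule is left/top inclusive and right/bottom exclusive, so
#' tiled AOIs count every cell exactly once.
#'
#' @param objects tibble with `x_um`, `y_um` columns (detected objects or a
#'   planted cell map's cells).
#' @param aoi list or one-row data frame with `x_um`, `y_um`, `w_um`,
#'   `h_um` (rectangle origin and size in micrometres).
#' @return one-row tibble: `count`, `area_mm2`, `density` (cells/mm^2).
#' @export
count_aoi <- function(objects, aoi) {
  aoi <- as.list(aoi)
  if (aoi$w_um <= 0 || aoi$h_um <= 0) {
    abort("AOI must have positive area.", class = "agingV1_invalid_argument")
  }
  inside <- objects$x_um >= aoi$x_um & objects$x_um < aoi$x_um + aoi$w_um &
    objects$y_um >= aoi$y_um & objects$y_um < aoi$y_um + aoi$h_um
  area_mm2 <- aoi$w_um * aoi$h_um / 1e6
  count <- sum(inside)
  tibble(count = count, area_mm2 = area_mm2, density = count / area_mm2)
}

#' Per-AOI counts of a planted cell map
#'
#' Exact counting over the map's own AOIs (no rendering): one row per AOI
#' with the NeuN+ and GABA+ counts and the AOI area.
#'
#' @param map a [make_cell_map()] object.
#' @return tibble: `aoi`, `neun_count`, `gaba_count`, `area_mm2`.
#' @export
cell_map_counts <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  tibble(aoi = seq_len(map$spec$n_aois)) |>
    dplyr::left_join(
      map$cells |>
        dplyr::group_by(.data$aoi) |>
        dplyr::summarise(
          neun_count = dplyr::n(),
          gaba_count = sum(.data$gaba),
          .groups = "drop"
        ),
      by = "aoi"
    ) |>
    dplyr::mutate(
      neun_count = dplyr::coalesce(.data$neun_count, 0L),
      gaba_count = dplyr::coalesce(as.integer(.data$gaba_count), 0L),
      area_mm2 = map$spec$aoi_area_mm2
    )
}

#' Layer-wise density and proportion table
#'
#' From per-AOI NeuN and GABA counts, computes per-AOI densities and the
#' per-AOI proportion `100 * GABA / NeuN` (AOIs with zero NeuN count are
#' excluded with a warning), then summarizes mean and SD per
#' `(group, layer)` — the analogue of the study's layer table. The per-AOI
#' measurements are attached as attribute `"per_aoi"` and feed
#' [two_way_anova()].
#'
#' @param aoi_counts tibble with columns `group`, `layer`, `aoi`,
#'   `neun_count`, `gaba_count`, `area_mm2`.
#' @return tibble with one row per `(group, layer)`: NeuN and GABA density
#'   mean/SD (cells/mm^2), proportion mean/SD (%), `n_aois`.
#' @export
layer_density_table <- function(aoi_counts) {
  required <- c("group", "layer", "aoi", "neun_count", "gaba_count", "area_mm2")
  stopifnot(all(required %in% names(aoi_counts)))
  bad <- aoi_counts$gaba_count > aoi_counts$neun_count
  if (any(bad)) {
    abort("GABA+ count exceeds NeuN count in some AOI.",
      class = "agingV1_invalid_argument"
    )
  }
  zero <- aoi_counts$neun_count == 0
  if (any(zero)) {
    warn(sprintf(
      "Excluding %d AOI(s) with zero NeuN count (proportion undefined).",
      sum(zero)
    ))
  }
  per_aoi <- aoi_counts |>
    dplyr::filter(.data$neun_count > 0) |>
    dplyr::mutate(
      neun_density = .data$neun_count / .data$area_mm2,
      gaba_density = .data$gaba_count / .data$area_mm2,
      proportion = 100 * .data$gaba_count / .data$neun_count
    )
  out <- per_aoi |>
    dplyr::group_by(.data$group, .data$layer) |>
    dplyr::summarise(
      neun_density_mean = mean(.data$neun_density),
      neun_density_sd = stats::sd(.data$neun_density),
      gaba_density_mean = mean(.data$gaba_density),
      gaba_density_sd = stats::sd(.data$gaba_density),
      proportion_mean = mean(.data$proportion),
      proportion_sd = stats::sd(.data$proportion),
      n_aois = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "per_aoi") <- per_aoi
  out
}

#' Simulate per-AOI histology counts for both groups and all layers
#'
#' Builds one [make_cell_map()] per `(group, layer)` at the given planted
#' densities and GABA fractions and returns the stacked per-AOI count
#' table.
#'
#' @param layer_params tibble with columns `group`, `layer`,
#'   `neun_density`, `gaba_fraction` (see [reference_layer_table()] for the
#'   published values; `gaba_fraction` is the proportion / 100).
#' @param seed integer seed.
#' @param aoi_area_mm2,n_aois AOI geometry shared across cells of the
#'   design.
#' @return tibble of per-AOI counts (`group`, `layer`, `aoi`, `neun_count`,
#'   `gaba_count`, `area_mm2`).
#' @export
simulate_histology <- function(layer_params, seed,
                               aoi_area_mm2 = 0.05, n_aois = 61L) {
  stopifnot(all(
    c("group", "layer", "neun_density", "gaba_fraction") %in%
      names(layer_params)
  ))
  child_seeds <- with_seed(
    seed, sample.int(.Machine$integer.max - 1, nrow(layer_params))
  )
  purrr::map_dfr(seq_len(nrow(layer_params)), function(i) {
    row <- layer_params[i, ]
    map <- make_cell_map(
      cell_map_spec(
        layer = row$layer,
        neun_density = row$neun_density,
        gaba_fraction = row$gaba_fraction,
        aoi_area_mm2 = aoi_area_mm2,
        n_aois = n_aois
      ),
      seed = child_seeds[i]
    )
    cell_map_counts(map) |>
      dplyr::mutate(group = row$group, layer = row$layer, .before = 1)
  })
}

#' Mean fluorescence intensity over AOIs
#'
#' Estimates the background as the mean of the lowest-decile pixels
#' (default mode) or uses a fixed constant, subtracts it, and averages the
#' per-AOI mean intensities on a `[0, 1]` scale — the 30-AOI intensity
#' measure used for GAD65/GAD67/GABA-A receptor labelling.
#'
#' @param channel numeric matrix (one image channel in `[0, 1]`).
#' @param pixel_size_um pixel pitch in micrometres.
#' @param aois optional tibble of rectangular AOIs (`x_um`, `y_um`, `w_um`,
#'   `h_um`); if `NULL`, `n_aois` random square AOIs of side `aoi_side_um`
#'   are drawn with `seed`.
#' @param n_aois,aoi_side_um,seed random-AOI parameters (default 30 AOIs).
#' @param background_mode `"lowest_decile"` (default) or `"constant"`.
#' @param background constant background level for `"constant"` mode.
#' @return one-row tibble: `mean_intensity`, `background`, `n_aois`; the
#'   per-AOI means are attached as attribute `"per_aoi"`.
#' @export
fluorescence_intensity <- function(channel, pixel_size_um = 1, aois = NULL,
                                   n_aois = 30L, aoi_side_um = 20,
                                   seed = 1,
                                   background_mode = c(
                                     "lowest_decile", "constant"
                                   ),
                                   background = 0) {
  background_mode <- match.arg(background_mode)
  stopifnot(is.matrix(channel))
  w_um <- nrow(channel) * pixel_size_um
  h_um <- ncol(channel) * pixel_size_um
  if (is.null(aois)) {
    if (n_aois < 1) {
      abort("Need at least one AOI.", class = "agingV1_invalid_argument")
    }
    aois <- with_seed(seed, tibble(
      x_um = runif(n_aois, 0, max(w_um - aoi_side_um, 0)),
      y_um = runif(n_aois, 0, max(h_um - aoi_side_um, 0)),
      w_um = aoi_side_um, h_um = aoi_side_um
    ))
  }
  if (!nrow(aois)) {
    abort("Need at least one AOI.", class = "agingV1_invalid_argument")
  }
  bg <- if (background_mode == "lowest_decile") {
    v <- sort(as.vector(channel))
    mean(v[seq_len(max(1L, floor(length(v) / 10)))])
  } else {
    background
  }
  corrected <- pmax(channel - bg, 0)
  if (all(corrected == 0)) {
    warn("Background is at or above the signal everywhere; intensity is 0.")
  }
  aoi_mean <- function(x0, y0, w, h) {
    i <- which((seq_len(nrow(channel)) - 0.5) * pixel_size_um >= x0 &
      (seq_len(nrow(channel)) - 0.5) * pixel_size_um < x0 + w)
    j <- which((seq_len(ncol(channel)) - 0.5) * pixel_size_um >= y0 &
      (seq_len(ncol(channel)) - 0.5) * pixel_size_um < y0 + h)
    if (!length(i) || !length(j)) {
      return(NA_real_)
    }
    mean(corrected[i, j, drop = FALSE])
  }
  per_aoi <- aois |>
    dplyr::mutate(
      mean_intensity = purrr::pmap_dbl(
        list(.data$x_um, .data$y_um, .data$w_um, .data$h_um), aoi_mean
      )
    )
  out <- tibble(
    mean_intensity = mean(per_aoi$mean_intensity, na.rm = TRUE),
    background = bg,
    n_aois = sum(!is.na(per_aoi$mean_intensity))
  )
  attr(out, "per_aoi") <- per_aoi
  out
}

#' Slice-level fluorescence intensity draws
#'
#' Truncated-normal (at 0) draws of per-slice mean intensities on the
#' `[0, 1]` scale, used to emulate group comparisons of marker intensity.
#'
#' @param mean,sd target moments.
#' @param n number of slices.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
make_intensity_samples <- function(mean, sd, n, seed) {
  with_seed(seed, rtrunc_norm(n, mean, sd, 0, Inf))
}

#' Lane parameters that yield a desired normalized-OD distribution
#'
#' For lognormal target and GAPDH optical densities, the per-lane ratio is
#' again lognormal; this helper returns target-band moments such that the
#' ratio has exactly the requested mean and SD given the loading-control
#' moments.
#'
#' @param ratio_mean,ratio_sd desired moments of target/GAPDH.
#' @param gapdh_mean,gapdh_cv loading-control mean and coefficient of
#'   variation.
#' @return list with `target_mean`, `target_sd`, `gapdh_mean`, `gapdh_sd`.
#' @export
blot_spec_for_ratio <- function(ratio_mean, ratio_sd,
                                gapdh_mean = 1, gapdh_cv = 0.05) {
  stopifnot(ratio_mean > 0, ratio_sd >= 0, gapdh_mean > 0, gapdh_cv >= 0)
  s2_r <- log(1 + (ratio_sd / ratio_mean)^2)
  s2_g <- log(1 + gapdh_cv^2)
  if (s2_r < s2_g) {
    abort("Ratio SD too small for the given GAPDH variability.",
      class = "agingV1_invalid_argument"
    )
  }
  s2_t <- s2_r - s2_g
  mu_g <- log(gapdh_mean) - s2_g / 2
  mu_r <- log(ratio_mean) - s2_r / 2
  mu_t <- mu_r + mu_g
  target_mean <- exp(mu_t + s2_t / 2)
  list(
    target_mean = target_mean,
    target_sd = target_mean * sqrt(exp(s2_t) - 1),
    gapdh_mean = gapdh_mean,
    gapdh_sd = gapdh_mean * sqrt(exp(s2_g) - 1)
  )
}

#' Generate synthetic western-blot lanes
#'
#' Lognormal draws of target-band and GAPDH-band optical densities per
#' lane, moment-matched to the per-group means/SDs; with SD 0 all lanes
#' equal the means.
#'
#' @param group_specs tibble with columns `group`, `target_mean`,
#'   `target_sd`, `gapdh_mean`, `gapdh_sd` (see [blot_spec_for_ratio()]).
#' @param n_per_group lanes per group (>= 1).
#' @param seed integer seed.
#' @param target label of the target protein (e.g. `"GAD67"`).
#' @return tibble: `group`, `lane`, `target`, `target_od`, `gapdh_od`,
#'   `ratio`.
#' @export
make_blot_lanes <- function(group_specs, n_per_group, seed,
                            target = "target") {
  stopifnot(all(
    c("group", "target_mean", "target_sd", "gapdh_mean", "gapdh_sd") %in%
      names(group_specs)
  ))
  if (n_per_group < 1) {
    abort("`n_per_group` must be >= 1.", class = "agingV1_invalid_argument")
  }
  if (any(group_specs$target_mean <= 0) || any(group_specs$gapdh_mean <= 0)) {
    abort("Band OD means must be positive.",
      class = "agingV1_invalid_argument"
    )
  }
  lanes <- with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(group_specs)), function(i) {
      g <- group_specs[i, ]
      tibble(
        group = g$group,
        lane = sprintf("%s%d", toupper(substr(g$group, 1, 1)), seq_len(n_per_group)),
        target = target,
        target_od = rlnorm_moments(n_per_group, g$target_mean, g$target_sd),
        gapdh_od = rlnorm_moments(n_per_group, g$gapdh_mean, g$gapdh_sd)
      )
    })
  })
  lanes$ratio <- blot_od_ratio(lanes)
  lanes
}

#' Normalized optical density of blot lanes
#'
#' Target-band OD expressed relative to the GAPDH band of the same lane.
#'
#' @param lanes tibble with columns `target_od` and `gapdh_od` (both > 0).
#' @return numeric vector of ratios.
#' @export
blot_od_ratio <- function(lanes) {
  if (any(lanes$target_od <= 0) || any(lanes$gapdh_od <= 0)) {
    abort("Optical densities must be positive.",
      class = "agingV1_invalid_argument"
    )
  }
  lanes$target_od / lanes$gapdh_od
}
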
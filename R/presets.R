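#' Group presets for the synthetic neuron generator
#'
#' A preset is the generator's configuration surface: the target moments of
#' the orientation (OSI) and direction (DSI) selectivity indices, of the
#' optimal evoked response (OR, spikes/s) and of the spontaneous activity
#' (SA, spikes/s), the fraction of simple cells, and the population size.
#' `young_preset()` and `old_preset()` carry the published group statistics
#' of the source study (e.g. young OSI 0.71 +/- 0.18, old SA 24.7 +/- 11.7,
#' 79 vs 83 neurons).
#'
#' @param name group label, e.g. `"young"` or `"old"`.
#' @param osi_mean,osi_sd target OSI moments (dimensionless, mean in [0, 1]).
#' @param dsi_mean,dsi_sd target DSI moments (dimensionless, mean in [0, 1]).
#' @param or_mean,or_sd target optimal-response moments (spikes/s).
#' @param sa_mean,sa_sd target spontaneous-activity moments (spikes/s).
#' @param simple_fraction fraction of simple cells in [0, 1].
#' @param n_neurons population size (non-negative integer).
#' @param sa_dist distribution family for SA draws: `"truncnorm"` (normal
#'   truncated at 0; appropriate for small means) or `"lognormal"`
#'   (moment-matched; appropriate when the mean is large relative to the SD,
#'   as in the aged group).
#' @return an object of class `group_preset` (a named list).
#' @export
#' @examples
#' young_preset(n_neurons = 10)
group_preset <- function(name,
                         osi_mean, osi_sd,
                         dsi_mean, dsi_sd,
                         or_mean, or_sd,
                         sa_mean, sa_sd,
                         simple_fraction,
                         n_neurons,
                         sa_dist = c("truncnorm", "lognormal")) {
  sa_dist <- match.arg(sa_dist)
  if (n_neurons < 0) {
    abort("`n_neurons` must be >= 0.", class = "agingV1_invalid_argument")
  }
  sds <- c(osi_sd, dsi_sd, or_sd, sa_sd)
  if (any(sds < 0)) {
    abort("All preset SDs must be >= 0.", class = "agingV1_invalid_argument")
  }
  if (osi_mean < 0 || osi_mean > 1 || dsi_mean < 0 || dsi_mean > 1) {
    abort("`osi_mean` and `dsi_mean` must lie in [0, 1].",
      class = "agingV1_invalid_argument"
    )
  }
  if (simple_fraction < 0 || simple_fraction > 1) {
    abort("`simple_fraction` must lie in [0, 1].",
      class = "agingV1_invalid_argument"
    )
  }
  structure(
    list(
      name = name,
      osi_mean = osi_mean, osi_sd = osi_sd,
      dsi_mean = dsi_mean, dsi_sd = dsi_sd,
      or_mean = or_mean, or_sd = or_sd,
      sa_mean = sa_mean, sa_sd = sa_sd,
      simple_fraction = simple_fraction,
      n_neurons = as.integer(n_neurons),
      sa_dist = sa_dist
    ),
    class = "group_preset"
  )
}

#' @rdname group_preset
#' @export
young_preset <- function(n_neurons = 79L) {
  group_preset(
    name = "young",
    osi_mean = 0.71, osi_sd = 0.18,
    dsi_mean = 0.48, dsi_sd = 0.25,
    or_mean = 47.1, or_sd = 27.9,
    sa_mean = 3.4, sa_sd = 2.6,
    simple_fraction = 32 / 79,
    n_neurons = n_neurons,
    sa_dist = "truncnorm"
  )
}

#' @rdname group_preset
#' @export
old_preset <- function(n_neurons = 83L) {
  group_preset(
    name = "old",
    osi_mean = 0.48, osi_sd = 0.18,
    dsi_mean = 0.33, dsi_sd = 0.17,
    or_mean = 99.1, or_sd = 29.5,
    sa_mean = 24.7, sa_sd = 11.7,
    simple_fraction = 29 / 83,
    n_neurons = n_neurons,
    sa_dist = "lognormal"
  )
}

#' @export
print.group_preset <- function(x, ...) {
  cat(
    sprintf(
      "<group_preset '%s'> %d neurons | OSI %.2f+/-%.2f DSI %.2f+/-%.2f | OR %.1f+/-%.1f SA %.1f+/-%.1f (%s) | simple %.2f\n",
      x$name, x$n_neurons, x$osi_mean, x$osi_sd, x$dsi_mean, x$dsi_sd,
      x$or_mean, x$or_sd, x$sa_mean, x$sa_sd, x$sa_dist, x$simple_fraction
    )
  )
  invisible(x)
}

#' Stimulus protocol for drifting-grating trials
#'
#' Describes the direction-tuning protocol: 24 motion directions in 15-degree
#' steps, 4-6 repetitions per direction, a 1-s pre-stimulus window at mean
#' luminance for spontaneous activity, and the grating temporal frequency.
#'
#' @param directions stimulus motion directions in degrees; must be unique,
#'   sorted, and span `[0, 360)`.
#' @param n_reps repetitions per direction (4-6 expected; warned outside).
#' @param stim_duration_s stimulus epoch duration in seconds (default 3 s;
#'   the study only bounds it below 5 s).
#' @param prestim_duration_s pre-stimulus epoch duration in seconds (> 0).
#' @param temporal_freq_hz grating temporal frequency in Hz.
#' @return an object of class `stimulus_protocol`.
#' @export
#' @examples
#' stimulus_protocol()
stimulus_protocol <- function(directions = seq(0, 345, by = 15),
                              n_reps = 5L,
                              stim_duration_s = 3,
                              prestim_duration_s = 1,
                              temporal_freq_hz = 2) {
  if (anyDuplicated(directions) || is.unsorted(directions) ||
    any(directions < 0) || any(directions >= 360)) {
    abort("`directions` must be unique, sorted, and within [0, 360).",
      class = "agingV1_invalid_argument"
    )
  }
  if (prestim_duration_s <= 0 || stim_duration_s <= 0) {
    abort("Epoch durations must be positive.",
      class = "agingV1_invalid_argument"
    )
  }
  if (temporal_freq_hz <= 0) {
    abort("`temporal_freq_hz` must be positive.",
      class = "agingV1_invalid_argument"
    )
  }
  if (n_reps < 4 || n_reps > 6) {
    warn(sprintf("`n_reps` = %d is outside the expected 4-6 range.", n_reps))
  }
  structure(
    list(
      directions = as.numeric(directions),
      n_reps = as.integer(n_reps),
      stim_duration_s = stim_duration_s,
      prestim_duration_s = prestim_duration_s,
      temporal_freq_hz = temporal_freq_hz
    ),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %d directions x %d reps | stim %gs, prestim %gs, %g Hz\n",
    length(x$directions), x$n_reps, x$stim_duration_s,
    x$prestim_duration_s, x$temporal_freq_hz
  ))
  invisible(x)
}

#' Specification of a synthetic double-labelled cell map
#'
#' Parameters of the spatial point process that emulates NeuN/GABA double
#' labelling in one cortical layer: the planted density of NeuN+ neurons,
#' the probability that a neuron is GABA+, and the AOI (area of interest)
#' geometry over which cells are counted.
#'
#' @param layer cortical layer label: one of `"I"`, `"II-III"`, `"IV"`,
#'   `"V"`, `"VI"`.
#' @param neun_density planted NeuN+ density in cells/mm^2 (>= 0).
#' @param gaba_fraction probability that a cell is GABA+ in [0, 1].
#' @param aoi_area_mm2 area of one square AOI in mm^2.
#' @param n_aois number of AOIs sampled (default 61, which at 2 groups x 5
#'   layers reproduces the residual degrees of freedom of the study's
#'   two-way ANOVA).
#' @return an object of class `cell_map_spec`.
#' @export
cell_map_spec <- function(layer = "IV",
                          neun_density = 17882,
                          gaba_fraction = 0.168,
                          aoi_area_mm2 = 0.05,
                          n_aois = 61L) {
  layers <- c("I", "II-III", "IV", "V", "VI")
  if (!layer %in% layers) {
    abort(sprintf("`layer` must be one of %s.", paste(layers, collapse = ", ")),
      class = "agingV1_invalid_argument"
    )
  }
  if (neun_density < 0) {
    abort("`neun_density` must be >= 0.", class = "agingV1_invalid_argument")
  }
  if (gaba_fraction < 0 || gaba_fraction > 1) {
    abort("`gaba_fraction` must lie in [0, 1].",
      class = "agingV1_invalid_argument"
    )
  }
  if (aoi_area_mm2 <= 0 || n_aois < 1) {
    abort("`aoi_area_mm2` must be > 0 and `n_aois` >= 1.",
      class = "agingV1_invalid_argument"
    )
  }
  structure(
    list(
      layer = layer,
      neun_density = neun_density,
      gaba_fraction = gaba_fraction,
      aoi_area_mm2 = aoi_area_mm2,
      n_aois = as.integer(n_aois)
    ),
    class = "cell_map_spec"
  )
}
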
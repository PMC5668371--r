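#' Detect spikes in a voltage trace by threshold crossing
#'
#' An action potential is counted wherever the trace crosses
#' `mean + threshold_k * SD` upward. The event time is the crossing sample;
#' crossings closer together than the refractory period are collapsed to
#' the first.
#'
#' @param trace a [synthesize_voltage()] object (or list with `samples` and
#'   `rate_hz`).
#' @param threshold_k threshold in SD units above the trace mean (> 0).
#' @param refractory_ms refractory period in milliseconds.
#' @return a tibble with one column `time_s` (sorted crossing times).
#' @export
detect_spikes <- function(trace, threshold_k = 4, refractory_ms = 1) {
  stopifnot(threshold_k > 0)
  x <- trace$samples
  if (!length(x)) {
    abort("Voltage trace is empty.", class = "agingV1_invalid_argument")
  }
  s <- stats::sd(x)
  if (s == 0) {
    warn("Flat voltage trace (SD = 0); returning zero spikes.")
    return(tibble(time_s = numeric(0)))
  }
  thr <- mean(x) + threshold_k * s
  above <- x > thr
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  times <- (crossings - 1) / trace$rate_hz
  # collapse events within the refractory period to the first
  if (length(times) > 1) {
    keep <- logical(length(times))
    last <- -Inf
    refrac <- refractory_ms / 1000
    for (i in seq_along(times)) {
      if (times[i] - last >= refrac) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  tibble(time_s = times)
}

#' Per-trial firing rates from a long spike table
#'
#' Computes, for every `(neuron_id, direction, rep)` cell of the protocol
#' design, the raw stimulus-epoch rate, the pre-stimulus rate, and the
#' evoked rate defined as their difference (the study's response measure:
#' mean firing rate with spontaneous activity subtracted). Trials without
#' spikes are included with zero rates; negative evoked rates are preserved.
#'
#' @param spikes long spike tibble with columns `neuron_id`,
#'   `direction_deg`, `rep`, `epoch`, `spike_time_s` (see
#'   [simulate_trials()]).
#' @param protocol a [stimulus_protocol()].
#' @return a tibble with columns `neuron_id`, `direction_deg`, `rep`,
#'   `raw_rate`, `prestim_rate`, `evoked_rate` (spikes/s).
#' @export
trial_rates <- function(spikes, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  required <- c("neuron_id", "direction_deg", "rep", "epoch", "spike_time_s")
  missing_cols <- setdiff(required, names(spikes))
  if (length(missing_cols)) {
    abort(paste0(
      "Spike table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "agingV1_invalid_argument")
  }
  bad_dir <- setdiff(unique(spikes$direction_deg), protocol$directions)
  if (length(bad_dir)) {
    abort(paste0(
      "Spike table contains directions absent from the protocol: ",
      paste(bad_dir, collapse = ", ")
    ), class = "agingV1_invalid_argument")
  }
  ids <- unique(spikes$neuron_id)
  if (!length(ids)) ids <- character(0)
  design <- tidyr::expand_grid(
    neuron_id = ids,
    direction_deg = protocol$directions,
    rep = seq_len(protocol$n_reps)
  )
  counts <- spikes |>
    dplyr::count(.data$neuron_id, .data$direction_deg, .data$rep,
      .data$epoch,
      name = "n_spikes"
    ) |>
    tidyr::pivot_wider(
      names_from = "epoch", values_from = "n_spikes", values_fill = 0L
    )
  for (col in c("prestim", "stim")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  design |>
    dplyr::left_join(counts,
      by = c("neuron_id", "direction_deg", "rep")
    ) |>
    dplyr::mutate(
      prestim = dplyr::coalesce(.data$prestim, 0L),
      stim = dplyr::coalesce(.data$stim, 0L),
      raw_rate = .data$stim / protocol$stim_duration_s,
      prestim_rate = .data$prestim / protocol$prestim_duration_s,
      evoked_rate = .data$raw_rate - .data$prestim_rate
    ) |>
    dplyr::select(
      "neuron_id", "direction_deg", "rep",
      "raw_rate", "prestim_rate", "evoked_rate"
    )
}

#' F1/F0 modulation ratio and simple/complex classification
#'
#' Builds a cycle histogram of stimulus-epoch spikes at the grating temporal
#' frequency (default 32 bins per cycle; the final partial cycle is
#' discarded), takes `F0` as the spontaneous-subtracted mean evoked rate and
#' `F1` as the amplitude of the first Fourier harmonic of the histogram,
#' and classifies the cell as simple iff `F1/F0 > 1`. If the evoked mean is
#' not positive the classification is undefined and the record is flagged.
#'
#' @param spikes long spike tibble for one neuron (see [simulate_trials()]).
#' @param protocol a [stimulus_protocol()].
#' @param direction the stimulus direction (degrees) whose trials are used;
#'   by default the direction with the highest mean evoked rate.
#' @param n_bins cycle-histogram resolution (bins per cycle).
#' @param subtract_spontaneous subtract the pre-stimulus rate from `F0`
#'   (default `TRUE`, consistent with the response definition); set `FALSE`
#'   to use the raw mean rate.
#' @return a one-row tibble: `direction_deg`, `f0`, `f1`, `ratio`,
#'   `cell_class` (`"simple"`, `"complex"`, or `NA` when flagged),
#'   `flagged`.
#' @export
modulation_ratio <- function(spikes, protocol, direction = NULL,
                             n_bins = 32L, subtract_spontaneous = TRUE) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  f <- protocol$temporal_freq_hz
  rates <- trial_rates(spikes, protocol)
  if (is.null(direction)) {
    by_dir <- rates |>
      dplyr::group_by(.data$direction_deg) |>
      dplyr::summarise(mean_evoked = mean(.data$evoked_rate), .groups = "drop")
    direction <- by_dir$direction_deg[which.max(by_dir$mean_evoked)]
  }
  n_cycles <- floor(protocol$stim_duration_s * f)
  if (n_cycles < 1) {
    abort("Stimulus epoch shorter than one grating cycle.",
      class = "agingV1_invalid_argument"
    )
  }
  t_use <- n_cycles / f
  stim <- spikes |>
    dplyr::filter(
      .data$epoch == "stim",
      .data$direction_deg == !!direction,
      .data$spike_time_s < t_use
    )
  prestim_rate <- rates |>
    dplyr::summarise(m = mean(.data$prestim_rate)) |>
    dplyr::pull("m")
  n_reps <- protocol$n_reps

  phase_bin <- floor((stim$spike_time_s * f) %% 1 * n_bins) + 1
  counts <- tabulate(phase_bin, nbins = n_bins)
  bin_dur <- 1 / (f * n_bins)
  h <- counts / (n_reps * n_cycles * bin_dur) # spikes/s per phase bin
  f0_raw <- mean(h)
  f0 <- if (subtract_spontaneous) f0_raw - prestim_rate else f0_raw
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  f1 <- Mod(sum(h * exp(-2i * pi * centers))) * 2 / n_bins
  flagged <- f0 <= 0
  ratio <- if (flagged) NA_real_ else f1 / f0
  tibble(
    direction_deg = direction,
    f0 = f0, f1 = f1, ratio = ratio,
    cell_class = if (flagged) {
      NA_character_
    } else if (ratio > 1) "simple" else "complex",
    flagged = flagged
  )
}
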
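#' Simulate spike trains for one neuron under a stimulus protocol
#'
#' Draws per-trial spike times from an inhomogeneous Poisson process whose
#' rate is `max(0, sa + E(theta) * (1 + m * cos(2 pi f t)))`, where
#' `E(theta)` is the neuron's evoked tuning curve, `m` its modulation depth
#' and `f` the grating temporal frequency. Pre-stimulus spikes are
#' homogeneous Poisson at the spontaneous rate. Sampling uses thinning, so
#' the counts are exact Poisson draws for the integrated rate.
#'
#' @param neuron a one-row tibble (or list) with the ground-truth fields
#'   produced by [make_population()]: `a1_true`, `a2_true`, `theta0_true`,
#'   `sigma_true`, `sa_true`, `modulation_depth`, `neuron_id`.
#' @param protocol a [stimulus_protocol()].
#' @param seed integer seed; identical `(neuron, protocol, seed)` give
#'   identical spike tables.
#' @return a long tibble with columns `neuron_id`, `direction_deg`, `rep`,
#'   `epoch` (`"prestim"` or `"stim"`), `spike_time_s` (time within the
#'   epoch). Trials with zero spikes contribute no rows but are implied by
#'   the protocol; downstream rate computation enumerates the full design.
#' @export
#' @examples
#' pop <- make_population(young_preset(n_neurons = 1), seed = 1)
#' spikes <- simulate_trials(pop[1, ], stimulus_protocol(), seed = 2)
#' head(spikes)
simulate_trials <- function(neuron, protocol, seed) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  neuron <- as.list(as.data.frame(neuron))
  if (protocol$stim_duration_s <= 0 || protocol$prestim_duration_s <= 0) {
    abort("Epoch durations must be positive.",
      class = "agingV1_invalid_argument"
    )
  }
  f <- protocol$temporal_freq_hz
  m <- neuron$modulation_depth
  sa <- neuron$sa_true
  t_stim <- protocol$stim_duration_s
  t_pre <- protocol$prestim_duration_s

  with_seed(seed, {
    one_trial <- function(direction, rep_idx) {
      e <- evoked_curve(
        direction, neuron$theta0_true,
        neuron$a1_true, neuron$a2_true, neuron$sigma_true
      )
      # stimulus epoch: thinning against the rate envelope
      rmax <- sa + e * (1 + max(m, 0))
      stim_times <- numeric(0)
      if (rmax > 0) {
        n_cand <- rpois(1, rmax * t_stim)
        if (n_cand > 0) {
          tt <- sort(runif(n_cand, 0, t_stim))
          rate <- pmax(0, sa + e * (1 + m * cos(2 * pi * f * tt)))
          stim_times <- tt[runif(n_cand) < rate / rmax]
        }
      }
      # pre-stimulus epoch: homogeneous at the spontaneous rate
      pre_times <- numeric(0)
      if (sa > 0) {
        n_pre <- rpois(1, sa * t_pre)
        if (n_pre > 0) pre_times <- sort(runif(n_pre, 0, t_pre))
      }
      n_s <- length(stim_times)
      n_p <- length(pre_times)
      tibble(
        neuron_id = rep(neuron$neuron_id, n_p + n_s),
        direction_deg = rep(direction, n_p + n_s),
        rep = rep(rep_idx, n_p + n_s),
        epoch = c(rep("prestim", n_p), rep("stim", n_s)),
        spike_time_s = c(pre_times, stim_times)
      )
    }
    design <- tidyr::expand_grid(
      direction = protocol$directions,
      rep_idx = seq_len(protocol$n_reps)
    )
    purrr::pmap_dfr(design, one_trial)
  })
}

#' Synthesize an extracellular voltage trace from spike times
#'
#' Plants a fixed biphasic spike template (one sine cycle over the template
#' support) at each spike time on top of Gaussian noise. Overlapping
#' templates are summed, not rejected. The planted times are retained as
#' ground truth so threshold-based spike detection can be validated.
#'
#' @param spike_times_s spike times in seconds, all within `duration_s`.
#' @param duration_s trace duration in seconds.
#' @param rate_hz sampling rate in Hz (default 20 kHz).
#' @param amplitude template peak amplitude (same units as `noise_sd`).
#' @param noise_sd Gaussian noise SD.
#' @param template_ms template support in milliseconds.
#' @param seed integer seed for the noise.
#' @return an object of class `voltage_trace`: list with `samples`,
#'   `rate_hz`, `duration_s`, and `planted_times_s`.
#' @export
synthesize_voltage <- function(spike_times_s, duration_s, rate_hz = 20000,
                               amplitude = 1, noise_sd = 0.1,
                               template_ms = 1.2, seed = 1) {
  if (duration_s <= 0 || rate_hz < 10000) {
    abort("`duration_s` must be > 0 and `rate_hz` >= 10 kHz.",
      class = "agingV1_invalid_argument"
    )
  }
  if (length(spike_times_s) &&
    (any(spike_times_s < 0) || any(spike_times_s >= duration_s))) {
    abort("All spike times must lie within [0, duration_s).",
      class = "agingV1_invalid_argument"
    )
  }
  n <- round(duration_s * rate_hz)
  n_t <- max(2L, round(template_ms / 1000 * rate_hz))
  template <- amplitude * sin(2 * pi * seq(0, 1, length.out = n_t))
  samples <- with_seed(seed, {
    if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  })
  for (t0 in spike_times_s) {
    i0 <- floor(t0 * rate_hz) + 1
    idx <- i0:min(i0 + n_t - 1, n)
    samples[idx] <- samples[idx] + template[seq_along(idx)]
  }
  structure(
    list(
      samples = samples, rate_hz = rate_hz, duration_s = duration_s,
      planted_times_s = sort(spike_times_s)
    ),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %.3f s @ %g Hz (%d samples), %d planted spikes\n",
    x$duration_s, x$rate_hz, length(x$samples), length(x$planted_times_s)
  ))
  invisible(x)
}
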
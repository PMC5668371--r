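#' Evoked direction-tuning curve (two Gaussian lobes)
#'
#' The noiseless evoked rate of a model neuron as a function of motion
#' direction: two Gaussian lobes of shared width `sigma` centred on the
#' preferred direction and on the opposite (null) direction, with angular
#' distances wrapped to the shortest arc.
#'
#' @param theta_deg stimulus motion directions (degrees).
#' @param theta_pref_deg preferred direction (degrees).
#' @param a1,a2 lobe amplitudes (spikes/s), `a1 >= a2 >= 0`.
#' @param sigma_deg shared Gaussian width (degrees, > 0).
#' @return evoked rate in spikes/s at each `theta_deg`.
#' @export
evoked_curve <- function(theta_deg, theta_pref_deg, a1, a2, sigma_deg) {
  d1 <- wrap_angle(theta_deg - theta_pref_deg)
  d2 <- wrap_angle(theta_deg - theta_pref_deg - 180)
  a1 * exp(-d1^2 / (2 * sigma_deg^2)) + a2 * exp(-d2^2 / (2 * sigma_deg^2))
}

#' Analytic selectivity indices of a noiseless model neuron
#'
#' Evaluates the orientation and direction selectivity indices
#' `(R_opt - R_null) / (R_opt - R_spon)` on the noiseless evoked curve:
#' the orientation null is the mean response 90 degrees either side of the
#' preferred direction, the direction null is the opposite direction, and
#' `R_spon` is the spontaneous rate.
#'
#' @inheritParams evoked_curve
#' @param sa spontaneous rate (spikes/s).
#' @return named list with `osi`, `dsi`, `r_opt`.
#' @export
analytic_indices <- function(a1, a2, sigma_deg, sa) {
  w90 <- exp(-90^2 / (2 * sigma_deg^2))
  w180 <- exp(-180^2 / (2 * sigma_deg^2))
  r_opt <- a1 + a2 * w180
  e90 <- (a1 + a2) * w90
  e180 <- a1 * w180 + a2
  denom <- r_opt - sa
  list(
    osi = (r_opt - e90) / denom,
    dsi = (r_opt - e180) / denom,
    r_opt = r_opt
  )
}

# Invert the analytic indices: given target (osi, dsi), peak evoked rate and
# spontaneous rate, solve for (a1, a2, sigma). The cross-lobe leakage
# w180 = w90^4 couples the equations, so a short fixed-point iteration is
# used; it contracts rapidly because w180 << 1 for all realistic widths.
solve_tuning_params <- function(osi, dsi, r_opt, sa,
                                tol = 1e-12, max_iter = 100L) {
  if (r_opt <= sa) {
    return(NULL)
  }
  denom <- r_opt - sa
  e90 <- r_opt - osi * denom
  e180 <- r_opt - dsi * denom
  k <- 0
  sigma <- NA_real_
  for (i in seq_len(max_iter)) {
    a1 <- (r_opt - k * e180) / (1 - k^2)
    a2 <- (e180 - k * r_opt) / (1 - k^2)
    if (a2 < 0 || a1 < a2) {
      return(NULL)
    }
    w90 <- e90 / (a1 + a2)
    if (w90 <= 0 || w90 >= 1) {
      return(NULL)
    }
    sigma_new <- sqrt(-90^2 / (2 * log(w90)))
    k_new <- w90^4
    converged <- is.finite(sigma) && abs(sigma_new - sigma) < tol
    sigma <- sigma_new
    k <- k_new
    if (converged) break
  }
  list(a1 = a1, a2 = a2, sigma = sigma)
}

#' Generate a synthetic neuron population from a group preset
#'
#' Draws per-neuron ground-truth tuning parameters so that the *analytic*
#' OSI and DSI of each noiseless tuning curve follow truncated-normal
#' distributions with the preset's moments (clipped to `[0, 1]`), the peak
#' evoked rate follows the preset's OR moments, and spontaneous activity
#' follows the preset's SA distribution (truncated normal or moment-matched
#' lognormal). Amplitudes and width are solved in closed form from the
#' target indices, which makes downstream parameter-recovery checks
#' well-posed. Draws that admit no amplitude solution (e.g. peak rate below
#' the spontaneous rate) are rejected and redrawn, up to a bounded number of
#' attempts.
#'
#' @param preset a [group_preset()].
#' @param seed integer seed; the same `(preset, seed)` pair always returns
#'   an identical population.
#' @param max_retries bound on redraws per neuron before erroring.
#' @return a tibble with one row per neuron: identifiers, ground-truth
#'   tuning parameters (`a0_true`, `a1_true`, `a2_true`, `theta0_true`,
#'   `sigma_true`, `sa_true`), the analytic `osi_true`/`dsi_true`/`or_true`,
#'   `modulation_depth`, `cell_class_true`, and recording `depth_um`.
#' @export
#' @examples
#' pop <- make_population(young_preset(n_neurons = 5), seed = 1)
#' pop[, c("neuron_id", "osi_true", "dsi_true", "sa_true")]
make_population <- function(preset, seed, max_retries = 50L) {
  stopifnot(inherits(preset, "group_preset"))
  n <- preset$n_neurons
  empty <- tibble(
    neuron_id = character(), group = character(),
    a0_true = numeric(), a1_true = numeric(), a2_true = numeric(),
    theta0_true = numeric(), sigma_true = numeric(), sa_true = numeric(),
    or_true = numeric(), osi_true = numeric(), dsi_true = numeric(),
    modulation_depth = numeric(), cell_class_true = character(),
    depth_um = numeric()
  )
  if (n == 0L) {
    return(empty)
  }
  with_seed(seed, {
    draw_one <- function(i) {
      for (attempt in seq_len(max_retries)) {
        osi <- rtrunc_norm(1, preset$osi_mean, preset$osi_sd, 0, 1)
        dsi <- rtrunc_norm(1, preset$dsi_mean, preset$dsi_sd, 0, 1)
        r_opt <- rtrunc_norm(1, preset$or_mean, preset$or_sd, 0.5, Inf)
        sa <- if (preset$sa_dist == "lognormal") {
          rlnorm_moments(1, preset$sa_mean, preset$sa_sd)
        } else {
          rtrunc_norm(1, preset$sa_mean, preset$sa_sd, 0, Inf)
        }
        if (r_opt <= sa + 0.5) next
        # keep indices strictly below 1 so the width equation stays solvable
        osi <- min(osi, 0.995)
        dsi <- min(dsi, 0.995)
        par <- solve_tuning_params(osi, dsi, r_opt, sa)
        if (is.null(par)) next
        is_simple <- runif(1) < preset$simple_fraction
        m <- if (is_simple) runif(1, 1.2, 2.0) else runif(1, 0, 0.3)
        return(tibble(
          neuron_id = sprintf("%s_%03d", preset$name, i),
          group = preset$name,
          a0_true = 0,
          a1_true = par$a1, a2_true = par$a2,
          theta0_true = runif(1, 0, 360),
          sigma_true = par$sigma,
          sa_true = sa,
          or_true = r_opt,
          osi_true = osi, dsi_true = dsi,
          modulation_depth = m,
          cell_class_true = if (is_simple) "simple" else "complex",
          depth_um = runif(1, 0, 1500)
        ))
      }
      abort(
        sprintf(
          "No feasible tuning parameters for neuron %d after %d attempts.",
          i, max_retries
        ),
        class = "agingV1_generation_error"
      )
    }
    purrr::map_dfr(seq_len(n), draw_one)
  })
}
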
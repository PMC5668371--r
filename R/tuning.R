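#' Double-Gaussian direction-tuning model
#'
#' Baseline plus two Gaussian lobes of shared width at the preferred and
#' null directions:
#' `R(theta) = a0 + a1 exp(-d0^2 / (2 sigma^2)) + a2 exp(-d1^2 / (2 sigma^2))`
#' where `d0`, `d1` are angular distances to `theta0` and `theta1` wrapped
#' to `(-180, 180]`. Under the default constraint `theta1 = theta0 + 180`.
#'
#' @param theta_deg directions at which to evaluate (degrees).
#' @param a0 baseline (mean response of the four lowest curve points).
#' @param a1,a2 lobe amplitudes.
#' @param theta0_deg preferred direction (degrees).
#' @param sigma_deg shared Gaussian SD (degrees).
#' @param theta1_deg null direction; defaults to `theta0_deg + 180`.
#' @return model response at each `theta_deg`.
#' @export
double_gaussian <- function(theta_deg, a0, a1, a2, theta0_deg, sigma_deg,
                            theta1_deg = theta0_deg + 180) {
  d0 <- wrap_angle(theta_deg - theta0_deg)
  d1 <- wrap_angle(theta_deg - theta1_deg)
  a0 + a1 * exp(-d0^2 / (2 * sigma_deg^2)) +
    a2 * exp(-d1^2 / (2 * sigma_deg^2))
}

#' Build a direction tuning curve from per-trial responses
#'
#' Averages the spontaneous-subtracted evoked rate over repetitions for each
#' stimulus direction and records the mean pre-stimulus rate across all
#' trials as the neuron's spontaneous activity.
#'
#' @param responses tibble of per-trial rates for one neuron (see
#'   [trial_rates()]): columns `direction_deg`, `rep`, `evoked_rate`,
#'   `prestim_rate`.
#' @param directions the expected stimulus directions (default the 24
#'   directions in 15-degree steps); an error lists any absent angle.
#' @return a tibble of class `tuning_curve` with columns `direction_deg`,
#'   `mean_response`, `sd_response`, `n_reps`, and attribute `sa`
#'   (spontaneous rate, spikes/s).
#' @export
build_tuning_curve <- function(responses, directions = seq(0, 345, by = 15)) {
  if (anyDuplicated(responses[c("direction_deg", "rep")])) {
    abort("Duplicate (direction, rep) rows in the response table.",
      class = "agingV1_invalid_argument"
    )
  }
  absent <- setdiff(directions, unique(responses$direction_deg))
  if (length(absent)) {
    abort(paste0(
      "Missing stimulus direction(s): ", paste(absent, collapse = ", ")
    ), class = "agingV1_invalid_argument")
  }
  n_reps <- responses |>
    dplyr::count(.data$direction_deg) |>
    dplyr::pull("n")
  if (any(n_reps < 4) || any(n_reps > 6)) {
    warn("Repetitions per direction outside the expected 4-6 range.")
  }
  curve <- responses |>
    dplyr::filter(.data$direction_deg %in% directions) |>
    dplyr::group_by(.data$direction_deg) |>
    dplyr::summarise(
      mean_response = mean(.data$evoked_rate),
      sd_response = if (dplyr::n() > 1) stats::sd(.data$evoked_rate) else 0,
      n_reps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$direction_deg)
  attr(curve, "sa") <- mean(responses$prestim_rate)
  class(curve) <- c("tuning_curve", class(curve))
  curve
}

# circular local maxima of the curve; used for multi-start initialization
peak_directions <- function(directions, y) {
  n <- length(y)
  prev <- y[c(n, seq_len(n - 1))]
  nxt <- y[c(seq_len(n)[-1], 1)]
  is_peak <- y >= prev & y >= nxt
  directions[is_peak][order(y[is_peak], decreasing = TRUE)]
}

#' Fit the double-Gaussian tuning model
#'
#' Responses are normalized by the curve maximum; the baseline `a0` is fixed
#' to the mean of the four lowest normalized points; the remaining
#' parameters `(a1, a2, theta0, sigma)` are fit by bounded
#' Levenberg-Marquardt least squares with the null lobe constrained to
#' `theta0 + 180` (set `free_theta1 = TRUE` to relax). Initialization is
#' multi-start: the preferred direction starts at the primary and secondary
#' response peaks, the width at 15, 30 and 60 degrees; the best
#' mean-squared error wins, ties broken by the smaller width. The fit is
#' `accepted` when the mse (on the normalized scale) is below
#' `error_threshold` (default 0.5, the study's fitting-error filter).
#'
#' @param curve a [build_tuning_curve()] result.
#' @param free_theta1 fit the null direction freely instead of constraining
#'   it opposite the preferred direction.
#' @param error_threshold acceptance threshold on the normalized mse.
#' @return an object of class `dg_fit` with normalized parameters, the
#'   normalization `scale` (spikes/s), `mse`, `accepted`, and the data.
#' @export
fit_double_gaussian <- function(curve, free_theta1 = FALSE,
                                error_threshold = 0.5) {
  directions <- curve$direction_deg
  y_raw <- curve$mean_response
  scale <- max(y_raw)
  degenerate <- function(reason) {
    structure(
      list(
        a0 = 0, a1 = 0, a2 = 0, theta0_deg = NA_real_,
        theta1_deg = NA_real_, sigma_deg = NA_real_,
        mse = NA_real_, accepted = FALSE, converged = FALSE,
        scale = scale, free_theta1 = free_theta1, reason = reason,
        curve = curve, sa = attr(curve, "sa")
      ),
      class = "dg_fit"
    )
  }
  if (!is.finite(scale) || scale <= 0) {
    return(degenerate("non-positive curve maximum"))
  }
  if (stats::sd(y_raw) == 0) {
    return(degenerate("flat curve"))
  }
  y <- y_raw / scale
  a0 <- mean(sort(y)[1:4])

  resid_fn <- function(par) {
    if (free_theta1) {
      y - double_gaussian(
        directions, a0, par[1], par[2], par[3], par[4],
        theta1_deg = par[5]
      )
    } else {
      y - double_gaussian(directions, a0, par[1], par[2], par[3], par[4])
    }
  }

  primary <- directions[which.max(y)]
  peaks <- peak_directions(directions, y)
  secondary <- peaks[abs(wrap_angle(peaks - primary)) > 45][1]
  if (is.na(secondary)) secondary <- (primary + 180) %% 360
  a1_start <- max(y) - a0
  starts <- tidyr::expand_grid(
    theta0 = c(primary, secondary),
    sigma = c(15, 30, 60)
  )

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th <- starts$theta0[i]
    a2_start <- max(y[which.min(abs(wrap_angle(directions - th - 180)))] - a0, 0)
    par0 <- c(a1_start, a2_start, th, starts$sigma[i])
    lower <- c(0, 0, -360, 3)
    upper <- c(10, 10, 720, 150)
    if (free_theta1) {
      par0 <- c(par0, th + 180)
      lower <- c(lower, -360)
      upper <- c(upper, 720)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    mse <- mean(fit$fvec^2)
    sig <- fit$par[4]
    if (is.null(best) || mse < best$mse - 1e-12 ||
      (abs(mse - best$mse) <= 1e-12 && sig < best$par[4])) {
      best <- list(par = fit$par, mse = mse, converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    return(degenerate("no start converged"))
  }

  par <- best$par
  a1 <- par[1]
  a2 <- par[2]
  theta0 <- par[3] %% 360
  sigma <- par[4]
  theta1 <- if (free_theta1) par[5] %% 360 else (theta0 + 180) %% 360
  # keep the convention that the larger lobe marks the preferred direction
  if (!free_theta1 && a2 > a1) {
    tmp <- a1
    a1 <- a2
    a2 <- tmp
    theta0 <- (theta0 + 180) %% 360
    theta1 <- (theta0 + 180) %% 360
  }
  structure(
    list(
      a0 = a0, a1 = a1, a2 = a2,
      theta0_deg = theta0, theta1_deg = theta1, sigma_deg = sigma,
      mse = best$mse, accepted = best$mse < error_threshold,
      converged = best$converged, scale = scale,
      free_theta1 = free_theta1, reason = NA_character_,
      curve = curve, sa = attr(curve, "sa")
    ),
    class = "dg_fit"
  )
}

#' @export
print.dg_fit <- function(x, ...) {
  if (is.na(x$mse)) {
    cat(sprintf("<dg_fit> degenerate (%s); accepted = FALSE\n", x$reason))
  } else {
    cat(sprintf(
      "<dg_fit> theta0 %.1f deg, sigma %.1f deg, a1 %.3f, a2 %.3f (norm.), mse %.4g, accepted = %s\n",
      x$theta0_deg, x$sigma_deg, x$a1, x$a2, x$mse, x$accepted
    ))
  }
  invisible(x)
}

#' Predict from a fitted tuning model
#'
#' @param object a `dg_fit`.
#' @param theta_deg directions at which to evaluate.
#' @param denormalize return spikes/s (multiply by the normalization scale)
#'   rather than the normalized fit scale.
#' @param ... unused.
#' @return numeric vector of fitted responses.
#' @export
predict.dg_fit <- function(object, theta_deg = NULL, denormalize = TRUE, ...) {
  if (is.null(theta_deg)) theta_deg <- object$curve$direction_deg
  if (is.na(object$mse)) {
    return(rep(NA_real_, length(theta_deg)))
  }
  val <- double_gaussian(
    theta_deg, object$a0, object$a1, object$a2,
    object$theta0_deg, object$sigma_deg,
    theta1_deg = object$theta1_deg
  )
  if (denormalize) val * object$scale else val
}

#' @rdname fit_double_gaussian
#' @param x a `dg_fit` object.
#' @param ... unused.
#' @method tidy dg_fit
#' @export
tidy.dg_fit <- function(x, ...) {
  tibble(
    term = c("a0", "a1", "a2", "theta0_deg", "theta1_deg", "sigma_deg"),
    estimate = c(
      x$a0 * x$scale, x$a1 * x$scale, x$a2 * x$scale,
      x$theta0_deg, x$theta1_deg, x$sigma_deg
    ),
    unit = c(
      "spikes/s", "spikes/s", "spikes/s",
      "degrees", "degrees", "degrees"
    )
  )
}

#' @rdname fit_double_gaussian
#' @method glance dg_fit
#' @export
glance.dg_fit <- function(x, ...) {
  tibble(
    mse = x$mse, accepted = x$accepted, converged = x$converged,
    scale = x$scale, n_directions = nrow(x$curve), sa = x$sa
  )
}

#' Orientation and direction selectivity indices
#'
#' Evaluates `(R_opt - R_null) / (R_opt - R_spon)` on the fitted tuning
#' curve: `R_opt` is the fitted response at the preferred direction, the
#' direction-selectivity null is the fitted response at the opposite
#' direction, the orientation-selectivity null is the mean fitted response
#' 90 degrees either side of the preferred direction, and `R_spon` is the
#' curve's spontaneous rate. Indices are clipped to `[0, 1]`. Neurons whose
#' fitted optimum does not exceed the spontaneous rate (or whose fit was
#' rejected) are flagged with undefined indices.
#'
#' @param fit a [fit_double_gaussian()] result.
#' @param curve the [build_tuning_curve()] the fit came from (used for the
#'   spontaneous rate and for `from_fit = FALSE`).
#' @param from_fit evaluate responses on the fitted curve (default) or on
#'   the raw direction bins nearest the preferred/null angles.
#' @param clip clip indices to `[0, 1]` (default `TRUE`).
#' @return one-row tibble: `osi`, `dsi`, `r_opt`, `flagged`.
#' @export
selectivity_indices <- function(fit, curve = fit$curve, from_fit = TRUE,
                                clip = TRUE) {
  sa <- attr(curve, "sa") %||% fit$sa
  flagged_out <- tibble(
    osi = NA_real_, dsi = NA_real_, r_opt = NA_real_, flagged = TRUE
  )
  if (!isTRUE(fit$accepted)) {
    return(flagged_out)
  }
  th0 <- fit$theta0_deg
  if (from_fit) {
    r_opt <- predict(fit, th0)
    r_null_dir <- predict(fit, th0 + 180)
    r_null_ori <- mean(predict(fit, c(th0 + 90, th0 - 90)))
  } else {
    nearest <- function(target) {
      curve$mean_response[
        which.min(abs(wrap_angle(curve$direction_deg - target)))
      ]
    }
    r_opt <- nearest(th0)
    r_null_dir <- nearest(th0 + 180)
    r_null_ori <- mean(c(nearest(th0 + 90), nearest(th0 - 90)))
  }
  denom <- r_opt - sa
  if (!is.finite(denom) || denom <= 0) {
    return(flagged_out)
  }
  osi <- (r_opt - r_null_ori) / denom
  dsi <- (r_opt - r_null_dir) / denom
  if (clip) {
    osi <- pmin(pmax(osi, 0), 1)
    dsi <- pmin(pmax(dsi, 0), 1)
  }
  tibble(osi = osi, dsi = dsi, r_opt = r_opt, flagged = FALSE)
}

#' Response-magnitude metrics of a tuning curve
#'
#' The optimal response (OR) is the largest mean response across the
#' stimulus directions; the average response (AR) is the mean over all
#' directions; SA is the spontaneous rate; and the signal-to-noise ratio is
#' `OR / max(SA, 1)` — spontaneous activity below 1 spike/s is floored at
#' 1 spike/s, the study's guard against ratio blow-up.
#'
#' @param curve a [build_tuning_curve()] result.
#' @return one-row tibble: `or_`, `ar`, `sa`, `snr`.
#' @export
response_metrics <- function(curve) {
  or_ <- max(curve$mean_response)
  ar <- mean(curve$mean_response)
  sa <- attr(curve, "sa")
  tibble(or_ = or_, ar = ar, sa = sa, snr = or_ / max(sa, 1))
}

#' Analyze one neuron end to end
#'
#' Composes the per-cell analysis: per-trial rates, tuning curve, response
#' metrics, double-Gaussian fit with the fitting-error filter, selectivity
#' indices (undefined indices flagged, the cell retained for SA/SNR), F1/F0
#' classification at the preferred direction, and cortical-layer assignment
#' from recording depth.
#'
#' @param spikes long spike tibble for one neuron (see [simulate_trials()]).
#' @param protocol a [stimulus_protocol()].
#' @param depth_um recording depth below the pia (micrometres), or `NA`.
#' @param layer_boundaries see [assign_layer()].
#' @param fit_options list of extra arguments to [fit_double_gaussian()].
#' @param neuron_id identifier used in error context; defaults to the one
#'   in `spikes`.
#' @return a one-row tibble (`neuron_record`): `neuron_id`, `osi`, `dsi`,
#'   `or_`, `ar`, `sa`, `snr`, `f1f0`, `cell_class`, `mse`, `fit_accepted`,
#'   `index_flagged`, `theta0_deg`, `sigma_deg`, `depth_um`, `layer`.
#' @export
analyze_neuron <- function(spikes, protocol, depth_um = NA_real_,
                           layer_boundaries = default_layer_boundaries(),
                           fit_options = list(), neuron_id = NULL) {
  neuron_id <- neuron_id %||% unique(spikes$neuron_id)[1] %||% "neuron"
  withCallingHandlers(
    {
      rates <- trial_rates(spikes, protocol)
      curve <- build_tuning_curve(rates, directions = protocol$directions)
      metrics <- response_metrics(curve)
      fit <- do.call(
        fit_double_gaussian,
        c(list(curve = curve), fit_options)
      )
      idx <- selectivity_indices(fit, curve)
      modul <- modulation_ratio(spikes, protocol)
      layer <- if (is.finite(depth_um)) {
        assign_layer(depth_um, layer_boundaries)
      } else {
        NA_character_
      }
      tibble(
        neuron_id = neuron_id,
        osi = idx$osi, dsi = idx$dsi,
        or_ = metrics$or_, ar = metrics$ar,
        sa = metrics$sa, snr = metrics$snr,
        f1f0 = modul$ratio, cell_class = modul$cell_class,
        mse = fit$mse, fit_accepted = fit$accepted,
        index_flagged = idx$flagged,
        theta0_deg = fit$theta0_deg, sigma_deg = fit$sigma_deg,
        depth_um = depth_um, layer = layer
      )
    },
    error = function(e) {
      abort(
        sprintf("While analyzing neuron '%s': %s", neuron_id, conditionMessage(e)),
        class = "agingV1_analysis_error", parent = e
      )
    }
  )
}

#' Simulate and analyze a whole population
#'
#' Runs [simulate_trials()] and [analyze_neuron()] for every neuron of a
#' ground-truth population, with per-neuron child seeds derived from `seed`
#' so the batch is reproducible as a whole.
#'
#' @param population a [make_population()] tibble.
#' @param protocol a [stimulus_protocol()].
#' @param seed integer master seed.
#' @param fit_options passed to [fit_double_gaussian()].
#' @param layer_boundaries see [assign_layer()].
#' @return the population tibble joined with per-neuron analysis columns
#'   (`osi`, `dsi`, `or_`, `ar`, `sa`, `snr`, `f1f0`, `cell_class`, fit
#'   diagnostics, `layer`).
#' @export
analyze_population <- function(population, protocol, seed,
                               fit_options = list(),
                               layer_boundaries = default_layer_boundaries()) {
  n <- nrow(population)
  if (n == 0L) {
    abort("Empty population.", class = "agingV1_invalid_argument")
  }
  child_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n))
  records <- purrr::map_dfr(seq_len(n), function(i) {
    neuron <- population[i, ]
    spikes <- simulate_trials(neuron, protocol, seed = child_seeds[i])
    analyze_neuron(
      spikes, protocol,
      depth_um = neuron$depth_um,
      layer_boundaries = layer_boundaries,
      fit_options = fit_options,
      neuron_id = neuron$neuron_id
    )
  })
  dplyr::left_join(
    population, dplyr::select(records, -"depth_um"),
    by = "neuron_id"
  )
}
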
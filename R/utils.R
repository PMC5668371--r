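#' Wrap angular differences to (-180, 180]
#'
#' Direction tuning lives on a 360-degree circle; all angular distances inside
#' the double-Gaussian exponentials use the shortest signed difference.
#'
#' @param delta_deg numeric vector of angular differences in degrees.
#' @return numeric vector wrapped to (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(0, 190, -190, 360, 180))
wrap_angle <- function(delta_deg) {
  out <- (delta_deg + 180) %% 360 - 180
  # map the -180 representative to +180 so the interval is (-180, 180]
  out[out == -180] <- 180
  out
}

#' Truncated-normal draws and moments
#'
#' Inverse-CDF sampling of a normal distribution truncated to \code{[lo, hi]}.
#' Used by the synthetic generator so that selectivity indices and firing
#' rates stay in their physical ranges while matching published moments.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param lo,hi truncation bounds.
#' @return numeric vector of length \code{n}.
#' @export
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  stopifnot(sd >= 0, lo < hi)
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lo), hi), n))
  }
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  u <- runif(n, p_lo, p_hi)
  stats::qnorm(u, mean, sd)
}

#' @rdname rtrunc_norm
#' @details `trunc_norm_mean()` returns the analytic mean of the truncated
#'   distribution, the oracle the generator's calibration is checked against.
#' @export
trunc_norm_mean <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) {
    return(pmin(pmax(mean, lo), hi))
  }
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Moment-matched lognormal parameters
#'
#' Converts a desired arithmetic mean and SD into the (meanlog, sdlog)
#' parameters of a lognormal distribution with those moments.
#'
#' @param mean,sd desired arithmetic mean (> 0) and SD (>= 0).
#' @return named list with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) {
    return(list(meanlog = log(mean), sdlog = 0))
  }
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

rlnorm_moments <- function(n, mean, sd) {
  p <- lognormal_params(mean, sd)
  if (p$sdlog == 0) rep(mean, n) else rlnorm(n, p$meanlog, p$sdlog)
}

# seeded evaluation without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Published reference values of the source study
#'
#' Loads the transcribed group statistics (means, SDs, sample sizes) and the
#' per-layer density/proportion table published by the source study of young
#' adult versus senescent rat V1. These constants parameterize the default
#' synthetic presets and drive the percent-change reproduction utilities.
#'
#' @return `reference_values()`: a tibble with columns `metric`, `group`,
#'   `mean`, `sd`, `n`, `units`. `reference_layer_table()`: a tibble with
#'   per-layer NeuN/GABA densities and GABA+ proportions for both groups.
#' @export
reference_values <- function() {
  path <- system.file("extdata", "reference_values.csv", package = "agingV1")
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname reference_values
#' @export
reference_layer_table <- function() {
  path <- system.file("extdata", "reference_layer_table.csv", package = "agingV1")
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
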
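#' Configuration of a full study run
#'
#' Bundles every knob of the end-to-end pipeline: the master seed, the two
#' group presets, the stimulus protocol, tuning-fit options, bin
#' specifications, layer boundaries, and the histology design (AOI
#' geometry, intensity slices, blot lanes).
#'
#' @param seed master integer seed; recorded in every output.
#' @param young,old [group_preset()]s for the two groups.
#' @param protocol a [stimulus_protocol()].
#' @param fit_options list passed to [fit_double_gaussian()].
#' @param bin_specs named list of [bin_spec()]s.
#' @param layer_boundaries see [assign_layer()].
#' @param aoi_area_mm2,n_aois histology AOI geometry per `(group, layer)`.
#' @param n_intensity_slices slices per group for marker-intensity
#'   comparisons (default 60: 10 sampled slices in each of 6 animals).
#' @param n_blot_lanes lanes per group (default 6, one per animal).
#' @param gapdh_cv lane-to-lane coefficient of variation of the loading
#'   control.
#' @return an object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         young = young_preset(),
                         old = old_preset(),
                         protocol = stimulus_protocol(),
                         fit_options = list(),
                         bin_specs = default_bin_specs(),
                         layer_boundaries = default_layer_boundaries(),
                         aoi_area_mm2 = 0.05,
                         n_aois = 61L,
                         n_intensity_slices = 60L,
                         n_blot_lanes = 6L,
                         gapdh_cv = 0.05) {
  stopifnot(
    inherits(young, "group_preset"), inherits(old, "group_preset"),
    inherits(protocol, "stimulus_protocol")
  )
  structure(
    list(
      seed = as.integer(seed), young = young, old = old,
      protocol = protocol, fit_options = fit_options,
      bin_specs = bin_specs, layer_boundaries = layer_boundaries,
      aoi_area_mm2 = aoi_area_mm2, n_aois = as.integer(n_aois),
      n_intensity_slices = as.integer(n_intensity_slices),
      n_blot_lanes = as.integer(n_blot_lanes),
      gapdh_cv = gapdh_cv
    ),
    class = "study_config"
  )
}

# metric columns compared between groups, in report order
.response_metrics <- c("osi", "dsi", "or_", "ar", "sa", "snr")
.marker_metrics <- c("gad65", "gad67", "gabaar")

#' Reproduce the published percent-change summaries
#'
#' Computes, from the transcribed published group means, the percent
#' changes of OR, AR, SA (nearest integer, as printed) and SNR between the
#' young and old groups, and the layer-wise relative decreases of the
#' GABA+/total-neuron proportion.
#'
#' @param values a [reference_values()]-shaped tibble.
#' @param layer_table a [reference_layer_table()]-shaped tibble.
#' @return list with two tibbles: `metric_changes` (`metric`, `young_mean`,
#'   `old_mean`, `percent_change`) and `layer_decreases` (`layer`,
#'   `young_proportion`, `old_proportion`, `percent_change`, `decrease`).
#' @export
#' @examples
#' reproduce_reference_changes()$metric_changes
reproduce_reference_changes <- function(values = reference_values(),
                                        layer_table = reference_layer_table()) {
  wide <- values |>
    dplyr::select("metric", "group", "mean") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean")
  metric_changes <- wide |>
    dplyr::filter(.data$metric %in% c("or", "ar", "sa", "snr")) |>
    dplyr::mutate(
      percent_change = purrr::map2_dbl(
        .data$young, .data$old,
        ~ percent_change(.x, .y, decimals = 1)
      ),
      # the spontaneous-activity change is printed to the nearest integer
      percent_change = dplyr::if_else(
        .data$metric == "sa",
        purrr::map2_dbl(.data$young, .data$old,
          ~ percent_change(.x, .y, decimals = 0)
        ),
        .data$percent_change
      )
    ) |>
    dplyr::rename(young_mean = "young", old_mean = "old")
  layer_decreases <- layer_table |>
    dplyr::select("layer", "group", "proportion_mean") |>
    tidyr::pivot_wider(names_from = "group", values_from = "proportion_mean") |>
    dplyr::mutate(
      percent_change = purrr::map2_dbl(
        .data$young, .data$old, ~ percent_change(.x, .y, decimals = 1)
      ),
      decrease = -.data$percent_change
    ) |>
    dplyr::rename(
      young_proportion = "young", old_proportion = "old"
    )
  list(metric_changes = metric_changes, layer_decreases = layer_decreases)
}

#' Run the complete study pipeline
#'
#' Deterministically (given the config seed) simulates both neuron
#' populations, analyzes every neuron, compares the groups (summaries,
#' binned distributions with chi-square tests, t-tests, percent changes),
#' simulates and quantifies the histology (layer density/proportion table
#' with two-way ANOVA, marker intensities, blot densitometry), and collects
#' an exclusion log. All derived seeds are children of `config$seed`.
#'
#' @param config a [study_config()].
#' @return an object of class `study_report`; see the package vignette for
#'   the component tables. Key elements: `neurons` (per-neuron records of
#'   both groups), `group_summaries`, `comparisons` (t-tests),
#'   `bins`/`chi_square`, `histology` (`table`, `anova`), `intensity`,
#'   `blots`, `percent_changes`, `reference_changes`, `exclusions`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1, 8))

  # --- single-unit arm -------------------------------------------------
  pop_young <- make_population(config$young, seed = seeds[1])
  pop_old <- make_population(config$old, seed = seeds[2])
  rec_young <- analyze_population(
    pop_young, config$protocol,
    seed = seeds[3],
    fit_options = config$fit_options,
    layer_boundaries = config$layer_boundaries
  )
  rec_old <- analyze_population(
    pop_old, config$protocol,
    seed = seeds[4],
    fit_options = config$fit_options,
    layer_boundaries = config$layer_boundaries
  )
  neurons <- dplyr::bind_rows(rec_young, rec_old)

  group_summaries <- purrr::map_dfr(
    .response_metrics,
    ~ summarize_group(neurons, .x, group = "group")
  )
  comparisons <- purrr::map_dfr(.response_metrics, function(m) {
    y <- neurons |>
      dplyr::filter(.data$group == config$young$name) |>
      dplyr::pull(m)
    o <- neurons |>
      dplyr::filter(.data$group == config$old$name) |>
      dplyr::pull(m)
    y <- y[!is.na(y)]
    o <- o[!is.na(o)]
    # fewer than two defined values per group: report means, flag the test
    if (length(y) < 2 || length(o) < 2) {
      return(tibble(
        metric = m, statistic = NA_real_, df = NA_real_,
        p_value = NA_real_,
        old_mean = if (length(o)) mean(o) else NA_real_,
        young_mean = if (length(y)) mean(y) else NA_real_,
        tails = 2, variant = "welch", underpowered = TRUE
      ))
    }
    t_test_groups(o, y) |>
      dplyr::mutate(metric = m, .before = 1) |>
      dplyr::rename(old_mean = "mean_a", young_mean = "mean_b") |>
      dplyr::mutate(underpowered = FALSE)
  })
  percent_changes <- comparisons |>
    dplyr::mutate(
      percent_change = purrr::pmap_dbl(
        list(.data$young_mean, .data$old_mean, .data$metric),
        function(y, o, m) {
          if (!is.finite(y) || y == 0 || !is.finite(o)) {
            return(NA_real_)
          }
          percent_change(y, o, decimals = if (m == "sa") 0 else 1)
        }
      )
    ) |>
    dplyr::select("metric", "young_mean", "old_mean", "percent_change")

  bins <- purrr::map_dfr(names(config$bin_specs), function(m) {
    col <- if (m == "or") "or_" else m
    neurons |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(function(d, key) {
        v <- d[[col]]
        suppressWarnings(bin_distribution(v[!is.na(v)], config$bin_specs[[m]]))
      }) |>
      dplyr::ungroup()
  })
  # chi-square on a count matrix, degrading to NA when the table is
  # degenerate (fewer than two non-empty rows/columns at tiny n)
  safe_chi <- function(counts, label) {
    counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
    res <- if (nrow(counts) < 2 || ncol(counts) < 2) {
      tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    } else {
      chi_square_test(counts)
    }
    dplyr::mutate(res, metric = label, .before = 1)
  }
  chi_square <- purrr::map_dfr(names(config$bin_specs), function(m) {
    tab <- bins |>
      dplyr::filter(.data$metric == m) |>
      dplyr::select("group", "bin", "count") |>
      tidyr::pivot_wider(names_from = "bin", values_from = "count")
    safe_chi(as.matrix(tab[, -1]), m)
  })
  # layer-distribution and simple/complex comparisons
  layer_tab <- neurons |>
    dplyr::filter(!is.na(.data$layer)) |>
    dplyr::count(.data$group, .data$layer) |>
    tidyr::pivot_wider(
      names_from = "layer", values_from = "n", values_fill = 0L
    )
  class_tab <- neurons |>
    dplyr::filter(!is.na(.data$cell_class)) |>
    dplyr::count(.data$group, .data$cell_class) |>
    tidyr::pivot_wider(
      names_from = "cell_class", values_from = "n", values_fill = 0L
    )
  chi_square <- dplyr::bind_rows(
    chi_square,
    safe_chi(as.matrix(layer_tab[, -1]), "layer_distribution"),
    safe_chi(as.matrix(class_tab[, -1]), "cell_class")
  )

  # --- histology arm ---------------------------------------------------
  layer_params <- reference_layer_table() |>
    dplyr::transmute(
      group = .data$group, layer = .data$layer,
      neun_density = .data$neun_density_mean,
      gaba_fraction = .data$proportion_mean / 100
    )
  aoi_counts <- simulate_histology(
    layer_params,
    seed = seeds[5],
    aoi_area_mm2 = config$aoi_area_mm2, n_aois = config$n_aois
  )
  density_table <- layer_density_table(aoi_counts)
  per_aoi <- attr(density_table, "per_aoi")
  anova <- purrr::map_dfr(
    c("neun_density", "gaba_density", "proportion"),
    function(v) {
      two_way_anova(per_aoi, v, "group", "layer") |>
        dplyr::mutate(measure = v, .before = 1)
    }
  )

  ref <- reference_values()
  ref_row <- function(metric, group) {
    dplyr::filter(ref, .data$metric == !!metric, .data$group == !!group)
  }
  intensity_seeds <- with_seed(seeds[6], sample.int(.Machine$integer.max - 1, 6))
  intensity <- purrr::imap_dfr(
    setNames(.marker_metrics, .marker_metrics),
    function(m, idx_name) {
      i <- match(m, .marker_metrics)
      ry <- ref_row(paste0(m, "_intensity"), "young")
      ro <- ref_row(paste0(m, "_intensity"), "old")
      y <- make_intensity_samples(
        ry$mean, ry$sd, config$n_intensity_slices, intensity_seeds[2 * i - 1]
      )
      o <- make_intensity_samples(
        ro$mean, ro$sd, config$n_intensity_slices, intensity_seeds[2 * i]
      )
      t_test_groups(o, y) |>
        dplyr::mutate(marker = m, .before = 1) |>
        dplyr::rename(old_mean = "mean_a", young_mean = "mean_b")
    }
  )

  blot_seeds <- with_seed(seeds[7], sample.int(.Machine$integer.max - 1, 3))
  blots <- purrr::map_dfr(.marker_metrics, function(m) {
    i <- match(m, .marker_metrics)
    specs <- purrr::map_dfr(c("young", "old"), function(g) {
      r <- ref_row(paste0(m, "_blot"), g)
      s <- blot_spec_for_ratio(r$mean, r$sd, gapdh_cv = config$gapdh_cv)
      tibble(
        group = g, target_mean = s$target_mean, target_sd = s$target_sd,
        gapdh_mean = s$gapdh_mean, gapdh_sd = s$gapdh_sd
      )
    })
    lanes <- make_blot_lanes(
      specs, config$n_blot_lanes,
      seed = blot_seeds[i], target = m
    )
    y <- lanes$ratio[lanes$group == "young"]
    o <- lanes$ratio[lanes$group == "old"]
    tt <- t_test_groups(o, y)
    tibble(
      marker = m,
      young_mean_ratio = mean(y), old_mean_ratio = mean(o),
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value
    )
  })

  exclusions <- neurons |>
    dplyr::filter(!.data$fit_accepted | .data$index_flagged) |>
    dplyr::transmute(
      neuron_id = .data$neuron_id,
      stage = "tuning_analysis",
      reason = dplyr::case_when(
        !.data$fit_accepted ~ "fit_error_above_threshold",
        .data$index_flagged ~ "indices_undefined"
      )
    )

  structure(
    list(
      config = config,
      seed = config$seed,
      config_hash = rlang::hash(config),
      neurons = neurons,
      group_summaries = group_summaries,
      comparisons = comparisons,
      percent_changes = percent_changes,
      bins = bins,
      chi_square = chi_square,
      histology = list(
        table = density_table, anova = anova, per_aoi = per_aoi
      ),
      intensity = intensity,
      blots = blots,
      reference_changes = reproduce_reference_changes(),
      exclusions = exclusions
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> seed %d, hash %s\n  %d neurons (%d excluded), %d group summaries, %d chi-square tests\n",
    x$seed, x$config_hash, nrow(x$neurons), nrow(x$exclusions),
    nrow(x$group_summaries), nrow(x$chi_square)
  ))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `study_report`.
#' @param ... unused.
#' @details `tidy()` on a report returns the group-comparison table
#'   (metric, group means, t statistic, p-value, percent change);
#'   `glance()` returns one row of run-level metadata.
#' @method tidy study_report
#' @export
tidy.study_report <- function(x, ...) {
  dplyr::left_join(
    x$comparisons,
    dplyr::select(x$percent_changes, "metric", "percent_change"),
    by = "metric"
  )
}

#' @rdname run_pipeline
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  tibble(
    seed = x$seed,
    config_hash = x$config_hash,
    n_neurons = nrow(x$neurons),
    n_excluded = nrow(x$exclusions),
    n_young = sum(x$neurons$group == x$config$young$name),
    n_old = sum(x$neurons$group == x$config$old$name)
  )
}

#' Write and read long-format spike tables
#'
#' Spike tables round-trip through CSV or JSON (chosen by file extension):
#' writing then reading reproduces the data model exactly, and both
#' representations analyze identically.
#'
#' @param spikes a long spike tibble (see [simulate_trials()]).
#' @param path file path ending in `.csv` or `.json`.
#' @return `write_trials()` the path invisibly; `read_trials()` the spike
#'   tibble.
#' @export
write_trials <- function(spikes, path) {
  required <- c("neuron_id", "direction_deg", "rep", "epoch", "spike_time_s")
  stopifnot(all(required %in% names(spikes)))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      spikes[required],
      path,
      digits = NA, dataframe = "columns"
    )
  } else {
    readr::write_csv(spikes[required], path)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  ext <- tolower(tools::file_ext(path))
  required <- c("neuron_id", "direction_deg", "rep", "epoch", "spike_time_s")
  if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- tibble::as_tibble(raw)
  } else {
    # parse warnings are redundant here: missing columns and malformed rows
    # are raised as typed errors below
    df <- suppressWarnings(readr::read_csv(
      path,
      show_col_types = FALSE,
      col_types = readr::cols(
        neuron_id = readr::col_character(),
        direction_deg = readr::col_double(),
        rep = readr::col_integer(),
        epoch = readr::col_character(),
        spike_time_s = readr::col_double()
      )
    ))
    probs <- readr::problems(df)
    if (nrow(probs)) {
      abort(sprintf(
        "Malformed row(s) in '%s', first at line %d.", path, probs$row[1] + 1
      ), class = "agingV1_io_error")
    }
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0(
      "File '", path, "' is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "agingV1_io_error")
  }
  df |>
    dplyr::mutate(
      rep = as.integer(.data$rep),
      direction_deg = as.numeric(.data$direction_deg),
      spike_time_s = as.numeric(.data$spike_time_s)
    ) |>
    dplyr::select(dplyr::all_of(required))
}

#' Write a study report to disk
#'
#' Writes every component table as CSV plus a JSON summary (including the
#' seed and config hash) into a directory.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()
  wr <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(df, path)
    files <<- c(files, path)
  }
  wr(report$neurons, "neurons")
  wr(report$group_summaries, "group_summaries")
  wr(report$comparisons, "comparisons")
  wr(report$percent_changes, "percent_changes")
  wr(report$bins, "bins")
  wr(report$chi_square, "chi_square")
  wr(report$histology$table, "density_table")
  wr(report$histology$anova, "density_anova")
  wr(report$intensity, "intensity")
  wr(report$blots, "blots")
  wr(report$reference_changes$metric_changes, "reference_metric_changes")
  wr(report$reference_changes$layer_decreases, "reference_layer_decreases")
  wr(report$exclusions, "exclusions")
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(
      seed = report$seed,
      config_hash = report$config_hash,
      glance = glance(report),
      percent_changes = report$percent_changes,
      chi_square = report$chi_square,
      blots = report$blots
    ),
    json_path,
    digits = NA, auto_unbox = TRUE, dataframe = "rows"
  )
  files <- c(files, json_path)
  invisible(files)
}
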
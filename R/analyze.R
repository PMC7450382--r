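#' Analysis configuration
#'
#' Bundles every tunable of the per-session analysis so results are
#' reproducible from a single object: raster cell size (cm), skeleton-filter
#' threshold/mode/grid, the k-means seed of the long/short classifier, the
#' similarity rescale mode and the minimum correlation overlap fraction.
#'
#' @param cell_size_cm Raster cell edge in cm (default 0.2).
#' @param skeleton_threshold,skeleton_mode,skeleton_grid See [skeleton_area()].
#' @param kmeans_seed Seed for [classify_long_short()] (default 0).
#' @param rescale Similarity rescale mode: `"x"`, `"both"`, `"none"`.
#' @param min_overlap Minimum overlap fraction for [cross_correlate()].
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(cell_size_cm = 0.2,
                            skeleton_threshold = 0.25,
                            skeleton_mode = "relative",
                            skeleton_grid = "drawing",
                            kmeans_seed = 0L,
                            rescale = "x",
                            min_overlap = 0.25) {
  if (cell_size_cm <= 0 || skeleton_threshold < 0 || min_overlap < 0 ||
      min_overlap > 1) {
    stop_figcopy("invalid analysis_config", "figcopy_config_error")
  }
  structure(list(cell_size_cm = cell_size_cm,
                 skeleton_threshold = skeleton_threshold,
                 skeleton_mode = skeleton_mode,
                 skeleton_grid = skeleton_grid,
                 kmeans_seed = as.integer(kmeans_seed),
                 rescale = rescale, min_overlap = min_overlap),
            class = "analysis_config")
}

config_hash <- function(config) {
  fnv1a_seed(paste(deparse(unclass(config)), collapse = ""))
}

#' Full per-session metric record
#'
#' Computes every session-level metric — stroke kinematics, spatial
#' arrangement and shape similarity — as a single flat one-row tibble,
#' deterministic given the config. Metric families are computed
#' independently: one failing family yields `NA`s for its columns plus a
#' reason code in attribute `failures`, without aborting the others.
#'
#' @param session An [rcft_session].
#' @param config An [analysis_config()].
#' @param stimulus Stimulus polyline tibble (default [rcft_template()]).
#' @return A one-row tibble; attribute `config_hash` identifies the
#'   configuration.
#' @export
analyze_session <- function(session, config = analysis_config(),
                            stimulus = rcft_template()) {
  stopifnot(inherits(session, "rcft_session"),
            inherits(config, "analysis_config"))
  failures <- character()
  run <- function(name, expr, fallback) {
    tryCatch(expr, figcopy_error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      fallback
    })
  }
  stroke_na <- tibble::tibble(
    n_strokes = nrow(session$strokes), n_long = NA_integer_,
    n_short = NA_integer_, mean_stroke_length_cm = NA_real_,
    first5_long_ratio = NA_real_, longest_stroke_speed_cm_s = NA_real_,
    transition_time_s = NA_real_, n_transitions = NA_integer_,
    elapsed_5long_s = NA_real_)
  spatial_na <- tibble::tibble(
    whole_area_cm2 = NA_real_, skeleton_area_cm2 = NA_real_,
    whole_center_x_cm = NA_real_, whole_center_y_cm = NA_real_,
    com_x_cm = NA_real_, com_y_cm = NA_real_, whole_top_cm = NA_real_,
    whole_bottom_cm = NA_real_, skeleton_top_cm = NA_real_,
    skeleton_bottom_cm = NA_real_, input_ratio = NA_real_)
  sim_na <- tibble::tibble(
    xcorr_max = NA_real_, peak_shift_x_cm = NA_real_,
    peak_shift_y_cm = NA_real_, xcorr_max_rescaled = NA_real_)

  out <- dplyr::bind_cols(
    run("stroke", stroke_metrics(session, seed = config$kmeans_seed),
        stroke_na),
    run("spatial",
        spatial_metrics(session, config$cell_size_cm,
                        config$skeleton_threshold, config$skeleton_mode,
                        config$skeleton_grid),
        spatial_na),
    run("similarity",
        similarity_metrics(session, stimulus, config$cell_size_cm,
                           config$rescale, config$min_overlap),
        sim_na))
  attr(out, "failures") <- failures
  attr(out, "config_hash") <- config_hash(config)
  out
}

#' Analyze every session of a cohort
#'
#' @param cohort Tibble from [generate_cohort()] (or any tibble with a
#'   `session` list-column plus identifier columns).
#' @param config An [analysis_config()].
#' @param stimulus Stimulus polyline tibble.
#' @return A tibble with one metric row per session, keeping the cohort's
#'   identifier columns.
#' @export
analyze_cohort <- function(cohort, config = analysis_config(),
                           stimulus = rcft_template()) {
  keys <- cohort[setdiff(names(cohort), "session")]
  rows <- purrr::map(cohort$session, analyze_session,
                     config = config, stimulus = stimulus)
  dplyr::bind_cols(keys, dplyr::bind_rows(rows))
}
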
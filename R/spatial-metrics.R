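#' Spatial arrangement of the drawing
#'
#' Bounding areas, centre of mass and the closing-in ratio of input. All
#' positions are in cm in the working-space-centred frame: negative values are
#' leftward/downward deviations from the centre of the working space,
#' positive values rightward/upward.
#'
#' @name spatial-metrics
NULL

bbox_tibble <- function(x, y) {
  tibble::tibble(
    x_min = min(x), x_max = max(x), y_min = min(y), y_max = max(y)) |>
    dplyr::mutate(
      width = .data$x_max - .data$x_min,
      height = .data$y_max - .data$y_min,
      area_cm2 = .data$width * .data$height,
      center_x = (.data$x_min + .data$x_max) / 2,
      center_y = (.data$y_min + .data$y_max) / 2,
      top_edge = .data$y_max, bottom_edge = .data$y_min)
}

#' Whole-area bounding box
#'
#' The whole area contains the entire drawing and is determined by the four
#' extremum coordinates over all samples (both spaces).
#'
#' @param session An [rcft_session].
#' @return One-row tibble: `x_min`, `x_max`, `y_min`, `y_max`, `width`,
#'   `height`, `area_cm2`, `center_x`, `center_y`, `top_edge`, `bottom_edge`.
#' @export
whole_area <- function(session) {
  s <- session$samples
  if (!nrow(s)) stop_figcopy("empty session", "figcopy_empty_error")
  bbox_tibble(s$x_cm, s$y_cm)
}

#' Skeleton-area bounding box
#'
#' Approximates the bounding box of the figure's framework by discarding
#' sparsely visited subregions: the grid extent is divided into 10 x 10
#' subregions, per-subregion sample counts are taken, samples in subregions
#' whose count falls below one quarter (`threshold`) of a reference count are
#' excluded, and the box is the extremum of the remaining samples.
#' `mode = "relative"` (default) references the maximum subregion count;
#' `mode = "absolute"` references the expected uniform share (total/100).
#' `grid = "drawing"` (default) lays the 10 x 10 grid over the drawing's own
#' bounding box, so input drawn above the working/perceptual midline can
#' survive the filter (closing-in drawings do exactly this);
#' `grid = "working_space"` restricts the grid to the lower display half.
#'
#' @param session An [rcft_session].
#' @param threshold Fraction of the reference count below which a subregion's
#'   samples are excluded (default 0.25; 0 disables filtering).
#' @param mode `"relative"` or `"absolute"`.
#' @param grid `"drawing"` or `"working_space"`.
#' @return One-row tibble in the same shape as [whole_area()]. When every
#'   subregion falls below threshold the whole-area box is returned with a
#'   warning.
#' @export
skeleton_area <- function(session, threshold = 0.25,
                          mode = c("relative", "absolute"),
                          grid = c("drawing", "working_space")) {
  mode <- match.arg(mode)
  grid <- match.arg(grid)
  s <- session$samples
  if (!nrow(s)) stop_figcopy("empty session", "figcopy_empty_error")
  if (grid == "working_space") {
    dev <- session$device
    half_w <- dev$width_mm / 20          # cm, display half-width
    quarter_h <- dev$height_mm / 40      # cm, midline sits one quarter up
    ext <- list(x = c(-half_w, half_w), y = c(-quarter_h, quarter_h))
    s <- s[s$y_norm <= 0, ]
    if (!nrow(s)) stop_figcopy("no samples in the working space",
                               "figcopy_empty_error")
  } else {
    ext <- list(x = range(s$x_cm), y = range(s$y_cm))
  }
  cw <- (ext$x[2] - ext$x[1]) / 10
  ch <- (ext$y[2] - ext$y[1]) / 10
  ix <- if (cw > 0) cell_index(s$x_cm, ext$x[1], cw, 10L) else rep(1L, nrow(s))
  iy <- if (ch > 0) cell_index(s$y_cm, ext$y[1], ch, 10L) else rep(1L, nrow(s))
  cellid <- (ix - 1L) * 10L + iy
  counts <- table(cellid)
  ref <- if (mode == "relative") max(counts) else nrow(s) / 100
  keep_cells <- as.integer(names(counts)[counts >= threshold * ref])
  kept <- s[cellid %in% keep_cells, ]
  if (!nrow(kept)) {
    warn("all subregions fall below the frequency threshold; using whole area")
    return(whole_area(session))
  }
  bbox_tibble(kept$x_cm, kept$y_cm)
}

#' Centre of mass of the inked drawing
#'
#' The drawing is rasterized into binary cells (mass 1 where there is input,
#' 0 elsewhere) and the centre of mass is the unweighted mean of the occupied
#' cell centres — robust to dwell time because a cell counts once however
#' often the pen visits it.
#'
#' @param session An [rcft_session].
#' @param cell_size Raster cell edge in cm (default 0.2).
#' @return One-row tibble `x_cm`, `y_cm`.
#' @export
center_of_mass <- function(session, cell_size = 0.2) {
  r <- session_raster(session, cell_size)
  com_of_raster(r)
}

#' @rdname center_of_mass
#' @param raster An [rcft_raster].
#' @export
com_of_raster <- function(raster) {
  cells <- raster_cells(raster)
  if (!nrow(cells)) stop_figcopy("empty raster", "figcopy_empty_error")
  tibble::tibble(x_cm = mean(cells$x), y_cm = mean(cells$y))
}

#' Ratio of input in the perceptual space
#'
#' The closing-in measure: the fraction of contact samples falling strictly
#' above the display midline (`y_norm > 0`, inside the perceptual half where
#' the stimulus is shown) out of all samples drawn.
#'
#' @param session An [rcft_session].
#' @return Fraction in `[0, 1]`.
#' @export
perceptual_input_ratio <- function(session) {
  s <- session$samples
  if (!nrow(s)) stop_figcopy("empty session", "figcopy_empty_error")
  mean(s$y_norm > 0)
}

#' All spatial-arrangement metrics for a session
#'
#' @param session An [rcft_session].
#' @param cell_size Raster cell for the centre of mass (cm).
#' @param skeleton_threshold,skeleton_mode,skeleton_grid Passed to
#'   [skeleton_area()].
#' @return A one-row tibble with whole/skeleton areas, centres, edges, centre
#'   of mass and the perceptual input ratio.
#' @export
spatial_metrics <- function(session, cell_size = 0.2,
                            skeleton_threshold = 0.25,
                            skeleton_mode = "relative",
                            skeleton_grid = "drawing") {
  wb <- whole_area(session)
  sb <- skeleton_area(session, skeleton_threshold, skeleton_mode, skeleton_grid)
  com <- center_of_mass(session, cell_size)
  tibble::tibble(
    whole_area_cm2 = wb$area_cm2,
    skeleton_area_cm2 = sb$area_cm2,
    whole_center_x_cm = wb$center_x,
    whole_center_y_cm = wb$center_y,
    com_x_cm = com$x_cm,
    com_y_cm = com$y_cm,
    whole_top_cm = wb$top_edge,
    whole_bottom_cm = wb$bottom_edge,
    skeleton_top_cm = sb$top_edge,
    skeleton_bottom_cm = sb$bottom_edge,
    input_ratio = perceptual_input_ratio(session)
  )
}
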
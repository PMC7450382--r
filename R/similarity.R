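#' 2-D normalized cross-correlation of binary rasters
#'
#' The input raster `m` (the drawing) is scanned over the stimulus raster `M`
#' at every integer cell shift. At each shift the coefficient is the Pearson
#' correlation of the overlapped binary values, with means and standard
#' deviations computed on the overlap only; shifts whose overlap is smaller
#' than `min_overlap` of the smaller raster's area (or below 2 cells), or on
#' which either pattern has zero variance, are undefined and stored as `NA`
#' (masked), never as 0. Defined coefficients always lie in `[-1, +1]`.
#'
#' A shift of `(0, 0)` means the two rasters' physical frames coincide (their
#' origins are aligned up to whole cells); positive shifts displace `m`
#' rightward/upward relative to `M`.
#'
#' @param m,M [rcft_raster] objects with equal `cell_size` (drawing and
#'   stimulus).
#' @param min_overlap Minimum overlap area as a fraction of the smaller
#'   raster (default 0.25).
#' @return An `rcft_xcorr` object: list with `values` (matrix indexed by x
#'   shift then y shift, `NA` where masked), `shifts_x`, `shifts_y` (cell
#'   shifts), and `cell_size`.
#' @export
cross_correlate <- function(m, M, min_overlap = 0.25) {
  stopifnot(inherits(m, "rcft_raster"), inherits(M, "rcft_raster"))
  if (abs(m$cell_size - M$cell_size) > 1e-12) {
    stop_figcopy("rasters have different cell sizes", "figcopy_resolution_error")
  }
  c0 <- m$cell_size
  gm <- m$grid * 1; gM <- M$grid * 1
  nmx <- nrow(gm); nmy <- ncol(gm); nMx <- nrow(gM); nMy <- ncol(gM)
  # integer cell offset between the two origins: at shift (0,0) the frames
  # coincide, so m's cell (1,1) sits at M-index (1 + ox, 1 + oy)
  ox <- as.integer(round((m$origin[1] - M$origin[1]) / c0))
  oy <- as.integer(round((m$origin[2] - M$origin[2]) / c0))
  min_cells <- max(2, ceiling(min_overlap * min(nmx * nmy, nMx * nMy)))
  sxs <- seq.int(1L - nmx - ox, nMx - 1L - ox)
  sys <- seq.int(1L - nmy - oy, nMy - 1L - oy)
  vals <- matrix(NA_real_, length(sxs), length(sys))
  for (a in seq_along(sxs)) {
    ux0 <- max(1L, 1L + ox + sxs[a]); ux1 <- min(nMx, nmx + ox + sxs[a])
    if (ux1 < ux0) next
    Mx <- ux0:ux1
    mx <- Mx - ox - sxs[a]
    for (b in seq_along(sys)) {
      uy0 <- max(1L, 1L + oy + sys[b]); uy1 <- min(nMy, nmy + oy + sys[b])
      if (uy1 < uy0) next
      n <- length(Mx) * (uy1 - uy0 + 1L)
      if (n < min_cells) next
      vm <- gm[mx, (uy0:uy1) - oy - sys[b], drop = FALSE]
      vM <- gM[Mx, uy0:uy1, drop = FALSE]
      sm <- sum(vm); sM <- sum(vM)
      # binary patterns: sum of squares equals the sum
      den2 <- (n * sm - sm * sm) * (n * sM - sM * sM)
      if (den2 <= 0) next
      # clamp floating-point overshoot; the coefficient is bounded by 1 exactly
      vals[a, b] <- max(-1, min(1, (n * sum(vm * vM) - sm * sM) / sqrt(den2)))
    }
  }
  structure(list(values = vals, shifts_x = sxs, shifts_y = sys,
                 cell_size = c0),
            class = "rcft_xcorr")
}

#' @export
print.rcft_xcorr <- function(x, ...) {
  cat(sprintf("<rcft_xcorr> %d x %d shifts, %d defined, max %.3f\n",
              length(x$shifts_x), length(x$shifts_y),
              sum(!is.na(x$values)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Tidy a correlation surface
#'
#' @param x An `rcft_xcorr` object.
#' @param ... Unused.
#' @return Tibble with `shift_x`, `shift_y` (cells) and `coefficient`
#'   (defined shifts only).
#' @method tidy rcft_xcorr
#' @export
tidy.rcft_xcorr <- function(x, ...) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  tibble::tibble(
    shift_x = x$shifts_x[idx[, 1]],
    shift_y = x$shifts_y[idx[, 2]],
    coefficient = x$values[idx])
}

#' Maximum similarity and peak shift
#'
#' The maximum defined coefficient of a correlation surface is the similarity
#' between the two patterns; the shift at which it peaks is taken as the
#' centre of the attention field. Ties are broken toward the smallest shift
#' magnitude, then in row-major order.
#'
#' @param surface An `rcft_xcorr` from [cross_correlate()].
#' @return One-row tibble: `coefficient`, `shift_x`, `shift_y` (cells),
#'   `shift_x_cm`, `shift_y_cm`.
#' @export
max_similarity <- function(surface) {
  v <- surface$values
  if (all(is.na(v))) {
    stop_figcopy("no defined correlation values", "figcopy_undefined_error")
  }
  mx <- max(v, na.rm = TRUE)
  idx <- which(!is.na(v) & v >= mx - 1e-15, arr.ind = TRUE)
  sx <- surface$shifts_x[idx[, 1]]
  sy <- surface$shifts_y[idx[, 2]]
  pick <- order(sx^2 + sy^2, idx[, 2], idx[, 1])[1]
  tibble::tibble(
    coefficient = v[idx[pick, 1], idx[pick, 2]],
    shift_x = sx[pick], shift_y = sy[pick],
    shift_x_cm = sx[pick] * surface$cell_size,
    shift_y_cm = sy[pick] * surface$cell_size)
}

#' Maximum similarity after x-axis size rescaling
#'
#' Because whole-area sizes vary between participants, the drawing's
#' coordinates are rescaled (about the whole-area centre, in vector space,
#' before rasterization) so its whole-area width matches the stimulus width;
#' the maximum cross-correlation is then recomputed. `mode = "both"` rescales
#' both axes; `mode = "none"` returns the unrescaled maximum.
#'
#' @param session An [rcft_session].
#' @param stimulus Stimulus polyline tibble (default [rcft_template()]).
#' @param cell_size Raster cell edge in cm.
#' @param mode `"x"` (default), `"both"` or `"none"`.
#' @param min_overlap Passed to [cross_correlate()].
#' @return One-row tibble as [max_similarity()].
#' @export
rescaled_similarity <- function(session, stimulus = rcft_template(),
                                cell_size = 0.2, mode = c("x", "both", "none"),
                                min_overlap = 0.25) {
  mode <- match.arg(mode)
  Mr <- rasterize_segments(stimulus, cell_size)
  df <- tibble::tibble(x = session$samples$x_cm, y = session$samples$y_cm,
                       polyline = session$samples$stroke)
  if (mode != "none") {
    wx <- diff(range(df$x)); wy <- diff(range(df$y))
    tx <- diff(range(stimulus$x)); ty <- diff(range(stimulus$y))
    if (wx <= 0 || (mode == "both" && wy <= 0)) {
      stop_figcopy("degenerate drawing width; cannot rescale",
                   "figcopy_rescale_error")
    }
    cx <- mean(range(df$x)); cy <- mean(range(df$y))
    df$x <- cx + (df$x - cx) * tx / wx
    if (mode == "both") df$y <- cy + (df$y - cy) * ty / wy
  }
  mr <- rasterize_segments(df, cell_size)
  max_similarity(cross_correlate(mr, Mr, min_overlap))
}

#' Shape-similarity metrics for a session
#'
#' Rasterizes the drawing and the stimulus at a common cell size and reports
#' the maximum normalized cross-correlation coefficient, its peak shift, and
#' the size-rescaled maximum.
#'
#' @inheritParams rescaled_similarity
#' @param rescale Rescale mode for the second coefficient (default `"x"`).
#' @return One-row tibble: `xcorr_max`, `peak_shift_x_cm`, `peak_shift_y_cm`,
#'   `xcorr_max_rescaled`.
#' @export
similarity_metrics <- function(session, stimulus = rcft_template(),
                               cell_size = 0.2, rescale = "x",
                               min_overlap = 0.25) {
  Mr <- rasterize_segments(stimulus, cell_size)
  mr <- session_raster(session, cell_size)
  peak <- max_similarity(cross_correlate(mr, Mr, min_overlap))
  resc <- if (identical(rescale, "none")) peak else
    rescaled_similarity(session, stimulus, cell_size, rescale, min_overlap)
  tibble::tibble(
    xcorr_max = peak$coefficient,
    peak_shift_x_cm = peak$shift_x_cm,
    peak_shift_y_cm = peak$shift_y_cm,
    xcorr_max_rescaled = resc$coefficient)
}
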
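#' Binary occupancy rasters
#'
#' A raster is a binary occupancy grid over a physical extent: cell
#' `(ix, iy)` covers the half-open square
#' `[origin_x + (ix-1) c, origin_x + ix c) x [origin_y + (iy-1) c, origin_y + iy c)`
#' with cell size `c` in cm (the top/right boundary of the last cell is
#' closed). The grid is stored as a logical matrix indexed `[ix, iy]` with
#' `ix` along +x and `iy` along +y. Rasters are the operands of the
#' normalized cross-correlation similarity and of the binary-mass centre of
#' mass.
#'
#' @name rcft_raster
NULL

new_raster <- function(grid, cell_size, origin) {
  structure(list(grid = grid, cell_size = cell_size, origin = origin),
            class = "rcft_raster")
}

#' @export
print.rcft_raster <- function(x, ...) {
  cat(sprintf("<rcft_raster> %d x %d cells of %.2f cm, %d occupied\n",
              nrow(x$grid), ncol(x$grid), x$cell_size, sum(x$grid)))
  invisible(x)
}

# snap an extent outward to whole cell multiples of `cell` in the absolute
# frame, so rasters of translated-by-cell-multiples inputs stay phase-aligned
snapped_extent <- function(xr, yr, cell) {
  list(x = c(floor(round(xr[1] / cell, 6)), ceiling(round(xr[2] / cell, 6))) * cell,
       y = c(floor(round(yr[1] / cell, 6)), ceiling(round(yr[2] / cell, 6))) * cell)
}

# grid-traversal of one segment: all cells whose half-open square the segment
# passes through, found by cutting the segment at every gridline crossing and
# locating the midpoint of each piece
segment_cells <- function(x0, y0, x1, y1, origin, cell, nx, ny) {
  if (x0 == x1 && y0 == y1) {
    return(cbind(cell_index(x0, origin[1], cell, nx),
                 cell_index(y0, origin[2], cell, ny)))
  }
  ts <- c(0, 1)
  if (x1 != x0) {
    ks <- seq(ceiling(round(min(x0, x1) / cell, 6)),
              floor(round(max(x0, x1) / cell, 6)))
    ts <- c(ts, (ks * cell - x0) / (x1 - x0))
  }
  if (y1 != y0) {
    ks <- seq(ceiling(round(min(y0, y1) / cell, 6)),
              floor(round(max(y0, y1) / cell, 6)))
    ts <- c(ts, (ks * cell - y0) / (y1 - y0))
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  # drop sub-nanometre slivers created by floating-point drift at boundaries
  keep_piece <- (ts[-1] - ts[-length(ts)]) * len > 1e-9
  if (!any(keep_piece)) keep_piece <- TRUE
  mid <- ((ts[-length(ts)] + ts[-1]) / 2)[keep_piece]
  mx <- x0 + mid * (x1 - x0)
  my <- y0 + mid * (y1 - y0)
  cx <- cell_index(mx, origin[1], cell, nx)
  cy <- cell_index(my, origin[2], cell, ny)
  keep <- !duplicated(cbind(cx, cy))
  cbind(cx[keep], cy[keep])
}

#' Rasterize polylines or a sample cloud
#'
#' `rasterize_segments()` marks every cell that a polyline segment passes
#' through (exact grid traversal, not point sampling); `rasterize_points()`
#' marks the cell containing each sample. The extent defaults to the input's
#' bounding box snapped outward to whole cell multiples, which keeps rasters
#' of identical shapes phase-aligned under cell-multiple translations.
#'
#' @param data Data frame with `x`, `y` in cm; for segments, also a
#'   `polyline` id column (consecutive rows within a polyline are connected;
#'   [rcft_template()] output qualifies). Session samples can be passed with
#'   `x = x_cm` etc. via [session_raster()].
#' @param cell_size Cell edge in cm (default 0.2).
#' @param extent Optional list with `x`, `y` ranges in cm; points falling
#'   outside a supplied extent are dropped.
#' @return An [rcft_raster] object.
#' @export
rasterize_segments <- function(data, cell_size = 0.2, extent = NULL) {
  if (cell_size <= 0) stop_figcopy("cell_size must be > 0", "figcopy_config_error")
  if (!nrow(data)) stop_figcopy("empty input", "figcopy_empty_error")
  if (is.null(data$polyline)) data$polyline <- 1L
  ext <- extent %||% snapped_extent(range(data$x), range(data$y), cell_size)
  nx <- max(1L, as.integer(round((ext$x[2] - ext$x[1]) / cell_size)))
  ny <- max(1L, as.integer(round((ext$y[2] - ext$y[1]) / cell_size)))
  grid <- matrix(FALSE, nx, ny)
  origin <- c(ext$x[1], ext$y[1])
  for (ids in split(seq_len(nrow(data)), data$polyline)) {
    xs <- data$x[ids]; ys <- data$y[ids]
    if (length(ids) == 1L) {
      cells <- segment_cells(xs, ys, xs, ys, origin, cell_size, nx, ny)
      grid[cells[cells[, 1] >= 1 & cells[, 1] <= nx &
                   cells[, 2] >= 1 & cells[, 2] <= ny, , drop = FALSE]] <- TRUE
      next
    }
    for (k in seq_len(length(ids) - 1L)) {
      cells <- segment_cells(xs[k], ys[k], xs[k + 1], ys[k + 1],
                             origin, cell_size, nx, ny)
      ok <- cells[, 1] >= 1 & cells[, 1] <= nx & cells[, 2] >= 1 & cells[, 2] <= ny
      grid[cells[ok, , drop = FALSE]] <- TRUE
    }
  }
  if (!any(grid)) stop_figcopy("rasterization produced no occupied cells",
                               "figcopy_empty_error")
  new_raster(grid, cell_size, origin)
}

#' @rdname rasterize_segments
#' @export
rasterize_points <- function(data, cell_size = 0.2, extent = NULL) {
  if (cell_size <= 0) stop_figcopy("cell_size must be > 0", "figcopy_config_error")
  if (!nrow(data)) stop_figcopy("empty input", "figcopy_empty_error")
  ext <- extent %||% snapped_extent(range(data$x), range(data$y), cell_size)
  nx <- max(1L, as.integer(round((ext$x[2] - ext$x[1]) / cell_size)))
  ny <- max(1L, as.integer(round((ext$y[2] - ext$y[1]) / cell_size)))
  ix <- cell_index(data$x, ext$x[1], cell_size, nx)
  iy <- cell_index(data$y, ext$y[1], cell_size, ny)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  if (!any(ok)) stop_figcopy("no points inside the raster extent",
                             "figcopy_empty_error")
  grid <- matrix(FALSE, nx, ny)
  grid[cbind(ix[ok], iy[ok])] <- TRUE
  new_raster(grid, cell_size, c(ext$x[1], ext$y[1]))
}

#' Rasterize a session's drawing
#'
#' Strokes are rasterized as connected segments between consecutive contact
#' samples (the inked trace), matching how the stimulus polylines are
#' rasterized.
#'
#' @param session An [rcft_session].
#' @inheritParams rasterize_segments
#' @export
session_raster <- function(session, cell_size = 0.2, extent = NULL) {
  df <- tibble::tibble(x = session$samples$x_cm, y = session$samples$y_cm,
                       polyline = session$samples$stroke)
  rasterize_segments(df, cell_size, extent)
}

#' Occupied-cell centre positions
#'
#' @param raster An [rcft_raster].
#' @return Tibble of occupied cell centres `x`, `y` in cm.
#' @export
raster_cells <- function(raster) {
  idx <- which(raster$grid, arr.ind = TRUE)
  tibble::tibble(
    x = raster$origin[1] + (idx[, 1] - 0.5) * raster$cell_size,
    y = raster$origin[2] + (idx[, 2] - 0.5) * raster$cell_size)
}
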
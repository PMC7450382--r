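# test fixtures are built in code: a square-pixel toy device, builders for
# event logs and sessions, and independent brute-force oracles

tiny_device <- function() device_spec(100L, 200L, 100, 200, 10)

# event tibble from (kind, t, x, y) vectors
make_events <- function(kind, t, x, y, device = tiny_device()) {
  pen_events(tibble::tibble(t_s = t, x_px = x, y_px = y, event_kind = kind),
             device)
}

# build a session from per-stroke sample tables in cm (working-centred frame);
# each element: data.frame(t, x, y); detach is emitted at the last sample time
session_from_strokes <- function(strokes, device = device_spec()) {
  rows <- lapply(strokes, function(st) {
    px <- cm_to_px(st$x, st$y, device)
    n <- nrow(st)
    tibble::tibble(
      t_s = c(st$t, st$t[n]),
      x_px = c(px$x_px, px$x_px[n]),
      y_px = c(px$y_px, px$y_px[n]),
      event_kind = c("attach", rep("move", n - 1L), "detach"))
  })
  segment_strokes(pen_events(dplyr::bind_rows(rows), device))
}

# rebuild an rcft_raster from a logical matrix (grid[ix, iy], cell centres)
raster_from_matrix <- function(mat, cell = 1, origin = c(0, 0)) {
  idx <- which(mat, arr.ind = TRUE)
  pts <- tibble::tibble(x = origin[1] + (idx[, 1] - 0.5) * cell,
                        y = origin[2] + (idx[, 2] - 0.5) * cell)
  ext <- list(x = c(origin[1], origin[1] + nrow(mat) * cell),
              y = c(origin[2], origin[2] + ncol(mat) * cell))
  rasterize_points(pts, cell, ext)
}

random_raster <- function(nx, ny, p = 0.4) {
  m <- matrix(stats::runif(nx * ny) < p, nx, ny)
  if (!any(m)) m[sample.int(nx * ny, 1)] <- TRUE
  raster_from_matrix(m)
}

# oracle: per-shift Pearson correlation computed directly with stats::cor
brute_xcorr <- function(m, M, min_overlap = 0.25) {
  gm <- m$grid * 1; gM <- M$grid * 1
  nmx <- nrow(gm); nmy <- ncol(gm); nMx <- nrow(gM); nMy <- ncol(gM)
  ox <- as.integer(round((m$origin[1] - M$origin[1]) / m$cell_size))
  oy <- as.integer(round((m$origin[2] - M$origin[2]) / m$cell_size))
  min_cells <- max(2, ceiling(min_overlap * min(nmx * nmy, nMx * nMy)))
  sxs <- seq.int(1L - nmx - ox, nMx - 1L - ox)
  sys <- seq.int(1L - nmy - oy, nMy - 1L - oy)
  vals <- matrix(NA_real_, length(sxs), length(sys))
  for (a in seq_along(sxs)) for (b in seq_along(sys)) {
    vm <- c(); vM <- c()
    for (ix in seq_len(nmx)) for (iy in seq_len(nmy)) {
      ux <- ix + ox + sxs[a]; uy <- iy + oy + sys[b]
      if (ux >= 1 && ux <= nMx && uy >= 1 && uy <= nMy) {
        vm <- c(vm, gm[ix, iy]); vM <- c(vM, gM[ux, uy])
      }
    }
    if (length(vm) >= min_cells && sd(vm) > 0 && sd(vM) > 0) {
      vals[a, b] <- stats::cor(vm, vM)
    }
  }
  list(values = vals, shifts_x = sxs, shifts_y = sys)
}

# oracle: optimal 2-cluster partition of 1-D data by exhaustive threshold
# enumeration (the 1-D k-means optimum is a contiguous split)
brute_split2 <- function(x) {
  xs <- sort(x)
  best <- NULL
  for (k in seq_len(length(xs) - 1)) {
    if (xs[k] == xs[k + 1]) next
    lo <- xs[1:k]; hi <- xs[(k + 1):length(xs)]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || wss < best$wss) {
      best <- list(wss = wss, threshold = (xs[k] + xs[k + 1]) / 2)
    }
  }
  best
}

# oracle: cells met by a segment, by dense sampling plus the exact gridline
# crossing points (which catch thin corner slivers that uniform sampling
# can step over)
brute_segment_cells <- function(x0, y0, x1, y1, origin, cell) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  ts <- if (len == 0) 0 else seq(0, 1, length.out = 4001L)
  if (x1 != x0) {
    ks <- seq(ceiling(round(min(x0, x1) / cell, 6)),
              floor(round(max(x0, x1) / cell, 6)))
    if (length(ks)) ts <- c(ts, (ks * cell - x0) / (x1 - x0))
  }
  if (y1 != y0) {
    ks <- seq(ceiling(round(min(y0, y1) / cell, 6)),
              floor(round(max(y0, y1) / cell, 6)))
    if (length(ks)) ts <- c(ts, (ks * cell - y0) / (y1 - y0))
  }
  ts <- pmin(pmax(ts, 0), 1)
  px <- x0 + ts * (x1 - x0); py <- y0 + ts * (y1 - y0)
  ix <- floor(round((px - origin[1]) / cell, 6)) + 1L
  iy <- floor(round((py - origin[2]) / cell, 6)) + 1L
  unique(paste(ix, iy))
}
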
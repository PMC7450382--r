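#' Synthetic drawing profiles
#'
#' A profile parameterizes the generative model behind [generate_session()]:
#' the behaviours seen in figure-copying sessions — fragmented, piecemeal
#' stroke production, long pauses before framework lines, upward placement
#' bias toward the stimulus (closing-in), global size change and positional
#' noise — each as an explicit dial.
#'
#' @param order_policy Component drawing order: `"global_first"` (framework
#'   then details, the typical healthy strategy), `"interleaved"` or
#'   `"local_first"`.
#' @param fragmentation Expected number of extra splits per component
#'   (Poisson; 0 = each template polyline is one stroke).
#' @param pause_mean_s,pause_sd_s Mean and SD in seconds of the log-normal
#'   inter-stroke pause (positive, right-skewed, as observed pauses are).
#' @param transition_extra_s Extra pause in seconds inserted before strokes
#'   of global (long) components.
#' @param speed_cm_s Drawing speed along the pen path.
#' @param vertical_offset_cm,horizontal_offset_cm Placement bias of the copy
#'   relative to the working-space centre (+y is toward the stimulus).
#' @param scale Global size factor of the copy.
#' @param jitter_sd_cm SD of isotropic Gaussian positional noise per sample.
#' @param seed RNG seed making the session deterministic.
#' @return An object of class `synthetic_profile`.
#' @export
synthetic_profile <- function(order_policy = c("global_first", "interleaved",
                                               "local_first"),
                              fragmentation = 1,
                              pause_mean_s = 1.4, pause_sd_s = 0.6,
                              transition_extra_s = 0,
                              speed_cm_s = 6.3,
                              vertical_offset_cm = 0, horizontal_offset_cm = 0,
                              scale = 1, jitter_sd_cm = 0.02,
                              seed = 0L) {
  order_policy <- match.arg(order_policy)
  if (fragmentation < 0 || speed_cm_s <= 0 || scale <= 0 || jitter_sd_cm < 0 ||
      pause_mean_s <= 0 || pause_sd_s < 0) {
    stop_figcopy("invalid profile parameters", "figcopy_config_error")
  }
  structure(list(order_policy = order_policy, fragmentation = fragmentation,
                 pause_mean_s = pause_mean_s, pause_sd_s = pause_sd_s,
                 transition_extra_s = transition_extra_s,
                 speed_cm_s = speed_cm_s,
                 vertical_offset_cm = vertical_offset_cm,
                 horizontal_offset_cm = horizontal_offset_cm,
                 scale = scale, jitter_sd_cm = jitter_sd_cm,
                 seed = as.integer(seed)),
            class = "synthetic_profile")
}

#' Group preset profiles
#'
#' Presets emulating the three study-group phenotypes: controls draw the
#' framework first, quickly and accurately; the impairment presets add slower
#' long strokes, longer transition pauses, fragmentation, upward (closing-in)
#' bias, and for the late-onset preset a leftward bias.
#'
#' @param ... Overrides passed to [synthetic_profile()].
#' @return A `synthetic_profile`.
#' @export
nc_profile <- function(...) {
  args <- list(...)
  do.call(synthetic_profile, utils::modifyList(list(), args))
}

#' @rdname nc_profile
#' @export
eoad_profile <- function(...) {
  base <- list(order_policy = "interleaved", fragmentation = 2,
               pause_mean_s = 2, pause_sd_s = 1.5, transition_extra_s = 3,
               speed_cm_s = 4.4, vertical_offset_cm = 4, scale = 1.1,
               jitter_sd_cm = 0.25)
  do.call(synthetic_profile, utils::modifyList(base, list(...)))
}

#' @rdname nc_profile
#' @export
load_profile <- function(...) {
  base <- list(order_policy = "interleaved", fragmentation = 1.2,
               pause_mean_s = 1.8, pause_sd_s = 1.2, transition_extra_s = 1.5,
               speed_cm_s = 4.1, vertical_offset_cm = 3,
               horizontal_offset_cm = -0.6, scale = 0.95, jitter_sd_cm = 0.2)
  do.call(synthetic_profile, utils::modifyList(base, list(...)))
}

# linear interpolation on a strictly increasing grid (lean stats::approx)
interp1 <- function(gx, gy, xout) {
  i <- findInterval(xout, gx, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= length(gx)] <- length(gx) - 1L
  dg <- gx[i + 1L] - gx[i]
  w <- ifelse(dg > 0, (xout - gx[i]) / dg, 0)
  gy[i] + w * (gy[i + 1L] - gy[i])
}

# split a polyline (vertex tibble) into pieces at arc-length positions
split_polyline <- function(xs, ys, at) {
  seglen <- sqrt(diff(xs)^2 + diff(ys)^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  at <- sort(at[at > 1e-9 & at < total - 1e-9])
  if (!length(at)) return(list(list(x = xs, y = ys)))
  bounds <- c(0, at, total)
  pieces <- vector("list", length(bounds) - 1L)
  for (i in seq_along(pieces)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    inner <- which(cum > lo + 1e-12 & cum < hi - 1e-12)
    px <- c(interp1(cum, xs, lo), xs[inner], interp1(cum, xs, hi))
    py <- c(interp1(cum, ys, lo), ys[inner], interp1(cum, ys, hi))
    pieces[[i]] <- list(x = px, y = py)
  }
  pieces
}

# smooth positional noise: white noise at ~6 Hz knots, linearly interpolated
# to the sample rate, so pen wobble distorts the shape without inflating the
# path length the way independent per-sample noise would
smooth_jitter <- function(n, sd, rate) {
  if (n < 2L) return(rnorm(n, 0, sd))
  step <- max(1L, as.integer(round(rate / 6)))
  knots <- unique(c(seq(1L, n, by = step), n))
  if (length(knots) < 2L) return(rep(rnorm(1L, 0, sd), n))
  interp1(knots, rnorm(length(knots), 0, sd), seq_len(n))
}

# resample a polyline at 60 Hz travel: n samples along arc length at `speed`
sample_polyline <- function(xs, ys, speed, rate) {
  seglen <- sqrt(diff(xs)^2 + diff(ys)^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  n <- max(2L, as.integer(ceiling(total / speed * rate)) + 1L)
  s <- seq(0, total, length.out = n)
  list(x = interp1(cum, xs, s),
       y = interp1(cum, ys, s),
       duration = total / speed)
}

#' Generate a synthetic drawing session
#'
#' Traces the stimulus template in the profile's component order, splitting
#' components into strokes per the fragmentation dial, emitting contact
#' samples at the device rate along the path at the profile speed, applying
#' scale, placement offsets and jitter, and separating strokes by log-normal
#' pauses (plus `transition_extra_s` before global components). The copy is
#' placed relative to the working-space centre. Deterministic given the
#' profile seed.
#'
#' @param profile A [synthetic_profile()].
#' @param template Stimulus polyline tibble (default [rcft_template()]).
#' @param device A [device_spec()].
#' @return An [rcft_session]; `meta` carries the profile and per-stroke
#'   component provenance.
#' @export
generate_session <- function(profile, template = rcft_template(),
                             device = device_spec()) {
  stopifnot(inherits(profile, "synthetic_profile"))
  rate <- device$sample_rate_hz
  comps <- unique(template$component[order(template$polyline)])
  kinds <- template$kind[match(comps, template$component)]
  ord <- switch(profile$order_policy,
    global_first = order(kinds != "global"),
    local_first = order(kinds != "local"),
    interleaved = {
      gi <- which(kinds == "global"); li <- which(kinds == "local")
      n <- max(length(gi), length(li))
      idx <- as.vector(rbind(c(gi, rep(NA, n - length(gi))),
                             c(li, rep(NA, n - length(li)))))
      idx[!is.na(idx)]
    })
  comps <- comps[ord]; kinds <- kinds[ord]

  withr::with_seed(profile$seed, {
    # plain accumulators; per-stroke geometry is computed inline so cohort
    # simulation stays cheap
    sx <- list(); sy <- list(); st <- list(); sid <- list()
    comp_of <- character(); kind_of <- character()
    t_down <- numeric(); t_up <- numeric(); n_samp <- integer()
    plen <- numeric(); xext <- numeric(); yext <- numeric()
    t_cur <- 0; stroke_id <- 0L
    lnorm_sdlog <- sqrt(log(1 + (profile$pause_sd_s / profile$pause_mean_s)^2))
    lnorm_meanlog <- log(profile$pause_mean_s) - lnorm_sdlog^2 / 2
    for (ci in seq_along(comps)) {
      part <- template[template$component == comps[ci], ]
      pls <- split(part, part$polyline)
      # distribute the component's extra splits over its polylines by length
      n_extra <- rpois(1L, profile$fragmentation)
      lens <- vapply(pls, function(p)
        sum(sqrt(diff(p$x)^2 + diff(p$y)^2)), numeric(1))
      alloc <- if (n_extra > 0)
        tabulate(sample.int(length(pls), n_extra, replace = TRUE,
                            prob = lens / sum(lens)), length(pls))
      else rep(0L, length(pls))
      for (pi in seq_along(pls)) {
        pp <- pls[[pi]]
        cuts <- if (alloc[pi] > 0) runif(alloc[pi], 0, lens[pi]) else numeric(0)
        for (piece in split_polyline(pp$x, pp$y, cuts)) {
          tr <- sample_polyline(piece$x, piece$y,
                                profile$speed_cm_s / profile$scale, rate)
          x <- tr$x * profile$scale + profile$horizontal_offset_cm
          y <- tr$y * profile$scale + profile$vertical_offset_cm
          if (profile$jitter_sd_cm > 0) {
            x <- x + smooth_jitter(length(x), profile$jitter_sd_cm, rate)
            y <- y + smooth_jitter(length(y), profile$jitter_sd_cm, rate)
          }
          gap <- rlnorm(1L, lnorm_meanlog, lnorm_sdlog) +
            if (kinds[ci] == "global") profile$transition_extra_s else 0
          if (stroke_id > 0L) t_cur <- t_cur + gap
          stroke_id <- stroke_id + 1L
          n <- length(x)
          ts <- t_cur + seq(0, by = 1 / rate, length.out = n)
          sx[[stroke_id]] <- x; sy[[stroke_id]] <- y; st[[stroke_id]] <- ts
          sid[[stroke_id]] <- rep.int(stroke_id, n)
          comp_of[stroke_id] <- comps[ci]; kind_of[stroke_id] <- kinds[ci]
          t_down[stroke_id] <- t_cur; t_up[stroke_id] <- ts[n]
          n_samp[stroke_id] <- n
          plen[stroke_id] <- sum(sqrt(diff(x)^2 + diff(y)^2))
          xext[stroke_id] <- max(x) - min(x)
          yext[stroke_id] <- max(y) - min(y)
          t_cur <- ts[n]
        }
      }
    }
    x_all <- unlist(sx, use.names = FALSE)
    y_all <- unlist(sy, use.names = FALSE)
    pitch <- px_pitch(device)
    x_px <- x_all * 10 / pitch[["x"]] + device$width_px / 2
    y_px <- 0.75 * device$height_px - y_all * 10 / pitch[["y"]]
    if (any(x_px < 0 | x_px >= device$width_px |
            y_px < 0 | y_px >= device$height_px)) {
      stop_figcopy("profile offsets/scale push the drawing off the display",
                   "figcopy_generation_error")
    }
    samp <- tibble::tibble(
      stroke = unlist(sid, use.names = FALSE),
      t_s = unlist(st, use.names = FALSE),
      x_cm = x_all, y_cm = y_all,
      # midline sits height_mm/40 cm above the working-space centre
      y_norm = y_all * 20 / device$height_mm - 0.5)
    strokes <- tibble::tibble(
      stroke = seq_len(stroke_id), t_down = t_down, t_up = t_up,
      n_samples = n_samp, path_length_cm = plen, x_extent_cm = xext,
      y_extent_cm = yext, duration_s = t_up - t_down,
      mean_speed_cm_s = plen / (t_up - t_down))
    meta <- tibble::tibble(stroke = seq_len(stroke_id),
                           component = comp_of, kind = kind_of)
    new_rcft_session(samp, strokes, device,
                     meta = list(profile = profile, components = meta))
  })
}

#' Generate a labelled multi-group cohort
#'
#' Produces `n_per_group` sessions per named profile, with per-session seeds
#' derived by hashing `(master_seed, group, index)` so cohorts are
#' reproducible and independent of generation order.
#'
#' @param profiles Named list of [synthetic_profile()] objects (>= 2 groups
#'   for downstream comparison; a single profile is allowed for calibration).
#' @param n_per_group Sessions per group (>= 1).
#' @param master_seed Integer master seed.
#' @param template,device Passed to [generate_session()].
#' @return A tibble with columns `group`, `id`, `seed` and a list-column
#'   `session`.
#' @export
generate_cohort <- function(profiles, n_per_group, master_seed = 1L,
                            template = rcft_template(),
                            device = device_spec()) {
  if (n_per_group < 1) {
    stop_figcopy("n_per_group must be >= 1", "figcopy_arity_error")
  }
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    stop_figcopy("profiles must be a named list", "figcopy_arity_error")
  }
  grid <- tidyr::expand_grid(group = names(profiles), id = seq_len(n_per_group))
  grid$seed <- purrr::map2_int(grid$group, grid$id,
                               function(g, i) fnv1a_seed(master_seed, g, i))
  grid$session <- purrr::pmap(grid, function(group, id, seed) {
    pr <- profiles[[group]]
    pr$seed <- seed
    generate_session(pr, template, device)
  })
  grid
}
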
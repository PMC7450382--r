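#' Drawing sessions
#'
#' A drawing session is the unit of analysis: an ordered set of strokes, each
#' a continuous-contact pen trajectory in the physical working-space-centred
#' frame (cm, +y up; see [px_to_cm()]). The object carries
#' \describe{
#'   \item{samples}{tibble of contact samples: `stroke`, `t_s`, `x_cm`,
#'     `y_cm`, `y_norm`;}
#'   \item{strokes}{tibble of per-stroke geometry: `stroke`, `t_down`, `t_up`,
#'     `n_samples`, `path_length_cm`, `x_extent_cm`, `y_extent_cm`,
#'     `duration_s`, `mean_speed_cm_s`;}
#'   \item{device}{the [device_spec()].}
#' }
#'
#' @name rcft_session
NULL

new_rcft_session <- function(samples, strokes, device, meta = list()) {
  structure(list(samples = samples, strokes = strokes, device = device,
                 meta = meta),
            class = "rcft_session")
}

#' @export
print.rcft_session <- function(x, ...) {
  cat(sprintf(
    "<rcft_session> %d strokes, %d samples, %.1f s\n",
    nrow(x$strokes), nrow(x$samples),
    if (nrow(x$strokes)) max(x$strokes$t_up) - min(x$strokes$t_down) else 0))
  invisible(x)
}

# per-stroke geometry from a stroke's ordered samples
stroke_geometry <- function(samples) {
  samples |>
    dplyr::group_by(.data$stroke) |>
    dplyr::summarise(
      t_down = dplyr::first(.data$t_s),
      n_samples = dplyr::n(),
      path_length_cm = sum(sqrt(diff(.data$x_cm)^2 + diff(.data$y_cm)^2)),
      x_extent_cm = max(.data$x_cm) - min(.data$x_cm),
      y_extent_cm = max(.data$y_cm) - min(.data$y_cm),
      .groups = "drop"
    )
}

#' Segment a validated event log into strokes
#'
#' A stroke is the pen trajectory from an `attach` event to the following
#' `detach`: its samples are the attach and move rows, `t_down` is the attach
#' time and `t_up` the detach time. Strokes with fewer than two contact
#' samples (taps) are dropped with a warning. Logs that fail
#' [validate_events()] are refused.
#'
#' @param events An event tibble from [pen_events()] or [read_pen_log()].
#' @param device A [device_spec()]; defaults to the one attached to `events`.
#' @return An [rcft_session] object.
#' @examples
#' ev <- pen_events(data.frame(
#'   t_s = (0:4) / 60, x_px = c(100, 120, 140, 160, 160),
#'   y_px = rep(1800, 5),
#'   event_kind = c("attach", "move", "move", "move", "detach")))
#' segment_strokes(ev)
#' @export
segment_strokes <- function(events, device = attr(events, "device")) {
  if (is.null(device)) device <- device_spec()
  report <- validate_events(events)
  if (!isTRUE(attr(report, "usable"))) {
    stop_figcopy(
      paste0("event log is unusable: ",
             paste(unique(report$violation), collapse = "; ")),
      "figcopy_session_invalid_error")
  }
  ev <- to_physical(events, device)
  ev$stroke <- cumsum(ev$event_kind == "attach")
  ups <- ev[ev$event_kind == "detach", c("stroke", "t_s")]
  names(ups)[2] <- "t_up"
  samples <- ev[ev$contact,
                c("stroke", "t_s", "x_cm", "y_cm", "y_norm")]

  counts <- table(samples$stroke)
  tap_ids <- as.integer(names(counts)[counts < 2])
  if (length(tap_ids)) {
    warn(sprintf("dropping %d single-sample stroke(s)", length(tap_ids)))
    samples <- samples[!samples$stroke %in% tap_ids, ]
    ups <- ups[!ups$stroke %in% tap_ids, ]
  }
  if (!nrow(samples)) {
    stop_figcopy("no strokes with >= 2 samples", "figcopy_empty_error")
  }
  # renumber strokes 1..n in drawing order
  ids <- sort(unique(samples$stroke))
  remap <- stats::setNames(seq_along(ids), ids)
  samples$stroke <- as.integer(remap[as.character(samples$stroke)])
  ups$stroke <- as.integer(remap[as.character(ups$stroke)])

  strokes <- stroke_geometry(samples) |>
    dplyr::left_join(ups, by = "stroke") |>
    dplyr::mutate(
      duration_s = .data$t_up - .data$t_down,
      mean_speed_cm_s = ifelse(.data$duration_s > 0,
                               .data$path_length_cm / .data$duration_s, NA_real_)
    ) |>
    dplyr::select("stroke", "t_down", "t_up", "n_samples", "path_length_cm",
                  "x_extent_cm", "y_extent_cm", "duration_s", "mean_speed_cm_s")
  new_rcft_session(samples, strokes, device)
}

#' Lower a session back to an event-log representation
#'
#' Produces the `attach`/`move`/`detach` rows that [segment_strokes()] would
#' re-segment into the same session (the detach row repeats the final contact
#' position at the stroke's `t_up`).
#'
#' @param session An [rcft_session].
#' @return An event tibble in device-pixel coordinates.
#' @export
session_to_events <- function(session) {
  stopifnot(inherits(session, "rcft_session"))
  dev <- session$device
  rows <- session$samples |>
    dplyr::group_by(.data$stroke) |>
    dplyr::group_map(function(df, key) {
      t_up <- session$strokes$t_up[session$strokes$stroke == key$stroke[1]]
      kind <- c("attach", rep("move", nrow(df) - 1L), "detach")
      tibble::tibble(
        t_s = c(df$t_s, t_up),
        x_cm = c(df$x_cm, df$x_cm[nrow(df)]),
        y_cm = c(df$y_cm, df$y_cm[nrow(df)]),
        event_kind = kind)
    }) |>
    dplyr::bind_rows()
  px <- cm_to_px(rows$x_cm, rows$y_cm, dev)
  ev <- tibble::tibble(t_s = rows$t_s, x_px = px$x_px, y_px = px$y_px,
                       event_kind = rows$event_kind)
  pen_events(ev, dev)
}
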
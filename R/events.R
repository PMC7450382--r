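#' Pen-event logs
#'
#' A pen-event log is the raw unit of ingestion: one row per pen event at the
#' device sampling rate, with columns
#' \describe{
#'   \item{t_s}{timestamp in seconds, non-decreasing;}
#'   \item{x_px, y_px}{position in device pixels, `x_px` rightward from the
#'     left edge, `y_px` downward from the top edge;}
#'   \item{event_kind}{one of `"attach"` (pen touches the surface), `"move"`
#'     (contact maintained), `"detach"` (pen lifted).}
#' }
#' `attach` and `move` rows are contact samples; a `detach` row marks the
#' lift-off time (its coordinates echo the last contact position).
#'
#' @name pen-events
NULL

event_kinds <- c("attach", "move", "detach")

#' Construct a pen-event table
#'
#' Validates and orders a data frame of raw pen events. If `t_s` is absent,
#' timestamps are synthesized as `index / sample_rate_hz` with a warning.
#'
#' @param data Data frame with columns `t_s` (optional), `x_px`, `y_px`,
#'   `event_kind`.
#' @param device A [device_spec()] used for coordinate bounds checks.
#' @return A tibble of events with the device attached as attribute `device`.
#' @export
pen_events <- function(data, device = device_spec()) {
  stopifnot(inherits(device, "device_spec"))
  need <- c("x_px", "y_px", "event_kind")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop_figcopy(paste0("event log lacks columns: ",
                        paste(missing, collapse = ", ")),
                 "figcopy_format_error")
  }
  ev <- tibble::as_tibble(data)
  if (!"t_s" %in% names(ev)) {
    warn("event log has no t_s column; synthesizing t_s = index / sample_rate_hz")
    ev$t_s <- (seq_len(nrow(ev)) - 1) / device$sample_rate_hz
  }
  ev <- dplyr::select(ev, "t_s", "x_px", "y_px", "event_kind")
  if (!all(ev$event_kind %in% event_kinds)) {
    stop_figcopy("event_kind must be one of attach/move/detach",
                 "figcopy_format_error")
  }
  if (is.unsorted(ev$t_s)) {
    stop_figcopy("timestamps are not non-decreasing", "figcopy_order_error")
  }
  bad_x <- ev$x_px < 0 | ev$x_px >= device$width_px
  bad_y <- ev$y_px < 0 | ev$y_px >= device$height_px
  if (any(bad_x | bad_y)) {
    stop_figcopy(sprintf("%d events lie outside the %d x %d px display",
                         sum(bad_x | bad_y), device$width_px, device$height_px),
                 "figcopy_range_error")
  }
  attr(ev, "device") <- device
  ev
}

#' Read or write an event-log CSV
#'
#' The on-disk format is a plain CSV with header `t_s,x_px,y_px,event_kind`,
#' paired with a JSON device sidecar (see [read_device_spec()]).
#'
#' @param path CSV file path.
#' @param device A [device_spec()], or a path to a device JSON sidecar.
#' @return `read_pen_log()` returns an ordered event tibble; `write_pen_log()`
#'   returns `path` invisibly.
#' @export
read_pen_log <- function(path, device = device_spec()) {
  if (is.character(device)) device <- read_device_spec(device)
  if (!file.exists(path)) {
    stop_figcopy(paste0("event log not found: ", path), "figcopy_format_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pen_events(raw, device)
}

#' @rdname read_pen_log
#' @param events An event tibble from [pen_events()].
#' @export
write_pen_log <- function(events, path) {
  readr::write_csv(events[, c("t_s", "x_px", "y_px", "event_kind")], path)
  invisible(path)
}

#' Check attach/move/detach pairing of an event log
#'
#' Sessions whose logs violate the contact state machine (a move or detach
#' with no preceding attach, or an attach never closed by a detach) are not
#' analyzable and are flagged unusable, mirroring the exclusion of recordings
#' with mismatched attach/detach and movement pairs.
#'
#' @param events An event tibble from [pen_events()].
#' @return A tibble of violations (`row`, `t_s`, `violation`) with attribute
#'   `usable` (`TRUE` when no violations). See also [events_usable()].
#' @examples
#' ev <- pen_events(data.frame(
#'   t_s = c(0, 1, 2), x_px = c(10, 12, 12), y_px = c(10, 12, 12),
#'   event_kind = c("attach", "move", "detach")))
#' validate_events(ev)
#' @export
validate_events <- function(events) {
  down <- FALSE
  out <- list()
  for (i in seq_len(nrow(events))) {
    kind <- events$event_kind[i]
    bad <- switch(kind,
      attach = if (down) "unmatched attach" else NA_character_,
      move   = if (!down) "orphan move" else NA_character_,
      detach = if (!down) "orphan detach" else NA_character_
    )
    if (!is.na(bad)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        row = i, t_s = events$t_s[i], violation = bad)
    }
    down <- switch(kind, attach = TRUE, detach = FALSE, down)
  }
  if (down) {
    out[[length(out) + 1L]] <- tibble::tibble(
      row = nrow(events), t_s = events$t_s[nrow(events)],
      violation = "unclosed attach")
  }
  report <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(row = integer(), t_s = numeric(), violation = character())
  attr(report, "usable") <- nrow(report) == 0L
  report
}

#' @rdname validate_events
#' @export
events_usable <- function(events) {
  isTRUE(attr(validate_events(events), "usable"))
}

#' Convert between device pixels and the physical working-space frame
#'
#' All metrics are reported in centimetres in a frame whose origin is the
#' centre of the working space (the lower half of the portrait display), with
#' +x rightward and +y upward. `px_to_cm()` also returns `y_norm`, the
#' display-normalized vertical coordinate on the -1..1 scale with 0 at the
#' display centre: the perceptual (stimulus) half is `y_norm > 0` and the
#' working (drawing) half is `y_norm <= 0` (the boundary is assigned to the
#' working space).
#'
#' @param x_px,y_px Pixel coordinates (`y_px` downward from the top edge).
#' @param x_cm,y_cm Physical coordinates in the working-space-centred frame.
#' @param device A [device_spec()].
#' @return A tibble: `px_to_cm()` gives `x_cm`, `y_cm`, `y_norm`;
#'   `cm_to_px()` gives `x_px`, `y_px`.
#' @examples
#' px_to_cm(720, 1620, device_spec())  # working-space centre -> (0, 0)
#' @export
px_to_cm <- function(x_px, y_px, device = device_spec()) {
  pitch <- px_pitch(device)
  if (any(pitch <= 0)) stop_figcopy("zero physical extent", "figcopy_config_error")
  cx <- device$width_px / 2
  cy <- 0.75 * device$height_px        # pixel row of the working-space centre
  tibble::tibble(
    x_cm = (x_px - cx) * pitch[["x"]] / 10,
    y_cm = (cy - y_px) * pitch[["y"]] / 10,
    y_norm = (device$height_px / 2 - y_px) / (device$height_px / 2)
  )
}

#' @rdname px_to_cm
#' @export
cm_to_px <- function(x_cm, y_cm, device = device_spec()) {
  pitch <- px_pitch(device)
  tibble::tibble(
    x_px = x_cm * 10 / pitch[["x"]] + device$width_px / 2,
    y_px = 0.75 * device$height_px - y_cm * 10 / pitch[["y"]]
  )
}

#' Physically calibrate an event log
#'
#' Appends `x_cm`, `y_cm`, `y_norm` and the logical `contact` column
#' (`TRUE` for attach/move rows) to an event tibble.
#'
#' @inheritParams validate_events
#' @param device A [device_spec()]; defaults to the device attached to the log.
#' @return The event tibble with physical coordinates appended.
#' @export
to_physical <- function(events, device = attr(events, "device")) {
  if (is.null(device)) device <- device_spec()
  phys <- px_to_cm(events$x_px, events$y_px, device)
  out <- dplyr::bind_cols(events, phys)
  out$contact <- out$event_kind %in% c("attach", "move")
  attr(out, "device") <- device
  out
}
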
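#' Pseudocolour stroke-order rendering
#'
#' Copying sequences are visualized by splitting the strokes into order
#' deciles and colouring each decile along a fixed red-to-blue ramp: with 40
#' strokes, the first 4 (the first 10%) are red, the next 4 yellow-ward, and
#' so on to blue.
#'
#' @name sequence-render
NULL

# fixed 10-anchor ramp, red through yellow/green to blue
sequence_palette_hex <- c(
  "#FF0000", "#FF4700", "#FF8F00", "#FFD700", "#AAC400",
  "#54B200", "#00A000", "#006A54", "#0035A9", "#0000FF")

#' @rdname sequence-render
#' @return `sequence_palette()` returns the 10 ordered hex colours.
#' @export
sequence_palette <- function() sequence_palette_hex

#' Assign order-decile bins to strokes
#'
#' Stroke `i` (1-based) of `n` receives bin `floor(10 * (i - 1) / n)`, an
#' integer 0-9; bins are non-decreasing in stroke order and all ten bins are
#' used whenever `n >= 10`.
#'
#' @param n_strokes Number of strokes (>= 1).
#' @return Integer vector of bin indices, length `n_strokes`.
#' @examples
#' assign_decile_colors(40)[1:8]  # 0 0 0 0 1 1 1 1
#' @export
assign_decile_colors <- function(n_strokes) {
  if (!is_scalar_number(n_strokes) || n_strokes < 1) {
    stop_figcopy("n_strokes must be a positive integer", "figcopy_arity_error")
  }
  as.integer(floor(10 * (seq_len(n_strokes) - 1) / n_strokes))
}

svg_num <- function(v) formatC(v, format = "f", digits = 3)

#' Render a session's copying sequence to SVG
#'
#' Writes a deterministic standalone SVG (byte-identical for identical
#' sessions): each stroke is a polyline in its decile colour, drawn over the
#' working space, optionally with the stimulus template shown in grey in the
#' perceptual space.
#'
#' @param session An [rcft_session].
#' @param path Output file path.
#' @param stimulus Optional stimulus polyline tibble drawn for context
#'   (default [rcft_template()]); `NULL` omits it.
#' @param scale_px_per_cm Rendering scale (default 20).
#' @return `path`, invisibly.
#' @export
write_sequence_svg <- function(session, path, stimulus = rcft_template(),
                               scale_px_per_cm = 20) {
  stopifnot(inherits(session, "rcft_session"))
  dev <- session$device
  half_w <- dev$width_mm / 20
  h_cm <- dev$height_mm / 10
  # viewport: full display, working-space-centred frame; SVG y runs downward
  top_cm <- 3 * h_cm / 4
  to_px <- function(x, y) list(x = (x + half_w) * scale_px_per_cm,
                               y = (top_cm - y) * scale_px_per_cm)
  w_px <- 2 * half_w * scale_px_per_cm
  h_px <- h_cm * scale_px_per_cm
  bins <- assign_decile_colors(nrow(session$strokes))
  cols <- sequence_palette_hex[bins + 1L]
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            svg_num(w_px), svg_num(h_px), svg_num(w_px), svg_num(h_px)),
    sprintf('<rect width="%s" height="%s" fill="#FFFFFF"/>', svg_num(w_px), svg_num(h_px)),
    sprintf('<line x1="0" y1="%s" x2="%s" y2="%s" stroke="#CCCCCC" stroke-dasharray="4 4"/>',
            svg_num((top_cm - h_cm / 4) * scale_px_per_cm), svg_num(w_px),
            svg_num((top_cm - h_cm / 4) * scale_px_per_cm))
  )
  if (!is.null(stimulus)) {
    # stimulus shown centred in the perceptual half
    off_y <- h_cm / 2
    for (pid in unique(stimulus$polyline)) {
      pp <- stimulus[stimulus$polyline == pid, ]
      p <- to_px(pp$x, pp$y + off_y)
      lines <- c(lines, sprintf(
        '<polyline points="%s" fill="none" stroke="#BBBBBB" stroke-width="1"/>',
        paste(sprintf("%s,%s", svg_num(p$x), svg_num(p$y)), collapse = " ")))
    }
  }
  for (i in seq_len(nrow(session$strokes))) {
    ss <- session$samples[session$samples$stroke == session$strokes$stroke[i], ]
    p <- to_px(ss$x_cm, ss$y_cm)
    lines <- c(lines, sprintf(
      '<polyline points="%s" fill="none" stroke="%s" stroke-width="2" stroke-linecap="round"/>',
      paste(sprintf("%s,%s", svg_num(p$x), svg_num(p$y)), collapse = " "),
      cols[i]))
  }
  lines <- c(lines, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Plot a session's copying sequence
#'
#' ggplot2 rendering of the stroke-order pseudocolour figure: strokes in
#' decile colours, the display midline dashed, and the stimulus in grey.
#'
#' @param object An [rcft_session].
#' @param stimulus Optional stimulus polyline tibble (default
#'   [rcft_template()]); `NULL` omits it.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rcft_session
#' @export
autoplot.rcft_session <- function(object, stimulus = rcft_template(), ...) {
  bins <- assign_decile_colors(nrow(object$strokes))
  samp <- object$samples |>
    dplyr::mutate(bin = factor(bins[match(.data$stroke,
                                          object$strokes$stroke)], levels = 0:9))
  h_cm <- object$device$height_mm / 10
  p <- ggplot2::ggplot(samp, ggplot2::aes(.data$x_cm, .data$y_cm,
                                          group = .data$stroke,
                                          colour = .data$bin)) +
    ggplot2::geom_hline(yintercept = h_cm / 4, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = sequence_palette_hex,
                                 limits = factor(0:9), name = "decile") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
  if (!is.null(stimulus)) {
    stim <- dplyr::mutate(stimulus, y = .data$y + h_cm / 2)
    p <- p + ggplot2::geom_path(
      data = stim, ggplot2::aes(.data$x, .data$y, group = .data$polyline),
      colour = "grey70", inherit.aes = FALSE)
  }
  p
}

#' Plot a correlation surface as a heat map
#'
#' @param object An `rcft_xcorr` from [cross_correlate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rcft_xcorr
#' @export
autoplot.rcft_xcorr <- function(object, ...) {
  df <- tidy.rcft_xcorr(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$shift_x, .data$shift_y,
                                   fill = .data$coefficient)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x shift (cells)", y = "y shift (cells)") +
    ggplot2::theme_minimal()
}
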
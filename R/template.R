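#' The simplified complex-figure stimulus template
#'
#' The stimulus is an eight-component simplification of the classic complex
#' figure: four global components (the large rectangle, its horizontal and
#' vertical cross-lines, and the diagonal cross) and four local components
#' (four horizontal arrows in the upper-left quadrant, a square hanging below
#' the rectangle, double concentric circles in the upper-right quadrant, and
#' three small triangles in the lower-left quadrant). Geometry is fixed by the
#' versioned constants below, in centimetres in a template frame whose origin
#' is the rectangle centre; the rectangle is 8 x 6 cm. The figure's published
#' layout fixes the composition but not absolute coordinates, so any
#' self-consistent geometry supports the downstream metrics.
#'
#' @return A tibble with one row per vertex: `component`, `kind`
#'   (`"global"`/`"local"`), `polyline` (integer id, unique across the
#'   template) and `x`, `y` in cm.
#' @examples
#' tpl <- rcft_template()
#' dplyr::distinct(tpl, component, kind)
#' @export
rcft_template <- function() {
  pl <- function(component, kind, xs, ys) {
    tibble::tibble(component = component, kind = kind, x = xs, y = ys)
  }
  circle <- function(cx, cy, r, n = 24) {
    th <- seq(0, 2 * pi, length.out = n + 1)
    list(x = cx + r * cos(th), y = cy + r * sin(th))
  }
  arrow <- function(y) {
    # shaft left-to-right, then upper barb, retrace to tip, lower barb
    pl("four_arrows", "local",
       c(-3.4, -0.6, -1.0, -0.6, -1.0),
       c(y, y, y + 0.25, y, y - 0.25))
  }
  tri <- function(cx) {
    pl("three_triangles", "local",
       c(cx - 0.35, cx + 0.35, cx, cx - 0.35),
       c(-2.4, -2.4, -1.6, -2.4))
  }
  parts <- list(
    pl("rectangle", "global", c(-4, 4, 4, -4, -4), c(-3, -3, 3, 3, -3)),
    pl("horizontal_cross", "global", c(-4, 4), c(0, 0)),
    pl("vertical_cross", "global", c(0, 0), c(-3, 3)),
    pl("diagonal_cross", "global", c(-4, 4), c(-3, 3)),
    pl("diagonal_cross", "global", c(-4, 4), c(3, -3)),
    arrow(0.6), arrow(1.2), arrow(1.8), arrow(2.4),
    pl("square", "local", c(2.2, 3.8, 3.8, 2.2, 2.2), c(-3, -3, -4.4, -4.4, -3)),
    {
      ci <- circle(2, 1.5, 0.8)
      pl("double_circles", "local", ci$x, ci$y)
    },
    {
      ci <- circle(2, 1.5, 0.45)
      pl("double_circles", "local", ci$x, ci$y)
    },
    tri(-3), tri(-2), tri(-1)
  )
  out <- purrr::imap(parts, function(df, i) {
    df$polyline <- i
    df
  }) |> dplyr::bind_rows()
  out[, c("component", "kind", "polyline", "x", "y")]
}

#' Summarise template composition
#'
#' @param template A template tibble from [rcft_template()].
#' @return Tibble with one row per component: `component`, `kind`,
#'   `n_polylines`, `path_length_cm`.
#' @export
template_components <- function(template = rcft_template()) {
  template |>
    dplyr::group_by(.data$component, .data$kind, .data$polyline) |>
    dplyr::summarise(
      len = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)), .groups = "drop") |>
    dplyr::group_by(.data$component, .data$kind) |>
    dplyr::summarise(n_polylines = dplyr::n(),
                     path_length_cm = sum(.data$len), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$kind == "global"), .data$component)
}

#' Aggregate the eight component scores
#'
#' Each of the eight components is rated 2 (accurately drawn, correctly
#' placed), 1 (one of accuracy or placement failed), 0.5 (inaccurate and
#' misplaced but recognizable) or 0 (unrecognizable); the total is their sum,
#' spanning 0.0-16.0. The visual judgement itself is a human rating; only the
#' aggregation arithmetic is encoded here.
#'
#' @param scores Numeric vector of exactly 8 values, each in
#'   \{0, 0.5, 1, 2\}.
#' @return The total score (scalar).
#' @examples
#' aggregate_component_scores(rep(2, 8))  # 16
#' @export
aggregate_component_scores <- function(scores) {
  if (length(scores) != 8L) {
    stop_figcopy("exactly 8 component scores are required", "figcopy_arity_error")
  }
  if (!is.numeric(scores) || !all(scores %in% c(0, 0.5, 1, 2))) {
    stop_figcopy("component scores must each be one of 0, 0.5, 1, 2",
                 "figcopy_domain_error")
  }
  sum(scores)
}
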
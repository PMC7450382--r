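#' Dunn-Sidak multiplicity adjustment
#'
#' Adjusts a pairwise p-value for a family of `k` comparisons as
#' `p = 1 - (1 - p0)^k`, clipped to `[0, 1]`. With the three study groups
#' there are three pairwise tests, hence the default `k = 3`.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param k Family size (default 3).
#' @return Adjusted p-value(s).
#' @examples
#' dunn_sidak(0.05)  # 0.142625
#' @export
dunn_sidak <- function(p, k = 3) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_figcopy("p-values must lie in [0, 1]", "figcopy_domain_error")
  }
  pmin(pmax(1 - (1 - p)^k, 0), 1)
}

#' Kruskal-Wallis test across groups
#'
#' Tidy wrapper for the rank-based H test with tie correction
#' (chi-square approximation, df = groups - 1).
#'
#' @param data Data frame with one row per session.
#' @param value,group Column names (strings) of the metric and group label.
#' @return One-row tibble: `statistic` (H), `df`, `p.value`, `n`.
#' @export
kruskal_wallis <- function(data, value, group) {
  df <- data[!is.na(data[[value]]), ]
  g <- factor(df[[group]])
  if (nlevels(g) < 2 || any(table(g) < 1)) {
    stop_figcopy("need >= 2 non-empty groups", "figcopy_arity_error")
  }
  if (length(unique(df[[value]])) < 2) {
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L,
                          p.value = 1, n = nrow(df)))
  }
  kt <- kruskal.test(df[[value]], g)
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p.value = kt$p.value, n = nrow(df))
}

#' Pairwise Mann-Whitney tests with Dunn-Sidak correction
#'
#' Two-tailed Mann-Whitney U per group pair (exact when the pooled size is at
#' most 20 and untied, otherwise the normal approximation with continuity and
#' tie correction), each adjusted as `1 - (1 - p0)^family`.
#'
#' @inheritParams kruskal_wallis
#' @param family Dunn-Sidak family size; default 3 (the three-group design),
#'   independent of how many pairs are actually tested.
#' @return Tibble with one row per pair: `group1`, `group2`, `n1`, `n2`,
#'   `statistic` (U), `p.value` (raw), `p.adjusted`.
#' @export
pairwise_mwu <- function(data, value, group, family = 3) {
  df <- data[!is.na(data[[value]]), ]
  g <- factor(df[[group]])
  if (any(table(g) < 1) || nlevels(g) < 2) {
    stop_figcopy("need >= 2 non-empty groups", "figcopy_arity_error")
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- df[[value]][g == pr[1]]
    y <- df[[value]][g == pr[2]]
    exact <- (length(x) + length(y)) <= 20 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE))
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   n1 = length(x), n2 = length(y),
                   statistic = unname(wt$statistic),
                   p.value = wt$p.value,
                   p.adjusted = dunn_sidak(wt$p.value, family))
  })
}

#' Pearson correlation with a two-tailed t-test
#'
#' Used to validate digital metrics against conventional scores.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, both with spread).
#' @return One-row tibble: `estimate` (r), `statistic` (t), `df`, `p.value`,
#'   `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_figcopy("need n >= 3", "figcopy_arity_error")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_figcopy("zero variance; correlation undefined",
                 "figcopy_undefined_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p.value = ct$p.value,
                 n = length(x))
}

#' Group comparison across all session metrics
#'
#' Builds the metric-table harness: for every metric column, per-group
#' summaries (mean, SD, median, IQR, non-missing n), the Kruskal-Wallis test,
#' and pairwise Mann-Whitney tests with Dunn-Sidak adjustment. Sessions with
#' a missing metric are excluded from that metric's tests only; a metric
#' computable in fewer than two groups is flagged (`note`), not fatal.
#'
#' @param data Data frame with one row per session: a group column plus
#'   numeric metric columns (e.g. from [analyze_cohort()]).
#' @param group Name of the group column (default `"group"`).
#' @param metrics Character vector of metric columns; defaults to all numeric
#'   columns except identifiers.
#' @param family Dunn-Sidak family size (default 3).
#' @return An object of class `rcft_comparison`; see [tidy.rcft_comparison()]
#'   and [glance.rcft_comparison()].
#' @export
compare_groups <- function(data, group = "group", metrics = NULL, family = 3) {
  metrics <- metrics %||% setdiff(
    names(data)[vapply(data, is.numeric, logical(1))],
    c(group, "id", "seed"))
  if (!length(metrics)) stop_figcopy("no metric columns", "figcopy_arity_error")
  summaries <- purrr::map_dfr(metrics, function(m) {
    data |>
      dplyr::group_by(group = .data[[group]]) |>
      dplyr::summarise(
        n = sum(!is.na(.data[[m]])),
        mean = mean(.data[[m]], na.rm = TRUE),
        sd = sd(.data[[m]], na.rm = TRUE),
        median = stats::median(.data[[m]], na.rm = TRUE),
        iqr_lo = stats::quantile(.data[[m]], 0.25, na.rm = TRUE, names = FALSE),
        iqr_hi = stats::quantile(.data[[m]], 0.75, na.rm = TRUE, names = FALSE),
        .groups = "drop") |>
      dplyr::mutate(metric = m, .before = 1)
  })
  rows <- purrr::map(metrics, function(m) {
    present <- summaries[summaries$metric == m & summaries$n > 0, ]
    if (nrow(present) < 2) {
      return(list(metric = m, kw = NULL, pairwise = NULL,
                  note = "metric available in fewer than 2 groups"))
    }
    kw <- tryCatch(kruskal_wallis(data, m, group),
                   figcopy_error = function(e) NULL)
    pw <- tryCatch(pairwise_mwu(data, m, group, family),
                   figcopy_error = function(e) NULL)
    list(metric = m, kw = kw, pairwise = pw, note = NA_character_)
  })
  structure(list(rows = rows, summaries = summaries, group = group,
                 family = family, metrics = metrics),
            class = "rcft_comparison")
}

#' @export
print.rcft_comparison <- function(x, ...) {
  cat(sprintf("<rcft_comparison> %d metrics, family size %g\n",
              length(x$metrics), x$family))
  print(glance.rcft_comparison(x))
  invisible(x)
}

#' Tidy and glance at a group comparison
#'
#' `tidy()` returns one row per metric and group pair with the raw and
#' Dunn-Sidak-adjusted Mann-Whitney p-values; `glance()` returns one row per
#' metric with the Kruskal-Wallis result.
#'
#' @param x An `rcft_comparison` from [compare_groups()].
#' @param ... Unused.
#' @method tidy rcft_comparison
#' @export
tidy.rcft_comparison <- function(x, ...) {
  purrr::map_dfr(x$rows, function(r) {
    if (is.null(r$pairwise)) return(tibble::tibble())
    dplyr::mutate(r$pairwise, metric = r$metric, .before = 1)
  })
}

#' @rdname tidy.rcft_comparison
#' @method glance rcft_comparison
#' @export
glance.rcft_comparison <- function(x, ...) {
  purrr::map_dfr(x$rows, function(r) {
    if (is.null(r$kw)) {
      return(tibble::tibble(metric = r$metric, statistic = NA_real_,
                            df = NA_real_, p.value = NA_real_, n = NA_integer_,
                            note = r$note))
    }
    dplyr::mutate(r$kw, metric = r$metric, note = r$note, .before = 1)
  })
}

#' Summary table in the published layout
#'
#' One row per metric: per-group "mean (SD)" strings and the adjusted
#' pairwise p-values.
#'
#' @param comparison An `rcft_comparison`.
#' @return A tibble.
#' @export
comparison_table <- function(comparison) {
  wide <- comparison$summaries |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f)", .data$mean, .data$sd)) |>
    dplyr::select("metric", "group", "cell") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
  pw <- tidy.rcft_comparison(comparison)
  if (nrow(pw)) {
    pw <- pw |>
      dplyr::mutate(pair = paste(.data$group1, "vs", .data$group2)) |>
      dplyr::select("metric", "pair", "p.adjusted") |>
      tidyr::pivot_wider(names_from = "pair", values_from = "p.adjusted")
    wide <- dplyr::left_join(wide, pw, by = "metric")
  }
  wide
}

#' Box plots of metrics by group
#'
#' @param object An `rcft_comparison`.
#' @param data Original per-session metric data frame used to build it.
#' @param ... Unused.
#' @return A ggplot object faceted by metric.
#' @method autoplot rcft_comparison
#' @export
autoplot.rcft_comparison <- function(object, data, ...) {
  long <- tidyr::pivot_longer(
    data, dplyr::all_of(object$metrics),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data[[object$group]], .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
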
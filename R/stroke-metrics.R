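#' One-dimensional k-means++ with restarts and a guaranteed global optimum
#'
#' 1-D k-means used to split stroke lengths into two classes: k-means++
#' initialisation, Lloyd iterations, `nstart` restarts keeping the lowest
#' within-cluster sum of squares, deterministic given `seed`. Because the
#' k = 2 optimum in one dimension is a contiguous threshold split, a
#' prefix-sum scan over all n - 1 splits is evaluated as an additional
#' candidate, so the returned partition is always the global optimum of the
#' k-means objective (Lloyd restarts can occasionally stall in a local
#' minimum).
#'
#' @param x Numeric values.
#' @param k Number of clusters (default 2).
#' @param seed RNG seed (default 0).
#' @param nstart Restarts (default 10).
#' @return List with `centers` (sorted ascending), `cluster` (index into
#'   `centers` per value) and `tot_withinss`.
#' @export
kmeans1d <- function(x, k = 2L, seed = 0L, nstart = 10L) {
  if (length(unique(x)) < k) {
    stop_figcopy("k-means is degenerate: fewer distinct values than clusters",
                 "figcopy_degenerate_error")
  }
  withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- x[sample.int(length(x), 1L)]
      while (length(centers) < k) {
        d2 <- vapply(x, function(v) min((v - centers)^2), numeric(1))
        centers <- c(centers, if (all(d2 == 0)) sample(x, 1L) else
          x[sample.int(length(x), 1L, prob = d2)])
      }
      repeat {
        cl <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
        new_centers <- vapply(seq_len(k), function(j)
          if (any(cl == j)) mean(x[cl == j]) else centers[j], numeric(1))
        if (isTRUE(all.equal(new_centers, centers, tolerance = 1e-12))) break
        centers <- new_centers
      }
      wss <- sum((x - centers[cl])^2)
      if (is.null(best) || wss < best$tot_withinss - 1e-12) {
        best <- list(centers = centers, cluster = cl, tot_withinss = wss)
      }
    }
    if (k == 2L) {
      # exact candidate: best contiguous split by prefix sums
      xs <- sort(x)
      n <- length(xs)
      cs <- cumsum(xs); cs2 <- cumsum(xs^2)
      ks <- which(xs[-n] != xs[-1])  # splits between distinct values only
      wss_lo <- cs2[ks] - cs[ks]^2 / ks
      wss_hi <- (cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / (n - ks)
      j <- ks[which.min(wss_lo + wss_hi)]
      thr <- (xs[j] + xs[j + 1]) / 2
      cl <- ifelse(x > thr, 2L, 1L)
      centers <- c(mean(x[cl == 1L]), mean(x[cl == 2L]))
      wss <- sum((x - centers[cl])^2)
      if (wss < best$tot_withinss - 1e-12) {
        best <- list(centers = centers, cluster = cl, tot_withinss = wss)
      }
    }
    ord <- order(best$centers)
    list(centers = best$centers[ord],
         cluster = match(best$cluster, ord),
         tot_withinss = best$tot_withinss)
  })
}

#' Classify strokes as long or short
#'
#' Strokes are operationally split into long and short lines by running 1-D
#' k-means++ (k = 2) separately on the x-projected and y-projected lengths
#' (axis-aligned extents); a stroke is *long* when it is labelled long in
#' either projection (the union rule; `rule = "x"` or `"y"` restrict to a
#' single projection for sensitivity analysis). Within a projection the final
#' label is thresholded at the midpoint of the two centroids, with ties
#' assigned to short; a projection with no spread contributes no long labels.
#'
#' @param session An [rcft_session].
#' @param seed RNG seed for the k-means initialisation (default 0).
#' @param rule `"union"` (default), `"x"`, or `"y"`.
#' @return A tibble with one row per stroke (`stroke`, `x_extent_cm`,
#'   `y_extent_cm`, `long_x`, `long_y`, `label`), with the per-projection
#'   centroids in attribute `centroids` and the rule/seed in attribute
#'   `method`.
#' @export
classify_long_short <- function(session, seed = 0L,
                                rule = c("union", "x", "y")) {
  rule <- match.arg(rule)
  st <- session$strokes
  if (nrow(st) < 2L) {
    stop_figcopy("need >= 2 strokes to classify", "figcopy_arity_error")
  }
  project <- function(v) {
    if (length(unique(v)) < 2L) {
      return(list(long = rep(FALSE, length(v)), centers = c(NA_real_, NA_real_)))
    }
    km <- kmeans1d(v, 2L, seed = seed)
    thr <- mean(km$centers)
    list(long = v > thr, centers = km$centers)
  }
  px <- project(st$x_extent_cm)
  py <- project(st$y_extent_cm)
  if (all(is.na(px$centers)) && all(is.na(py$centers))) {
    stop_figcopy("all projected lengths identical in both projections",
                 "figcopy_degenerate_error")
  }
  long <- switch(rule,
                 union = px$long | py$long,
                 x = px$long,
                 y = py$long)
  out <- tibble::tibble(
    stroke = st$stroke,
    x_extent_cm = st$x_extent_cm,
    y_extent_cm = st$y_extent_cm,
    long_x = px$long, long_y = py$long,
    label = ifelse(long, "long", "short"))
  attr(out, "centroids") <- list(x = px$centers, y = py$centers)
  attr(out, "method") <- list(k = 2L, seed = seed, rule = rule, nstart = 10L)
  out
}

#' Fraction of long strokes among the first five
#'
#' The first five strokes are taken as the beginning of the task (typically
#' the strokes that lay down the figure's framework).
#'
#' @param classification Output of [classify_long_short()].
#' @return Fraction in `[0, 1]`.
#' @export
first5_long_ratio <- function(classification) {
  if (nrow(classification) < 5L) {
    stop_figcopy("need >= 5 strokes for the first-5 ratio",
                 "figcopy_insufficient_error")
  }
  head5 <- classification$label[order(classification$stroke)][1:5]
  sum(head5 == "long") / 5
}

#' Drawing speed of the longest stroke
#'
#' Speed (path length / duration) of the stroke with the greatest path
#' length, the stroke most likely used to construct the figure's framework.
#' Ties go to the earliest stroke.
#'
#' @param session An [rcft_session].
#' @return Speed in cm/s.
#' @export
longest_stroke_speed <- function(session) {
  st <- session$strokes
  if (!nrow(st)) stop_figcopy("no strokes", "figcopy_empty_error")
  i <- which.max(st$path_length_cm)  # first maximum = earliest stroke
  if (!is.finite(st$duration_s[i]) || st$duration_s[i] <= 0) {
    stop_figcopy("longest stroke has zero duration; speed undefined",
                 "figcopy_undefined_error")
  }
  st$path_length_cm[i] / st$duration_s[i]
}

#' Short-to-long transition times
#'
#' For every adjacent stroke pair in which stroke *i* is short and stroke
#' *i + 1* is long, the transition time is the gap between the short stroke's
#' pen-up and the long stroke's pen-down. The summary mean excludes outlier
#' gaps above `outlier_s` (default 60 s); the raw list is retained.
#'
#' @param session An [rcft_session].
#' @param classification Output of [classify_long_short()].
#' @param outlier_s Exclusion threshold in seconds for the mean (default 60).
#' @return List with `gaps_s` (numeric vector, possibly empty) and
#'   `mean_s` (outlier-excluded mean; `NA` when no gap qualifies).
#' @export
transition_times <- function(session, classification, outlier_s = 60) {
  st <- session$strokes[order(session$strokes$stroke), ]
  lab <- classification$label[order(classification$stroke)]
  n <- nrow(st)
  idx <- which(lab[-n] == "short" & lab[-1] == "long")
  gaps <- st$t_down[idx + 1L] - st$t_up[idx]
  kept <- gaps[gaps <= outlier_s]
  list(gaps_s = gaps,
       mean_s = if (length(kept)) mean(kept) else NA_real_)
}

#' Elapsed time of the five early long strokes
#'
#' Time from the session's first pen-down to the pen-up of the fifth long
#' stroke — roughly the time spent laying down the rectangle and its
#' horizontal/vertical/diagonal cross-lines.
#'
#' @inheritParams transition_times
#' @return Time in seconds.
#' @export
elapsed_time_5_long <- function(session, classification) {
  st <- session$strokes[order(session$strokes$stroke), ]
  lab <- classification$label[order(classification$stroke)]
  long_idx <- which(lab == "long")
  if (length(long_idx) < 5L) {
    stop_figcopy("fewer than 5 long strokes", "figcopy_insufficient_error")
  }
  st$t_up[long_idx[5L]] - st$t_down[1L]
}

#' All pen-stroke metrics for a session
#'
#' Composes the stroke feature family into a single one-row tibble:
#' stroke counts by class, mean Euclidean path length, first-5 long ratio,
#' longest-stroke speed, outlier-excluded mean transition time and the
#' elapsed time of the five early long strokes. Metrics whose preconditions
#' fail (e.g. fewer than five long strokes) are `NA`.
#'
#' @param session An [rcft_session].
#' @param seed RNG seed for the long/short classification.
#' @param rule Projection rule passed to [classify_long_short()].
#' @return A one-row tibble.
#' @export
stroke_metrics <- function(session, seed = 0L, rule = "union") {
  cls <- classify_long_short(session, seed = seed, rule = rule)
  tt <- transition_times(session, cls)
  maybe <- function(expr) tryCatch(expr, figcopy_error = function(e) NA_real_)
  tibble::tibble(
    n_strokes = nrow(session$strokes),
    n_long = sum(cls$label == "long"),
    n_short = sum(cls$label == "short"),
    mean_stroke_length_cm = mean(session$strokes$path_length_cm),
    first5_long_ratio = maybe(first5_long_ratio(cls)),
    longest_stroke_speed_cm_s = maybe(longest_stroke_speed(session)),
    transition_time_s = tt$mean_s,
    n_transitions = length(tt$gaps_s),
    elapsed_5long_s = maybe(elapsed_time_5_long(session, cls))
  )
}
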
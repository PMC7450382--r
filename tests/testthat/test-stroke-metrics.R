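# fixture: strokes with prescribed extents/times, drawn as thin L-shapes so
# x/y extents are controlled independently
session_with_extents <- function(xe, ye, t0 = seq_along(xe) * 10,
                                 dur = rep(1, length(xe))) {
  strokes <- lapply(seq_along(xe), function(i) {
    data.frame(t = c(t0[i], t0[i] + dur[i] / 2, t0[i] + dur[i]),
               x = c(0, xe[i], xe[i]) - 4,
               y = c(0, 0, ye[i]) - 4)
  })
  session_from_strokes(strokes)
}

test_that("1-D k-means++ recovers the optimal threshold partition", {
  s <- session_with_extents(c(1, 1, 1, 9, 9), rep(0.5, 5))
  cls <- classify_long_short(s)
  expect_equal(cls$label, c("short", "short", "short", "long", "long"))

  # partitions match exhaustive threshold enumeration on random fixtures
  withr::with_seed(7, {
    for (i in 1:40) {
      n <- sample(5:40, 1)
      x <- round(c(runif(n %/% 2, 0, 3), runif(n - n %/% 2, 0, 9)), 2)
      if (length(unique(x)) < 2) next
      km <- kmeans1d(x, 2, seed = i)
      thr <- brute_split2(x)$threshold
      expect_identical(km$cluster == 2, x > thr, info = paste("fixture", i))
    }
  })

  expect_error(kmeans1d(rep(2, 5)), class = "figcopy_degenerate_error")
})

test_that("the union rule labels a stroke long if either projection says so", {
  # x flags stroke 4-5, y flags stroke 1 -> union flags all three
  s <- session_with_extents(c(1, 1, 1, 9, 9), c(8, 0.5, 0.5, 0.5, 0.5))
  un <- classify_long_short(s, rule = "union")
  lx <- classify_long_short(s, rule = "x")
  ly <- classify_long_short(s, rule = "y")
  expect_identical(un$label == "long",
                   lx$label == "long" | ly$label == "long")
  expect_true(all(which(lx$label == "long") %in% which(un$label == "long")))
  expect_true(all(which(ly$label == "long") %in% which(un$label == "long")))

  # identical bimodal projections: union equals either alone
  s2 <- session_with_extents(c(1, 1, 8, 8), c(1, 1, 8, 8))
  expect_identical(classify_long_short(s2, rule = "union")$label,
                   classify_long_short(s2, rule = "x")$label)

  expect_error(
    classify_long_short(session_with_extents(c(2, 2, 2), c(3, 3, 3))),
    class = "figcopy_degenerate_error")
})

test_that("first-5 ratio counts long strokes at the task's beginning", {
  s <- session_with_extents(c(9, 9, 9, 9, 1, 1), rep(0.5, 6))
  cls <- classify_long_short(s)
  expect_equal(first5_long_ratio(cls), 0.8)

  s2 <- session_with_extents(c(9, 9, 9, 9, 9, 1), rep(0.5, 6))
  # ordered long-first: manual count of labels among strokes 1-5
  cls2 <- classify_long_short(s2)
  expect_equal(first5_long_ratio(cls2),
               sum(cls2$label[1:5] == "long") / 5)

  s3 <- session_with_extents(c(1, 9, 9, 1), rep(0.5, 4))
  expect_error(first5_long_ratio(classify_long_short(s3)),
               class = "figcopy_insufficient_error")
})

test_that("drawing speed comes from the longest stroke, not the fastest", {
  s <- session_from_strokes(list(
    data.frame(t = c(0, 1), x = c(0, 5), y = c(0, 0)),      # 5 cm in 1 s
    data.frame(t = c(10, 14), x = c(2, 2), y = c(-5, 5))))  # 10 cm in 4 s
  expect_equal(longest_stroke_speed(s), 2.5)

  s1 <- session_from_strokes(list(
    data.frame(t = c(0, 2), x = c(0, 0), y = c(-5, 5))))
  expect_equal(longest_stroke_speed(s1), 5)

  # brute-force max-by-length scan on a random synthetic session
  sess <- generate_session(synthetic_profile(seed = 9))
  st <- sess$strokes
  i <- which.max(st$path_length_cm)
  expect_equal(longest_stroke_speed(sess),
               st$path_length_cm[i] / st$duration_s[i])
})

test_that("transition times collect short-to-long gaps and drop >60 s outliers", {
  # strokes: short, long, short, long, short, long with gaps 1, 2, 100 s
  xe <- c(1, 9, 1, 9, 1, 9)
  t0 <- c(0, 3, 10, 14, 20, 122)  # gaps before longs: 3-2=1, 14-12=2, 122-22=100
  s <- session_with_extents(xe, rep(0.5, 6), t0 = t0, dur = rep(2, 6))
  cls <- classify_long_short(s)
  tt <- transition_times(s, cls)
  expect_equal(tt$gaps_s, c(1, 2, 100))
  expect_equal(tt$mean_s, 1.5)

  # invariance to adding further >60 s gaps
  t0b <- c(t0, 300, 500)
  sb <- session_with_extents(c(xe, 1, 9), rep(0.5, 8), t0 = t0b,
                             dur = rep(2, 8))
  ttb <- transition_times(sb, classify_long_short(sb))
  expect_equal(ttb$mean_s, 1.5)
  expect_equal(length(ttb$gaps_s), 4)

  # no short->long adjacency: mean is missing, not zero
  sl <- session_with_extents(c(9, 9, 1), rep(0.5, 3))
  ttl <- transition_times(sl, classify_long_short(sl))
  expect_length(ttl$gaps_s, 0)
  expect_true(is.na(ttl$mean_s))

  # alternating fixture: list length equals the number of S->L adjacencies
  xs <- rep(c(1, 9), 6)
  sa <- session_with_extents(xs, rep(0.5, 12), t0 = seq_along(xs) * 5,
                             dur = rep(1, 12))
  ca <- classify_long_short(sa)
  lab <- ca$label
  expect_length(transition_times(sa, ca)$gaps_s,
                sum(lab[-length(lab)] == "short" & lab[-1] == "long"))
})

test_that("elapsed time of 5 early long strokes spans session start to 5th long pen-up", {
  # five long strokes of 1 s separated by 1 s gaps: 5th pen-up at t = 9 s
  s_all <- session_with_extents(c(9, 9, 9, 9, 9, 1), rep(0.5, 6),
                                t0 = (0:5) * 2, dur = rep(1, 6))
  cls_all <- classify_long_short(s_all)
  expect_equal(elapsed_time_5_long(s_all, cls_all), 9)

  # inserting a short stroke before the 5th long stroke increases the value
  s_ins <- session_with_extents(c(9, 9, 9, 9, 1, 9), rep(0.5, 6),
                                t0 = (0:5) * 2, dur = rep(1, 6))
  expect_gt(elapsed_time_5_long(s_ins, classify_long_short(s_ins)), 9)

  s_few <- session_with_extents(c(9, 9, 1, 1, 1, 1), rep(0.5, 6))
  expect_error(elapsed_time_5_long(s_few, classify_long_short(s_few)),
               class = "figcopy_insufficient_error")
})

test_that("stroke_metrics composes the feature family with missing-value fallbacks", {
  s <- generate_session(synthetic_profile(seed = 21))
  m <- stroke_metrics(s)
  expect_equal(m$n_long + m$n_short, m$n_strokes)
  expect_equal(m$mean_stroke_length_cm, mean(s$strokes$path_length_cm))
  expect_true(m$first5_long_ratio >= 0 && m$first5_long_ratio <= 1)

  s3 <- session_with_extents(c(1, 9, 1), rep(0.5, 3))
  m3 <- stroke_metrics(s3)
  expect_equal(m3$n_strokes, 3)
  expect_true(is.na(m3$first5_long_ratio))
})
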
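test_that("event logs parse, bound-check and round-trip through CSV", {
  dev <- tiny_device()
  ev <- make_events(c("attach", "move", "detach"), c(0, 1 / 60, 2 / 60),
                    c(10, 11, 11), c(20, 21, 21), dev)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$t_s, c(0, 1 / 60, 2 / 60))

  expect_error(
    make_events("attach", 0, 5000, 10, dev),
    class = "figcopy_range_error")
  expect_error(
    pen_events(data.frame(x_px = 1, event_kind = "attach"), dev),
    class = "figcopy_format_error")
  expect_error(
    make_events(c("attach", "move"), c(1, 0), c(1, 1), c(1, 1), dev),
    class = "figcopy_order_error")

  # a synthetic 40-stroke log written to CSV reads back identically
  s <- generate_session(synthetic_profile(fragmentation = 3, seed = 11))
  log <- session_to_events(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pen_log(log, path)
  back <- read_pen_log(path, s$device)
  expect_equal(as.data.frame(back), as.data.frame(log), tolerance = 1e-12)
})

test_that("missing timestamps are synthesized from the sample rate", {
  dev <- tiny_device()
  expect_warning(
    ev <- pen_events(data.frame(x_px = c(1, 2, 3), y_px = c(1, 2, 3),
                                event_kind = c("attach", "move", "detach")),
                     dev),
    "synthesizing")
  expect_equal(ev$t_s, (0:2) / dev$sample_rate_hz)
})

test_that("attach/detach pairing violations are reported and block segmentation", {
  dev <- tiny_device()
  ok <- make_events(c("attach", "move", "detach"), 0:2, c(1, 2, 2),
                    c(1, 2, 2), dev)
  expect_true(events_usable(ok))

  orphan <- make_events(c("move", "attach", "detach"), 0:2, c(1, 1, 1),
                        c(1, 1, 1), dev)
  rep <- validate_events(orphan)
  expect_false(attr(rep, "usable"))
  expect_true("orphan move" %in% rep$violation)
  expect_error(segment_strokes(orphan), class = "figcopy_session_invalid_error")

  double <- make_events(c("attach", "attach", "detach"), 0:2, c(1, 1, 1),
                        c(1, 1, 1), dev)
  expect_true("unmatched attach" %in% validate_events(double)$violation)

  # exhaustive check of all length-3 event sequences against a reference
  # state machine
  kinds <- c("attach", "move", "detach")
  combos <- expand.grid(a = kinds, b = kinds, c = kinds,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    seq3 <- unlist(combos[i, ])
    ev <- make_events(seq3, 0:2, c(1, 1, 1), c(1, 1, 1), dev)
    down <- FALSE; bad <- FALSE
    for (k in seq3) {
      if (k == "attach") { if (down) bad <- TRUE; down <- TRUE }
      if (k == "move" && !down) bad <- TRUE
      if (k == "detach") { if (!down) bad <- TRUE; down <- FALSE }
    }
    if (down) bad <- TRUE
    expect_identical(events_usable(ev), !bad, info = paste(seq3, collapse = ","))
  }
})

test_that("pixel-to-physical conversion uses per-axis pitch and inverts exactly", {
  dev <- device_spec()  # 1440 px over 162 mm
  a <- px_to_cm(720, 1620, dev)
  b <- px_to_cm(820, 1620, dev)
  expect_equal(b$x_cm - a$x_cm, 162 / 1440 * 100 / 10)  # 1.125 cm
  # display centre is the space boundary
  expect_equal(px_to_cm(100, 1080, dev)$y_norm, 0)

  xs <- runif(200, 0, dev$width_px - 1)
  ys <- runif(200, 0, dev$height_px - 1)
  cm <- px_to_cm(xs, ys, dev)
  back <- cm_to_px(cm$x_cm, cm$y_cm, dev)
  expect_lt(max(abs(back$x_px - xs)), 1e-9)
  expect_lt(max(abs(back$y_px - ys)), 1e-9)
})

test_that("segmentation builds one stroke per attach run with physical geometry", {
  dev <- tiny_device()
  ev <- make_events(c("attach", "move", "move", "move", "detach"),
                    (0:4) / 10, c(50, 52, 54, 56, 56), c(160, 158, 156, 154, 154),
                    dev)
  s <- segment_strokes(ev)
  expect_equal(nrow(s$strokes), 1)
  expect_equal(s$strokes$n_samples, 4)

  # 3-4-5 triangle: straight segment from (0,0) to (3,4) cm
  s2 <- session_from_strokes(list(
    data.frame(t = c(0, 1), x = c(0, 3), y = c(0, 4))))
  expect_equal(s2$strokes$path_length_cm, 5)
  expect_equal(s2$strokes$x_extent_cm, 3)
  expect_equal(s2$strokes$y_extent_cm, 4)
  expect_equal(s2$strokes$duration_s, 1)
  expect_equal(s2$strokes$mean_speed_cm_s, 5)

  # 40 attach/detach pairs -> 40 strokes; contact samples are partitioned
  n <- 40
  rows <- lapply(seq_len(n), function(i) {
    t0 <- (i - 1) * 1
    tibble::tibble(t_s = t0 + c(0, 0.1, 0.2),
                   x_px = c(10, 12, 12) + i, y_px = c(150, 152, 152),
                   event_kind = c("attach", "move", "detach"))
  })
  ev40 <- pen_events(dplyr::bind_rows(rows), dev)
  s40 <- segment_strokes(ev40)
  expect_equal(nrow(s40$strokes), n)
  expect_equal(nrow(s40$samples), sum(ev40$event_kind %in% c("attach", "move")))

  # single-sample taps are dropped with a warning
  tap <- make_events(c("attach", "detach", "attach", "move", "detach"),
                     (0:4) / 10, c(10, 10, 20, 22, 22), c(150, 150, 150, 152, 152),
                     dev)
  expect_warning(st <- segment_strokes(tap), "single-sample")
  expect_equal(nrow(st$strokes), 1)
})

test_that("samples partition into perceptual and working halves by y_norm", {
  s <- generate_session(synthetic_profile(seed = 5, vertical_offset_cm = 4))
  midline_cm <- s$device$height_mm / 40
  expect_equal(s$samples$y_norm, s$samples$y_cm / (2 * midline_cm) - 0.5)
  above <- s$samples$y_norm > 0
  expect_gt(sum(above), 0)           # the offset pushes input over the midline
  expect_gt(sum(!above), 0)
  expect_equal(sum(above) + sum(!above), nrow(s$samples))
})
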
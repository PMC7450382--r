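test_that("the whole area is the extremum bounding box of all input", {
  s <- session_from_strokes(list(
    data.frame(t = c(0, 1), x = c(-2, 3), y = c(-1, 4))))
  wb <- whole_area(s)
  expect_equal(c(wb$x_min, wb$x_max, wb$y_min, wb$y_max), c(-2, 3, -1, 4))
  expect_equal(wb$area_cm2, 25)
  expect_equal(wb$center_y, 1.5)
  expect_equal(wb$top_edge, 4)

  # degenerate single point
  sp <- session_from_strokes(list(
    data.frame(t = c(0, 0.1), x = c(1, 1), y = c(2, 2))))
  wp <- whole_area(sp)
  expect_equal(wp$area_cm2, 0)
  expect_equal(c(wp$center_x, wp$center_y), c(1, 2))

  # brute per-axis scan on a synthetic tracing
  sess <- generate_session(synthetic_profile(seed = 2))
  wbs <- whole_area(sess)
  expect_equal(wbs$x_min, min(sess$samples$x_cm))
  expect_equal(wbs$y_max, max(sess$samples$y_cm))
})

test_that("the skeleton filter drops sparsely visited subregions", {
  # dense rectangle border plus one stray far sample
  border <- local({
    t <- seq(0, 1, length.out = 400)
    xy <- lapply(t, function(u) {
      p <- u * 4
      if (p < 1) c(p * 4 - 2, -2) else if (p < 2) c(2, (p - 1) * 4 - 2)
      else if (p < 3) c(2 - (p - 2) * 4, 2) else c(-2, 2 - (p - 3) * 4)
    })
    data.frame(t = seq_along(t) / 60,
               x = vapply(xy, `[`, numeric(1), 1),
               y = vapply(xy, `[`, numeric(1), 2))
  })
  stray <- data.frame(t = c(10, 10.05), x = c(7.5, 7.6), y = c(5.5, 5.6))
  s <- session_from_strokes(list(border, stray))
  sk <- skeleton_area(s)
  wb <- whole_area(s)
  expect_lt(sk$x_max, 7)       # the stray cell is excluded
  expect_equal(wb$x_max, 7.6)  # but still bounds the whole area
  expect_equal(c(sk$x_min, sk$y_min), c(-2, -2), tolerance = 1e-6)

  # grid-count oracle: recompute retained extremums directly
  ext <- list(x = range(s$samples$x_cm), y = range(s$samples$y_cm))
  ix <- pmin(floor((s$samples$x_cm - ext$x[1]) / diff(ext$x) * 10) + 1, 10)
  iy <- pmin(floor((s$samples$y_cm - ext$y[1]) / diff(ext$y) * 10) + 1, 10)
  counts <- table(paste(ix, iy))
  keep <- names(counts)[counts >= 0.25 * max(counts)]
  inkeep <- paste(ix, iy) %in% keep
  expect_equal(sk$x_max, max(s$samples$x_cm[inkeep]))
  expect_equal(sk$y_max, max(s$samples$y_cm[inkeep]))

  # threshold 0 keeps everything
  sk0 <- skeleton_area(s, threshold = 0)
  expect_equal(as.data.frame(sk0), as.data.frame(wb))

  # uniform occupancy: skeleton equals whole box
  g <- expand.grid(x = seq(-4.95, 4.95, by = 0.1), y = seq(-4.95, 4.95, by = 0.1))
  su <- session_from_strokes(list(
    data.frame(t = seq_len(nrow(g)) / 60, x = g$x, y = g$y)))
  sku <- skeleton_area(su)
  expect_equal(as.data.frame(sku), as.data.frame(whole_area(su)))
})

test_that("skeleton containment and threshold monotonicity hold on random sessions", {
  for (seed in c(3, 14, 27)) {
    s <- generate_session(eoad_profile(seed = seed))
    wb <- whole_area(s)
    sk <- skeleton_area(s)
    expect_gte(sk$x_min, wb$x_min)
    expect_lte(sk$x_max, wb$x_max)
    expect_gte(sk$y_min, wb$y_min)
    expect_lte(sk$y_max, wb$y_max)
    # raising the threshold never enlarges the box
    sk2 <- skeleton_area(s, threshold = 0.5)
    expect_gte(sk2$x_min, sk$x_min)
    expect_lte(sk2$area_cm2, sk$area_cm2 + 1e-9)
  }
})

test_that("centre of mass is the unweighted mean of occupied cells", {
  # cells centred at (0,0) and (2,2)
  r <- rasterize_points(tibble::tibble(x = c(0, 2), y = c(0, 2)), 1,
                        extent = list(x = c(-0.5, 2.5), y = c(-0.5, 2.5)))
  expect_equal(as.numeric(com_of_raster(r)), c(1, 1))

  r1 <- rasterize_points(tibble::tibble(x = 0.3, y = 0.9), 0.2)
  cells <- raster_cells(r1)
  expect_equal(as.numeric(com_of_raster(r1)), unname(c(cells$x, cells$y)))

  # random occupancy: matches the direct binary-mass sum
  withr::with_seed(12, {
    m <- matrix(runif(15 * 11) < 0.3, 15, 11)
    m[1, 1] <- TRUE
    r2 <- raster_from_matrix(m)
    idx <- which(m, arr.ind = TRUE)
    expect_equal(as.numeric(com_of_raster(r2)),
                 c(mean(idx[, 1] - 0.5), mean(idx[, 2] - 0.5)))
  })

  # translation equivariance on a real session raster
  s <- generate_session(synthetic_profile(seed = 4))
  com0 <- center_of_mass(s)
  s2 <- s
  s2$samples$x_cm <- s2$samples$x_cm + 1.2
  s2$samples$y_cm <- s2$samples$y_cm - 0.8
  com1 <- center_of_mass(s2)
  expect_equal(com1$x_cm - com0$x_cm, 1.2, tolerance = 1e-9)
  expect_equal(com1$y_cm - com0$y_cm, -0.8, tolerance = 1e-9)
})

test_that("the ratio of input counts samples above the display midline", {
  dev <- device_spec()
  mid <- dev$height_mm / 40
  # 3 of 12 samples above the midline
  pts <- data.frame(t = (1:12) / 60,
                    x = rep(0, 12),
                    y = c(rep(mid + 1, 3), rep(mid - 1, 9)))
  s <- session_from_strokes(list(pts))
  expect_equal(perceptual_input_ratio(s), 0.25)

  below <- session_from_strokes(list(
    data.frame(t = c(0, 1), x = c(0, 1), y = c(-2, -3))))
  expect_equal(perceptual_input_ratio(below), 0)

  # invariant under horizontal shift, monotone under upward shift
  s2 <- s
  s2$samples$x_cm <- s2$samples$x_cm + 3
  expect_equal(perceptual_input_ratio(s2), 0.25)
  s3 <- s
  s3$samples$y_norm <- s3$samples$y_norm + 0.1
  expect_gte(perceptual_input_ratio(s3), 0.25)

  # synthetic closing-in session: ratio equals a direct count
  sess <- generate_session(eoad_profile(seed = 8))
  expect_equal(perceptual_input_ratio(sess),
               sum(sess$samples$y_norm > 0) / nrow(sess$samples))
})
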
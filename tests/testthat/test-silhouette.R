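test_that("constructor validates masks and derives the pixel scale", {
  s <- frontal_silhouette(matrix(1L, 10, 10), width_m = 10)
  expect_equal(s$scale, 1.0)
  expect_equal(sum(s$mask), 100L)
  expect_equal(silhouette_area(s), 100)

  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  s4 <- frontal_silhouette(checker, width_m = 4)
  expect_equal(sum(s4$mask), 8L)

  # scale invariant and area self-consistency on a non-trivial mask
  set.seed(11)
  m <- random_mask(30, 50)
  s2 <- frontal_silhouette(m, width_m = 14.35)
  expect_equal(s2$scale, 14.35 / 50)
  expect_equal(silhouette_area(s2), sum(m) * s2$scale^2)

  expect_error(frontal_silhouette(matrix(0L, 5, 5), 5), "empty mask")
  expect_error(frontal_silhouette(matrix(c(0, 2), 2, 2), 2), "only 0 and 1")
  expect_error(frontal_silhouette(matrix(1L, 2, 2), -1), "positive")
})

test_that("reference conversion: 1031 columns over 14.35 m give the printed scale", {
  s <- frontal_silhouette(matrix(1L, 2, 1031), width_m = 14.35)
  expect_equal(round(s$scale, 4), 0.0139)
  expect_equal(length_to_pixels(1.15, s), 83L)
})

test_that("length_to_pixels rounds to whole pixels with a floor of one", {
  s <- frontal_silhouette(matrix(1L, 2, 100), width_m = 10)  # scale 0.1
  expect_equal(length_to_pixels(s$scale, s), 1L)
  expect_equal(length_to_pixels(10 * s$scale, s), 10L)
  expect_equal(length_to_pixels(s$scale / 5, s), 1L)  # sub-pixel floors at 1
  expect_error(length_to_pixels(-1, s), "positive")
})

test_that("silhouettes round-trip through text, PNG and PGM files", {
  set.seed(21)
  s <- frontal_silhouette(random_mask(12, 17), width_m = 3.4)

  txt <- withr::local_tempfile(fileext = ".txt")
  write_silhouette(s, txt)
  expect_equal(read_silhouette(txt, 3.4)$mask, s$mask)

  png_f <- withr::local_tempfile(fileext = ".png")
  write_silhouette(s, png_f)
  expect_equal(read_silhouette(png_f, 3.4)$mask, s$mask)

  # plain-text PGM, occupied = dark
  pgm <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "# comment", "17 12", "255",
               paste(t(ifelse(s$mask == 1L, 0L, 255L)), collapse = " ")), pgm)
  expect_equal(read_silhouette(pgm, 3.4)$mask, s$mask)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 1", "1 0"), bad)
  expect_error(read_silhouette(bad, 1), "non-rectangular")
  writeLines(c("0 0", "0 0"), bad)
  expect_error(read_silhouette(bad, 1), "empty mask")
  expect_error(read_silhouette("does/not/exist.txt", 1), "cannot read")
})

test_that("window integral handles interior, straddling and exterior windows", {
  ones <- frontal_silhouette(matrix(1L, 8, 40), width_m = 40)
  expect_equal(window_probability(ones, 20, 4), 1.0)
  expect_equal(window_probability(ones, -400, 4), 0.0)

  half <- frontal_silhouette(rbind(matrix(1L, 4, 40), matrix(0L, 4, 40)), 40)
  expect_equal(window_probability(half, 20, 4), 0.5)

  # straddling the right edge: half the window out of bounds
  expect_equal(window_probability(ones, 40, 4), 0.5)
  expect_error(window_probability(ones, 20, -1), "positive")
})

test_that("vectorized window integral equals the naive pixel-loop oracle", {
  set.seed(31)
  for (i in 1:100) {
    nr <- sample(3:40, 1); nc <- sample(5:80, 1)
    m <- random_mask(nr, nc, runif(1, 0.1, 0.9))
    w <- runif(1, 0.5, 30)
    s <- frontal_silhouette(m, w)
    l <- runif(1, 0.02, 0.6) * w
    d <- runif(1, -1.5 * w, 2.5 * w)   # interior, straddling and exterior
    expect_identical(window_probability(s, d, l),
                     naive_window_probability(m, w, d, l))
  }
})

test_that("window integral is bounded, mirror-symmetric and superset-monotone", {
  set.seed(41)
  for (i in 1:20) {
    m <- random_mask(10, 60)
    s <- frontal_silhouette(m, 12)
    d <- runif(50, -12, 24)
    p <- window_probability(s, d, 1.3)
    expect_true(all(p >= 0 & p <= 1))

    # adding occupied pixels never decreases the probability anywhere
    m2 <- m
    m2[sample(which(m == 0L), min(30, sum(m == 0L)))] <- 1L
    p2 <- window_probability(frontal_silhouette(m2, 12), d, 1.3)
    expect_true(all(p2 >= p))
  }

  # mirror symmetry for a mask symmetric about its vertical midline
  set.seed(42)
  half <- random_mask(12, 30)
  sym <- cbind(half, half[, 30:1])
  s <- frontal_silhouette(sym, 10)
  d <- seq(-2, 12, by = 0.05)
  p_left <- window_probability(s, d, 0.9)
  p_right <- window_probability(s, 10 - d, 0.9)
  # discretization can shift the window by one pixel; bound the disagreement
  # by one column's worth of occupancy
  L <- length_to_pixels(0.9, s)
  expect_true(all(abs(p_left - p_right) <= nrow(sym) / (L * nrow(sym)) + 1e-12))
})

test_that("parametric generator rasterizes components deterministically", {
  # full-canvas rectangle occupies every pixel
  full <- generate_silhouette(
    silhouette_spec(10, 5, rects = rbind(c(0, 10, 0, 5))), resolution = 50)
  expect_true(all(full$mask == 1L))
  expect_true(all(colSums(full$mask) == nrow(full$mask)))

  # all component sizes zero -> empty mask is an error
  expect_error(
    generate_silhouette(silhouette_spec(10, 5, disks = rbind(c(5, 2, 0)))),
    "empty mask")

  # components outside the canvas are rejected
  expect_error(silhouette_spec(10, 5, disks = rbind(c(9.5, 2, 1))), "outside")
  expect_error(silhouette_spec(10, 5, rects = rbind(c(2, 11, 0, 1))), "outside")

  # bit-exact reproducibility for a fixed spec and resolution
  a <- generate_silhouette(silhouette_spec_737(), resolution = 300)
  b <- generate_silhouette(silhouette_spec_737(), resolution = 300)
  expect_identical(a$mask, b$mask)
})

test_that("default airliner silhouette has a trimodal occupancy profile", {
  s <- generate_silhouette(silhouette_spec_737(), resolution = 1031)
  peaks <- profile_peaks(occupancy_profile(s))
  expect_length(peaks, 3L)
  x <- (peaks - 0.5) * s$scale
  # engine-fuselage-engine at the spec's component centers
  expect_equal(x, c(14.35 / 2 - 4.7, 14.35 / 2, 14.35 / 2 + 4.7),
               tolerance = 0.02)
})
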
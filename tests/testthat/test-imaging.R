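make_stack <- function(...) {
  mats <- list(...)
  arr <- array(0, c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

test_that("illumination correction modes behave algebraically", {
  f1 <- matrix(runif(64 * 64, 50, 200), 64)
  stack <- make_stack(f1, f1 * 1.1)
  expect_identical(correct_illumination(stack, "none"), stack)

  flat <- render_flatfield(c(64, 64), 0.3)
  corrupted <- make_stack(f1 * flat, f1 * 1.1 * flat)
  fixed <- correct_illumination(corrupted, "divide_flatfield", reference = flat)
  expect_equal(fixed[1, , ], f1, tolerance = 1e-12)
  expect_error(
    correct_illumination(corrupted, "divide_flatfield",
                         reference = matrix(0, 64, 64)), "zeros")

  # constant frame: the estimated background equals the constant
  const <- make_stack(matrix(7, 32, 32))
  sub <- correct_illumination(const, "subtract_background")
  expect_true(all(sub == 0))

  # background + one bright object: estimator recovers the offset from
  # the dim majority (median of pixels after dropping the brightest 10%)
  mixed <- matrix(10, 32, 32); mixed[10:15, 10:15] <- 500
  keep <- mixed <= quantile(mixed, 0.9, names = FALSE)
  b <- median(mixed[keep])
  expect_equal(b, 10)
  sub2 <- correct_illumination(make_stack(mixed), "subtract_background")
  expect_equal(sub2[1, 1, 1], max(10 - b, 0))
  expect_equal(sub2[1, 12, 12], 500 - b)

  # noisy background: the estimate is centered, not biased low
  set.seed(12)
  noisy <- matrix(rnorm(96 * 96, mean = 50, sd = 5), 96)
  out <- correct_illumination(make_stack(noisy), "subtract_background")
  est <- noisy - out[1, , ]            # pixels not clipped at zero
  expect_lt(abs(mean(est[noisy > 60]) - 50), 1)
})

test_that("nuclear segmentation finds disks and splits touching pairs", {
  blank <- matrix(5, 96, 96)
  expect_identical(max(segment_nuclei(blank)), 0L)

  one <- draw_disk(matrix(0, 96, 96), c(48, 48), 10, 100)
  lab <- segment_nuclei(one)
  expect_identical(max(lab), 1L)
  cent <- mask_centroids(lab)
  expect_lt(sqrt((cent$row - 48)^2 + (cent$col - 48)^2), 1)
  expect_lt(abs(sum(lab > 0) / (pi * 100) - 1), 0.1)

  two <- draw_disk(draw_disk(matrix(0, 96, 96), c(40, 48), 10, 100),
                   c(58, 48), 10, 100)
  expect_identical(max(segment_nuclei(two, split_touching = TRUE)), 2L)

  # area filter removes specks and giants
  speck <- draw_disk(one, c(10, 10), 2, 100)
  expect_identical(max(segment_nuclei(speck, min_area_px = 20)), 1L)
})

test_that("cytoring matches the brute-force distance oracle on hand cases", {
  m <- draw_disk(matrix(0L, 64, 64), c(32, 32), 8, 1L)
  expect_identical(build_cytoring(m, 10), oracle_cytoring(m, 10))

  expect_identical(build_cytoring(matrix(0L, 32, 32), 10),
                   matrix(0L, 32, 32))

  two <- draw_disk(matrix(0L, 64, 64), c(26, 32), 5, 1L)
  two <- draw_disk(two, c(38, 32), 5, 2L)
  ring <- build_cytoring(two, 10)
  expect_identical(ring, oracle_cytoring(two, 10))
  expect_identical(sum(ring > 0L & two > 0L), 0L)  # disjoint from nuclei
  # every contested pixel goes to its nearer nucleus
  idx <- which(ring > 0L, arr.ind = TRUE) - 1L
  d1 <- (idx[, 1] - 26)^2 + (idx[, 2] - 32)^2
  d2 <- (idx[, 1] - 38)^2 + (idx[, 2] - 32)^2
  lab <- ring[ring > 0L]
  expect_true(all(lab[d1 < d2] == 1L) && all(lab[d2 < d1] == 2L))
})

test_that("cytoring construction is exact on random masks and rings stay disjoint", {
  set.seed(101)
  for (i in 1:25) {
    m <- random_label_mask(96)
    w <- sample(c(4, 7, 10), 1)
    ring <- build_cytoring(m, w)
    expect_identical(ring, oracle_cytoring(m, w))
    expect_identical(sum(ring > 0L & m > 0L), 0L)
  }
})

test_that("measurement is a pure per-compartment mean ratio", {
  m <- draw_disk(matrix(0L, 64, 64), c(32, 32), 8, 1L)
  ring <- build_cytoring(m, 10)

  uni <- matrix(3.5, 64, 64)
  res <- measure_cells(uni, m, ring, 5L)
  expect_equal(res$cn_ratio, 1)
  expect_identical(res$frame, 5L)

  frame <- matrix(0, 64, 64)
  frame[m == 1L] <- 2
  frame[ring == 1L] <- 4
  expect_equal(measure_cells(frame, m, ring)$cn_ratio, 2)

  # global positive scaling leaves the ratio untouched
  expect_equal(measure_cells(frame * 37.5, m, ring)$cn_ratio, 2)

  expect_error(measure_cells(matrix(1, 32, 32), m, ring), "shape")

  # empty ring is flagged, not dropped
  res2 <- measure_cells(frame, m, matrix(0L, 64, 64))
  expect_identical(res2$flag, "EMPTY_RING")
  expect_true(is.na(res2$cn_ratio))
})

test_that("flatfield-corrupted noiseless renders are recovered within 3%", {
  cfg <- small_movie_config(n_cells = 3, frac_dividing = 0, seed = 31,
                            duration_h = 2, division_window_h = c(1.2, 1.8))
  pop <- simulate_cell_population(cfg)
  rc <- render_config(image_shape = c(400, 400), background_offset = 50,
                      flatfield_amplitude = 0.25)
  img <- render_timelapse(pop$cells, rc, cfg)
  erk <- correct_illumination(img[, 2, , ], "subtract_background")
  erk <- correct_illumination(erk, "divide_flatfield",
                              reference = attr(img, "flatfield"))
  for (f in c(1, 5, 9)) {
    nuc <- segment_nuclei(img[f, 1, , ] - 50)
    ring <- build_cytoring(nuc, 10)
    m <- measure_cells(erk[f, , ], nuc, ring, f - 1L)
    cents <- mask_centroids(nuc)
    for (i in seq_along(pop$cells)) {
      d <- sqrt((cents$row - pop$cells[[i]]$path[f, 1])^2 +
                  (cents$col - pop$cells[[i]]$path[f, 2])^2)
      j <- which.min(d)
      expect_lt(abs(m$cn_ratio[m$label == cents$label[j]] /
                      pop$cells[[i]]$cn_erk[f] - 1), 0.03)
    }
  }
})
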
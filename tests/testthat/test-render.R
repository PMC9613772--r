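test_that("empty scene renders pure background", {
  cfg <- small_movie_config(n_cells = 1, duration_h = 2,
                            frac_dividing = 0,
                            division_window_h = c(1.2, 1.8))
  rc <- render_config(image_shape = c(32, 32), background_offset = 100,
                      flatfield_amplitude = 0, gaussian_noise_sd = 0)
  img <- render_timelapse(list(), rc, cfg)
  expect_true(all(img == 100))
  expect_identical(dim(img), c(n_frames(cfg), 3L, 32L, 32L))
})

test_that("oracle disk/annulus quantification recovers ground-truth C/N", {
  cfg <- small_movie_config(n_cells = 1, frac_dividing = 0, seed = 9,
                            motion_sd_px = 0)
  pop <- simulate_cell_population(cfg)
  rc <- render_config(image_shape = c(400, 400), background_offset = 0)
  img <- render_timelapse(pop$cells, rc, cfg)
  cell <- pop$cells[[1]]
  for (f in c(1, 10, 25)) {
    nucpix <- matrix(FALSE, 400, 400)
    nucpix <- draw_disk(nucpix, cell$path[f, ], rc$nucleus_radius_px, TRUE)
    annpix <- draw_disk(matrix(FALSE, 400, 400), cell$path[f, ],
                        rc$cyto_radius_px, TRUE) & !nucpix
    frame <- img[f, 2, , ]
    cn <- mean(frame[annpix]) / mean(frame[nucpix])
    expect_lt(abs(cn / cell$cn_erk[f] - 1), 0.02)
  }
})

test_that("frame 0 contains one nuclear component per cell", {
  cfg <- small_movie_config(n_cells = 30, duration_h = 2, seed = 21,
                            frac_dividing = 0,
                            division_window_h = c(1.2, 1.8))
  pop <- simulate_cell_population(cfg)
  rc <- render_config(image_shape = c(400, 400))
  img <- render_timelapse(pop$cells, rc, cfg)
  comps <- EBImage::bwlabel(img[1, 1, , ] > rc$background_offset + 1)
  expect_equal(max(comps), 30)
})

test_that("division splits the nucleus into two displaced daughters", {
  cfg <- small_movie_config(n_cells = 1, frac_dividing = 1, seed = 13,
                            motion_sd_px = 0)
  pop <- simulate_cell_population(cfg)
  cell <- pop$cells[[1]]
  rc <- render_config(image_shape = c(400, 400))
  img <- render_timelapse(pop$cells, rc, cfg)
  before <- cell$division_frame            # 1-based index of last pre-drop frame
  after <- cell$division_frame + cfg$drop_span_frames + 1L
  n_before <- max(EBImage::bwlabel(img[before, 1, , ] > rc$background_offset + 1))
  n_after <- max(EBImage::bwlabel(img[after, 1, , ] > rc$background_offset + 1))
  expect_equal(n_before, 1)
  expect_equal(n_after, 2)
  cents <- mask_centroids(segment_nuclei(img[after, 1, , ] - rc$background_offset))
  expect_gte(sqrt(diff(cents$row)^2 + diff(cents$col)^2),
             2 * rc$nucleus_radius_px)
})

test_that("the rendered drop signature lowers the measured C/N", {
  cfg <- small_movie_config(n_cells = 1, frac_dividing = 1, seed = 13,
                            motion_sd_px = 0)
  pop <- simulate_cell_population(cfg)
  cell <- pop$cells[[1]]
  rc <- render_config(image_shape = c(400, 400), background_offset = 0)
  img <- render_timelapse(pop$cells, rc, cfg)
  drop_f <- cell$division_frame + 1L
  nuc <- segment_nuclei(img[drop_f, 1, , ])
  ring <- build_cytoring(nuc, 10)
  m <- measure_cells(img[drop_f, 3, , ], nuc, ring, drop_f - 1L)
  expect_lt(abs(m$cn_ratio[1] / cell$cn_akt[drop_f] - 1), 0.02)
  expect_lt(m$cn_ratio[1], cell$akt_activity[drop_f] * 0.6)
})

test_that("unresolvably overlapping nuclei raise an error naming the cells", {
  cfg <- small_movie_config(n_cells = 2, duration_h = 2, seed = 2,
                            frac_dividing = 0,
                            division_window_h = c(1.2, 1.8))
  pop <- simulate_cell_population(cfg)
  # force the second cell onto the first
  pop$cells[[2]]$path <- pop$cells[[1]]$path +
    matrix(c(3, 0), n_frames(cfg), 2, byrow = TRUE)
  rc <- render_config(image_shape = c(400, 400))
  expect_error(render_timelapse(pop$cells, rc, cfg), "overlap.*1, 2")
})

test_that("flatfield, blur and noise are applied on demand", {
  cfg <- small_movie_config(n_cells = 1, duration_h = 2, seed = 3,
                            frac_dividing = 0, motion_sd_px = 0,
                            division_window_h = c(1.2, 1.8),
                            arena_px = c(128, 128))
  rc0 <- render_config(image_shape = c(128, 128), background_offset = 10)
  pop2 <- simulate_cell_population(cfg)
  base <- render_timelapse(pop2$cells, rc0, cfg)
  rc_ff <- render_config(image_shape = c(128, 128), background_offset = 10,
                         flatfield_amplitude = 0.2)
  ff <- render_timelapse(pop2$cells, rc_ff, cfg)
  flat <- attr(ff, "flatfield")
  expect_equal(mean(flat), 1, tolerance = 1e-12)
  expect_equal(ff[1, 2, , ], (base[1, 2, , ] - 10) * flat + 10,
               tolerance = 1e-9)
  rc_blur <- render_config(image_shape = c(128, 128), background_offset = 10,
                           psf_sigma_px = 1)
  bl <- render_timelapse(pop2$cells, rc_blur, cfg)
  # blur softens edges: variance drops, intensity is conserved
  expect_lt(sd(bl[1, 1, , ]), sd(base[1, 1, , ]))
  expect_equal(sum(bl[1, 1, , ]), sum(base[1, 1, , ]), tolerance = 1e-3)
  set.seed(1)
  rc_noise <- render_config(image_shape = c(128, 128), background_offset = 10,
                            gaussian_noise_sd = 5)
  nz <- render_timelapse(pop2$cells, rc_noise, cfg)
  resid <- nz[1, 1, , ] - base[1, 1, , ]
  expect_lt(abs(sd(resid) - 5), 0.3)
})
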
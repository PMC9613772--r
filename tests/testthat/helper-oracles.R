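# Brute-force per-pixel cytoring oracle: for every background pixel,
# the exact squared Euclidean distance to every label's pixel set over
# the whole image; nearest label wins, ties to the lower label.
oracle_cytoring <- function(mask, width) {
  nr <- nrow(mask); nc <- ncol(mask)
  pr <- rep(0:(nr - 1), nc)
  pc <- rep(0:(nc - 1), each = nr)
  best_d2 <- rep(Inf, nr * nc)
  best_lab <- rep(0L, nr * nc)
  for (L in sort(unique(mask[mask > 0L]))) {
    idx <- which(mask == L)
    rl <- (idx - 1L) %% nr
    cl <- (idx - 1L) %/% nr
    d2 <- outer(pr, rl, `-`)^2 + outer(pc, cl, `-`)^2
    d2min <- do.call(pmin, as.data.frame(d2))
    upd <- d2min < best_d2
    best_lab[upd] <- L
    best_d2[upd] <- d2min[upd]
  }
  ring <- ifelse(best_d2 <= width^2 & as.vector(mask) == 0L, best_lab, 0L)
  matrix(as.integer(ring), nr, nc)
}

# random label mask of non-overlapping disks and rectangles
random_label_mask <- function(max_side = 96, n_shapes = NULL) {
  nr <- sample(48:max_side, 1)
  nc <- sample(48:max_side, 1)
  if (is.null(n_shapes)) n_shapes <- sample(2:5, 1)
  mask <- matrix(0L, nr, nc)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  lab <- 0L
  for (s in seq_len(n_shapes)) {
    for (try in 1:50) {
      r <- sample(3:9, 1)
      ctr <- c(stats::runif(1, 0, nr - 1), stats::runif(1, 0, nc - 1))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums((centers - matrix(ctr, nrow(centers), 2,
                                             byrow = TRUE))^2))) >
            r + max(radii) + 2) {
        lab <- lab + 1L
        rect <- stats::runif(1) < 0.3
        for (i in max(0, floor(ctr[1] - r)):min(nr - 1, ceiling(ctr[1] + r)))
          for (j in max(0, floor(ctr[2] - r)):min(nc - 1, ceiling(ctr[2] + r))) {
            inside <- if (rect) TRUE else
              (i - ctr[1])^2 + (j - ctr[2])^2 <= r^2
            if (inside) mask[i + 1, j + 1] <- lab
          }
        centers <- rbind(centers, ctr)
        radii <- c(radii, r)
        break
      }
    }
  }
  mask
}

# label masks stamped directly from ground-truth cell paths (the
# renderer's nuclear channel without photometry)
stamp_masks <- function(cells, n_frames, radius, dims) {
  lapply(seq_len(n_frames), function(f) {
    m <- matrix(0L, dims[1], dims[2])
    for (cell in cells) {
      if (!cell$in_frame[f]) next
      ctr <- cell$path[f, ]
      if (ctr[1] < 0 || ctr[1] > dims[1] - 1 ||
          ctr[2] < 0 || ctr[2] > dims[2] - 1) next
      r0 <- max(0, floor(ctr[1] - radius)); r1 <- min(dims[1] - 1, ceiling(ctr[1] + radius))
      c0 <- max(0, floor(ctr[2] - radius)); c1 <- min(dims[2] - 1, ceiling(ctr[2] + radius))
      for (i in r0:r1) for (j in c0:c1)
        if ((i - ctr[1])^2 + (j - ctr[2])^2 <= radius^2)
          m[i + 1, j + 1] <- cell$cell_id
    }
    m
  })
}

# draw a filled disk into a matrix (test fixture builder)
draw_disk <- function(mat, center, radius, value = 1) {
  nr <- nrow(mat); nc <- ncol(mat)
  for (i in max(0, floor(center[1] - radius)):min(nr - 1, ceiling(center[1] + radius)))
    for (j in max(0, floor(center[2] - radius)):min(nc - 1, ceiling(center[2] + radius)))
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2)
        mat[i + 1, j + 1] <- value
  mat
}

# small population whose movies render quickly
small_movie_config <- function(n_cells = 3, seed = 5, duration_h = 6,
                               frac_dividing = 1 / n_cells,
                               division_window_h = c(2, 5),
                               motion_sd_px = 0.5, ...) {
  sim_config(n_cells = n_cells, frac_dividing = frac_dividing,
             duration_h = duration_h, division_window_h = division_window_h,
             motion_sd_px = motion_sd_px, seed = seed, ...)
}
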
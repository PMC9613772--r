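#' Smooth multiplicative flatfield used by the renderer
#'
#' A separable cosine dome scaled to `1 + amplitude * f(x, y)` and then
#' normalized to unit mean, so that dividing a corrupted image by this
#' field restores it exactly.
#'
#' @param shape length-2 (rows, cols).
#' @param amplitude shading amplitude (0 gives a constant field of 1).
#' @return matrix of the given shape with mean exactly 1.
#' @export
render_flatfield <- function(shape, amplitude) {
  r <- seq_len(shape[1]) - 1
  c <- seq_len(shape[2]) - 1
  fr <- cos(pi * (r - (shape[1] - 1) / 2) / (shape[1] - 1))
  fc <- cos(pi * (c - (shape[2] - 1) / 2) / (shape[2] - 1))
  f <- 1 + amplitude * outer(fr, fc)
  f / mean(f)
}

# cytoplasmic fraction of total KTR intensity for a given C/N ratio;
# clipped so both compartments always carry signal
phi_from_cn <- function(cn) pmin(pmax(cn / (1 + cn), 0.05), 0.95)

#' Render a synthetic KTR time-lapse movie
#'
#' Draws every simulated cell as a filled nuclear disk (channel 1,
#' nuclear marker) plus nucleus + cytoplasmic annulus in the two KTR
#' channels (2 = ERK, 3 = Akt). A fixed per-pixel intensity budget is
#' split between compartments by the cytoplasmic fraction
#' `phi = cn / (1 + cn)` (clipped to \[0.05, 0.95\]), so that the mean
#' annulus intensity divided by the mean nuclear intensity equals the
#' ground-truth C/N ratio exactly in the noiseless case.
#'
#' At division the dropped C/N of the mother's final pre-split frames
#' renders the cytoplasm collapse; from the end of the drop span the
#' nucleus splits into two daughters displaced by at least
#' `2 * nucleus_radius_px`, the tracked daughter continuing the mother's
#' path. Frames are optionally blurred (`psf_sigma_px`), multiplied by a
#' smooth flatfield, offset by `background_offset` and corrupted by
#' Gaussian noise, in that order.
#'
#' @param cells list of ground-truth cells from
#'   [simulate_cell_population()].
#' @param render a [render_config()].
#' @param config the [sim_config()] the cells came from.
#' @return numeric array of dim (frames, 3, rows, cols); attribute
#'   `"flatfield"` holds the applied field.
#' @export
render_timelapse <- function(cells, render, config) {
  stopifnot(inherits(render, "render_config"), inherits(config, "sim_config"))
  nf <- n_frames(config)
  dims <- render$image_shape
  rn <- render$nucleus_radius_px
  rc <- render$cyto_radius_px
  total <- render$total_ktr_intensity

  flat <- render_flatfield(dims, render$flatfield_amplitude)
  out <- array(0, c(nf, 3L, dims[1], dims[2]))

  for (f in seq_len(nf)) {
    centers <- list(); cns_e <- c(); cns_a <- c(); ids <- c()
    for (cell in cells) {
      if (!cell$in_frame[f]) next
      post_split <- cell$divides &&
        (f - 1L) >= cell$division_frame + config$drop_span_frames
      ctr <- cell$path[f, ]
      centers[[length(centers) + 1L]] <- ctr
      cns_e <- c(cns_e, cell$cn_erk[f]); cns_a <- c(cns_a, cell$cn_akt[f])
      ids <- c(ids, cell$cell_id)
      if (post_split) {
        off <- daughter_offset(ctr, dims, 2 * rn + 3)
        centers[[length(centers) + 1L]] <- ctr + off
        cns_e <- c(cns_e, cell$cn_erk[f]); cns_a <- c(cns_a, cell$cn_akt[f])
        ids <- c(ids, cell$cell_id)
      }
    }
    if (length(centers)) {
      cm <- do.call(rbind, centers)
      if (nrow(cm) > 1) {
        d <- as.matrix(stats::dist(cm))
        diag(d) <- Inf
        bad <- which(d < 2 * rn, arr.ind = TRUE)
        bad <- bad[ids[bad[, 1]] != ids[bad[, 2]], , drop = FALSE]
        if (nrow(bad) > 0)
          stop("unresolvable nucleus overlap at frame ", f - 1L,
               " between cells ",
               paste(unique(sort(ids[unique(as.vector(bad))])), collapse = ", "))
      }
      nuc <- matrix(0, dims[1], dims[2])
      erk <- matrix(0, dims[1], dims[2])
      akt <- matrix(0, dims[1], dims[2])
      for (j in seq_len(nrow(cm))) {
        pix <- disk_pixels(cm[j, ], rn, dims)
        ann <- annulus_pixels(cm[j, ], rn, rc, dims)
        pe <- phi_from_cn(cns_e[j]); pa <- phi_from_cn(cns_a[j])
        nuc[pix] <- 1
        erk[pix] <- total * (1 - pe); erk[ann] <- total * pe
        akt[pix] <- total * (1 - pa); akt[ann] <- total * pa
      }
      out[f, 1, , ] <- nuc * total
      out[f, 2, , ] <- erk
      out[f, 3, , ] <- akt
    }
    for (ch in 1:3) {
      img <- matrix(out[f, ch, , ], dims[1], dims[2])
      if (render$psf_sigma_px > 0)
        img <- EBImage::gblur(img, sigma = render$psf_sigma_px)
      img <- img * flat + render$background_offset
      if (render$gaussian_noise_sd > 0)
        img <- img + stats::rnorm(length(img), sd = render$gaussian_noise_sd)
      out[f, ch, , ] <- img
    }
  }
  attr(out, "flatfield") <- flat
  out
}

# pixel indices (into a dims matrix) of a filled disk, clipped at borders
disk_pixels <- function(center, radius, dims) {
  r0 <- max(0L, floor(center[1] - radius)); r1 <- min(dims[1] - 1L, ceiling(center[1] + radius))
  c0 <- max(0L, floor(center[2] - radius)); c1 <- min(dims[2] - 1L, ceiling(center[2] + radius))
  if (r1 < r0 || c1 < c0) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  idx <- which(d2 <= radius^2, arr.ind = TRUE)
  (rr[idx[, 1]] + 1L) + (cc[idx[, 2]]) * dims[1]
}

annulus_pixels <- function(center, r_in, r_out, dims) {
  r0 <- max(0L, floor(center[1] - r_out)); r1 <- min(dims[1] - 1L, ceiling(center[1] + r_out))
  c0 <- max(0L, floor(center[2] - r_out)); c1 <- min(dims[2] - 1L, ceiling(center[2] + r_out))
  if (r1 < r0 || c1 < c0) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  idx <- which(d2 <= r_out^2 & d2 > r_in^2, arr.ind = TRUE)
  (rr[idx[, 1]] + 1L) + (cc[idx[, 2]]) * dims[1]
}

# displacement for the second daughter, pointed toward the arena center
# so it stays in frame
daughter_offset <- function(center, dims, len) {
  v <- c(dims[1] / 2, dims[2] / 2) - center
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) v <- c(1, 0) else v <- v / nv
  v * len
}
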
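#' Illumination correction for a time-lapse image series
#'
#' Two standard pre-quantification corrections, applied per channel:
#' division by a smooth unit-mean flatfield (removing multiplicative
#' shading) and subtraction of a per-frame robust background estimate
#' (removing the additive camera offset). Since the C/N readout is a
#' ratio, multiplicative shading distorts it only locally, but an
#' additive offset biases it everywhere, so background subtraction is the
#' critical step before measurement.
#'
#' @param frames numeric array (frames, rows, cols) for one channel.
#' @param mode "none" (identity), "divide_flatfield" or
#'   "subtract_background".
#' @param reference optional flatfield matrix for divide mode; when
#'   missing the field is estimated as the heavily smoothed temporal
#'   median frame, normalized to unit mean.
#' @param bg_percentile percentile of the retained (non-cellular) pixels
#'   used as the per-frame background estimate (default 0.5, the
#'   median). With symmetric camera noise the median of the cell-free
#'   pixels estimates the true offset without the downward bias a low
#'   percentile would carry.
#' @param bg_exclude_upper fraction of the brightest pixels excluded
#'   before estimating the background (default 0.1), a stand-in for
#'   masking out the cells.
#' @return corrected array of the same shape.
#' @export
correct_illumination <- function(frames,
                                 mode = c("none", "divide_flatfield",
                                          "subtract_background"),
                                 reference = NULL,
                                 bg_percentile = 0.5,
                                 bg_exclude_upper = 0.1) {
  mode <- match.arg(mode)
  stopifnot(length(dim(frames)) == 3, dim(frames)[1] >= 1)
  if (mode == "none") return(frames)
  dims <- dim(frames)[2:3]
  if (mode == "divide_flatfield") {
    if (is.null(reference)) {
      med <- apply(frames, c(2, 3), stats::median)
      reference <- EBImage::gblur(med, sigma = max(dims) / 8)
      reference <- reference / mean(reference)
    }
    if (!all(dim(reference) == dims)) stop("reference shape mismatch")
    if (any(reference == 0)) stop("flatfield reference contains zeros")
    for (f in seq_len(dim(frames)[1]))
      frames[f, , ] <- frames[f, , ] / reference
  } else {
    for (f in seq_len(dim(frames)[1])) {
      img <- frames[f, , ]
      keep <- img <= stats::quantile(img, 1 - bg_exclude_upper, names = FALSE)
      b <- stats::quantile(img[keep], bg_percentile, names = FALSE)
      frames[f, , ] <- pmax(img - b, 0)
    }
  }
  frames
}

#' Segment nuclei in a nuclear-marker frame
#'
#' A classical pipeline: global threshold (Otsu by default), hole
#' filling, optional distance-transform watershed to split touching
#' nuclei, and an area filter. The interface accepts externally produced
#' label masks everywhere downstream, so a trained segmenter can replace
#' this stage without touching the rest of the pipeline.
#'
#' @param nuclear_frame single-channel matrix.
#' @param threshold_method "otsu" or a numeric absolute threshold.
#' @param min_area_px,max_area_px component area bounds in pixels.
#' @param split_touching if TRUE, split touching nuclei by watershed on
#'   the distance transform.
#' @return integer label matrix (0 = background); an all-constant frame
#'   yields zero labels.
#' @export
segment_nuclei <- function(nuclear_frame, threshold_method = "otsu",
                           min_area_px = 20, max_area_px = Inf,
                           split_touching = FALSE) {
  stopifnot(is.matrix(nuclear_frame))
  rng <- range(nuclear_frame)
  if (diff(rng) == 0)
    return(matrix(0L, nrow(nuclear_frame), ncol(nuclear_frame)))
  if (identical(threshold_method, "otsu")) {
    norm <- (nuclear_frame - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm))
    bw <- norm > th
  } else {
    bw <- nuclear_frame > threshold_method
  }
  bw <- EBImage::fillHull(EBImage::Image(bw * 1))
  labels <- if (split_touching) {
    dm <- EBImage::distmap(bw)
    EBImage::watershed(dm, tolerance = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  labels <- EBImage::imageData(labels)
  storage.mode(labels) <- "integer"
  areas <- tabulate(labels)
  drop <- which(areas < min_area_px | areas > max_area_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  # relabel 1..K in raster order of first appearance
  keep <- sort(unique(labels[labels > 0L]))
  if (length(keep)) labels <- matrix(match(labels, keep, nomatch = 0L),
                                     nrow(labels), ncol(labels))
  storage.mode(labels) <- "integer"
  labels
}

#' Build the perinuclear cytoring for every nucleus
#'
#' The cytoring of nucleus L is the set of pixels within `width_px`
#' (Euclidean distance, default 10 px) of L's pixels, excluding the
#' nuclear pixels of every label. A pixel in range of several nuclei is
#' assigned to the nearest one, with ties going to the lower label, so
#' rings are mutually disjoint and disjoint from all nuclei. Rings are
#' clipped at image borders.
#'
#' Distances are compared as exact integer squared pixel distances, so
#' the construction is bit-exact: no floating-point distance-transform
#' approximation is involved.
#'
#' @param mask integer label matrix of nuclei.
#' @param width_px ring width in pixels (>= 1).
#' @return integer label matrix of rings (same label numbers as `mask`).
#' @export
build_cytoring <- function(mask, width_px = 10) {
  stopifnot(is.matrix(mask), width_px >= 1)
  nr <- nrow(mask); nc <- ncol(mask)
  labs <- sort(unique(mask[mask > 0L]))
  ring <- matrix(0L, nr, nc)
  if (!length(labs)) return(ring)
  w <- as.integer(ceiling(width_px))
  w2 <- width_px^2
  best_d2 <- matrix(Inf, nr, nc)
  best_lab <- matrix(0L, nr, nc)
  for (L in labs) {              # ascending: ties keep the lower label
    idx <- which(mask == L)
    rl <- ((idx - 1L) %% nr)
    cl <- ((idx - 1L) %/% nr)
    r0 <- max(0L, min(rl) - w); r1 <- min(nr - 1L, max(rl) + w)
    c0 <- max(0L, min(cl) - w); c1 <- min(nc - 1L, max(cl) + w)
    rr <- r0:r1; cc <- c0:c1
    pr <- rep.int(rr, length(cc))
    pc <- rep(cc, each = length(rr))
    d2 <- outer(pr, rl, `-`)^2 + outer(pc, cl, `-`)^2
    d2min <- d2[cbind(seq_along(pr), max.col(-d2, ties.method = "first"))]
    ok <- d2min <= w2
    if (!any(ok)) next
    flat <- (pr[ok] + 1L) + pc[ok] * nr
    closer <- d2min[ok] < best_d2[flat]
    upd <- flat[closer]
    best_d2[upd] <- d2min[ok][closer]
    best_lab[upd] <- L
  }
  sel <- best_lab > 0L & mask == 0L
  ring[sel] <- best_lab[sel]
  ring
}

#' Measure nuclear and cytoring intensity per cell
#'
#' For each nucleus label: mean KTR intensity over the nuclear pixels,
#' mean over the cytoring pixels, and their ratio
#' `cn_ratio = ring_mean / nuc_mean` — the per-cell, per-frame kinase
#' activity readout. Labels with an empty ring or non-positive nuclear
#' mean get `cn_ratio = NA` plus a flag rather than being dropped.
#'
#' @param ktr_frame single-channel intensity matrix.
#' @param nuclei integer nuclear label matrix (same shape).
#' @param rings integer cytoring label matrix (same shape, labels a
#'   subset of the nuclear labels).
#' @param frame_idx frame index recorded in the output (0-based).
#' @return data.frame: frame, label, nuc_mean, ring_mean, cn_ratio, flag.
#' @export
measure_cells <- function(ktr_frame, nuclei, rings, frame_idx = 0L) {
  if (!all(dim(ktr_frame) == dim(nuclei)) || !all(dim(ktr_frame) == dim(rings)))
    stop("frame and mask shapes differ")
  labs <- sort(unique(nuclei[nuclei > 0L]))
  if (!length(labs))
    return(data.frame(frame = integer(0), label = integer(0),
                      nuc_mean = numeric(0), ring_mean = numeric(0),
                      cn_ratio = numeric(0), flag = character(0)))
  extra <- setdiff(unique(rings[rings > 0L]), labs)
  if (length(extra)) stop("ring labels not present in nucleus mask: ",
                          paste(extra, collapse = ", "))
  nuc_mean <- vapply(labs, function(L) mean(ktr_frame[nuclei == L]), 0)
  ring_mean <- vapply(labs, function(L) {
    px <- ktr_frame[rings == L]
    if (length(px)) mean(px) else NA_real_
  }, 0)
  flag <- rep("", length(labs))
  flag[is.na(ring_mean)] <- "EMPTY_RING"
  flag[!is.na(nuc_mean) & nuc_mean <= 0] <-
    paste0(flag[!is.na(nuc_mean) & nuc_mean <= 0], "NONPOS_NUC")
  cn <- ifelse(flag == "", ring_mean / nuc_mean, NA_real_)
  data.frame(frame = as.integer(frame_idx), label = labs,
             nuc_mean = nuc_mean, ring_mean = ring_mean,
             cn_ratio = cn, flag = flag)
}
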
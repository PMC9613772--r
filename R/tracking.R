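#' Centroids of a label mask
#'
#' @param mask integer label matrix.
#' @return data.frame: label, row, col (0-based pixel centroids).
#' @export
mask_centroids <- function(mask) {
  labs <- sort(unique(mask[mask > 0L]))
  if (!length(labs))
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0)))
  nr <- nrow(mask)
  idx <- which(mask > 0L)
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  l <- mask[idx]
  data.frame(label = labs,
             row = as.vector(tapply(r, l, mean)[as.character(labs)]),
             col = as.vector(tapply(c, l, mean)[as.character(labs)]))
}

# Exact solver for the square linear assignment problem (Hungarian /
# shortest augmenting path). Returns assign[i] = column chosen for row i.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0) return(integer(0))
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)            # p[j + 1] = row matched to column j
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat { j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1; if (j0 == 1L) break }
  }
  assign <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Link per-frame nucleus labels into persistent cell tracks
#'
#' Frame-to-frame linking by optimal one-to-one assignment on centroid
#' distance, with a hard displacement gate: links longer than
#' `max_disp_px` are never made. Unmatched labels in the current frame
#' start new tracks; unmatched previous tracks terminate (no gap
#' bridging — transiently lost cells yield short tracks that the
#' full-duration filter removes). When one nucleus splits into two
#' (division geometry), the optimal assignment continues the track as
#' the nearer daughter and the other daughter starts a new track.
#'
#' @param masks list of integer label matrices, one per frame, in time
#'   order (>= 2 frames, equal shapes).
#' @param max_disp_px displacement gate in pixels.
#' @return data.frame: track_id, frame (0-based), label, row, col.
#' @export
link_tracks <- function(masks, max_disp_px = 25) {
  stopifnot(length(masks) >= 2)
  shp <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == shp), TRUE)))
    stop("mask shapes differ across frames")
  BIG <- 1e9

  cent <- lapply(masks, mask_centroids)
  prev <- cent[[1]]
  n0 <- nrow(prev)
  track_of <- seq_len(n0)        # track id per row of prev
  next_id <- n0 + 1L
  rows <- list(data.frame(track_id = track_of, frame = 0L,
                          label = prev$label, row = prev$row, col = prev$col))

  for (f in 2:length(masks)) {
    cur <- cent[[f]]
    np <- nrow(prev); nc <- nrow(cur)
    link <- rep(0L, np)          # index into cur, 0 = unmatched
    if (np > 0 && nc > 0) {
      d <- sqrt(outer(prev$row, cur$row, `-`)^2 +
                  outer(prev$col, cur$col, `-`)^2)
      cost <- ifelse(d <= max_disp_px, d, BIG)
      m <- max(np, nc)
      sq <- matrix(BIG, m, m)
      sq[seq_len(np), seq_len(nc)] <- cost
      a <- solve_assignment(sq)
      for (i in seq_len(np)) {
        j <- a[i]
        if (j <= nc && cost[i, j] < BIG) link[i] <- j
      }
    }
    new_track_of <- integer(nc)
    new_track_of[link[link > 0L]] <- track_of[link > 0L]
    for (j in seq_len(nc)) {
      if (new_track_of[j] == 0L) {
        new_track_of[j] <- next_id
        next_id <- next_id + 1L
      }
    }
    if (nc > 0)
      rows[[f]] <- data.frame(track_id = new_track_of, frame = f - 1L,
                              label = cur$label, row = cur$row, col = cur$col)
    prev <- cur
    track_of <- new_track_of
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Keep only tracks spanning the whole time course
#'
#' Mirrors the conservative track filter of the source pipeline: any
#' track not present from frame 0 through `n_frames_required - 1` is
#' dropped, preventing quantification of transiently tracked cells.
#'
#' @param tracks data.frame from [link_tracks()].
#' @param n_frames_required required span in frames.
#' @return list with `kept` and `dropped` data.frames; `dropped` gains a
#'   `reason` column ("late_start", "early_end" or "late_start;early_end").
#' @export
filter_full_duration <- function(tracks, n_frames_required) {
  stopifnot(n_frames_required >= 1)
  if (nrow(tracks) == 0)
    return(list(kept = tracks, dropped = cbind(tracks, reason = character(0))))
  spans <- stats::aggregate(frame ~ track_id, tracks, function(f) c(min(f), max(f)))
  lo <- spans$frame[, 1]; hi <- spans$frame[, 2]
  full <- lo == 0L & hi == n_frames_required - 1L
  kept_ids <- spans$track_id[full]
  reason <- paste0(ifelse(lo > 0L, "late_start", ""),
                   ifelse(lo > 0L & hi < n_frames_required - 1L, ";", ""),
                   ifelse(hi < n_frames_required - 1L, "early_end", ""))
  names(reason) <- spans$track_id
  kept <- tracks[tracks$track_id %in% kept_ids, ]
  dropped <- tracks[!tracks$track_id %in% kept_ids, ]
  if (nrow(dropped)) dropped$reason <- reason[as.character(dropped$track_id)]
  else dropped$reason <- character(0)
  rownames(kept) <- rownames(dropped) <- NULL
  list(kept = kept, dropped = dropped)
}

#' Attach per-frame measurements to tracks
#'
#' @param tracks data.frame from [link_tracks()].
#' @param measurements data.frame from [measure_cells()] rows across
#'   frames (one channel).
#' @return tracks with nuc_mean, ring_mean, cn_ratio, flag columns merged
#'   by (frame, label).
#' @export
attach_measurements <- function(tracks, measurements) {
  out <- merge(tracks, measurements, by = c("frame", "label"),
               all.x = TRUE, sort = FALSE)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}
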
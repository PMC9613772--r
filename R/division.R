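#' Parameters of the division-drop detector
#'
#' A dividing cell rounds up at mitosis; the morphology change produces a
#' transient, steep drop of the C/N ratio that is unique to division.
#' The detector looks for the earliest frame at which the relative drop
#' over a short span exceeds `min_drop_frac` and the dip is prominent
#' against its surroundings.
#'
#' @param min_drop_frac minimum relative C/N drop, in (0, 1).
#' @param max_drop_span_frames maximum span (frames) over which the drop
#'   may develop.
#' @param min_prominence minimum dip prominence in C/N units (depth of
#'   the local minimum relative to the surrounding trace).
#' @param earliest_frame divisions at or before this frame are
#'   disallowed. The default (frame 8, i.e. 2 h at 15-min sampling)
#'   excludes the pre-stimulus baseline *and* the rapid post-stimulus
#'   rise: a relative-drop criterion is ill-defined while the C/N level
#'   is still near baseline, where noise excursions are large relative
#'   to the signal. No cell completes S and G2 that early, so the gate
#'   costs no sensitivity.
#' @param truncate_offset_frames frames removed before the detected peak
#'   when truncating (the tail is morphology, not kinase activity).
#' @param detection_channel which KTR channel drives detection; for
#'   dual-reporter 15-min data the Akt channel is used, for 5-min data
#'   the ERK channel.
#' @return object of class `detect_params`.
#' @export
detect_params <- function(min_drop_frac = 0.35,
                          max_drop_span_frames = 2,
                          min_prominence = 0.2,
                          earliest_frame = 8,
                          truncate_offset_frames = 5,
                          detection_channel = c("Akt", "ERK")) {
  detection_channel <- match.arg(detection_channel)
  if (min_drop_frac <= 0 || min_drop_frac >= 1)
    stop("min_drop_frac must lie in (0, 1)")
  if (truncate_offset_frames < 0) stop("truncate_offset_frames must be >= 0")
  structure(list(min_drop_frac = min_drop_frac,
                 max_drop_span_frames = as.integer(max_drop_span_frames),
                 min_prominence = min_prominence,
                 earliest_frame = as.integer(earliest_frame),
                 truncate_offset_frames = as.integer(truncate_offset_frames),
                 detection_channel = detection_channel),
            class = "detect_params")
}

# prominence of the dip whose bottom is 1-based index b: depth of cn[b]
# below the lower of the two flanking maxima, each flank searched until
# the trace first goes below cn[b] (or the trace end, which acts as a top)
dip_prominence <- function(cn, b) {
  n <- length(cn)
  left_top <- -Inf
  j <- b - 1L
  while (j >= 1L && cn[j] >= cn[b]) { left_top <- max(left_top, cn[j]); j <- j - 1L }
  if (!is.finite(left_top)) left_top <- cn[b]
  right_top <- -Inf
  j <- b + 1L
  while (j <= n && cn[j] >= cn[b]) { right_top <- max(right_top, cn[j]); j <- j + 1L }
  if (!is.finite(right_top)) right_top <- cn[b]
  min(left_top, right_top) - cn[b]
}

#' Detect a cell-division event in a C/N trace
#'
#' Scans the trace for the earliest frame `p > earliest_frame` at which
#' the relative drop `(cn[p - s] - cn[p]) / cn[p - s]` over some span
#' `s <= max_drop_span_frames` exceeds `min_drop_frac`, and the inverted
#' trace has a local-minimum prominence above `min_prominence` at the dip
#' bottom. The earliest qualifying candidate wins (one division per cell
#' is analyzed). Candidates failing secondary checks are returned with QC
#' flags rather than silently dropped: `SPURIOUS_CANDIDATE` when the drop
#' is not sustained for at least one further frame, `NEAR_START` when the
#' peak is within `truncate_offset_frames` of the trace start (so the
#' trace cannot be truncated).
#'
#' @param cn_trace numeric C/N series (frame 0 first).
#' @param params a [detect_params()].
#' @return list (class `division_call`) with `peak_frame` (0-based),
#'   `drop_frac_observed`, `dip_frame`, `qc_flags`; or `NULL` when no
#'   candidate qualifies. A call is *accepted* when `qc_flags` is empty.
#' @export
detect_division <- function(cn_trace, params = detect_params()) {
  n <- length(cn_trace)
  if (n < params$truncate_offset_frames + 2)
    stop("trace too short for detection")
  span_max <- params$max_drop_span_frames
  first_p <- max(params$earliest_frame + 1L, 1L)
  for (p in first_p:(n - 1L)) {          # p is a 0-based frame index
    pi <- p + 1L
    best <- NULL
    for (s in seq_len(min(span_max, p))) {
      ref <- cn_trace[pi - s]
      if (!is.finite(ref) || ref <= 0) next
      rel <- (ref - cn_trace[pi]) / ref
      if (rel > params$min_drop_frac && (is.null(best) || rel > best$rel))
        best <- list(rel = rel, s = s)
    }
    if (is.null(best)) next
    # dip bottom: minimum over the possible drop span starting at p
    dip_i <- pi + which.min(cn_trace[pi:min(pi + span_max - 1L, n)]) - 1L
    if (dip_prominence(cn_trace, dip_i) <= params$min_prominence) next
    flags <- character(0)
    ref <- cn_trace[pi - best$s]
    if (pi < n && cn_trace[pi + 1L] > ref * (1 - params$min_drop_frac / 2))
      flags <- c(flags, "SPURIOUS_CANDIDATE")
    if (p < params$truncate_offset_frames)
      flags <- c(flags, "NEAR_START")
    return(structure(list(peak_frame = p,
                          drop_frac_observed = best$rel,
                          dip_frame = dip_i - 1L,
                          qc_flags = flags),
                     class = "division_call"))
  }
  NULL
}

#' Truncate a trace before its detected division
#'
#' The frames from `truncate_offset_frames` before the detected peak to
#' the end of the trace reflect mitotic morphology rather than kinase
#' activity and are removed. With a peak at frame `p` (0-based) and
#' offset `k`, the result keeps frames `0 ... p - k - 1` (length
#' `p - k`).
#'
#' @param trace numeric series.
#' @param call a `division_call` or `NULL` (trace returned unchanged).
#' @param params a [detect_params()].
#' @return the truncated series, or `NULL` when `peak_frame <
#'   truncate_offset_frames` (the cell is excluded, flag `NEAR_START`).
#' @export
truncate_trace <- function(trace, call, params = detect_params()) {
  if (is.null(call)) return(trace)
  keep <- call$peak_frame - params$truncate_offset_frames
  if (keep < 0) return(NULL)
  if (keep == 0) return(trace[0])
  trace[seq_len(min(keep, length(trace)))]
}

#' Fate-classification configuration
#'
#' A cell with no accepted division call counts as non-dividing only if
#' it was present long enough: 48 h at 15-min sampling, or at least
#' 41.67 h at 5-min sampling (41.67 h being 500 five-minute frames; the
#' comparison carries a half-frame tolerance so the rounded threshold
#' does not exclude exactly-500-frame tracks).
#'
#' @param sampling_interval_h frame spacing in hours.
#' @param min_presence_h_15min,min_presence_h_5min presence thresholds.
#' @return object of class `fate_config`.
#' @export
fate_config <- function(sampling_interval_h = 0.25,
                        min_presence_h_15min = 48,
                        min_presence_h_5min = 41.67) {
  stopifnot(min_presence_h_15min > 0, min_presence_h_5min > 0)
  required <- if (sampling_interval_h <= 0.1) min_presence_h_5min
              else min_presence_h_15min
  structure(list(sampling_interval_h = sampling_interval_h,
                 min_presence_h_15min = min_presence_h_15min,
                 min_presence_h_5min = min_presence_h_5min,
                 required_h = required),
            class = "fate_config")
}

#' Classify every track as dividing, non-dividing or excluded
#'
#' Dividing: the track has an accepted (unflagged) division call.
#' Non-dividing: no call, and the track was present for at least the
#' presence threshold of the sampling interval. Everything else is
#' excluded with a reason; flagged calls are routed to the QC report
#' (the programmatic stand-in for manual review of candidate divisions).
#'
#' @param tracks data.frame with track_id and frame columns.
#' @param calls named list of `division_call` (or NULL) per track id.
#' @param fate a [fate_config()].
#' @param n_frames_total total frames in the movie (unused beyond
#'   validation; presence is measured from the track itself).
#' @return data.frame: track_id, fate, reason; attribute `"qc"` holds the
#'   flagged-call report.
#' @export
classify_fates <- function(tracks, calls, fate = fate_config(),
                           n_frames_total = NULL) {
  ids <- sort(unique(tracks$track_id))
  unknown <- setdiff(names(calls)[!vapply(calls, is.null, TRUE)],
                     as.character(ids))
  if (length(unknown))
    stop("calls reference unknown tracks: ", paste(unknown, collapse = ", "))
  fates <- character(length(ids)); reason <- character(length(ids))
  qc <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    tr <- tracks[tracks$track_id == id, ]
    call <- calls[[as.character(id)]]
    presence_h <- (max(tr$frame) - min(tr$frame)) * fate$sampling_interval_h
    if (!is.null(call) && length(call$qc_flags) == 0) {
      fates[k] <- "dividing"; reason[k] <- ""
    } else if (!is.null(call)) {
      fates[k] <- "excluded"
      reason[k] <- paste(call$qc_flags, collapse = ";")
      qc[[length(qc) + 1L]] <- data.frame(
        track_id = id, peak_frame = call$peak_frame,
        drop_frac_observed = call$drop_frac_observed,
        qc_flags = reason[k])
    } else if (presence_h >= fate$required_h - fate$sampling_interval_h / 2) {
      fates[k] <- "non-dividing"; reason[k] <- ""
    } else {
      fates[k] <- "excluded"; reason[k] <- "SHORT_PRESENCE"
    }
  }
  out <- data.frame(track_id = ids, fate = fates, reason = reason)
  attr(out, "qc") <- if (length(qc)) do.call(rbind, qc) else
    data.frame(track_id = integer(0), peak_frame = integer(0),
               drop_frac_observed = numeric(0), qc_flags = character(0))
  out
}
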
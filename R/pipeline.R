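#' Per-channel trace matrix from a simulated population
#'
#' @param pop result of [simulate_cell_population()].
#' @param channel "ERK" or "Akt".
#' @param observed if TRUE (default) the observed C/N series including
#'   the division drop, else the latent activity.
#' @return cells x frames numeric matrix.
#' @export
trace_matrix <- function(pop, channel = c("ERK", "Akt"), observed = TRUE) {
  channel <- match.arg(channel)
  field <- if (observed) {
    if (channel == "ERK") "cn_erk" else "cn_akt"
  } else {
    if (channel == "ERK") "erk_activity" else "akt_activity"
  }
  do.call(rbind, lapply(pop$cells, `[[`, field))
}

#' Run the trace-level analysis pipeline
#'
#' The full downstream analysis on a table of per-cell C/N traces:
#' detect the division drop on the detection channel, truncate both
#' channels before the detected peak, classify each cell as dividing /
#' non-dividing / excluded, and compute windowed median features.
#'
#' @param traces long data.frame with columns cell_id, frame, time_h,
#'   channel ("ERK"/"Akt"), cn_ratio (as produced by
#'   [simulate_cell_population()] or read from a quantification CSV).
#' @param detect a [detect_params()].
#' @param window a [window_spec()].
#' @param fate a [fate_config()]; defaults to the trace's sampling
#'   interval when NULL.
#' @return list with
#'   \describe{
#'     \item{features}{data.frame cell_id, median_erk, median_akt, divided
#'       (dividing/non-dividing cells only).}
#'     \item{fates}{data.frame cell_id, fate, reason (every input cell).}
#'     \item{calls}{named list of division calls (or NULL) per cell.}
#'     \item{truncated}{named list per cell: list(erk, akt, times_h) after
#'       truncation.}
#'   }
#' @export
run_trace_pipeline <- function(traces, detect = detect_params(),
                               window = window_spec(), fate = NULL) {
  need <- c("cell_id", "frame", "time_h", "channel", "cn_ratio")
  if (!all(need %in% names(traces))) stop("traces missing required columns")
  ids <- sort(unique(traces$cell_id))
  interval <- sort(unique(traces$time_h))
  interval <- if (length(interval) > 1) min(diff(interval)) else 0.25
  if (is.null(fate)) fate <- fate_config(sampling_interval_h = interval)

  calls <- vector("list", length(ids)); names(calls) <- as.character(ids)
  truncated <- vector("list", length(ids)); names(truncated) <- as.character(ids)
  fates <- character(length(ids)); reason <- character(length(ids))
  med_e <- numeric(length(ids)); med_a <- numeric(length(ids))

  for (k in seq_along(ids)) {
    tr <- traces[traces$cell_id == ids[k], ]
    tr <- tr[order(tr$frame), ]
    erk <- tr$cn_ratio[tr$channel == "ERK"]
    akt <- tr$cn_ratio[tr$channel == "Akt"]
    times <- tr$time_h[tr$channel == "ERK"]
    det_trace <- if (detect$detection_channel == "Akt" && length(akt)) akt else erk
    call <- detect_division(det_trace, detect)
    calls[k] <- list(call)      # keeps the slot when call is NULL
    if (!is.null(call) && length(call$qc_flags) == 0) {
      erk_t <- truncate_trace(erk, call, detect)
      akt_t <- truncate_trace(akt, call, detect)
      fates[k] <- "dividing"
    } else if (!is.null(call)) {
      fates[k] <- "excluded"
      reason[k] <- paste(call$qc_flags, collapse = ";")
      erk_t <- erk; akt_t <- akt
    } else {
      presence_h <- (max(tr$frame) - min(tr$frame)) * interval
      if (presence_h >= fate$required_h - interval / 2) {
        fates[k] <- "non-dividing"
      } else {
        fates[k] <- "excluded"; reason[k] <- "SHORT_PRESENCE"
      }
      erk_t <- erk; akt_t <- akt
    }
    truncated[[k]] <- list(erk = erk_t, akt = akt_t, times_h = times)
    med_e[k] <- if (length(erk_t)) window_median(erk_t, times, window) else NA_real_
    med_a[k] <- if (length(akt_t)) window_median(akt_t, times, window) else NA_real_
    if (fates[k] %in% c("dividing", "non-dividing") &&
        is.na(med_e[k]) && is.na(med_a[k])) {
      fates[k] <- "excluded"       # nothing left inside the window
      reason[k] <- "NO_WINDOW_DATA"
    }
  }

  keep <- fates %in% c("dividing", "non-dividing")
  features <- data.frame(cell_id = ids[keep],
                         median_erk = med_e[keep],
                         median_akt = med_a[keep],
                         divided = fates[keep] == "dividing")
  list(features = features,
       fates = data.frame(cell_id = ids, fate = fates, reason = reason),
       calls = calls, truncated = truncated)
}

#' Pooled in-window ERK/Akt point pairs per fate class
#'
#' Collects every (cell, in-window timepoint) paired activity value from
#' the pipeline's truncated traces, split by fate, ready for
#' [pooled_pearson()].
#'
#' @param result output of [run_trace_pipeline()].
#' @param window a [window_spec()].
#' @return list with `dividing` and `nondividing`, each a data.frame of
#'   paired `erk`, `akt` columns.
#' @export
pooled_points <- function(result, window = window_spec()) {
  out <- list(dividing = list(erk = c(), akt = c()),
              nondividing = list(erk = c(), akt = c()))
  for (k in seq_len(nrow(result$fates))) {
    fate <- result$fates$fate[k]
    if (!fate %in% c("dividing", "non-dividing")) next
    id <- as.character(result$fates$cell_id[k])
    tr <- result$truncated[[id]]
    n <- min(length(tr$erk), length(tr$akt))
    if (n == 0) next
    t <- tr$times_h[seq_len(n)]
    sel <- t >= window$t_lo_h & t <= window$t_hi_h
    slot <- if (fate == "dividing") "dividing" else "nondividing"
    out[[slot]]$erk <- c(out[[slot]]$erk, tr$erk[seq_len(n)][sel])
    out[[slot]]$akt <- c(out[[slot]]$akt, tr$akt[seq_len(n)][sel])
  }
  lapply(out, as.data.frame)
}
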
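#' Write a simulated dataset to disk as TIFF + CSV fixtures
#'
#' Images go to one 16-bit multi-page TIFF per channel (page order =
#' time order); traces and ground truth go to CSV. The trace CSV
#' round-trips exactly (shortest round-trippable decimal representation).
#'
#' @param traces long trace data.frame (cell_id, frame, time_h, channel,
#'   cn_ratio) or NULL.
#' @param images array (frames, channels, rows, cols) from
#'   [render_timelapse()], or NULL.
#' @param out_dir output directory (created if needed).
#' @param ground_truth optional data.frame (cell_id, divides,
#'   division_time_h, division_frame).
#' @param intensity_scale intensities are divided by this before the
#'   16-bit quantization (default 4096; must exceed the image maximum /
#'   65535 headroom you need).
#' @return invisibly, the named vector of written file paths.
#' @export
write_fixture <- function(traces = NULL, images = NULL, out_dir,
                          ground_truth = NULL, intensity_scale = 4096) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- character(0)
  # doubles are written with 17 significant digits so the CSV
  # round-trips bit-exactly under strtod parsing
  fmt17 <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.double(col)) ifelse(is.na(col), NA, sprintf("%.17g", col))
      else col)
    df
  }
  if (!is.null(traces)) {
    p <- file.path(out_dir, "traces.csv")
    utils::write.csv(fmt17(traces), p, row.names = FALSE, quote = FALSE)
    paths["traces"] <- p
  }
  if (!is.null(ground_truth)) {
    p <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(fmt17(ground_truth), p, row.names = FALSE, quote = FALSE)
    paths["ground_truth"] <- p
  }
  if (!is.null(images)) {
    ch_names <- c("nuclear", "erk", "akt")[seq_len(dim(images)[2])]
    for (ch in seq_along(ch_names)) {
      p <- file.path(out_dir, paste0("channel_", ch_names[ch], ".tif"))
      pages <- lapply(seq_len(dim(images)[1]), function(f) {
        img <- images[f, ch, , ] / intensity_scale
        pmin(pmax(round(img * 65535) / 65535, 0), 1)
      })
      tiff::writeTIFF(pages, p, bits.per.sample = 16)
      paths[ch_names[ch]] <- p
    }
  }
  invisible(paths)
}

#' Read a per-channel multi-page TIFF stack
#'
#' @param path TIFF file written by [write_fixture()].
#' @param intensity_scale the scale used at write time.
#' @return array (frames, rows, cols) in original intensity units.
#' @export
read_timelapse_tiff <- function(path, intensity_scale = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * intensity_scale
  arr
}

#' Read a trace CSV written by [write_fixture()]
#'
#' @param path CSV path.
#' @return data.frame with cell_id, frame, time_h, channel, cn_ratio.
#' @export
read_trace_csv <- function(path) {
  utils::read.csv(path, colClasses = c(
    cell_id = "integer", frame = "integer", time_h = "numeric",
    channel = "character", cn_ratio = "numeric"))
}

#' Write / read a series of label masks as a 16-bit multi-page TIFF
#'
#' @param masks list of integer label matrices.
#' @param path TIFF path.
#' @return `write_label_masks` returns the path invisibly;
#'   `read_label_masks` the list of integer matrices.
#' @export
write_label_masks <- function(masks, path) {
  pages <- lapply(masks, function(m) {
    if (max(m) > 65535L) stop("labels exceed 16-bit range")
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_masks
#' @export
read_label_masks <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
}
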
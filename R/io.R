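# Plain-text readers and writers for the pipeline's interchange formats:
# interval CSV ethograms, per-frame chamber CSV, traces CSV + JSON metadata,
# ground-truth JSON, multi-page TIFF movies and 16-bit labeled TIFF masks.

#' Write / read an ethogram as interval CSV
#'
#' Columns: `onset_s`, `offset_s`, `behavior`.
#'
#' @param track a [behavior_track()].
#' @param path file path.
#' @export
write_ethogram <- function(track, path) {
  stopifnot(inherits(track, "BehaviorTrack"))
  utils::write.csv(track$intervals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ethogram
#' @param duration_s session duration (required on read; the CSV holds only
#'   intervals).
#' @param ... passed to [behavior_track()].
#' @export
read_ethogram <- function(path, duration_s, ...) {
  iv <- utils::read.csv(path, stringsAsFactors = FALSE)
  behavior_track(iv, duration_s, ...)
}

#' Write / read a chamber track as per-frame CSV
#'
#' Columns: `frame` (0-based), `label`.
#'
#' @param chambers character vector of per-frame compartment labels.
#' @param path file path.
#' @export
write_chamber_track <- function(chambers, path) {
  utils::write.csv(
    data.frame(frame = seq_along(chambers) - 1L, label = chambers),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chamber_track
#' @export
read_chamber_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$label[order(df$frame)]
}

#' Write / read traces as CSV plus JSON metadata
#'
#' The CSV holds one row per neuron (rownames = neuron ids) and one column
#' per frame; the JSON sidecar stores `frame_rate_hz` and `session_id`.
#'
#' @param rec a [calcium_recording()].
#' @param path CSV path; metadata is written next to it as
#'   `<path>.meta.json` unless `meta_path` is given.
#' @param meta_path optional metadata path.
#' @export
write_traces <- function(rec, path, meta_path = paste0(path, ".meta.json")) {
  stopifnot(inherits(rec, "CalciumRecording"))
  df <- as.data.frame(rec$traces)
  colnames(df) <- paste0("f", seq_len(ncol(df)) - 1L)
  utils::write.csv(cbind(neuron = rownames(rec$traces), df), path,
                   row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate_hz = rec$frame_rate_hz, session_id = rec$session_id),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, meta_path = paste0(path, ".meta.json")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$neuron
  colnames(m) <- NULL
  calcium_recording(m, as.numeric(meta$frame_rate_hz),
                    session_id = meta$session_id, roi_ids = df$neuron)
}

#' Write / read ground truth as JSON
#'
#' @param truth a `GroundTruth` data.frame.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(as.data.frame(truth), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.frame(truth)
  class(truth) <- c("GroundTruth", "data.frame")
  truth
}

#' Write / read a movie as multi-page TIFF
#'
#' Frames are stored as 16-bit pages scaled to the stack maximum; the scale
#' and frame rate are kept in a `<path>.meta.json` sidecar so intensities
#' are restored on read (quantization error <= max / 65535).
#'
#' @param stack a [video_stack()].
#' @param path file path.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "VideoStack"))
  scale <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(f) stack$frames[f, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  jsonlite::write_json(
    list(scale = scale, frame_rate_hz = stack$frame_rate_hz),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param frame_rate_hz acquisition rate; defaults to the sidecar value.
#' @export
read_movie <- function(path, frame_rate_hz = NULL) {
  meta_path <- paste0(path, ".meta.json")
  scale <- 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    scale <- meta$scale
    frame_rate_hz <- frame_rate_hz %||% as.numeric(meta$frame_rate_hz)
  }
  if (is.null(frame_rate_hz)) {
    stop("`frame_rate_hz` is required when no sidecar metadata is present")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * scale
  video_stack(arr, frame_rate_hz)
}

#' Write / read an ROI mask as 16-bit labeled TIFF
#'
#' @param mask an [roi_mask()].
#' @param path file path.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ROIMask"))
  tiff::writeTIFF(mask$label / 65535, path, bits.per.sample = 16,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  img <- tiff::readTIFF(path)
  roi_mask(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)))
}

#' Write / read a responder table as CSV
#'
#' @param table a `ResponderTable` from [classify_all()].
#' @param path file path.
#' @export
write_responder_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responder_table
#' @export
read_responder_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("ResponderTable", "data.frame")
  df
}
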
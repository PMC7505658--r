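#' Fluorescence video stack
#'
#' @param frames 3-D numeric array `(frame, row, col)` of non-negative
#'   intensities, at least 2 frames.
#' @param frame_rate_hz acquisition rate, frames/s.
#' @return An object of class `VideoStack`.
#' @export
video_stack <- function(frames, frame_rate_hz) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("`frames` must be a 3-D array (frame, row, col)")
  }
  if (dim(frames)[1] < 2) stop("a video stack needs at least 2 frames")
  if (any(frames < 0)) stop("intensities must be >= 0")
  stopifnot_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz),
            class = "VideoStack")
}

#' @export
print.VideoStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<VideoStack> %d frames of %dx%d px @ %.3g Hz\n",
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

#' ROI mask
#'
#' @param label integer matrix with ROI ids 1..K (0 = background); ids must
#'   be contiguous and every ROI must contain at least one pixel.
#' @return An object of class `ROIMask` with per-ROI centroids.
#' @export
roi_mask <- function(label) {
  if (!is.matrix(label)) stop("`label` must be a matrix")
  label <- matrix(as.integer(round(label)), nrow(label), ncol(label))
  ids <- sort(unique(label[label > 0]))
  if (length(ids) && !identical(ids, seq_len(max(ids)))) {
    stop("ROI ids must be contiguous from 1")
  }
  centroids <- t(vapply(ids, function(i) {
    px <- which(label == i, arr.ind = TRUE)
    colMeans(px)
  }, c(row = 0, col = 0)))
  structure(list(label = label, ids = ids, centroids = centroids),
            class = "ROIMask")
}

#' @export
print.ROIMask <- function(x, ...) {
  cat(sprintf("<ROIMask> %d ROIs on %dx%d px\n", length(x$ids),
              nrow(x$label), ncol(x$label)))
  invisible(x)
}

#' Calcium recording (neurons x frames)
#'
#' @param traces numeric matrix `(neuron, frame)`; rownames are neuron ids.
#' @param frame_rate_hz frames/s.
#' @param session_id session identifier.
#' @param roi_ids neuron/ROI identifiers (default: trace rownames).
#' @return An object of class `CalciumRecording`.
#' @export
calcium_recording <- function(traces, frame_rate_hz, session_id = "session",
                              roi_ids = rownames(traces)) {
  if (!is.matrix(traces)) stop("`traces` must be a matrix (neuron x frame)")
  stopifnot_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  if (is.null(roi_ids)) roi_ids <- paste0("n", seq_len(nrow(traces)))
  rownames(traces) <- roi_ids
  structure(list(traces = traces, frame_rate_hz = frame_rate_hz,
                 session_id = session_id, roi_ids = roi_ids),
            class = "CalciumRecording")
}

#' @export
print.CalciumRecording <- function(x, ...) {
  cat(sprintf("<CalciumRecording '%s'> %d neurons x %d frames @ %.3g Hz\n",
              x$session_id, nrow(x$traces), ncol(x$traces), x$frame_rate_hz))
  invisible(x)
}

# Separable Gaussian blur with replicate (edge-extend) padding, so flat
# fields and smooth gradients pass through unchanged regardless of the
# kernel radius relative to the frame size.
gaussian_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_rows <- function(mat) {
    padded <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                    mat[rep(nrow(mat), r), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(r + 1):(r + nrow(mat)), ], nrow(mat), ncol(mat))
  }
  t(blur_rows(t(blur_rows(m))))
}

# Translate a frame by integer (dr, dc), filling vacated pixels with the
# frame median.
shift_frame <- function(frame, dr, dc, fill = stats::median(frame)) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Estimate the smooth background of each frame
#'
#' The background is the low-spatial-frequency component of each frame:
#' structure at scales larger than `low_cut` pixels, obtained by Gaussian
#' smoothing with `sigma = low_cut / 4` (replicate boundary, so flat fields
#' and smooth gradients are preserved).  `high_cut` bounds the scale of
#' structure regarded as background from above and must exceed `low_cut`;
#' with the default 10,000 it is larger than any frame and only `low_cut`
#' is operative.  Output is floored at a small epsilon so it can be used as
#' a divisor.
#'
#' @param stack a [video_stack()].
#' @param low_cut,high_cut spatial cutoffs in pixels (defaults 100 and
#'   10,000).
#' @return A [video_stack()] of per-frame backgrounds.
#' @export
estimate_background <- function(stack, low_cut = 100, high_cut = 10000) {
  stopifnot(inherits(stack, "VideoStack"))
  if (low_cut <= 0 || high_cut <= 0) stop("cutoffs must be > 0")
  if (low_cut >= high_cut) stop("`low_cut` must be smaller than `high_cut`")
  d <- dim(stack$frames)
  if (d[2] < 3 || d[3] < 3) stop("frames must be at least 3x3 px")
  sigma <- low_cut / 4
  out <- stack$frames
  for (f in seq_len(d[1])) {
    out[f, , ] <- pmax(gaussian_blur(stack$frames[f, , ], sigma), 1e-9)
  }
  video_stack(out, stack$frame_rate_hz)
}

#' Divide a stack by its background
#'
#' @param stack,background [video_stack()]s with matching dimensions;
#'   `background` must be strictly positive.
#' @return A [video_stack()] of ratio frames (flat regions are ~1).
#' @export
divide_background <- function(stack, background) {
  stopifnot(inherits(stack, "VideoStack"), inherits(background, "VideoStack"))
  if (!identical(dim(stack$frames), dim(background$frames))) {
    stop("stack and background dimensions differ")
  }
  if (any(background$frames <= 0)) stop("background must be strictly positive")
  video_stack(stack$frames / background$frames, stack$frame_rate_hz)
}

# Cross-correlation score of `frame` shifted by (dr, dc) against `ref`,
# computed on the overlapping region.
shift_score <- function(ref, frame, dr, dc) {
  nr <- nrow(ref); nc <- ncol(ref)
  r_ref <- max(1, 1 + dr):min(nr, nr + dr)
  c_ref <- max(1, 1 + dc):min(nc, nc + dc)
  r_frm <- r_ref - dr
  c_frm <- c_ref - dc
  a <- ref[r_ref, c_ref]; b <- frame[r_frm, c_frm]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

#' Rigid translation registration of a stack
#'
#' Aligns every frame to the first frame by the integer-pixel translation
#' maximizing the normalized cross-correlation (searched over
#' `[-max_shift, max_shift]^2`).  Vacated pixels are filled with the frame
#' median.  All-constant frames get shift (0, 0) and a low-quality flag.
#'
#' @param stack a [video_stack()] with >= 2 frames.
#' @param max_shift maximum shift searched, pixels.
#' @return List with `stack` (aligned [video_stack()]), `shifts` (matrix
#'   `n_frames x 2`, columns `dr`, `dc`: the detected displacement of each
#'   frame relative to the reference; its negative is applied to align) and
#'   `quality` (per-frame peak correlation; `NA` for degenerate frames).
#' @export
register_translation <- function(stack, max_shift = 8) {
  stopifnot(inherits(stack, "VideoStack"))
  d <- dim(stack$frames)
  ref <- stack$frames[1, , ]
  shifts <- matrix(0L, d[1], 2, dimnames = list(NULL, c("dr", "dc")))
  quality <- rep(NA_real_, d[1])
  out <- stack$frames
  grid <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  for (f in seq_len(d[1])[-1]) {
    frame <- stack$frames[f, , ]
    scores <- vapply(seq_len(nrow(grid)), function(i) {
      shift_score(ref, frame, grid$dr[i], grid$dc[i])
    }, 0)
    if (all(is.na(scores))) {
      warning("frame ", f, " is constant; shift (0,0) assigned")
      next
    }
    best <- which.max(scores)
    shifts[f, ] <- -c(grid$dr[best], grid$dc[best])
    quality[f] <- scores[best]
    if (any(shifts[f, ] != 0)) {
      out[f, , ] <- shift_frame(frame, grid$dr[best], grid$dc[best])
    }
  }
  quality[1] <- 1
  list(stack = video_stack(out, stack$frame_rate_hz), shifts = shifts,
       quality = quality)
}

#' Extract mean-intensity ROI traces
#'
#' @param stack a [video_stack()].
#' @param mask an [roi_mask()] with the same frame dimensions.
#' @return Numeric matrix `(roi, frame)` of mean in-ROI intensities.
#' @export
extract_traces <- function(stack, mask) {
  stopifnot(inherits(stack, "VideoStack"), inherits(mask, "ROIMask"))
  d <- dim(stack$frames)
  if (!identical(d[2:3], dim(mask$label))) {
    stop("mask dimensions do not match the frames")
  }
  flat <- matrix(stack$frames, nrow = d[1])  # frame x pixel
  lab <- as.vector(mask$label)
  traces <- matrix(NA_real_, length(mask$ids), d[1])
  for (i in mask$ids) {
    px <- which(lab == i)
    if (!length(px)) stop("ROI ", i, " is empty")
    traces[i, ] <- if (length(px) == 1) flat[, px] else rowMeans(flat[, px])
  }
  rownames(traces) <- paste0("roi", mask$ids)
  traces
}

#' Compute dF/F from raw traces
#'
#' `(x - F) / F` per neuron, where `F` is the mean intensity over the whole
#' recording; consequently every output trace has mean zero.
#'
#' @param raw numeric matrix `(neuron, frame)` of raw intensities; every
#'   neuron's mean must be > 0.
#' @param frame_rate_hz frames/s.
#' @param session_id session identifier.
#' @return A [calcium_recording()] in dF/F units.
#' @export
compute_dff <- function(raw, frame_rate_hz, session_id = "session") {
  if (!is.matrix(raw)) stop("`raw` must be a matrix (neuron x frame)")
  f0 <- rowMeans(raw)
  if (any(f0 <= 0)) {
    stop("non-positive mean intensity for neuron(s): ",
         paste(which(f0 <= 0), collapse = ", "))
  }
  dff <- sweep(sweep(raw, 1, f0, "-"), 1, f0, "/")
  calcium_recording(dff, frame_rate_hz, session_id = session_id,
                    roi_ids = rownames(raw))
}

#' Track ROIs into a new recording
#'
#' A single global integer translation (searched over
#' `[-max_shift, max_shift]^2`) is chosen to maximize the summed brightness
#' of the new recording's maximum-intensity projection inside the translated
#' ROI footprints.  ROIs whose translated footprint is not brighter than
#' `threshold` are dropped; bright sources not covered by any kept ROI
#' become new ROIs.
#'
#' @param reference_mask an [roi_mask()] from the reference session.
#' @param new_stack a [video_stack()] of the new session (same frame size).
#' @param max_shift maximum translation searched, pixels.
#' @param threshold brightness threshold for accepting an ROI; default
#'   `"auto"` = median + 2 MAD of the max projection.
#' @return List with `shift` (chosen `c(dr, dc)`), `mapping` (named integer
#'   vector old id -> new id, `NA` for dropped ROIs), `new_ids` (ids
#'   assigned to unmatched sources) and `mask` (updated [roi_mask()] in the
#'   new session's coordinates).
#' @export
track_rois <- function(reference_mask, new_stack, max_shift = 8,
                       threshold = "auto") {
  stopifnot(inherits(reference_mask, "ROIMask"),
            inherits(new_stack, "VideoStack"))
  d <- dim(new_stack$frames)
  if (!identical(d[2:3], dim(reference_mask$label))) {
    stop("mask and stack frame dimensions differ")
  }
  maxproj <- apply(new_stack$frames, c(2, 3), max)
  if (identical(threshold, "auto")) {
    threshold <- stats::median(maxproj) + 2 * stats::mad(maxproj)
  }
  footprint <- reference_mask$label > 0
  grid <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    shifted <- shift_frame(reference_mask$label, grid$dr[i], grid$dc[i],
                           fill = 0)
    sum(maxproj[shifted > 0])
  }, 0)
  best <- which.max(scores)
  shift <- c(dr = grid$dr[best], dc = grid$dc[best])
  shifted_label <- shift_frame(reference_mask$label, shift[1], shift[2],
                               fill = 0)
  kept <- vapply(reference_mask$ids, function(i) {
    px <- shifted_label == i
    sum(px) > 0 && mean(maxproj[px]) > threshold
  }, TRUE)
  mapping <- rep(NA_integer_, length(reference_mask$ids))
  names(mapping) <- paste0("roi", reference_mask$ids)
  new_label <- matrix(0L, d[2], d[3])
  next_id <- 0L
  for (i in reference_mask$ids[kept]) {
    next_id <- next_id + 1L
    mapping[paste0("roi", i)] <- next_id
    new_label[shifted_label == i] <- next_id
  }
  # unmatched bright sources become new ROIs
  bright <- maxproj > threshold
  bright[new_label > 0] <- FALSE
  comp <- EBImage::bwlabel(bright)
  comp <- matrix(as.integer(comp), d[2], d[3])
  new_ids <- integer(0)
  for (cid in setdiff(unique(as.vector(comp)), 0L)) {
    px <- comp == cid
    if (sum(px) < 2) next  # ignore single-pixel speckle
    next_id <- next_id + 1L
    new_label[px & new_label == 0] <- next_id
    new_ids <- c(new_ids, next_id)
  }
  list(shift = shift, mapping = mapping, new_ids = new_ids,
       mask = roi_mask(new_label))
}

#' Preprocess a raw stack into dF/F traces
#'
#' Convenience wrapper: background estimation, background division,
#' translation registration, ROI extraction and dF/F.
#'
#' @param stack a [video_stack()] of raw frames.
#' @param mask an [roi_mask()].
#' @param low_cut,high_cut background-filter cutoffs (see
#'   [estimate_background()]).
#' @param max_shift registration search radius, pixels.
#' @param session_id session identifier.
#' @return List with `recording` (a [calcium_recording()]), `shifts` and
#'   `quality` from registration.
#' @export
preprocess_stack <- function(stack, mask, low_cut = 100, high_cut = 10000,
                             max_shift = 8, session_id = "session") {
  bg <- estimate_background(stack, low_cut, high_cut)
  flat <- divide_background(stack, bg)
  reg <- register_translation(flat, max_shift = max_shift)
  raw <- extract_traces(reg$stack, mask)
  rec <- compute_dff(raw, stack$frame_rate_hz, session_id = session_id)
  list(recording = rec, shifts = reg$shifts, quality = reg$quality)
}
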
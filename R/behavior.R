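#' Controlled vocabulary of scored behaviors
#'
#' Behaviors that may appear in an ethogram: biting attack received
#' (`defeat`), stretch-attend/stretch-approach risk assessment
#' (`assessment`), rapid movement away from the threat (`flight`), biting
#' attack delivered (`attack`), close nose contact (`sniffing`), `upright`
#' posture, `put_down`, `follow`, `cornering`, free `locomotion`, `freeze`
#' and head/body `orientation` toward a conspecific.
#'
#' @format Character vector of behavior labels.
#' @export
behavior_vocabulary <- c(
  "defeat", "assessment", "flight", "attack", "sniffing", "upright",
  "put_down", "follow", "cornering", "locomotion", "freeze", "orientation"
)

#' Behaviors counted as close social encounter
#'
#' Used to restrict ensemble analyses to frames of close social contact.
#' @format Character vector.
#' @export
close_contact_behaviors <- c("defeat", "upright", "orientation", "sniffing", "follow")

#' Construct a behavior track (ethogram)
#'
#' An ethogram is a table of half-open intervals `[onset_s, offset_s)` in
#' seconds, each tagged with a behavior from [behavior_vocabulary].
#'
#' @param intervals data.frame with columns `onset_s`, `offset_s`,
#'   `behavior`.
#' @param duration_s session duration in seconds.
#' @param session_id identifier for the session.
#' @param session_kind one of `"defeat"`, `"approach_avoidance"`,
#'   `"context"`, `"aggression"`, or `NA`.
#' @param phases optional named list of `c(start_s, end_s)` phase windows
#'   (e.g. `defeat`, `avoidance`).
#' @param chamber_track optional per-calcium-frame compartment labels, see
#'   [chamber_predicate()].
#' @return An object of class `BehaviorTrack`.
#' @export
behavior_track <- function(intervals, duration_s, session_id = "session",
                           session_kind = NA_character_, phases = NULL,
                           chamber_track = NULL) {
  stopifnot(is.data.frame(intervals))
  required <- c("onset_s", "offset_s", "behavior")
  if (!all(required %in% names(intervals))) {
    stop("`intervals` must have columns onset_s, offset_s, behavior")
  }
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  intervals$behavior <- as.character(intervals$behavior)
  bad <- setdiff(unique(intervals$behavior), behavior_vocabulary)
  if (length(bad)) {
    stop("unknown behavior label(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(intervals) && any(intervals$onset_s >= intervals$offset_s)) {
    stop("every interval must satisfy onset_s < offset_s")
  }
  if (nrow(intervals) && any(intervals$onset_s < 0)) {
    stop("interval onsets must be >= 0")
  }
  clipped <- FALSE
  if (nrow(intervals) && any(intervals$offset_s > duration_s)) {
    warning("intervals extending beyond the session end were clipped")
    intervals$offset_s <- pmin(intervals$offset_s, duration_s)
    intervals <- intervals[intervals$onset_s < intervals$offset_s, , drop = FALSE]
    clipped <- TRUE
  }
  structure(
    list(intervals = intervals[order(intervals$onset_s), , drop = FALSE],
         duration_s = duration_s, session_id = session_id,
         session_kind = session_kind, phases = phases,
         chamber_track = chamber_track, clipped = clipped),
    class = "BehaviorTrack"
  )
}

#' @export
print.BehaviorTrack <- function(x, ...) {
  cat(sprintf("<BehaviorTrack '%s'> %.0f s, %d intervals, %d behaviors\n",
              x$session_id, x$duration_s, nrow(x$intervals),
              length(unique(x$intervals$behavior))))
  invisible(x)
}

# Merge overlapping intervals of one behavior into disjoint intervals.
merge_intervals <- function(onsets, offsets) {
  if (!length(onsets)) return(cbind(onset = numeric(0), offset = numeric(0)))
  o <- order(onsets)
  onsets <- onsets[o]; offsets <- offsets[o]
  m_on <- onsets[1]; m_off <- offsets[1]
  out_on <- numeric(0); out_off <- numeric(0)
  for (i in seq_along(onsets)[-1]) {
    if (onsets[i] <= m_off) {
      m_off <- max(m_off, offsets[i])
    } else {
      out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
      m_on <- onsets[i]; m_off <- offsets[i]
    }
  }
  cbind(onset = c(out_on, m_on), offset = c(out_off, m_off))
}

# Fraction of each calcium-frame window [f/r, (f+1)/r) covered by the union
# of the given intervals (frames indexed 1..n_frames; frame i covers
# [(i-1)/rate, i/rate)).
frame_coverage <- function(onsets, offsets, frame_rate_hz, n_frames) {
  cov <- numeric(n_frames)
  if (!length(onsets)) return(cov)
  merged <- merge_intervals(onsets, offsets)
  for (i in seq_len(nrow(merged))) {
    a <- merged[i, 1]; b <- merged[i, 2]
    f0 <- max(1L, floor(a * frame_rate_hz) + 1L)
    f1 <- min(n_frames, ceiling(b * frame_rate_hz))
    if (f0 > f1) next
    f <- f0:f1
    ov <- pmin(b, f / frame_rate_hz) - pmax(a, (f - 1) / frame_rate_hz)
    cov[f] <- cov[f] + pmax(ov, 0)
  }
  pmin(cov * frame_rate_hz, 1)
}

#' Rasterize an ethogram onto calcium frames
#'
#' A calcium frame `f` (0-based in time; frame `f` covers
#' `[f/rate, (f+1)/rate)` seconds) is labeled with a behavior when more than
#' 50% of its window overlaps that behavior's intervals.
#'
#' @param track a [behavior_track()].
#' @param frame_rate_hz calcium frame rate (frames/s).
#' @param n_frames number of calcium frames.
#' @return Logical matrix `n_frames x behaviors` (columns named by the
#'   behaviors present in the ethogram).
#' @export
resample_to_calcium <- function(track, frame_rate_hz, n_frames) {
  stopifnot(inherits(track, "BehaviorTrack"))
  stopifnot_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  if (!is.numeric(n_frames) || n_frames < 1) stop("`n_frames` must be > 0")
  n_frames <- as.integer(n_frames)
  iv <- track$intervals
  if (any(iv$offset_s > n_frames / frame_rate_hz)) {
    warning("intervals extend beyond the recording end; clipping")
  }
  behaviors <- sort(unique(iv$behavior))
  out <- matrix(FALSE, n_frames, length(behaviors),
                dimnames = list(NULL, behaviors))
  for (b in behaviors) {
    sel <- iv$behavior == b
    cov <- frame_coverage(iv$onset_s[sel], iv$offset_s[sel],
                          frame_rate_hz, n_frames)
    out[, b] <- cov > 0.5
  }
  out
}

# Constructor for frame-wise predicate labels.
predicate_labels <- function(state, predicate, n_instances,
                             evaluable = NULL) {
  state <- factor(state, levels = c("positive", "negative", "excluded"))
  if (anyNA(state)) stop("predicate states must be positive/negative/excluded")
  if (is.null(evaluable)) {
    evaluable <- any(state == "positive") && any(state == "negative")
  }
  structure(
    list(state = state, predicate = predicate,
         n_instances = as.integer(n_instances), evaluable = evaluable),
    class = "PredicateLabels"
  )
}

#' @export
print.PredicateLabels <- function(x, ...) {
  tab <- table(x$state)
  cat(sprintf("<PredicateLabels '%s'> %d frames (+%d / -%d / excl %d), %d instance(s)%s\n",
              x$predicate, length(x$state), tab[["positive"]],
              tab[["negative"]], tab[["excluded"]], x$n_instances,
              if (x$evaluable) "" else ", NOT evaluable"))
  invisible(x)
}

#' Frame-wise predicate for a scored behavior
#'
#' Frames with the behavior are positive, all other frames negative.  The
#' instance count is the number of source bouts; recordings with fewer than
#' two instances are flagged not-evaluable downstream.
#'
#' @inheritParams resample_to_calcium
#' @param behavior a label from [behavior_vocabulary].
#' @return A `PredicateLabels` object.
#' @export
behavior_predicate <- function(track, behavior, frame_rate_hz, n_frames) {
  if (!behavior %in% behavior_vocabulary) {
    stop("unknown behavior: ", behavior)
  }
  ras <- resample_to_calcium(track, frame_rate_hz, n_frames)
  pos <- if (behavior %in% colnames(ras)) ras[, behavior] else
    rep(FALSE, n_frames)
  n_bouts <- sum(track$intervals$behavior == behavior)
  state <- ifelse(pos, "positive", "negative")
  predicate_labels(state, behavior, n_bouts,
                   evaluable = n_bouts > 0 && any(pos) && any(!pos))
}

#' Flight predicate: peri-onset windows
#'
#' For each flight onset `t0`, frames in `[t0 - window_s, t0)` are negative
#' and frames in `[t0, t0 + window_s)` positive; all remaining frames are
#' excluded.  A frame claimed positive by one flight and negative by another
#' is excluded.
#'
#' @inheritParams resample_to_calcium
#' @param window_s half-window length in seconds (default 2).
#' @return A `PredicateLabels` object (instances = number of flights).
#' @export
flight_predicate <- function(track, frame_rate_hz, n_frames, window_s = 2) {
  stopifnot(inherits(track, "BehaviorTrack"))
  onsets <- track$intervals$onset_s[track$intervals$behavior == "flight"]
  if (!length(onsets)) stop("no flight bouts in ethogram")
  n_frames <- as.integer(n_frames)
  pos <- rep(FALSE, n_frames); neg <- rep(FALSE, n_frames)
  for (t0 in onsets) {
    cn <- frame_coverage(max(t0 - window_s, 0), t0, frame_rate_hz, n_frames)
    cp <- frame_coverage(t0, t0 + window_s, frame_rate_hz, n_frames)
    neg <- neg | (cn > 0.5)
    pos <- pos | (cp > 0.5)
  }
  contested <- pos & neg
  state <- rep("excluded", n_frames)
  state[pos & !contested] <- "positive"
  state[neg & !contested] <- "negative"
  predicate_labels(state, "flight", length(onsets))
}

#' Chamber-occupancy predicate
#'
#' Frames in the target chamber are positive, all other frames (corridor and
#' the other chamber) negative.
#'
#' @param chambers per-frame compartment labels, values in
#'   `{"home", "corridor", "far"}`.
#' @param target `"home"` or `"far"`.
#' @return A `PredicateLabels` object; instances = number of distinct visits
#'   to the target chamber.
#' @export
chamber_predicate <- function(chambers, target = c("far", "home")) {
  target <- match.arg(target)
  chambers <- as.character(chambers)
  bad <- setdiff(unique(chambers), c("home", "corridor", "far"))
  if (length(bad)) stop("unknown chamber label(s): ", paste(bad, collapse = ", "))
  pos <- chambers == target
  runs <- rle(pos)
  n_visits <- sum(runs$values)
  predicate_labels(ifelse(pos, "positive", "negative"), paste0(target, "_chamber"),
                   n_visits)
}

#' Session-phase predicate (tonic social responding)
#'
#' Positive frames are those of the enclosed-defeat phase, negative frames
#' those of the post-defeat approach-avoidance phase; all other frames
#' (e.g. pre-defeat habituation) are excluded.  Used to classify tonic
#' Social+/Social- neurons.
#'
#' @param frame_rate_hz calcium frame rate.
#' @param n_frames number of calcium frames.
#' @param defeat_bounds numeric `c(start_s, end_s)` of the defeat phase.
#' @param avoidance_bounds numeric `c(start_s, end_s)` of the
#'   approach-avoidance phase.
#' @return A `PredicateLabels` object (instances = 2, one per phase).
#' @export
phase_predicate <- function(frame_rate_hz, n_frames, defeat_bounds,
                            avoidance_bounds) {
  check_bounds <- function(b, nm) {
    if (length(b) != 2 || b[1] >= b[2]) stop(sprintf("`%s` must be c(start, end) with start < end", nm))
  }
  check_bounds(defeat_bounds, "defeat_bounds")
  check_bounds(avoidance_bounds, "avoidance_bounds")
  if (max(defeat_bounds[1], avoidance_bounds[1]) <
      min(defeat_bounds[2], avoidance_bounds[2])) {
    stop("defeat and avoidance phases overlap")
  }
  n_frames <- as.integer(n_frames)
  pos <- frame_coverage(defeat_bounds[1], defeat_bounds[2], frame_rate_hz, n_frames) > 0.5
  neg <- frame_coverage(avoidance_bounds[1], avoidance_bounds[2], frame_rate_hz, n_frames) > 0.5
  state <- rep("excluded", n_frames)
  state[pos] <- "positive"
  state[neg] <- "negative"
  predicate_labels(state, "social_phase", 2L)
}

#' Per-frame active-behavior signature
#'
#' For each calcium frame, the sorted set of currently active behaviors
#' (among `behaviors`) pasted into one label, e.g. `"defeat+sniffing"`;
#' frames with none active get `""`.  Used to balance behavior composition
#' between compared frame sets (see [session_separation_ks()]).
#'
#' @inheritParams resample_to_calcium
#' @param behaviors behaviors contributing to the signature (default
#'   [close_contact_behaviors]).
#' @return Character vector of length `n_frames`.
#' @export
behavior_signature <- function(track, frame_rate_hz, n_frames,
                               behaviors = close_contact_behaviors) {
  ras <- resample_to_calcium(track, frame_rate_hz, n_frames)
  keep <- intersect(colnames(ras), behaviors)
  if (!length(keep)) return(rep("", n_frames))
  sub <- ras[, sort(keep), drop = FALSE]
  apply(sub, 1, function(row) paste(colnames(sub)[row], collapse = "+"))
}

#' Frames of close social encounter
#'
#' Union of frames labeled with any close-contact behavior
#' ([close_contact_behaviors]); used to restrict ensemble analyses.
#'
#' @inheritParams resample_to_calcium
#' @return Integer vector of frame indices (1-based).
#' @export
close_contact_frames <- function(track, frame_rate_hz, n_frames) {
  ras <- resample_to_calcium(track, frame_rate_hz, n_frames)
  keep <- intersect(colnames(ras), close_contact_behaviors)
  if (!length(keep)) return(integer(0))
  which(rowSums(ras[, keep, drop = FALSE]) > 0)
}
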
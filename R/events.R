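#' Z-score a recording
#'
#' `(x - mean) / SD` per neuron over the whole recording (population-SD
#' denominator `n`, matching per-recording normalization of frame vectors).
#' Neurons with zero SD are dropped and reported.
#'
#' @param rec a [calcium_recording()].
#' @return A [calcium_recording()] of z-scored traces, with attribute
#'   `excluded` listing zero-SD neuron ids.
#' @export
zscore_recording <- function(rec) {
  stopifnot(inherits(rec, "CalciumRecording"))
  x <- rec$traces
  mu <- rowMeans(x)
  n <- ncol(x)
  sdev <- sqrt(rowMeans((x - mu)^2))
  bad <- sdev == 0
  if (any(bad)) {
    warning("dropping zero-SD neuron(s): ",
            paste(rownames(x)[bad], collapse = ", "))
  }
  z <- (x[!bad, , drop = FALSE] - mu[!bad]) / sdev[!bad]
  out <- calcium_recording(z, rec$frame_rate_hz, session_id = rec$session_id,
                           roi_ids = rownames(x)[!bad])
  attr(out, "excluded") <- rownames(x)[bad]
  out
}

#' Peri-event matrix for one neuron
#'
#' Extracts trace segments `[t - window_before_s, t + window_after_s)`
#' around each event time; events whose window extends beyond the recording
#' are dropped and counted.
#'
#' @param trace numeric per-frame values (typically z-scored).
#' @param events event (onset or offset) times in seconds.
#' @param frame_rate_hz frames/s.
#' @param window_before_s,window_after_s window half-lengths in seconds
#'   (defaults 5 and 5).
#' @return A `PeriEventMatrix`: matrix `(trial, time)` with attributes
#'   `onset_col` (first column at/after the event), `frame_rate_hz`,
#'   `events` (times used) and `n_dropped`.
#' @export
peri_event <- function(trace, events, frame_rate_hz, window_before_s = 5,
                       window_after_s = 5) {
  nb <- as.integer(round(window_before_s * frame_rate_hz))
  na_ <- as.integer(round(window_after_s * frame_rate_hz))
  n <- length(trace)
  segs <- list(); used <- numeric(0); dropped <- 0L
  for (t0 in events) {
    f0 <- floor(t0 * frame_rate_hz) + 1   # frame containing the event
    lo <- f0 - nb; hi <- f0 + na_ - 1
    if (lo < 1 || hi > n) { dropped <- dropped + 1L; next }
    segs[[length(segs) + 1]] <- trace[lo:hi]
    used <- c(used, t0)
  }
  if (!length(segs)) stop("no events with a complete window inside the recording")
  m <- do.call(rbind, segs)
  structure(m, class = c("PeriEventMatrix", "matrix"),
            onset_col = nb + 1L, frame_rate_hz = frame_rate_hz,
            events = used, n_dropped = dropped)
}

#' Trial-averaged peri-event trace
#'
#' @param pem a `PeriEventMatrix` from [peri_event()].
#' @return Numeric vector: mean across trials per time bin.
#' @export
peri_event_mean <- function(pem) {
  stopifnot(inherits(pem, "PeriEventMatrix"))
  colMeans(unclass(pem))
}

# Exact two-sided Wilcoxon signed-rank p-value by dynamic programming over
# the (possibly tied, doubled) ranks; zeros dropped; normal approximation
# with tie correction above `exact_max` pairs.
signed_rank_test <- function(d, exact_max = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p = 1, statistic = 0, n = 0L, direction = 0))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  direction <- sign(w - n * (n + 1) / 4)
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))       # doubled ranks are integers
    total <- sum(r2)
    counts <- numeric(total + 1)          # counts[k+1] = #subsets with sum k
    counts[1] <- 1
    for (ri in r2) {
      counts[(ri + 1):(total + 1)] <- counts[(ri + 1):(total + 1)] +
        counts[1:(total + 1 - ri)]
    }
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[1:(w2 + 1)]) / 2^n
    p_ge <- sum(counts[(w2 + 1):(total + 1)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p = p, statistic = w, n = as.integer(n), direction = direction)
}

#' Onset/offset change test
#'
#' For each trial the z-scores of the frames before and after the event are
#' averaged, and the per-trial before vs after means are compared with a
#' two-sided Wilcoxon signed-rank test (exact for up to 25 trials, normal
#' approximation with tie correction above; all-zero differences give
#' `p = 1`).
#'
#' @param pem a `PeriEventMatrix` from [peri_event()].
#' @return List with `p`, `direction` (+1 activated, -1 suppressed, 0
#'   none), `statistic` (signed-rank sum `W`), `n_trials`, `before_mean`
#'   and `after_mean`.
#' @export
onset_change_test <- function(pem) {
  stopifnot(inherits(pem, "PeriEventMatrix"))
  m <- unclass(pem)
  if (nrow(m) < 2) stop("at least 2 trials are required")
  onset <- attr(pem, "onset_col")
  before <- rowMeans(m[, seq_len(onset - 1), drop = FALSE])
  after <- rowMeans(m[, onset:ncol(m), drop = FALSE])
  res <- signed_rank_test(after - before)
  list(p = res$p, direction = res$direction, statistic = res$statistic,
       n_trials = nrow(m), before_mean = mean(before),
       after_mean = mean(after))
}

#' Peri-event summary for many neurons
#'
#' @param rec a (typically z-scored) [calcium_recording()].
#' @param events event times in seconds.
#' @param window_before_s,window_after_s window half-lengths in seconds.
#' @param behavior label recorded in the output.
#' @return data.frame: `neuron`, `behavior`, `n_trials`, `before_mean`,
#'   `after_mean`, `p`, `direction`.
#' @export
peri_event_summary <- function(rec, events, window_before_s = 5,
                               window_after_s = 5, behavior = "event") {
  stopifnot(inherits(rec, "CalciumRecording"))
  rows <- lapply(rownames(rec$traces), function(id) {
    pem <- peri_event(rec$traces[id, ], events, rec$frame_rate_hz,
                      window_before_s, window_after_s)
    tst <- onset_change_test(pem)
    data.frame(neuron = id, behavior = behavior, n_trials = tst$n_trials,
               before_mean = tst$before_mean, after_mean = tst$after_mean,
               p = tst$p, direction = tst$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
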
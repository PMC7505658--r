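#' Responder classes plantable in synthetic neurons
#'
#' Tonic classes (`Social+`, `Social-`, `Far+`, `Home+`) are elevated or
#' suppressed throughout a phase or chamber occupancy; phasic classes
#' (`Defeat+/-`, `Assessment+/-`, `Flight+/-`, `Sniff+`, `Attack+`) are
#' locked to individual behavior bouts. `none` neurons carry no signal.
#'
#' @format Character vector of class names.
#' @export
responder_classes <- c(
  "Social+", "Social-", "Defeat+", "Defeat-", "Assessment+", "Assessment-",
  "Flight+", "Flight-", "Far+", "Home+", "Sniff+", "Attack+", "none"
)

# Default class mixture: one primary class per neuron, proportions chosen to
# echo the population-level prevalence of the main responder types while
# leaving a non-responder remainder.
default_class_fractions <- c(
  "Social+" = 0.16, "Social-" = 0.10, "Defeat+" = 0.12, "Defeat-" = 0.03,
  "Assessment+" = 0.12, "Assessment-" = 0.03, "Flight+" = 0.02,
  "Flight-" = 0.05, "Far+" = 0.09, "Home+" = 0.07, "Sniff+" = 0.05,
  "Attack+" = 0.04
)

#' Configuration for a synthetic experiment
#'
#' @param n_neurons number of simulated neurons.
#' @param frame_rate_hz calcium frame rate, frames/s (5-100).
#' @param session_plan data.frame with columns `kind` (one of `defeat`,
#'   `approach_avoidance`, `context`, `aggression`) and `duration_s`.
#' @param class_fractions named proportions over [responder_classes]
#'   (excluding `none`); must sum to <= 1, the remainder being
#'   non-responders.
#' @param bout_rate_hz mean number of bouts per behavior per second of
#'   session (bout counts are Poisson with mean `bout_rate_hz * duration`).
#' @param bout_duration_s mean bout length, seconds (exponential).
#' @param response_amplitude planted response size, dF/F units.
#' @param noise_sd additive Gaussian noise SD, dF/F units.
#' @param kernel_rise_s,kernel_decay_s calcium-indicator kernel time
#'   constants, seconds (GCaMP6s-like defaults 0.2 / 1.8).
#' @param remodel_fraction proportion of neurons whose tuning is resampled
#'   between repeated sessions of the same kind.
#' @param seed master seed; all generator randomness derives from it.
#' @return An object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_neurons = 100,
                             frame_rate_hz = 10,
                             session_plan = data.frame(kind = "defeat",
                                                       duration_s = 600),
                             class_fractions = default_class_fractions,
                             bout_rate_hz = 0.02,
                             bout_duration_s = 5,
                             response_amplitude = 1,
                             noise_sd = 0.2,
                             kernel_rise_s = 0.2,
                             kernel_decay_s = 1.8,
                             remodel_fraction = 0,
                             seed = 1) {
  stopifnot_scalar(n_neurons, "n_neurons", positive = TRUE)
  stopifnot_scalar(frame_rate_hz, "frame_rate_hz", positive = TRUE)
  if (frame_rate_hz < 5 || frame_rate_hz > 100) {
    stop("`frame_rate_hz` must lie in [5, 100]")
  }
  stopifnot(is.data.frame(session_plan),
            all(c("kind", "duration_s") %in% names(session_plan)))
  bad <- setdiff(session_plan$kind,
                 c("defeat", "approach_avoidance", "context", "aggression"))
  if (length(bad)) stop("unknown session kind(s): ", paste(bad, collapse = ", "))
  if (any(session_plan$duration_s <= 0)) stop("session durations must be > 0")
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% setdiff(responder_classes, "none"))) {
    stop("`class_fractions` must be named with responder classes")
  }
  if (any(class_fractions < 0) || sum(class_fractions) > 1 + 1e-9) {
    stop("`class_fractions` must be non-negative and sum to <= 1")
  }
  if (any(bout_rate_hz < 0)) stop("`bout_rate_hz` must be >= 0")
  stopifnot_scalar(bout_duration_s, "bout_duration_s", positive = TRUE)
  stopifnot_scalar(response_amplitude, "response_amplitude")
  if (response_amplitude < 0) stop("`response_amplitude` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  stopifnot_scalar(kernel_rise_s, "kernel_rise_s", positive = TRUE)
  stopifnot_scalar(kernel_decay_s, "kernel_decay_s", positive = TRUE)
  if (kernel_rise_s >= kernel_decay_s) {
    stop("`kernel_rise_s` must be smaller than `kernel_decay_s`")
  }
  if (remodel_fraction < 0 || remodel_fraction > 1) {
    stop("`remodel_fraction` must lie in [0, 1]")
  }
  structure(
    list(n_neurons = as.integer(n_neurons), frame_rate_hz = frame_rate_hz,
         session_plan = session_plan, class_fractions = class_fractions,
         bout_rate_hz = bout_rate_hz, bout_duration_s = bout_duration_s,
         response_amplitude = response_amplitude, noise_sd = noise_sd,
         kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
         remodel_fraction = remodel_fraction, seed = seed),
    class = "SyntheticConfig"
  )
}

# Behaviors generated for each session kind, with the phase window (as a
# fraction of the session) in which their bouts may occur.  Defeat sessions
# have a habituation / enclosed-defeat / approach-avoidance phase structure.
session_behavior_plan <- function(kind) {
  switch(kind,
    defeat = list(
      phases = list(habituation = c(0, 0.2), defeat = c(0.2, 0.6),
                    avoidance = c(0.6, 1)),
      behaviors = list(
        defeat = "defeat", upright = "defeat", orientation = "defeat",
        sniffing = "defeat", follow = "defeat",
        assessment = "avoidance", flight = "avoidance",
        locomotion = "all")
    ),
    approach_avoidance = list(
      phases = list(avoidance = c(0, 1)),
      behaviors = list(assessment = "all", flight = "all", locomotion = "all")
    ),
    context = list(
      phases = list(context = c(0, 1)),
      behaviors = list(locomotion = "all")
    ),
    aggression = list(
      phases = list(aggression = c(0, 1)),
      behaviors = list(attack = "all", sniffing = "all", follow = "all",
                       orientation = "all", locomotion = "all")
    ),
    stop("unknown session kind: ", kind)
  )
}

# Draw non-overlapping bouts for one behavior inside [w0, w1).  The bout
# count is Poisson with mean rate * session_duration; at least `min_bouts`
# bouts are required (resampled up to `max_tries` times).
draw_bouts <- function(rate_hz, duration_s, window, mean_dur_s,
                       min_bouts = 2, max_tries = 200) {
  w0 <- window[1]; w1 <- window[2]
  for (try in seq_len(max_tries)) {
    n <- rpois(1, rate_hz * duration_s)
    if (n < min_bouts) next
    durs <- rexp(n, 1 / mean_dur_s)
    durs <- pmin(durs, (w1 - w0) / (2 * n))  # guarantee packability
    for (attempt in 1:50) {
      on_raw <- runif(n, w0, w1 - durs)
      o <- order(on_raw)
      onsets <- on_raw[o]
      offs <- onsets + durs[o]
      if ((n == 1 || all(offs[-n] <= onsets[-1])) && all(offs <= w1)) {
        return(cbind(onset = onsets, offset = offs))
      }
    }
  }
  stop(sprintf(
    "could not generate >= %d non-overlapping bouts (rate %.4g Hz) after %d tries",
    min_bouts, rate_hz, max_tries))
}

# Three-compartment occupancy as a semi-Markov walk home <-> corridor <-> far
# with exponential dwell times; resampled until every compartment is visited
# at least `min_visits` times.
draw_chamber_track <- function(duration_s, frame_rate_hz, min_visits = 2,
                               dwell_s = c(home = 25, corridor = 5, far = 25),
                               max_tries = 200) {
  n_frames <- round(duration_s * frame_rate_hz)
  for (try in seq_len(max_tries)) {
    t <- 0; state <- "home"
    states <- character(0); times <- numeric(0)
    while (t < duration_s) {
      states <- c(states, state); times <- c(times, t)
      t <- t + rexp(1, 1 / dwell_s[[state]])
      state <- switch(state,
        home = "corridor",
        far = "corridor",
        corridor = if (runif(1) < 0.5) "home" else "far")
    }
    frame_t <- (seq_len(n_frames) - 1) / frame_rate_hz
    labels <- states[findInterval(frame_t, times)]
    runs <- rle(labels)
    counts <- tapply(rep(1L, length(runs$values)), runs$values, sum)
    if (all(c("home", "corridor", "far") %in% names(counts)) &&
        all(counts[c("home", "corridor", "far")] >= min_visits)) {
      return(labels)
    }
  }
  stop("could not generate a chamber track visiting all compartments >= ",
       min_visits, " times")
}

#' Generate a synthetic ethogram (and chamber track) for one session
#'
#' Bouts per behavior follow a Poisson count process (mean
#' `bout_rate_hz * duration`) with exponential durations, placed without
#' overlap inside the behavior's phase window; every behavior relevant to
#' the session kind has at least two bouts (resampled until satisfied).
#' Context sessions additionally carry a three-compartment chamber track
#' that visits every compartment at least twice.
#'
#' @param cfg a [synthetic_config()].
#' @param session_kind one of `defeat`, `approach_avoidance`, `context`,
#'   `aggression`.
#' @param duration_s session length; defaults to the first matching entry of
#'   `cfg$session_plan`.
#' @param seed seed for this session (defaults to `cfg$seed`).
#' @param session_id session identifier.
#' @return A [behavior_track()] with `phases` (absolute seconds) and, for
#'   context sessions, a per-frame `chamber_track`.
#' @export
generate_ethogram <- function(cfg, session_kind, duration_s = NULL,
                              seed = cfg$seed, session_id = session_kind) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  plan <- session_behavior_plan(session_kind)
  if (is.null(duration_s)) {
    hit <- which(cfg$session_plan$kind == session_kind)
    if (!length(hit)) stop("no ", session_kind, " session in cfg$session_plan")
    duration_s <- cfg$session_plan$duration_s[hit[1]]
  }
  phases <- lapply(plan$phases, function(p) p * duration_s)
  rate_for <- function(b) {
    if (length(cfg$bout_rate_hz) > 1 && b %in% names(cfg$bout_rate_hz)) {
      cfg$bout_rate_hz[[b]]
    } else {
      cfg$bout_rate_hz[[1]]
    }
  }
  with_seed(seed, {
    iv <- do.call(rbind, lapply(names(plan$behaviors), function(b) {
      win <- if (identical(plan$behaviors[[b]], "all")) c(0, duration_s)
             else phases[[plan$behaviors[[b]]]]
      bouts <- draw_bouts(rate_for(b), duration_s, win, cfg$bout_duration_s)
      data.frame(onset_s = bouts[, "onset"], offset_s = bouts[, "offset"],
                 behavior = b)
    }))
    chambers <- if (session_kind == "context") {
      draw_chamber_track(duration_s, cfg$frame_rate_hz)
    }
    behavior_track(iv, duration_s, session_id = session_id,
                   session_kind = session_kind, phases = phases,
                   chamber_track = chambers)
  })
}

#' Ground truth: planted class and amplitude per neuron
#'
#' Each neuron receives exactly one primary responder class, sampled from
#' `cfg$class_fractions` (remainder `none`), and the configured response
#' amplitude.
#'
#' @param cfg a [synthetic_config()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return data.frame of class `GroundTruth` with columns `neuron`, `class`,
#'   `amplitude`, `remodeled`.
#' @export
generate_ground_truth <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  fr <- cfg$class_fractions
  probs <- c(fr, none = 1 - sum(fr))
  truth <- with_seed(seed, data.frame(
    neuron = paste0("n", seq_len(cfg$n_neurons)),
    class = sample(names(probs), cfg$n_neurons, replace = TRUE, prob = probs),
    amplitude = cfg$response_amplitude,
    remodeled = FALSE,
    stringsAsFactors = FALSE
  ))
  truth$amplitude[truth$class == "none"] <- 0
  class(truth) <- c("GroundTruth", "data.frame")
  truth
}

#' Resample tuning for a subset of neurons (across-session remodeling)
#'
#' For the second of two sessions of the same kind, exactly
#' `round(remodel_fraction * n_neurons)` neurons have their class resampled
#' from the configured mixture; the rest keep their tuning.  Remodeled
#' neurons are flagged.
#'
#' @param truth a `GroundTruth` from [generate_ground_truth()].
#' @param cfg a [synthetic_config()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return A new `GroundTruth` with updated `class` and `remodeled` flags.
#' @export
apply_remodeling <- function(truth, cfg, seed = cfg$seed) {
  stopifnot(inherits(truth, "GroundTruth"), inherits(cfg, "SyntheticConfig"))
  n <- nrow(truth)
  n_re <- round(cfg$remodel_fraction * n)
  out <- truth
  out$remodeled <- FALSE
  if (n_re == 0) return(out)
  fr <- cfg$class_fractions
  probs <- c(fr, none = 1 - sum(fr))
  with_seed(seed, {
    idx <- sample.int(n, n_re)
    out$class[idx] <- sample(names(probs), n_re, replace = TRUE, prob = probs)
  })
  out$remodeled[idx] <- TRUE
  out$amplitude <- ifelse(out$class == "none", 0, cfg$response_amplitude)
  out
}

#' Calcium-indicator impulse kernel
#'
#' Difference of exponentials `exp(-t/decay) - exp(-t/rise)` sampled at the
#' frame rate and normalized to unit sum, so a sustained drive plateaus at
#' the drive amplitude while brief bouts produce smaller, slower transients.
#'
#' @param frame_rate_hz frames per second.
#' @param rise_s,decay_s time constants in seconds (rise < decay).
#' @return Numeric kernel vector.
#' @export
gcamp_kernel <- function(frame_rate_hz, rise_s = 0.2, decay_s = 1.8) {
  if (rise_s >= decay_s) stop("rise must be smaller than decay")
  t <- seq(0, rise_s + 6 * decay_s, by = 1 / frame_rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / sum(k)
}

# Causal convolution of a drive with the kernel, truncated to trace length.
convolve_drive <- function(drive, kernel) {
  n <- length(drive)
  out <- convolve(c(drive, numeric(length(kernel))), rev(kernel), type = "open")
  out[seq_len(n)]
}

# Map a planted class to its (sign, drive indicator) for this session.
class_drive <- function(cls, ras, phases, chambers, n_frames,
                        frame_rate_hz) {
  ind_beh <- function(b) {
    if (!is.null(ras) && b %in% colnames(ras)) as.numeric(ras[, b])
    else numeric(n_frames)
  }
  ind_phase <- function(p) {
    if (!is.null(phases) && p %in% names(phases)) {
      as.numeric(frame_coverage(phases[[p]][1], phases[[p]][2],
                                frame_rate_hz, n_frames) > 0.5)
    } else numeric(n_frames)
  }
  ind_chamber <- function(ch) {
    if (!is.null(chambers)) as.numeric(chambers == ch) else numeric(n_frames)
  }
  switch(cls,
    "Social+" = list(sign = 1, drive = ind_phase("defeat")),
    "Social-" = list(sign = -1, drive = ind_phase("defeat")),
    "Defeat+" = list(sign = 1, drive = ind_beh("defeat")),
    "Defeat-" = list(sign = -1, drive = ind_beh("defeat")),
    "Assessment+" = list(sign = 1, drive = ind_beh("assessment")),
    "Assessment-" = list(sign = -1, drive = ind_beh("assessment")),
    "Flight+" = list(sign = 1, drive = ind_beh("flight")),
    "Flight-" = list(sign = -1, drive = ind_beh("flight")),
    "Sniff+" = list(sign = 1, drive = ind_beh("sniffing")),
    "Attack+" = list(sign = 1, drive = ind_beh("attack")),
    "Far+" = list(sign = 1, drive = ind_chamber("far")),
    "Home+" = list(sign = 1, drive = ind_chamber("home")),
    list(sign = 0, drive = numeric(n_frames))
  )
}

#' Generate dF/F traces for planted neurons
#'
#' Each neuron's signal is `amplitude * sign * (kernel %*% drive)` where the
#' drive is the frame indicator of the neuron's tuned phase, chamber or
#' behavior bouts (suppressed classes carry a negative sign), convolved with
#' the indicator kernel; independent Gaussian noise of SD `cfg$noise_sd` is
#' added.
#'
#' @param cfg a [synthetic_config()].
#' @param truth a `GroundTruth` with one row per neuron.
#' @param track a [behavior_track()] for the session (from
#'   [generate_ethogram()]).
#' @param seed seed for the noise draw (defaults to `cfg$seed`).
#' @return A [calcium_recording()].
#' @export
generate_traces <- function(cfg, truth, track, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SyntheticConfig"), inherits(truth, "GroundTruth"),
            inherits(track, "BehaviorTrack"))
  if (nrow(truth) != cfg$n_neurons) {
    stop("`truth` must have one row per configured neuron")
  }
  n_frames <- round(track$duration_s * cfg$frame_rate_hz)
  ras <- resample_to_calcium(track, cfg$frame_rate_hz, n_frames)
  if (!is.null(track$chamber_track) &&
      length(track$chamber_track) != n_frames) {
    stop("chamber track length does not match the session frame count")
  }
  kernel <- gcamp_kernel(cfg$frame_rate_hz, cfg$kernel_rise_s,
                         cfg$kernel_decay_s)
  signals <- matrix(0, nrow(truth), n_frames)
  drive_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class[i]
    if (cls == "none" || truth$amplitude[i] == 0) next
    key <- cls
    sig <- if (!is.null(drive_cache[[key]])) {
      drive_cache[[key]]
    } else {
      cd <- class_drive(cls, ras, track$phases, track$chamber_track,
                        n_frames, cfg$frame_rate_hz)
      s <- cd$sign * convolve_drive(cd$drive, kernel)
      drive_cache[[key]] <- s
      s
    }
    signals[i, ] <- truth$amplitude[i] * sig
  }
  noise <- with_seed(seed, matrix(rnorm(length(signals), sd = cfg$noise_sd),
                                  nrow(signals), ncol(signals)))
  traces <- signals + noise
  rownames(traces) <- truth$neuron
  calcium_recording(traces, cfg$frame_rate_hz,
                    session_id = track$session_id, roi_ids = truth$neuron)
}

#' Generate a complete synthetic experiment
#'
#' Runs the session plan of `cfg`: for each session an ethogram (and chamber
#' track where applicable) and traces are generated.  Repeated sessions of
#' the same kind share neurons; when `remodel_fraction > 0` the tuning of a
#' fixed-size subset is resampled for the repeat (see [apply_remodeling()]).
#'
#' @param cfg a [synthetic_config()].
#' @return List with elements `cfg`, `truth` (list of per-session
#'   `GroundTruth`) and `sessions` (list of `list(track, recording)`).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  base_truth <- generate_ground_truth(cfg, seed = child_seed(cfg$seed, 0))
  sessions <- vector("list", nrow(cfg$session_plan))
  truths <- vector("list", nrow(cfg$session_plan))
  seen <- character(0)
  for (i in seq_len(nrow(cfg$session_plan))) {
    kind <- cfg$session_plan$kind[i]
    dur <- cfg$session_plan$duration_s[i]
    id <- sprintf("%s_%d", kind, sum(seen == kind) + 1)
    seen <- c(seen, kind)
    truth_i <- if (sum(seen == kind) > 1 && cfg$remodel_fraction > 0) {
      apply_remodeling(base_truth, cfg, seed = child_seed(cfg$seed, 100 + i))
    } else {
      base_truth
    }
    track <- generate_ethogram(cfg, kind, duration_s = dur,
                               seed = child_seed(cfg$seed, i),
                               session_id = id)
    rec <- generate_traces(cfg, truth_i, track,
                           seed = child_seed(cfg$seed, 200 + i))
    sessions[[i]] <- list(track = track, recording = rec)
    truths[[i]] <- truth_i
    names(sessions)[i] <- names(truths)[i] <- id
  }
  list(cfg = cfg, truth = truths, sessions = sessions)
}

#' Render a synthetic endoscope movie from traces
#'
#' Each neuron is a 2-D Gaussian spot whose brightness follows
#' `1 + trace`, added to a smooth low-spatial-frequency background.  An
#' optional global integer translation is applied from a given frame onward
#' (planted drift for testing registration).  The ground-truth ROI mask is
#' returned alongside.
#'
#' @param cfg a [synthetic_config()].
#' @param rec a [calcium_recording()] whose traces drive the spots.
#' @param layout_seed seed for spot placement and background.
#' @param frame_dim `c(rows, cols)`, each <= 512.
#' @param spot_sigma Gaussian spot SD in pixels.
#' @param spot_gain peak spot brightness relative to background scale.
#' @param drift optional `list(shift = c(dr, dc), from = k)`: frames with
#'   index `>= k` (1-based) are translated by integer `(dr, dc)`.
#' @return List with `stack` (a [video_stack()]), `mask` (an [roi_mask()])
#'   and `centers` (matrix of spot centers, row/col).
#' @export
generate_movie <- function(cfg, rec, layout_seed = cfg$seed,
                           frame_dim = c(64, 64), spot_sigma = 2,
                           spot_gain = 30, drift = NULL) {
  stopifnot(inherits(rec, "CalciumRecording"))
  n <- nrow(rec$traces)
  if (n > 200) stop("at most 200 neurons can be rendered")
  if (any(frame_dim > 512) || any(frame_dim < 8)) {
    stop("`frame_dim` must lie in [8, 512] per side")
  }
  nr <- frame_dim[1]; nc <- frame_dim[2]
  margin <- ceiling(4 * spot_sigma)
  centers <- with_seed(layout_seed, {
    ok <- FALSE
    for (try in 1:200) {
      cand <- cbind(row = runif(n, margin, nr - margin),
                    col = runif(n, margin, nc - margin))
      if (n < 2 || min(dist(cand)) >= 4 * spot_sigma) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", n, " spots at least 4 sigma apart; ",
                  "use a larger frame or fewer neurons")
    cand
  })
  background <- with_seed(child_seed(layout_seed, 1), {
    raw <- matrix(runif(nr * nc), nr, nc)
    sm <- gaussian_blur(raw, sigma = min(nr, nc) / 6)
    100 + 40 * (sm - min(sm)) / max(max(sm) - min(sm), 1e-12)
  })
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  spots <- lapply(seq_len(n), function(i) {
    exp(-((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2) /
          (2 * spot_sigma^2))
  })
  n_frames <- ncol(rec$traces)
  frames <- array(0, dim = c(n_frames, nr, nc))
  static <- Reduce(`+`, lapply(spots, function(s) spot_gain * s))
  for (f in seq_len(n_frames)) {
    img <- background + static
    for (i in seq_len(n)) {
      img <- img + spot_gain * rec$traces[i, f] * spots[[i]]
    }
    frames[f, , ] <- pmax(img, 0)
  }
  if (!is.null(drift)) {
    for (f in seq_len(n_frames)) {
      if (f >= drift$from) {
        frames[f, , ] <- shift_frame(frames[f, , ], drift$shift[1],
                                     drift$shift[2])
      }
    }
  }
  label <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    within <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
      (2 * spot_sigma)^2
    label[within] <- i
  }
  list(stack = video_stack(frames, rec$frame_rate_hz),
       mask = roi_mask(label), centers = centers)
}
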
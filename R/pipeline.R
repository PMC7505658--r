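# Configuration-driven orchestration: run every enabled analysis stage on
# synthetic or file-based inputs, with a JSON manifest for provenance.

#' Run configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `inputs` (paths to
#' real data) must be given.
#'
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param inputs list of real-input paths: `traces` (vector of trace CSVs,
#'   see [read_traces()]), `ethograms` (vector of interval CSVs, parallel to
#'   `traces`), `durations_s` (session durations), optional `chambers`
#'   (per-frame label CSVs); or `NULL`.
#' @param stages character subset of
#'   `c("responders", "events", "ensemble", "overlap")`.
#' @param seed master seed for all stochastic stages.
#' @param out_dir output directory (created if missing).
#' @param n_shuffles shuffles for the responder null.
#' @return A `RunConfig` list.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL,
                       stages = c("responders", "events", "ensemble",
                                  "overlap"),
                       seed = 1, out_dir = tempfile("socialscope_run_"),
                       n_shuffles = 1000) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop("exactly one of `synthetic` or `inputs` must be supplied")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "SyntheticConfig"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(seed)) stop("a seed is required for reproducible runs")
  structure(list(synthetic = synthetic, inputs = inputs, stages = stages,
                 seed = seed, out_dir = out_dir, n_shuffles = n_shuffles),
            class = "RunConfig")
}

# Assemble the per-recording predicate list for a session.
session_predicates <- function(track, rec) {
  n_frames <- ncol(rec$traces)
  rate <- rec$frame_rate_hz
  preds <- list()
  behaviors <- intersect(unique(track$intervals$behavior),
                         c("defeat", "assessment", "attack", "sniffing",
                           "upright", "follow", "orientation"))
  for (b in behaviors) {
    preds[[b]] <- behavior_predicate(track, b, rate, n_frames)
  }
  if (any(track$intervals$behavior == "flight")) {
    preds[["flight"]] <- flight_predicate(track, rate, n_frames)
  }
  if (!is.null(track$phases) &&
      all(c("defeat", "avoidance") %in% names(track$phases))) {
    preds[["social_phase"]] <- phase_predicate(rate, n_frames,
                                               track$phases$defeat,
                                               track$phases$avoidance)
  }
  if (!is.null(track$chamber_track)) {
    preds[["far_chamber"]] <- chamber_predicate(track$chamber_track, "far")
    preds[["home_chamber"]] <- chamber_predicate(track$chamber_track, "home")
  }
  preds
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic (or file)
#' inputs, writes all result tables plus a JSON manifest (stage status,
#' seed, input digests) to `cfg$out_dir`.  Identical configuration and seed
#' give identical outputs.
#'
#' @param cfg a [run_config()].
#' @return The manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("socialscope")),
                   seed = cfg$seed, stages = list(), outputs = character(0))
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  note_stage <- function(name, status, detail = NULL) {
    manifest$stages[[name]] <<- list(status = status, detail = detail)
  }
  emit <- function(writer, obj, fname) {
    path <- file.path(cfg$out_dir, fname)
    writer(obj, path)
    manifest$outputs <<- union(manifest$outputs, fname)
    path
  }

  # --- inputs ---------------------------------------------------------
  sessions <- list(); truths <- NULL
  if (!is.null(cfg$synthetic)) {
    logf("generating synthetic experiment (seed %s)", format(cfg$seed))
    syn_cfg <- cfg$synthetic
    syn_cfg$seed <- cfg$seed
    exp <- generate_experiment(syn_cfg)
    sessions <- exp$sessions
    truths <- exp$truth
    for (id in names(sessions)) {
      emit(write_ethogram, sessions[[id]]$track,
           sprintf("ethogram_%s.csv", id))
      emit(write_traces, sessions[[id]]$recording,
           sprintf("traces_%s.csv", id))
      if (!is.null(sessions[[id]]$track$chamber_track)) {
        emit(write_chamber_track, sessions[[id]]$track$chamber_track,
             sprintf("chambers_%s.csv", id))
      }
      emit(write_ground_truth, truths[[id]],
           sprintf("ground_truth_%s.json", id))
    }
    note_stage("inputs", "ok", sprintf("%d synthetic session(s)",
                                       length(sessions)))
  } else {
    inp <- cfg$inputs
    for (i in seq_along(inp$traces)) {
      missing <- !file.exists(c(inp$traces[i], inp$ethograms[i]))
      if (any(missing)) {
        stop("missing input file: ",
             c(inp$traces[i], inp$ethograms[i])[missing][1])
      }
      rec <- read_traces(inp$traces[i])
      track <- read_ethogram(inp$ethograms[i], inp$durations_s[i],
                             session_id = rec$session_id)
      if (!is.null(inp$chambers) && !is.na(inp$chambers[i])) {
        track$chamber_track <- read_chamber_track(inp$chambers[i])
      }
      sessions[[rec$session_id]] <- list(track = track, recording = rec)
    }
    note_stage("inputs", "ok", sprintf("%d session(s) read", length(sessions)))
  }

  recs <- lapply(sessions, `[[`, "recording")
  preds <- lapply(sessions, function(s) session_predicates(s$track,
                                                           s$recording))

  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    logf("stage %s ...", name)
    tryCatch({
      fn()
      note_stage(name, "ok")
    }, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      note_stage(name, "failed", conditionMessage(e))
    })
    invisible(NULL)
  }

  table_env <- new.env(parent = emptyenv())
  run_stage("responders", function() {
    tab <- classify_all(recs, preds, n_shuffles = cfg$n_shuffles,
                        seed = child_seed(cfg$seed, 9000))
    table_env$responders <- tab
    emit(write_responder_table, tab, "responders.csv")
  })

  run_stage("events", function() {
    rows <- list()
    for (id in names(sessions)) {
      track <- sessions[[id]]$track
      z <- zscore_recording(sessions[[id]]$recording)
      for (b in intersect(unique(track$intervals$behavior),
                          c("defeat", "assessment", "attack", "sniffing"))) {
        ev <- track$intervals$onset_s[track$intervals$behavior == b]
        res <- tryCatch(
          peri_event_summary(z, ev, behavior = b),
          error = function(e) NULL)
        if (!is.null(res)) {
          res$session <- id
          rows[[paste(id, b)]] <- res
        }
      }
    }
    if (!length(rows)) stop("no session had usable events")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    emit(function(o, p) utils::write.csv(o, p, row.names = FALSE), out,
         "peri_event_summary.csv")
  })

  run_stage("ensemble", function() {
    results <- list()
    kinds <- vapply(sessions, function(s) s$track$session_kind, "")
    # context: chamber-labeled LDA and Home-Far cluster distance
    for (id in names(sessions)[kinds == "context"]) {
      s <- sessions[[id]]
      ds <- build_frame_dataset(list(s$recording),
                                list(s$track$chamber_track))
      emb <- fit_lda(ds)
      results[[paste0("chamber_distance_", id)]] <-
        cluster_distance(emb, "home", others = "far")
    }
    # repeated like sessions: remodeling KS on close-contact frames
    for (kind in unique(kinds[duplicated(kinds)])) {
      ids <- names(sessions)[kinds == kind][1:2]
      restrict <- lapply(ids, function(id) {
        s <- sessions[[id]]
        close_contact_frames(s$track, s$recording$frame_rate_hz,
                             ncol(s$recording$traces))
      })
      if (any(vapply(restrict, length, 0L) < 8)) next
      ds <- build_frame_dataset(lapply(sessions[ids], `[[`, "recording"),
                                labels = as.list(ids), restrict = restrict)
      ks <- session_separation_ks(ds)
      results[[paste0("session_ks_", kind)]] <- ks$p
      dec <- decode_sessions(ds, seed = child_seed(cfg$seed, 9100))
      results[[paste0("decode_accuracy_", kind)]] <- dec$accuracy
    }
    if (!length(results)) stop("no session combination supports ensemble analysis")
    emit(function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                             digits = NA),
         results, "ensemble_summary.json")
  })

  run_stage("overlap", function() {
    tab <- table_env$responders
    if (is.null(tab)) stop("overlap requires the responders stage")
    pred_pairs <- list(c("defeat", "assessment"), c("defeat", "sniffing"),
                       c("attack", "sniffing"))
    results <- list()
    for (pp in pred_pairs) {
      if (!all(pp %in% tab$predicate)) next
      sa <- responder_set(tab, pp[1], "+")
      sb <- responder_set(tab, pp[2], "+")
      uni <- tryCatch(common_universe(list(sa, sb)), error = function(e) NULL)
      if (is.null(uni)) next
      ov <- overlap_fisher(sa, sb, uni)
      results[[paste(pp, collapse = "_x_")]] <-
        ov[c("n_universe", "n_a", "n_b", "n_overlap", "fraction",
             "chance", "p")]
    }
    if (!length(results)) stop("no predicate pair had responders to compare")
    emit(function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                             digits = NA),
         results, "overlap_summary.json")
  })

  manifest$input_digests <- as.list(tools::md5sum(
    file.path(cfg$out_dir, manifest$outputs)))
  names(manifest$input_digests) <- manifest$outputs
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logf("done; %d output file(s)", length(manifest$outputs))
  invisible(manifest)
}

#' Write a small synthetic fixture bundle
#'
#' One defeat + context + aggression experiment with ground truth, written
#' as plain-text files; used by the test suite and documentation examples.
#'
#' @param seed master seed.
#' @param dir output directory.
#' @return Named md5 digests of the written files (invisibly).
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("socialscope_fixtures_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- synthetic_config(
    n_neurons = 30,
    session_plan = data.frame(
      kind = c("defeat", "context", "aggression"),
      duration_s = c(300, 240, 240)),
    bout_rate_hz = 0.03,
    seed = seed)
  exp <- generate_experiment(cfg)
  for (id in names(exp$sessions)) {
    write_ethogram(exp$sessions[[id]]$track,
                   file.path(dir, sprintf("ethogram_%s.csv", id)))
    write_traces(exp$sessions[[id]]$recording,
                 file.path(dir, sprintf("traces_%s.csv", id)))
    if (!is.null(exp$sessions[[id]]$track$chamber_track)) {
      write_chamber_track(exp$sessions[[id]]$track$chamber_track,
                          file.path(dir, sprintf("chambers_%s.csv", id)))
    }
    write_ground_truth(exp$truth[[id]],
                       file.path(dir, sprintf("ground_truth_%s.json", id)))
  }
  files <- list.files(dir, full.names = TRUE)
  invisible(stats::setNames(tools::md5sum(files), basename(files)))
}
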
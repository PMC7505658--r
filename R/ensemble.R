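#' Build a labeled frame dataset from one or more recordings
#'
#' Each recording is z-scored separately ([zscore_recording()]); only
#' neurons present in every recording are kept; frames are stacked as rows
#' with their labels.  An optional per-recording frame restriction (e.g.
#' [close_contact_frames()]) is applied.
#'
#' @param recordings list of [calcium_recording()]s.
#' @param labels either one character/factor vector per recording (list,
#'   length = frames of that recording) or a single label per recording
#'   (e.g. the session id), recycled over its frames.
#' @param restrict optional list of frame-index vectors (1-based), one per
#'   recording; `NULL` keeps all frames.
#' @return A `FrameDataset`: list with `x` (matrix frame x neuron),
#'   `labels` (factor), `recording` (factor of source recording ids).
#' @export
build_frame_dataset <- function(recordings, labels, restrict = NULL) {
  if (!length(recordings)) stop("`recordings` must be non-empty")
  if (length(labels) != length(recordings)) {
    stop("`labels` must have one element per recording")
  }
  zs <- lapply(recordings, zscore_recording)
  common <- Reduce(intersect, lapply(zs, function(r) rownames(r$traces)))
  if (!length(common)) stop("no neurons common to all recordings")
  rates <- vapply(recordings, `[[`, 0, "frame_rate_hz")
  xs <- list(); ls <- list(); rs <- list(); fs <- list()
  for (i in seq_along(zs)) {
    xi <- t(zs[[i]]$traces[common, , drop = FALSE])  # frame x neuron
    li <- labels[[i]]
    if (length(li) == 1) li <- rep(li, nrow(xi))
    if (length(li) != nrow(xi)) {
      stop("labels for recording ", i, " do not match its frame count")
    }
    fi <- seq_len(nrow(xi))
    if (!is.null(restrict)) {
      idx <- restrict[[i]]
      if (!length(idx)) stop("restriction for recording ", i, " is empty")
      xi <- xi[idx, , drop = FALSE]
      li <- li[idx]
      fi <- fi[idx]
    }
    xs[[i]] <- xi
    ls[[i]] <- as.character(li)
    rs[[i]] <- rep(zs[[i]]$session_id, nrow(xi))
    fs[[i]] <- fi
  }
  structure(list(x = do.call(rbind, xs), labels = factor(unlist(ls)),
                 recording = factor(unlist(rs)), neurons = common,
                 frame_idx = unlist(fs),
                 frame_rate_hz = if (length(unique(rates)) == 1) rates[1]
                                 else NA_real_),
            class = "FrameDataset")
}

#' @export
print.FrameDataset <- function(x, ...) {
  cat(sprintf("<FrameDataset> %d frames x %d neurons, labels: %s\n",
              nrow(x$x), ncol(x$x),
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' Fisher linear discriminant analysis of frame vectors
#'
#' Solves the Fisher criterion with the pooled within-class scatter
#' (pseudo-inverse when singular) via symmetric whitening, and projects the
#' frames onto the leading `n_labels - 1` discriminants (further capped by
#' the rank of the between-class scatter).
#'
#' @param ds a `FrameDataset`; at least 2 labels and more frames than
#'   labels.
#' @param x,y alternatively, a frame-by-feature matrix and label vector.
#' @return An `EnsembleEmbedding`: list with `projections`
#'   (frame x discriminant), `labels`, `scalings`, `center`,
#'   `eigenvalues`.
#' @export
fit_lda <- function(ds = NULL, x = NULL, y = NULL) {
  if (!is.null(ds)) {
    stopifnot(inherits(ds, "FrameDataset"))
    x <- ds$x; y <- ds$labels
  }
  y <- droplevels(factor(y))
  k <- nlevels(y)
  if (k < 2) stop("at least 2 distinct labels are required")
  if (nrow(x) <= k) stop("need more frames than labels")
  if (any(table(y) < 2)) stop("every label needs at least 2 frames")
  p <- ncol(x)
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (lev in levels(y)) {
    xi <- xc[y == lev, , drop = FALSE]
    mi <- colMeans(xi)
    di <- sweep(xi, 2, mi)
    sw <- sw + crossprod(di)
    sb <- sb + nrow(xi) * tcrossprod(mi)
  }
  sw <- sw / (nrow(x) - k)
  # symmetric whitening of sw (pseudo-inverse square root)
  es <- eigen(sw, symmetric = TRUE)
  tol <- max(es$values) * 1e-10
  keep <- es$values > tol
  w_half <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  m <- crossprod(w_half, sb %*% w_half)
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)
  n_disc <- min(k - 1, sum(em$values > max(em$values[1], 1e-12) * 1e-9))
  n_disc <- max(n_disc, 1L)
  scalings <- w_half %*% em$vectors[, seq_len(n_disc), drop = FALSE]
  proj <- xc %*% scalings
  colnames(proj) <- paste0("LD", seq_len(n_disc))
  structure(list(projections = proj, labels = y, scalings = scalings,
                 center = center, eigenvalues = em$values[seq_len(n_disc)]),
            class = "EnsembleEmbedding")
}

#' Project new frames onto a fitted embedding
#'
#' @param emb an `EnsembleEmbedding` from [fit_lda()].
#' @param x matrix of frames (frame x neuron) in the same feature space.
#' @return Matrix of projections (frame x discriminant).
#' @export
project_frames <- function(emb, x) {
  stopifnot(inherits(emb, "EnsembleEmbedding"))
  sweep(x, 2, emb$center) %*% emb$scalings
}

# Mean pairwise Euclidean distance between rows of a and rows of b,
# computed in blocks to bound memory.
mean_cross_distance <- function(a, b, block = 512L) {
  total <- 0; count <- 0
  nb2 <- rowSums(b^2)
  for (i0 in seq(1, nrow(a), by = block)) {
    i1 <- min(i0 + block - 1, nrow(a))
    ai <- a[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(ai^2), nb2, "+") - 2 * tcrossprod(ai, b)
    total <- total + sum(sqrt(pmax(d2, 0)))
    count <- count + length(d2)
  }
  total / count
}

#' Average inter-cluster distance in the projected space
#'
#' Mean Euclidean distance between every frame of the named cluster and
#' every frame of the other clusters, in the full discriminant space.
#'
#' @param emb an `EnsembleEmbedding` from [fit_lda()].
#' @param cluster_label label of the reference cluster.
#' @param others optional labels to compare against (default: all other
#'   labels).
#' @return Mean pairwise distance (numeric scalar).
#' @export
cluster_distance <- function(emb, cluster_label, others = NULL) {
  stopifnot(inherits(emb, "EnsembleEmbedding"))
  if (nlevels(emb$labels) < 2) stop("at least 2 clusters are required")
  if (!cluster_label %in% levels(emb$labels)) {
    stop("unknown cluster label: ", cluster_label)
  }
  sel_other <- if (is.null(others)) emb$labels != cluster_label else
    emb$labels %in% others
  a <- emb$projections[emb$labels == cluster_label, , drop = FALSE]
  b <- emb$projections[sel_other, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("empty cluster in distance computation")
  mean_cross_distance(a, b)
}

#' Paired comparison of cluster separation across conditions
#'
#' Two-sided paired t-test of per-subject cluster distances (e.g. Home-Far
#' LDA distance before vs after defeat).  Zero-variance differences are
#' flagged: identical samples give `t = 0, p = 1`; a constant non-zero
#' difference gives `p = 0` with `zero_variance = TRUE`.
#'
#' @param pre,post equal-length numeric vectors of per-subject distances
#'   (n >= 3).
#' @return List with `t`, `df`, `p`, `mean_diff`, `zero_variance`.
#' @export
compare_separation <- function(pre, post) {
  if (length(pre) != length(post)) stop("`pre` and `post` must be paired")
  n <- length(pre)
  if (n < 3) stop("at least 3 paired subjects are required")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0,
                  zero_variance = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d), zero_variance = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), zero_variance = FALSE)
}

# Contiguous runs of restricted frame indices within each session: the
# bout-level unit used for holdout splitting.
frame_blocks <- function(frame_idx) {
  cumsum(c(1L, as.integer(diff(frame_idx) != 1L)))
}

#' Session-remodeling test on the first linear discriminant
#'
#' Quantifies whether ensemble activity occupies different regions across
#' two sessions of the same kind: an LDA is fitted to discriminate the two
#' session labels and a two-sample Kolmogorov-Smirnov test is applied to
#' the LD1 projections of the two sessions' frames.
#'
#' A frame-level KS with the discriminant fitted on all frames is
#' anti-conservative for two reasons: the discriminant is chosen to
#' separate the very frames being tested, and frames within a behavior bout
#' are serially dependent, so the nominal frame count overstates the
#' information content.  The default `holdout = "blocks"` therefore splits
#' each session's frames into contiguous blocks (bouts of the restricted
#' frame set), fits the discriminant on alternate blocks, and applies the
#' KS test to the held-out blocks thinned to at most one frame per
#' `thin_s` seconds.  Because bouts are exchangeable draws within a
#' session, held-out blocks of the two sessions are identically
#' distributed under the no-remodeling null, while a genuine tuning change
#' persists across blocks and is detected.  `holdout = "none"` gives the
#' descriptive in-sample variant (all frames, no thinning), whose p-value
#' should be read as a separation index rather than a calibrated test.
#'
#' When the sessions' behavior composition itself varies (bout counts are
#' random), a persistent composition difference masquerades as remodeling.
#' Supplying per-frame `strata` (e.g. [behavior_signature()] labels)
#' balances the held-out frame sets: within every stratum both sessions
#' contribute equally many test frames, so only tuning differences remain.
#'
#' @param ds a `FrameDataset` whose labels are the two session ids.
#' @param holdout `"blocks"` (default) or `"none"`.
#' @param thin_s minimum spacing of test frames in seconds (default 1;
#'   only used by `"blocks"`).
#' @param strata optional per-frame stratum labels (parallel to the rows of
#'   `ds$x`); held-out frames are balanced across sessions within stratum.
#' @return List with `statistic` (KS D), `p`, `n1`, `n2`, `holdout`.
#' @export
session_separation_ks <- function(ds, holdout = c("blocks", "none"),
                                  thin_s = 1, strata = NULL) {
  stopifnot(inherits(ds, "FrameDataset"))
  holdout <- match.arg(holdout)
  y <- droplevels(ds$labels)
  if (nlevels(y) != 2) stop("exactly two session labels are required")
  if (any(table(y) < 4)) stop("each session needs at least 4 frames")
  if (!is.null(strata) && length(strata) != length(y)) {
    stop("`strata` must have one entry per frame of the dataset")
  }
  if (holdout == "blocks") {
    thin <- max(1L, round(thin_s * (ds$frame_rate_hz %||% 1)))
    train <- logical(length(y))
    test_keep <- logical(length(y))
    for (lev in levels(y)) {
      idx <- which(y == lev)
      blk <- frame_blocks(ds$frame_idx[idx])
      if (max(blk) < 2) {
        stop("session ", lev, " has fewer than 2 frame blocks; ",
             "block holdout is not possible")
      }
      train[idx[blk %% 2L == 1L]] <- TRUE
      for (b in unique(blk[blk %% 2L == 0L])) {
        sub <- idx[blk == b]
        test_keep[sub[seq(1, length(sub), by = thin)]] <- TRUE
      }
    }
    if (!is.null(strata)) {
      # refine strata by coarse within-block position (matches the bout
      # duration mix / kernel ramp state) and by the gap to the previous
      # block (matches how much kernel tail of the preceding bout remains)
      pos_bucket <- integer(length(y))
      gap_bucket <- integer(length(y))
      for (lev in levels(y)) {
        idx <- which(y == lev)
        blk <- frame_blocks(ds$frame_idx[idx])
        pos <- stats::ave(seq_along(idx), blk, FUN = seq_along) - 1
        pos_bucket[idx] <- pmin(pos %/% max(1L, 2L * thin), 2L)
        starts <- ds$frame_idx[idx][!duplicated(blk)]
        ends <- ds$frame_idx[idx][rev(!duplicated(rev(blk)))]
        gaps <- c(Inf, starts[-1] - ends[-length(ends)])
        gap_bucket[idx] <- findInterval(gaps[blk], c(0, 2, 5) *
                                          (ds$frame_rate_hz %||% 1))
      }
      balance <- function(str) {
        balanced <- logical(length(y))
        lev1 <- levels(y)[1]; lev2 <- levels(y)[2]
        for (s in unique(str[test_keep])) {
          i1 <- which(test_keep & str == s & y == lev1)
          i2 <- which(test_keep & str == s & y == lev2)
          m <- min(length(i1), length(i2))
          if (m == 0) next
          pick <- function(ix) ix[round(seq(1, length(ix), length.out = m))]
          balanced[pick(i1)] <- TRUE
          balanced[pick(i2)] <- TRUE
        }
        balanced
      }
      # graded fallback: full strata, then signature-only, then unbalanced
      # (possible when the sessions' block signatures barely overlap).
      # At least 8 balanced frames per session are required: below that the
      # discrete KS null cannot resolve small p-values even under complete
      # separation.
      candidates <- list(paste(strata, pos_bucket, gap_bucket, sep = "|"),
                         strata)
      for (str in candidates) {
        balanced <- balance(str)
        if (sum(balanced & y == levels(y)[1]) >= 8) {
          test_keep <- balanced
          break
        }
      }
    }
    emb <- fit_lda(x = ds$x[train, , drop = FALSE], y = y[train])
    proj <- project_frames(emb, ds$x[test_keep, , drop = FALSE])[, 1]
    grp <- y[test_keep]
  } else {
    emb <- fit_lda(x = ds$x, y = y)
    proj <- emb$projections[, 1]
    grp <- y
  }
  ks <- suppressWarnings(stats::ks.test(proj[grp == levels(y)[1]],
                                        proj[grp == levels(y)[2]]))
  list(statistic = unname(ks$statistic), p = ks$p.value,
       n1 = sum(grp == levels(y)[1]), n2 = sum(grp == levels(y)[2]),
       holdout = holdout)
}

#' Cross-validated session decoding accuracy
#'
#' Stratified k-fold cross-validation of an LDA classifier on session
#' labels.
#'
#' @param ds a `FrameDataset` with >= 2 session labels; every label needs
#'   at least `folds` frames.
#' @param folds number of folds (default 5).
#' @param seed seed controlling the fold assignment.
#' @return List with `accuracy`, `folds`, `per_fold` accuracies.
#' @export
decode_sessions <- function(ds, folds = 5, seed = NULL) {
  stopifnot(inherits(ds, "FrameDataset"))
  y <- droplevels(ds$labels)
  if (nlevels(y) < 2) stop("at least 2 session labels are required")
  if (any(table(y) < folds)) {
    stop("every session needs at least `folds` frames")
  }
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  per_fold <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- MASS::lda(ds$x[tr, , drop = FALSE], grouping = y[tr])
    pred <- stats::predict(fit, ds$x[!tr, , drop = FALSE])$class
    mean(pred == y[!tr])
  }, 0)
  list(accuracy = mean(per_fold), folds = folds, per_fold = per_fold)
}
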
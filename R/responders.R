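#' Area under the ROC curve for one neuron and one predicate
#'
#' Discriminability of positive from negative frames by thresholding the
#' trace, computed via the rank-sum identity
#' `auROC = (R_pos - n_pos(n_pos+1)/2) / (n_pos * n_neg)` with average
#' ranks, so ties contribute one half.  Excluded frames are dropped.
#'
#' @param trace numeric per-frame values for one neuron.
#' @param labels a `PredicateLabels` object (or a factor/character vector of
#'   `positive`/`negative`/`excluded` states) of the same length.
#' @return auROC in `[0, 1]`, or `NA` when either class is empty
#'   (not evaluable).
#' @export
compute_auroc <- function(trace, labels) {
  state <- if (inherits(labels, "PredicateLabels")) labels$state else
    factor(labels, levels = c("positive", "negative", "excluded"))
  if (length(trace) != length(state)) {
    stop("trace and labels have different lengths")
  }
  keep <- state != "excluded"
  x <- trace[keep]
  pos <- state[keep] == "positive"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(x)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Shuffled-label null distribution of the auROC
#'
#' Permutes the positive/negative assignment over the included frames
#' `n_shuffles` times and returns the mean and SD of the resulting auROC
#' distribution.
#'
#' @inheritParams compute_auroc
#' @param n_shuffles number of label permutations (default 1000).
#' @param seed optional seed for reproducibility.
#' @return List with `null_mean`, `null_sd`, `n_shuffles` and a
#'   `low_shuffles` flag when `n_shuffles < 100`.
#' @export
shuffle_null <- function(trace, labels, n_shuffles = 1000, seed = NULL) {
  state <- if (inherits(labels, "PredicateLabels")) labels$state else
    factor(labels, levels = c("positive", "negative", "excluded"))
  keep <- state != "excluded"
  x <- trace[keep]
  np <- sum(state[keep] == "positive")
  nn <- sum(state[keep] == "negative")
  if (np == 0 || nn == 0) stop("labels are not evaluable (single class)")
  low <- n_shuffles < 100
  if (low) warning("fewer than 100 shuffles; null estimates will be noisy")
  r <- rank(x)
  n <- length(r)
  aurocs <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    (sum(r[sample.int(n, np)]) - np * (np + 1) / 2) / (np * nn)
  }, 0))
  list(null_mean = mean(aurocs), null_sd = stats::sd(aurocs),
       n_shuffles = as.integer(n_shuffles), low_shuffles = low)
}

# Fast shared-permutation null for a population: one set of `n_shuffles`
# label permutations applied to every neuron's rank vector (each neuron
# still receives a valid permutation null; only the Monte-Carlo draws are
# shared).  `ranks` is neurons x included-frames.
shuffle_null_matrix <- function(ranks, np, n_shuffles = 1000, seed = NULL) {
  n <- ncol(ranks)
  nn <- n - np
  sel <- with_seed(seed, vapply(seq_len(n_shuffles),
                                function(i) sample.int(n, np),
                                integer(np)))
  ind <- matrix(0, n, n_shuffles)
  ind[cbind(as.vector(sel), rep(seq_len(n_shuffles), each = np))] <- 1
  sums <- ranks %*% ind                     # neurons x shuffles
  aurocs <- (sums - np * (np + 1) / 2) / (np * nn)
  list(null_mean = rowMeans(aurocs),
       null_sd = apply(aurocs, 1, stats::sd))
}

#' Dual-criterion responder classification
#'
#' A neuron is `+` when its auROC exceeds `hi` \emph{and} lies at least
#' `k` null SDs from the null mean; `-` when the auROC is below `lo` under
#' the same SD rule; otherwise `none`.  A zero null SD passes the SD rule
#' whenever the auROC differs from the null mean.
#'
#' @param auroc observed (day-averaged) auROC; `NA` gives `not_evaluable`.
#' @param null_mean,null_sd shuffled-label null moments.
#' @param hi,lo auROC cutoffs (defaults 0.65 / 0.35).
#' @param k SD-rule multiplier (default 3).
#' @return One of `"+"`, `"-"`, `"none"`, `"not_evaluable"`.
#' @export
classify_neuron <- function(auroc, null_mean, null_sd, hi = 0.65, lo = 0.35,
                            k = 3) {
  if (is.na(auroc)) return("not_evaluable")
  if (null_sd < 0) stop("`null_sd` must be >= 0")
  sd_ok <- if (null_sd == 0) auroc != null_mean else
    abs(auroc - null_mean) >= k * null_sd
  if (auroc > hi && sd_ok) return("+")
  if (auroc < lo && sd_ok) return("-")
  "none"
}

#' Classify all neurons across recordings and predicates
#'
#' For each neuron and predicate, recordings with fewer than `min_instances`
#' behavior instances (or an unevaluable label set) are dropped; the auROC
#' is averaged across the remaining recordings and classified against the
#' pooled null (mean of per-recording null means; per-recording null SDs
#' pooled by root-mean-square).  Neurons with no eligible recording are
#' `not_evaluable`.
#'
#' @param recordings list of [calcium_recording()]s with consistent neuron
#'   ids (rownames).
#' @param predicates list parallel to `recordings`; each element a named
#'   list of `PredicateLabels` for that recording.
#' @param min_instances minimum behavior instances per recording
#'   (default 2).
#' @param n_shuffles shuffles for the null (default 1000).
#' @param seed seed for the permutation null.
#' @param hi,lo,k classification parameters, see [classify_neuron()].
#' @return A `ResponderTable`: data.frame with columns `neuron`,
#'   `predicate`, `auroc`, `null_mean`, `null_sd`, `n_recordings`, `class`.
#' @export
classify_all <- function(recordings, predicates, min_instances = 2,
                         n_shuffles = 1000, seed = NULL, hi = 0.65,
                         lo = 0.35, k = 3) {
  if (!length(recordings)) stop("`recordings` must be a non-empty list")
  if (length(predicates) != length(recordings)) {
    stop("`predicates` must parallel `recordings`")
  }
  neurons <- Reduce(union, lapply(recordings, function(r) rownames(r$traces)))
  pred_names <- Reduce(union, lapply(predicates, names))
  rows <- list()
  for (p in pred_names) {
    # accumulators: per neuron, auROCs and null moments across recordings
    acc_auroc <- matrix(NA_real_, length(neurons), length(recordings),
                        dimnames = list(neurons, NULL))
    acc_nm <- acc_auroc; acc_ns <- acc_auroc
    for (ri in seq_along(recordings)) {
      lab <- predicates[[ri]][[p]]
      if (is.null(lab)) next
      if (lab$n_instances < min_instances || !lab$evaluable) next
      rec <- recordings[[ri]]
      state <- lab$state
      keep <- state != "excluded"
      pos <- state[keep] == "positive"
      np <- sum(pos); nn <- sum(!pos)
      if (np == 0 || nn == 0) next
      tr <- rec$traces[, keep, drop = FALSE]
      ranks <- t(apply(tr, 1, rank))
      obs <- (ranks[, pos, drop = FALSE] |> rowSums()) -
        np * (np + 1) / 2
      obs <- obs / (np * nn)
      null <- shuffle_null_matrix(ranks, np, n_shuffles,
                                  seed = child_seed(seed, ri * 37 +
                                                      match(p, pred_names)))
      ids <- rownames(rec$traces)
      acc_auroc[ids, ri] <- obs
      acc_nm[ids, ri] <- null$null_mean
      acc_ns[ids, ri] <- null$null_sd
    }
    n_rec <- rowSums(!is.na(acc_auroc))
    auroc <- rowMeans(acc_auroc, na.rm = TRUE)
    null_mean <- rowMeans(acc_nm, na.rm = TRUE)
    null_sd <- sqrt(rowMeans(acc_ns^2, na.rm = TRUE))
    cls <- vapply(seq_along(neurons), function(i) {
      if (n_rec[i] == 0) "not_evaluable" else
        classify_neuron(auroc[i], null_mean[i], null_sd[i], hi, lo, k)
    }, "")
    rows[[p]] <- data.frame(
      neuron = neurons, predicate = p,
      auroc = ifelse(n_rec > 0, auroc, NA_real_),
      null_mean = ifelse(n_rec > 0, null_mean, NA_real_),
      null_sd = ifelse(n_rec > 0, null_sd, NA_real_),
      n_recordings = n_rec, class = cls, row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ResponderTable", "data.frame")
  out
}

#' Responder set for one predicate and sign
#'
#' @param table a `ResponderTable` from [classify_all()].
#' @param predicate predicate name.
#' @param sign `"+"` or `"-"`.
#' @return List with `members` (neuron ids with the given class) and
#'   `universe` (neuron ids evaluable for the predicate), of class
#'   `ResponderSet`.
#' @export
responder_set <- function(table, predicate, sign = "+") {
  stopifnot(inherits(table, "ResponderTable"))
  sub <- table[table$predicate == predicate, , drop = FALSE]
  if (!nrow(sub)) stop("predicate not present in table: ", predicate)
  universe <- sub$neuron[sub$class != "not_evaluable"]
  members <- sub$neuron[sub$class == sign]
  structure(list(predicate = predicate, sign = sign,
                 members = members, universe = universe),
            class = "ResponderSet")
}
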
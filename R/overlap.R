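#' Common universe of neurons across responder sets
#'
#' Overlap statistics include only neurons recorded (and evaluable) across
#' all compared predicates, so each comparison has its own universe.
#'
#' @param sets list of `ResponderSet`s (see [responder_set()]) or plain
#'   lists with a `universe` element.
#' @return Character vector: intersection of the universes.
#' @export
common_universe <- function(sets) {
  if (length(sets) < 2) stop("at least 2 sets are required")
  uni <- Reduce(intersect, lapply(sets, function(s) s$universe))
  if (!length(uni)) stop("the universes have an empty intersection")
  uni
}

#' Chance overlap as a product of responder proportions
#'
#' The expected fraction of neurons responsive to all compared predicates
#' under independence: the product of the per-predicate responsive
#' proportions.
#'
#' @param proportions numeric vector of fractions in `[0, 1]` (e.g.
#'   `c(100/246, 93/343)`).
#' @return Product of the proportions.
#' @export
chance_overlap <- function(proportions) {
  if (any(proportions < 0 | proportions > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  prod(proportions)
}

#' Fisher's exact test for responder-set overlap
#'
#' Builds the 2x2 table `{in A / not in A} x {in B / not in B}` over the
#' common universe and applies the classic two-sided Fisher exact test
#' (sum of hypergeometric probabilities of tables at most as probable as
#' the observed one).  The observed overlap fraction is reported relative
#' to `|A|` (the conditional convention, e.g. "81/152 = 53%"), while the
#' chance fraction is the unconditional product of proportions; the two
#' are deliberately on different scales.
#'
#' @param set_a,set_b `ResponderSet`s or character vectors of neuron ids.
#' @param universe character vector of neuron ids containing both sets;
#'   defaults to [common_universe()] of the two sets.
#' @param chance optional externally supplied chance fraction (e.g. the
#'   product of headline proportions); default: product of the in-universe
#'   proportions.
#' @return An `OverlapResult`: list with `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `fraction` (`n_overlap / n_a`), `chance`, `p`, `table`.
#' @export
overlap_fisher <- function(set_a, set_b, universe = NULL, chance = NULL) {
  a <- if (inherits(set_a, "ResponderSet")) set_a$members else set_a
  b <- if (inherits(set_b, "ResponderSet")) set_b$members else set_b
  if (is.null(universe)) {
    universe <- common_universe(list(set_a, set_b))
  }
  if (!length(universe)) stop("`universe` must be non-empty")
  a <- intersect(a, universe)
  b <- intersect(b, universe)
  n <- length(universe)
  n_ab <- length(intersect(a, b))
  tab <- matrix(c(n_ab, length(a) - n_ab,
                  length(b) - n_ab, n - length(a) - length(b) + n_ab),
                2, 2, byrow = TRUE,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  if (is.null(chance)) chance <- (length(a) / n) * (length(b) / n)
  structure(
    list(n_universe = n, n_a = length(a), n_b = length(b),
         n_overlap = n_ab,
         fraction = if (length(a)) n_ab / length(a) else NA_real_,
         chance = chance, p = p, table = tab),
    class = "OverlapResult"
  )
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(
    "<OverlapResult> %d/%d = %.0f%% overlap (chance %.0f%%), Fisher p = %.3g (universe %d)\n",
    x$n_overlap, x$n_a, 100 * x$fraction, 100 * x$chance, x$p, x$n_universe))
  invisible(x)
}

#' Venn region counts for 2 or 3 responder sets
#'
#' @param sets list of 2 or 3 `ResponderSet`s or character vectors.
#' @param universe neuron ids over which regions are counted; defaults to
#'   [common_universe()].
#' @return Named integer vector of the `2^n - 1` region counts, e.g.
#'   `A`, `B`, `AB` (exclusive regions) for two sets.
#' @export
venn_counts <- function(sets, universe = NULL) {
  n_sets <- length(sets)
  if (n_sets < 2 || n_sets > 3) stop("2 or 3 sets are supported")
  members <- lapply(sets, function(s) {
    if (inherits(s, "ResponderSet")) s$members else s
  })
  if (is.null(universe)) {
    universe <- tryCatch(common_universe(sets),
                         error = function(e) Reduce(union, members))
  }
  members <- lapply(members, intersect, universe)
  nm <- names(sets) %||% LETTERS[seq_len(n_sets)]
  if (is.null(names(sets)) || any(!nzchar(nm))) nm <- LETTERS[seq_len(n_sets)]
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n_sets))[-1, , drop = FALSE]
  counts <- apply(combos, 1, function(inc) {
    inside <- Reduce(intersect, members[which(inc)])
    outside <- Reduce(union, c(members[which(!inc)], list(character(0))))
    length(setdiff(inside, outside))
  })
  names(counts) <- apply(combos, 1, function(inc) {
    paste(nm[which(inc)], collapse = "")
  })
  counts
}
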
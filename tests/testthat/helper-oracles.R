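# Independent brute-force oracles used to validate the analytical
# implementations, plus small fixture builders.

# auROC by explicit concordant-pair counting (ties count one half).
auroc_pairs <- function(x, pos) {
  xp <- x[pos]; xn <- x[!pos]
  total <- 0
  for (a in xp) for (b in xn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(xp) * length(xn))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign patterns
# over the |d| ranks (average ranks for ties; zeros dropped).
signed_rank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Minimal single-behavior ethogram.
tiny_track <- function(intervals, duration_s = 60, ...) {
  behavior_track(intervals, duration_s, ...)
}

# A small defeat experiment used by several suites.
small_defeat_experiment <- function(seed = 1, n_neurons = 30,
                                    duration_s = 300, noise_sd = 0.2,
                                    class_fractions = NULL) {
  cfg <- synthetic_config(
    n_neurons = n_neurons,
    session_plan = data.frame(kind = "defeat", duration_s = duration_s),
    bout_rate_hz = 0.03,
    noise_sd = noise_sd,
    class_fractions = class_fractions %||%
      socialscope:::default_class_fractions,
    seed = seed)
  generate_experiment(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
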
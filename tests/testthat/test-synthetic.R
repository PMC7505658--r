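test_that("ethogram generation is seed-deterministic and well-formed", {
  cfg <- synthetic_config(n_neurons = 10, seed = 7)
  a <- generate_ethogram(cfg, "defeat")
  b <- generate_ethogram(cfg, "defeat")
  expect_identical(a$intervals, b$intervals)
  c <- generate_ethogram(cfg, "defeat", seed = 8)
  expect_false(identical(a$intervals, c$intervals))

  # bouts of one behavior are disjoint and inside the session
  for (beh in unique(a$intervals$behavior)) {
    iv <- a$intervals[a$intervals$behavior == beh, ]
    iv <- iv[order(iv$onset_s), ]
    expect_true(all(iv$onset_s < iv$offset_s))
    expect_true(all(iv$onset_s >= 0) && all(iv$offset_s <= a$duration_s))
    if (nrow(iv) > 1) {
      expect_true(all(iv$offset_s[-nrow(iv)] <= iv$onset_s[-1]))
    }
    expect_gte(nrow(iv), 2)
  }
})

test_that("zero bout rate violates the minimum-instance constraint", {
  cfg <- synthetic_config(n_neurons = 5, bout_rate_hz = 0, seed = 1)
  expect_error(generate_ethogram(cfg, "defeat"), "non-overlapping bouts")
})

test_that("bout counts follow the Poisson mean rate x duration", {
  cfg <- synthetic_config(
    n_neurons = 5, bout_rate_hz = 0.02,
    session_plan = data.frame(kind = "approach_avoidance", duration_s = 600),
    seed = 1)
  counts <- vapply(1:200, function(s) {
    eth <- generate_ethogram(cfg, "approach_avoidance", seed = s)
    sum(eth$intervals$behavior == "assessment")
  }, 0)
  # conditioned on >= 2; for Poisson(12) the truncation effect is negligible
  se <- sqrt(12 / 200)
  expect_lt(abs(mean(counts) - 12), 3 * se)
})

test_that("context chamber track partitions frames and revisits compartments", {
  cfg <- synthetic_config(
    n_neurons = 5,
    session_plan = data.frame(kind = "context", duration_s = 400),
    seed = 3)
  eth <- generate_ethogram(cfg, "context")
  ch <- eth$chamber_track
  expect_length(ch, 400 * cfg$frame_rate_hz)
  expect_true(all(ch %in% c("home", "corridor", "far")))
  runs <- rle(ch)
  for (comp in c("home", "corridor", "far")) {
    expect_gte(sum(runs$values == comp), 2)
  }
})

test_that("traces: pure-noise, noiseless construction, and Flight- direction", {
  # amplitude 0 -> pure noise of the configured SD
  cfg0 <- synthetic_config(n_neurons = 20, response_amplitude = 0,
                           noise_sd = 0.3, seed = 11)
  eth <- generate_ethogram(cfg0, "defeat")
  truth <- generate_ground_truth(cfg0)
  rec <- generate_traces(cfg0, truth, eth)
  nf <- ncol(rec$traces)
  expect_true(all(abs(rowMeans(rec$traces)) <= 3 * 0.3 / sqrt(nf)))

  # noiseless planted Defeat+ equals the kernel-convolved bout indicator
  cfg1 <- synthetic_config(n_neurons = 2, noise_sd = 0,
                           class_fractions = c("Defeat+" = 1), seed = 12)
  truth1 <- generate_ground_truth(cfg1)
  expect_true(all(truth1$class == "Defeat+"))
  rec1 <- generate_traces(cfg1, truth1, eth <- generate_ethogram(cfg1, "defeat"))
  nf1 <- ncol(rec1$traces)
  ras <- resample_to_calcium(eth, cfg1$frame_rate_hz, nf1)
  kernel <- gcamp_kernel(cfg1$frame_rate_hz, cfg1$kernel_rise_s,
                         cfg1$kernel_decay_s)
  expected <- cfg1$response_amplitude *
    socialscope:::convolve_drive(as.numeric(ras[, "defeat"]), kernel)
  expect_equal(unname(rec1$traces[1, ]), expected, tolerance = 1e-10)

  # "none" neurons are constant without noise
  cfgn <- synthetic_config(n_neurons = 3, noise_sd = 0,
                           class_fractions = c("Defeat+" = 0), seed = 5)
  truthn <- generate_ground_truth(cfgn)
  recn <- generate_traces(cfgn, truthn, generate_ethogram(cfgn, "defeat"))
  expect_true(all(apply(recn$traces, 1, function(x) max(x) - min(x)) == 0))

  # planted Flight- neuron: activity drops after flight onset
  cfgf <- synthetic_config(n_neurons = 3, noise_sd = 0.2,
                           class_fractions = c("Flight-" = 1), seed = 6)
  truthf <- generate_ground_truth(cfgf)
  ethf <- generate_ethogram(cfgf, "defeat")
  recf <- generate_traces(cfgf, truthf, ethf)
  onsets <- ethf$intervals$onset_s[ethf$intervals$behavior == "flight"]
  r <- cfgf$frame_rate_hz
  for (i in seq_len(nrow(truthf))) {
    pre <- post <- numeric(0)
    for (t0 in onsets) {
      f0 <- floor(t0 * r) + 1
      lo <- f0 - 2 * r; hi <- f0 + 2 * r - 1
      if (lo < 1 || hi > ncol(recf$traces)) next
      pre <- c(pre, recf$traces[i, lo:(f0 - 1)])
      post <- c(post, recf$traces[i, f0:hi])
    }
    expect_lt(mean(post), mean(pre))
  }
})

test_that("trace generation is seed-deterministic", {
  cfg <- synthetic_config(n_neurons = 8, seed = 21)
  eth <- generate_ethogram(cfg, "defeat")
  truth <- generate_ground_truth(cfg)
  expect_identical(generate_traces(cfg, truth, eth)$traces,
                   generate_traces(cfg, truth, eth)$traces)
})

test_that("remodeling flags exactly the configured fraction", {
  base <- synthetic_config(n_neurons = 100, seed = 2)
  truth <- generate_ground_truth(base)

  cfg0 <- synthetic_config(n_neurons = 100, remodel_fraction = 0, seed = 2)
  r0 <- apply_remodeling(truth, cfg0)
  expect_identical(r0$class, truth$class)
  expect_false(any(r0$remodeled))

  cfg1 <- synthetic_config(n_neurons = 100, remodel_fraction = 1, seed = 2)
  expect_true(all(apply_remodeling(truth, cfg1)$remodeled))

  cfg5 <- synthetic_config(n_neurons = 100, remodel_fraction = 0.5, seed = 2)
  expect_identical(sum(apply_remodeling(truth, cfg5)$remodeled), 50L)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(frame_rate_hz = 3), "\\[5, 100\\]")
  expect_error(synthetic_config(kernel_rise_s = 2, kernel_decay_s = 1),
               "smaller than")
  expect_error(synthetic_config(class_fractions = c("Defeat+" = 1.2)),
               "sum to <= 1")
  expect_error(synthetic_config(remodel_fraction = 1.5), "\\[0, 1\\]")
})

test_that("synthetic movies render spots on a smooth background", {
  cfg <- synthetic_config(n_neurons = 6, frame_rate_hz = 5,
                          session_plan = data.frame(kind = "defeat",
                                                    duration_s = 60),
                          bout_rate_hz = 0.1, seed = 9)
  eth <- generate_ethogram(cfg, "defeat")
  truth <- generate_ground_truth(cfg)
  rec <- generate_traces(cfg, truth, eth)

  mv <- generate_movie(cfg, rec, layout_seed = 4, frame_dim = c(48, 48))
  expect_s3_class(mv$stack, "VideoStack")
  expect_identical(dim(mv$stack$frames)[1], ncol(rec$traces))
  expect_identical(length(mv$mask$ids), nrow(rec$traces))

  # deterministic given seeds
  mv2 <- generate_movie(cfg, rec, layout_seed = 4, frame_dim = c(48, 48))
  expect_identical(mv$stack$frames, mv2$stack$frames)

  # zero-amplitude traces give a static movie (background + static spots)
  rec0 <- calcium_recording(matrix(0, 6, 10), cfg$frame_rate_hz)
  mv0 <- generate_movie(cfg, rec0, layout_seed = 4, frame_dim = c(48, 48))
  for (f in 2:10) {
    expect_equal(mv0$stack$frames[f, , ], mv0$stack$frames[1, , ])
  }
})
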
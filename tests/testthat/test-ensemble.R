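test_that("frame datasets stack z-scored frames over common neurons", {
  m1 <- matrix(rnorm(40 * 100), 40, dimnames = list(paste0("n", 1:40)))
  m2 <- matrix(rnorm(35 * 80), 35, dimnames = list(paste0("n", 6:40)))
  r1 <- calcium_recording(m1, 10, session_id = "a")
  r2 <- calcium_recording(m2, 10, session_id = "b")
  ds <- build_frame_dataset(list(r1, r2), labels = list("a", "b"))
  expect_identical(ncol(ds$x), 35L)  # shared neurons n6..n40
  expect_identical(ds$neurons, paste0("n", 6:40))
  expect_identical(nrow(ds$x), 180L)
  expect_error(build_frame_dataset(list(r1, r2), labels = list("a", "b"),
                                   restrict = list(integer(0), 1:10)),
               "empty")
  ds_r <- build_frame_dataset(list(r1, r2), labels = list("a", "b"),
                              restrict = list(1:50, 1:40))
  expect_identical(nrow(ds_r$x), 90L)

  m3 <- matrix(rnorm(10 * 20), 10, dimnames = list(paste0("x", 1:10)))
  r3 <- calcium_recording(m3, 10, session_id = "c")
  expect_error(build_frame_dataset(list(r1, r3), labels = list("a", "c")),
               "common")
})

test_that("LDA separates separable clouds and matches MASS on projections", {
  set.seed(11)
  n <- 200
  x <- rbind(matrix(rnorm(n * 5), n), matrix(rnorm(n * 5, mean = 3), n))
  y <- rep(c("a", "b"), each = n)
  emb <- fit_lda(x = x, y = y)
  expect_identical(ncol(emb$projections), 1L)  # 2 labels -> 1 discriminant
  pa <- emb$projections[y == "a", 1]; pb <- emb$projections[y == "b", 1]
  pooled_sd <- sqrt((stats::var(pa) + stats::var(pb)) / 2)
  expect_gt(abs(mean(pa) - mean(pb)), 5 * pooled_sd)

  # cross-check against the reference implementation: projections agree
  # up to sign/scale (|correlation| ~ 1)
  mass <- MASS::lda(x, grouping = y)
  mass_proj <- predict(mass, x)$x[, 1]
  expect_gt(abs(stats::cor(emb$projections[, 1], mass_proj)), 0.999)
})

test_that("LDA is invariant to affine rescaling of a neuron (distance ratios)", {
  set.seed(12)
  x <- rbind(matrix(rnorm(300), 100), matrix(rnorm(300, 1), 100),
             matrix(rnorm(300, c(0, 2, 0)), 100, byrow = FALSE))
  y <- rep(c("a", "b", "c"), each = 100)
  d_ratio <- function(x) {
    emb <- fit_lda(x = x, y = y)
    cluster_distance(emb, "a", others = "b") /
      cluster_distance(emb, "a", others = "c")
  }
  x2 <- x
  x2[, 2] <- 10 * x2[, 2] + 3
  expect_equal(d_ratio(x), d_ratio(x2), tolerance = 1e-6)
})

test_that("cluster distances match hand-enumerated cases", {
  mk_emb <- function(pts, labs) {
    structure(list(projections = pts, labels = factor(labs)),
              class = "EnsembleEmbedding")
  }
  e1 <- mk_emb(rbind(c(0, 0), c(3, 4)), c("A", "B"))
  expect_equal(cluster_distance(e1, "A"), 5)

  e2 <- mk_emb(rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2)),
               c("A", "A", "B", "B"))
  expect_equal(cluster_distance(e2, "A"), (4 + sqrt(20) + sqrt(20) + 4) / 4)

  e3 <- mk_emb(rbind(c(1, 1), c(1, 1)), c("A", "B"))
  expect_equal(cluster_distance(e3, "A"), 0)

  expect_error(cluster_distance(mk_emb(rbind(c(0, 0)), "A"), "A"),
               "2 clusters")

  # rigid motion invariance
  set.seed(4)
  pts <- matrix(rnorm(60), 30)
  labs <- rep(c("A", "B"), 15)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e_a <- mk_emb(pts, labs)
  e_b <- mk_emb(sweep(pts %*% rot, 2, c(3, -1), "+"), labs)
  expect_equal(cluster_distance(e_a, "A"), cluster_distance(e_b, "A"),
               tolerance = 1e-12)
})

test_that("paired separation comparison handles degenerate inputs", {
  expect_error(compare_separation(1:2, 2:3), "at least 3")
  same <- c(1.2, 3.4, 2.2, 5)
  r0 <- compare_separation(same, same)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$zero_variance)

  rc <- compare_separation(c(1, 2, 3), c(2, 3, 4))
  expect_true(rc$zero_variance)
  expect_equal(rc$p, 0)

  set.seed(9)
  pre <- rnorm(8, 1); post <- pre + 1 + rnorm(8, sd = 0.2)
  r <- compare_separation(pre, post)
  expect_lt(r$p, 0.01)
  expect_gt(r$t, 0)
  expect_identical(r$df, 7)
})

test_that("defeat reshapes chamber encoding in synthetic subjects", {
  # smaller single-subject version of the population acceptance check
  dist_for <- function(fracs, seed) {
    cfg <- synthetic_config(
      n_neurons = 30,
      session_plan = data.frame(kind = "context", duration_s = 400),
      class_fractions = fracs, seed = seed)
    exp <- generate_experiment(cfg)
    s <- exp$sessions[[1]]
    ds <- build_frame_dataset(list(s$recording),
                              labels = list(s$track$chamber_track))
    emb <- fit_lda(ds)
    cluster_distance(emb, "home", others = "far")
  }
  pre <- dist_for(c("Far+" = 0), seed = 41)
  post <- dist_for(c("Far+" = 0.27, "Home+" = 0.23), seed = 41)
  expect_gt(post, pre)
})

test_that("session KS distinguishes remodeled from stable pairs", {
  run_ks <- function(seed, remodel) {
    cfg <- synthetic_config(
      n_neurons = 40,
      session_plan = data.frame(kind = c("defeat", "defeat"),
                                duration_s = c(600, 600)),
      remodel_fraction = remodel, seed = seed)
    exp <- generate_experiment(cfg)
    ids <- names(exp$sessions)
    restrict <- list(); sigs <- list()
    for (k in seq_along(ids)) {
      s <- exp$sessions[[ids[k]]]
      nf <- ncol(s$recording$traces); r <- s$recording$frame_rate_hz
      fr <- close_contact_frames(s$track, r, nf)
      restrict[[k]] <- fr
      sigs[[k]] <- behavior_signature(s$track, r, nf)[fr]
    }
    ds <- build_frame_dataset(lapply(exp$sessions, `[[`, "recording"),
                              labels = as.list(ids), restrict = restrict)
    session_separation_ks(ds, strata = unlist(sigs))$p
  }
  expect_lt(run_ks(1, 0.5), 0.001)
  expect_gt(run_ks(1, 0), 0.05)
})

test_that("session KS edge cases: identical and disjoint projections", {
  # identical projections -> D = 0, p = 1 (in-sample variant, no fitting
  # pathology: use a symmetric dataset)
  set.seed(2)
  x <- matrix(rnorm(200 * 4), 200)
  xx <- rbind(x, x)
  y <- rep(c("s1", "s2"), each = 200)
  ds <- structure(list(x = xx, labels = factor(y),
                       frame_idx = rep(1:200, 2), frame_rate_hz = 10),
                  class = "FrameDataset")
  ks <- session_separation_ks(ds, holdout = "none")
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p, 1)

  # disjoint supports -> D = 1
  x2 <- rbind(matrix(rnorm(100 * 2), 100), matrix(rnorm(100 * 2, 50), 100))
  ds2 <- structure(list(x = x2, labels = factor(rep(c("s1", "s2"), each = 100)),
                        frame_idx = rep(1:100, 2), frame_rate_hz = 10),
                   class = "FrameDataset")
  expect_equal(session_separation_ks(ds2, holdout = "none")$statistic, 1)
})

test_that("session decoding is seeded, calibrated at chance, perfect when separable", {
  set.seed(21)
  # random labels on noise -> accuracy near chance
  x <- matrix(rnorm(400 * 10), 400)
  y <- rep(c("s1", "s2"), each = 200)
  ds <- structure(list(x = x, labels = factor(y)), class = "FrameDataset")
  acc <- decode_sessions(ds, folds = 5, seed = 3)$accuracy
  se <- sqrt(0.5 * 0.5 / 400)
  expect_lt(abs(acc - 0.5), 5 * se)

  # identical seed -> identical folds and accuracy
  expect_identical(decode_sessions(ds, folds = 5, seed = 3)$accuracy, acc)

  # perfectly separated sessions -> accuracy 1
  x2 <- rbind(matrix(rnorm(100 * 5), 100), matrix(rnorm(100 * 5, 10), 100))
  ds2 <- structure(list(x = x2,
                        labels = factor(rep(c("s1", "s2"), each = 100))),
                   class = "FrameDataset")
  expect_equal(decode_sessions(ds2, folds = 5, seed = 1)$accuracy, 1)

  expect_error(decode_sessions(structure(list(
    x = matrix(rnorm(12), 6), labels = factor(rep(c("a", "b"), 3))),
    class = "FrameDataset"), folds = 5), "at least")
})

test_that("label permutation destroys compare_separation significance", {
  set.seed(55)
  pre <- rnorm(6, 1, 0.3); post <- pre + rnorm(6, 0, 0.3)  # no true effect
  ps <- replicate(50, {
    flip <- runif(6) < 0.5
    a <- ifelse(flip, post, pre); b <- ifelse(flip, pre, post)
    compare_separation(a, b)$p
  })
  expect_gt(mean(ps > 0.05), 0.8)
})
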
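test_that("background estimation preserves flat fields and gradients", {
  flat <- array(7, dim = c(2, 32, 32))
  bg <- estimate_background(video_stack(flat, 10), low_cut = 16)
  expect_lt(max(abs(bg$frames - 7)) / 7, 1e-6)

  # smooth gradient + one bright 3-px spot: background recovers the
  # gradient; the residual at the spot's centre stays positive
  grad <- outer(seq(10, 20, length.out = 48), seq(1, 2, length.out = 48))
  frame <- grad
  frame[24, 24] <- frame[24, 24] + 50
  frame[23:25, 24] <- frame[23:25, 24] + 20
  st <- video_stack(array(rep(frame, 2), c(48, 48, 2)) |>
                      aperm(c(3, 1, 2)), 10)
  bg2 <- estimate_background(st, low_cut = 12)
  interior <- cbind(rep(10:38, 29), rep(10:38, each = 29))
  off_spot <- interior[abs(interior[, 1] - 24) > 6 |
                         abs(interior[, 2] - 24) > 6, ]
  rel_err <- abs(bg2$frames[1, , ][off_spot] - grad[off_spot]) /
    grad[off_spot]
  expect_lt(max(rel_err), 0.05)
  resid <- st$frames[1, , ] - bg2$frames[1, , ]
  expect_gt(resid[24, 24], 0)

  expect_error(estimate_background(video_stack(flat, 10), low_cut = -1),
               "> 0")
  expect_error(estimate_background(video_stack(flat, 10), low_cut = 200,
                                   high_cut = 100), "smaller")
})

test_that("background division returns ratio stacks", {
  set.seed(8)
  base <- array(runif(2 * 16 * 16, 50, 100), c(2, 16, 16))
  st <- video_stack(base, 10)
  expect_equal(divide_background(st, st)$frames,
               array(1, dim(base)))
  s <- array(runif(length(base), -0.1, 0.1), dim(base))
  st2 <- video_stack(base * (1 + s), 10)
  expect_equal(divide_background(st2, st)$frames, 1 + s, tolerance = 1e-6)
  bad <- st; bad$frames[1, 1, 1] <- 0
  expect_error(divide_background(st2, bad), "strictly positive")
  small <- video_stack(base[, 1:8, , drop = FALSE], 10)
  expect_error(divide_background(small, st), "dimensions differ")
})

test_that("background division after estimation is idempotent on pure background", {
  # linear gradients lie in the null space of the Gaussian high-pass in the
  # kernel interior, so a second estimate/divide pass is a no-op there
  grad <- outer(seq(80, 120, length.out = 64), seq(1, 1.5, length.out = 64))
  frames <- array(rep(grad, 3), c(64, 64, 3)) |> aperm(c(3, 1, 2))
  st <- video_stack(frames, 10)
  flat1 <- divide_background(st, estimate_background(st, low_cut = 12))
  flat2 <- divide_background(flat1, estimate_background(flat1, low_cut = 12))
  interior <- 21:44  # > 2 kernel radii from every edge
  expect_lt(max(abs(flat2$frames[, interior, interior] -
                      flat1$frames[, interior, interior])), 1e-6)
  expect_lt(max(abs(flat1$frames[, interior, interior] - 1)), 1e-9)
})

test_that("registration recovers planted integer shifts exactly", {
  set.seed(5)
  ref <- matrix(runif(40 * 40, 10, 100), 40, 40)
  frames <- array(0, c(4, 40, 40))
  frames[1, , ] <- ref
  frames[2, , ] <- ref
  shifted <- socialscope:::shift_frame(ref, 3, -2)
  frames[3, , ] <- shifted
  frames[4, , ] <- shifted
  reg <- register_translation(video_stack(frames, 10), max_shift = 5)
  expect_identical(unname(reg$shifts[2, ]), c(0L, 0L))
  expect_identical(unname(reg$shifts[3, ]), c(3L, -2L))
  expect_identical(unname(reg$shifts[4, ]), c(3L, -2L))
  # interior pixels restored exactly
  expect_equal(reg$stack$frames[3, 10:30, 10:30], ref[10:30, 10:30])

  # constant frame: shift (0,0) with a warning and NA quality
  frames[4, , ] <- 5
  expect_warning(regc <- register_translation(video_stack(frames, 10),
                                              max_shift = 3), "constant")
  expect_identical(unname(regc$shifts[4, ]), c(0L, 0L))
  expect_true(is.na(regc$quality[4]))
})

test_that("trace extraction averages ROI pixels", {
  frames <- array(0, c(3, 8, 8))
  for (f in 1:3) frames[f, , ] <- f * matrix(1:64, 8, 8)
  label <- matrix(0L, 8, 8)
  label[2, 3] <- 1L           # single pixel
  label[5:6, 5:6] <- 2L       # 4-pixel square
  tr <- extract_traces(video_stack(frames, 10), roi_mask(label))
  px <- frames[, 2, 3]
  expect_equal(unname(tr[1, ]), px)
  expect_equal(unname(tr[2, ]), sapply(1:3, function(f) {
    mean(frames[f, 5:6, 5:6])
  }))

  # uniform frames give every ROI the frame value
  uni <- array(rep(c(4, 9), times = c(64, 64)), c(8, 8, 2)) |>
    aperm(c(3, 1, 2))
  tru <- extract_traces(video_stack(uni, 10), roi_mask(label))
  expect_equal(unname(tru[, 1]), c(4, 4))
  expect_equal(unname(tru[, 2]), c(9, 9))
})

test_that("dF/F normalizes to the whole-recording mean", {
  expect_equal(unname(compute_dff(matrix(c(8, 12), 1), 10)$traces[1, ]),
               c(-0.2, 0.2))
  expect_equal(unname(compute_dff(matrix(c(5, 10, 15), 1), 10)$traces[1, ]),
               c(-0.5, 0, 0.5))
  expect_equal(unname(compute_dff(matrix(7, 1, 5), 10)$traces[1, ]),
               rep(0, 5))
  set.seed(2)
  raw <- matrix(runif(5 * 100, 10, 20), 5)
  rec <- compute_dff(raw, 10)
  expect_true(all(abs(rowMeans(rec$traces)) < 1e-9))
  expect_error(compute_dff(matrix(c(-1, 1), 1), 10), "non-positive")
})

test_that("ROI tracking finds the global shift or reports new ROIs", {
  set.seed(10)
  # two bright blobs on a dim background
  img <- matrix(10, 48, 48)
  blob <- function(img, r, c) {
    img[(r - 1):(r + 1), (c - 1):(c + 1)] <- 200
    img
  }
  img <- blob(img, 12, 12); img <- blob(img, 30, 35)
  label <- matrix(0L, 48, 48)
  label[11:13, 11:13] <- 1L; label[29:31, 34:36] <- 2L
  mask <- roi_mask(label)
  mk_stack <- function(im) {
    video_stack(array(rep(im, 2), c(48, 48, 2)) |> aperm(c(3, 1, 2)), 10)
  }
  # identical field of view: identity mapping
  res <- track_rois(mask, mk_stack(img), max_shift = 6)
  expect_identical(unname(res$shift), c(0L, 0L))
  expect_identical(unname(res$mapping), c(1L, 2L))
  expect_length(res$new_ids, 0)

  # field shifted by (4, 0): all ROIs matched at that shift
  res4 <- track_rois(mask, mk_stack(socialscope:::shift_frame(img, 4, 0,
                                                              fill = 10)),
                     max_shift = 6)
  expect_identical(unname(res4$shift), c(4L, 0L))
  expect_false(any(is.na(res4$mapping)))

  # shift beyond the search radius: ROIs dropped, sources become new
  res_far <- track_rois(mask, mk_stack(socialscope:::shift_frame(img, 12, 0,
                                                                 fill = 10)),
                        max_shift = 4)
  expect_true(all(is.na(res_far$mapping)))
  expect_gte(length(res_far$new_ids), 2)
})

test_that("full pipeline recovers planted traces from rendered movies", {
  cfg <- synthetic_config(n_neurons = 8, frame_rate_hz = 5,
                          session_plan = data.frame(kind = "defeat",
                                                    duration_s = 120),
                          bout_rate_hz = 0.05, noise_sd = 0.1, seed = 77)
  eth <- generate_ethogram(cfg, "defeat")
  truth <- generate_ground_truth(cfg)
  rec <- generate_traces(cfg, truth, eth)
  mv <- generate_movie(cfg, rec, layout_seed = 5, frame_dim = c(64, 64),
                       drift = list(shift = c(3, -2), from = 300))
  out <- preprocess_stack(mv$stack, mv$mask, low_cut = 24, max_shift = 5)
  # planted drift recovered exactly on the drifted frames
  expect_true(all(out$shifts[300:nrow(out$shifts), 1] == 3))
  expect_true(all(out$shifts[300:nrow(out$shifts), 2] == -2))
  expect_true(all(out$shifts[2:299, ] == 0))
  # extracted dF/F tracks the planted traces
  cors <- vapply(seq_len(nrow(truth)), function(i) {
    stats::cor(out$recording$traces[i, ], rec$traces[i, ])
  }, 0)
  signal <- truth$class != "none"
  expect_true(all(cors[signal] >= 0.9))
})
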
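# EMA preprocessing: head correction, down-sampling, parameterizations,
# silence removal, normalization, context stacking.

test_that("head correction: identity pose, rigid co-motion, pure translation", {
  set.seed(1)
  Tn <- 50
  base <- matrix(rnorm(Tn * 27, sd = 5), Tn, 27)
  ident <- cbind(matrix(0, Tn, 6))
  r1 <- head_correct(make_ema(base, pose = ident))
  expect_equal(r1$coords, make_ema(base)$coords, tolerance = 1e-12)

  # sensors rigidly co-moving with the head: corrected trajectory constant
  pose <- cbind(matrix(rnorm(Tn * 3), Tn, 3),
                matrix(runif(Tn * 3, -0.3, 0.3), Tn, 3))
  p0 <- c(10, 20, 30)
  moved <- t(vapply(seq_len(Tn), function(t) {
    R <- emasynth:::euler_rotation(pose[t, 4], pose[t, 5], pose[t, 6])
    rep(drop(R %*% p0 + pose[t, 1:3]), 9)
  }, numeric(27)))
  rc <- head_correct(make_ema(moved, pose = pose))
  expect_lt(max(apply(rc$coords, 2, sd)), 1e-9)

  # pure head translation with stationary articulators
  delta <- c(1, 2, 3)
  pose_t <- cbind(matrix(delta, Tn, 3, byrow = TRUE), matrix(0, Tn, 3))
  rt <- head_correct(make_ema(base, pose = pose_t))
  expect_equal(rt$coords, base - matrix(rep(delta, 9), Tn, 27, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(head_correct(make_ema(base, pose = ident * NA)), "pose")
})

test_that("down-sampling: frame counts, constants, sinusoid amplitude", {
  Tn <- 4000
  const <- make_ema(matrix(7, Tn, 27), rate = 400)
  dc <- downsample_frames(const, 4)
  expect_equal(nrow(dc$coords), 1000)
  expect_equal(dc$rate, 100)
  expect_lt(max(abs(dc$coords - 7)), 1e-8)

  t <- (0:(Tn - 1)) / 400
  sine <- make_ema(matrix(sin(2 * pi * 1 * t), Tn, 27), rate = 400)
  ds <- downsample_frames(sine, 4)
  got <- ds$coords[, 1]
  expected <- sin(2 * pi * 1 * (0:999) / 100)
  mid <- 100:900 # avoid filter edge effects
  expect_lt(max(abs(got[mid] - expected[mid])) / 1, 0.01)

  expect_equal(nrow(downsample_frames(make_ema(matrix(0, 4001, 27),
                                               rate = 400))$coords), 1001)
  expect_error(downsample_frames(const, 2.5), "integer")
  expect_error(downsample_frames(const, 3), "divisible")
})

test_that("midsagittal projection drops lip corners and the z coordinate", {
  set.seed(2)
  Tn <- 20
  coords <- matrix(rnorm(Tn * 27), Tn, 27)
  rec <- make_ema(coords, rate = 100)
  f <- project_midsagittal(rec)
  expect_equal(ncol(f$frames), 14)
  expect_equal(f$parameterization, "midsag14")

  # data already in the x-y plane comes back unchanged
  coords_xy <- coords
  coords_xy[, seq(3, 27, by = 3)] <- 0
  f2 <- project_midsagittal(make_ema(coords_xy, rate = 100))
  expect_equal(f2$frames, f$frames)

  # mirrored lateral offsets give identical projections
  coords_m <- coords
  coords_m[, seq(3, 27, by = 3)] <- -coords[, seq(3, 27, by = 3)]
  f3 <- project_midsagittal(make_ema(coords_m, rate = 100))
  expect_equal(f3$frames, f$frames)

  rec_missing <- ema_recording(coords[, 1:24], 100,
                               sensors = ema_sensor_order()[1:8])
  expect_error(project_midsagittal(rec_missing), "missing sensors")
})

test_that("PCA: perfect reconstruction at full rank, latent recovery, monotone error", {
  set.seed(3)
  Tn <- 400
  latent <- matrix(rnorm(Tn * 5), Tn, 5)
  load <- matrix(rnorm(5 * 27), 5, 27)
  X <- latent %*% load + matrix(rnorm(Tn * 27, sd = 0.01), Tn, 27)
  feats <- artic_features(X, "raw27")

  full <- fit_pca(feats, 27)
  rec <- reconstruct_pca(full, apply_pca(full, feats))
  expect_lt(max(abs(rec - X)), 1e-8)

  m5 <- fit_pca(feats, 5)
  expect_gte(sum(m5$explained[1:5]), 0.99)
  expect_true(all(diff(m5$explained) <= 1e-12))
  G <- crossprod(m5$rotation)
  expect_lt(max(abs(G - diag(5))), 1e-8)

  errs <- vapply(c(3, 5, 10, 20, 27), function(k) {
    m <- fit_pca(feats, k)
    mean((reconstruct_pca(m, apply_pca(m, feats)) - X)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))

  expect_error(fit_pca(feats, 28), "exceeds")
  Xdeg <- X; Xdeg[, 3] <- 1
  expect_error(fit_pca(artic_features(Xdeg, "raw27"), 5), "zero-variance")
})

test_that("silence removal keeps speech frames and maps indices", {
  X <- matrix(seq_len(200 * 2), 200, 2)
  f <- artic_features(X, "custom", rate = 100)
  seg <- segmentation(c(0, 1), c(1, 2), c("aa", "SILENCE"))
  out <- remove_silence(f, seg)
  expect_equal(nrow(out$frames), 100)
  expect_equal(attr(out, "index_map"), 1:100)

  all_speech <- segmentation(0, 2, "aa")
  expect_equal(nrow(remove_silence(f, all_speech)$frames), 200)

  all_sil <- segmentation(0, 2, "SILENCE")
  expect_warning(out0 <- remove_silence(f, all_sil), "silence")
  expect_equal(nrow(out0$frames), 0)
})

test_that("segmentations validate and round-trip through text", {
  expect_error(segmentation(c(0, 0.5), c(0.6, 1), c("a", "b")), "overlap")
  expect_error(segmentation(1, 0.5, "a"), "start < end")
  seg <- segmentation(c(0, 0.5, 1), c(0.5, 1, 1.8), c("SILENCE", "aa", "bb"))
  tf <- tempfile()
  write_segmentation(seg, tf)
  seg2 <- read_segmentation(tf)
  expect_equal(seg2$start, seg$start)
  expect_equal(seg2$label, seg$label)
})

test_that("normalizer: z-scoring, inversion, no leakage to held-out data", {
  set.seed(4)
  X <- matrix(rnorm(500, mean = 3, sd = 2), 100, 5)
  nm <- fit_normalizer(X)
  Z <- apply_normalizer(nm, X)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-10)
  expect_lt(max(abs(invert_normalizer(nm, Z) - X)), 1e-10)

  held <- X + 5 # shifted held-out set: stays off-center after normalization
  expect_gt(min(abs(colMeans(apply_normalizer(nm, held)))), 1)

  Xc <- X; Xc[, 2] <- 42
  expect_error(fit_normalizer(Xc), "dimension\\(s\\): 2")
})

test_that("context stacking is causal with first-frame replication", {
  set.seed(5)
  X <- matrix(rnorm(20 * 14), 20, 14)
  S <- stack_context(X, 4)
  expect_equal(dim(S), c(20, 70))
  expect_equal(S[10, ], c(X[10, ], X[9, ], X[8, ], X[7, ], X[6, ]),
               ignore_attr = TRUE)
  expect_equal(S[1, ], rep(X[1, ], 5), ignore_attr = TRUE) # replication pad

  const <- matrix(1:14, 20, 14, byrow = TRUE)
  Sc <- stack_context(const, 4)
  expect_true(all(Sc == Sc[rep(1, 20), ]))

  # perturbing frame t+1 leaves rows <= t unchanged
  X2 <- X; X2[11, ] <- X2[11, ] + 100
  S2 <- stack_context(X2, 4)
  expect_equal(S2[1:10, ], S[1:10, ])
})

test_that("EMA files round-trip with and without head correction", {
  set.seed(6)
  coords <- matrix(rnorm(10 * 27), 10, 27)
  pose <- cbind(matrix(rnorm(30), 10, 3), matrix(0.1, 10, 3))
  rec <- make_ema(coords, pose = pose)
  tf <- tempfile()
  write_ema(rec, tf)
  rec2 <- read_ema(tf)
  expect_equal(rec2$coords, rec$coords, tolerance = 1e-9)
  expect_equal(rec2$reference_pose, pose, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rec2$rate, 400)

  hc <- head_correct(rec)
  write_ema(hc, tf)
  expect_null(read_ema(tf)$reference_pose)
})
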
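# Frame averaging, the cropping protocol, the corrupting teacher, soft
# labels and the volume-level split.

test_that("frame averaging is the per-frame mean over repetitions", {
  # single repetition: identity
  d1 <- array(runif(2 * 1 * 8 * 6), c(2, 1, 8, 6))
  v1 <- oct_volume(d1)
  expect_equal(frame_average(v1), array(d1[, 1, , ], c(2, 8, 6)))
  # two constant repetitions a, b -> (a + b) / 2 everywhere
  d2 <- array(0, c(1, 2, 4, 4))
  d2[1, 1, , ] <- 0.2; d2[1, 2, , ] <- 0.6
  expect_equal(unique(as.vector(frame_average(oct_volume(d2)))), 0.4)
  # linearity and idempotence on repetition-constant volumes
  d3 <- array(runif(3 * 4 * 8 * 6), c(3, 4, 8, 6))
  for (r in 2:4) d3[, r, , ] <- d3[, 1, , ]
  expect_equal(frame_average(oct_volume(d3)), array(d3[, 1, , ], c(3, 8, 6)))
})

test_that("averaging repetitions improves PSNR against the noise-free image", {
  ph <- generate_phantom(small_phantom_config(seed = 5))
  avg <- frame_average(ph$volume)
  p_avg <- psnr(ph$noise_free[1, , ], avg[1, , ])
  p_one <- psnr(ph$noise_free[1, , ], ph$volume$data[1, 1, , ])
  expect_gt(p_avg, p_one)
})

test_that("the lens cropping protocols give the documented windows", {
  f400 <- matrix(runif(960 * 400), 960, 400)
  p <- extract_patches(f400, default_crop_spec("intraoral"))
  expect_length(p, 2L)
  expect_equal(vapply(p, function(q) attr(q, "window")[["start"]], 0),
               c(0, 144))
  expect_equal(dim(p[[1]]), c(256L, 256L))
  f600 <- matrix(runif(960 * 600), 960, 600)
  p3 <- extract_patches(f600, default_crop_spec("LSM03"))
  expect_length(p3, 3L)
  expect_equal(vapply(p3, function(q) attr(q, "window")[["start"]], 0),
               c(0, 256, 344))
  # a frame-wide single window returns the frame's leading block verbatim
  f256 <- matrix(runif(300 * 256), 300, 256)
  p1 <- extract_patches(f256, crop_spec(256, 256, 0))
  expect_equal(p1[[1]], f256[1:256, ], ignore_attr = TRUE)
  expect_error(extract_patches(f400, default_crop_spec("LSM03")),
               "window \\[256, 512\\) exceeds")
})

test_that("stitching patches back reproduces the covered region exactly", {
  f <- matrix(runif(300 * 400), 300, 400)
  spec <- default_crop_spec("intraoral")
  patches <- extract_patches(f, spec)
  canvas <- stitch_patches(patches, 300, 400)
  expect_equal(canvas[1:256, 1:400], f[1:256, 1:400])
  expect_true(all(is.na(canvas[257:300, ])))
})

test_that("the corrupting teacher degrades labels in a controlled way", {
  ph <- generate_phantom(small_phantom_config(seed = 6))
  truth <- ph$masks$labels[2, , ]
  # no jitter, no flips: the pseudo label is the truth
  t0 <- teacher_oracle(jitter = 0, flip_rate = 0, seed = 1)
  expect_identical(pseudo_label(t0, truth), matrix(as.integer(truth),
                                                  nrow(truth)))
  # full flipping with K = 3: about 2/3 of pixels disagree
  t1 <- teacher_oracle(jitter = 0, flip_rate = 1, seed = 2)
  lab1 <- pseudo_label(t1, truth)
  expect_equal(mean(lab1 != truth), 2 / 3, tolerance = 0.05)
  # jitter alone: imperfect but far better than a shuffled mask
  t2 <- teacher_oracle(jitter = 2, flip_rate = 0, seed = 3)
  lab2 <- pseudo_label(t2, truth)
  d_jit <- mdice(confusion(lab2, truth))
  shuffled <- matrix(sample(as.vector(truth)), nrow(truth))
  d_shuf <- mdice(confusion(shuffled, truth))
  expect_lt(d_jit, 1)
  expect_gt(d_jit, d_shuf)
  # determinism
  expect_identical(pseudo_label(t2, truth), pseudo_label(t2, truth))
  # external mode validates its callable
  bad <- teacher_oracle("external-model", model = function(img) img * 0 + 7)
  expect_error(pseudo_label(bad, truth, averaged_frame = truth * 0.1),
               "outside")
  good <- teacher_oracle("external-model",
                         model = function(img) matrix(1L, nrow(img), ncol(img)))
  expect_true(all(pseudo_label(good, truth, averaged_frame = truth * 0.1) == 1L))
})

test_that("soft-label encoding spreads exactly 1 - confidence over the other classes", {
  m <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  s <- encode_soft_labels(m, 0.95, 3L)
  expect_equal(s[1, 1, ], c(0.95, 0.025, 0.025))
  expect_equal(s[2, 1, ], c(0.025, 0.95, 0.025))
  expect_equal(s[1, 2, ], c(0.025, 0.025, 0.95))
  expect_equal(apply(s, c(1, 2), sum), matrix(1, 2, 2), tolerance = 1e-6)
  # binary case from the (1 - c)/(K - 1) rule
  s2 <- encode_soft_labels(matrix(0L, 1, 1), 0.95, 2L)
  expect_equal(as.vector(s2[1, 1, ]), c(0.95, 0.05))
  # confidence 1 is one-hot
  s3 <- encode_soft_labels(m, 1, 3L)
  expect_true(all(s3 %in% c(0, 1)))
  # argmax recovers the mask whenever confidence > 1/K
  s4 <- encode_soft_labels(m, 0.4, 3L)
  expect_equal(apply(s4, c(1, 2), which.max) - 1L, m)
  expect_error(encode_soft_labels(matrix(3L, 1, 1), 0.95, 3L), "labels")
})

test_that("make_dataset enumerates frames x windows and splits by volume", {
  spec <- crop_spec(64, 32, c(0, 16, 32))
  vols <- lapply(1:5, function(s) phantom_entry(seed = s, n_frames = 4))
  ds <- make_dataset(vols, spec, split = c(1, 0, 0), seed = 1)
  expect_length(ds$train, 5 * 4 * 3)    # volumes x frames x windows
  expect_length(ds$val, 0)
  # identical seeds give identical membership; volumes never straddle roles
  ds1 <- make_dataset(vols, spec, split = c(0.6, 0.2, 0.2), seed = 9)
  ds2 <- make_dataset(vols, spec, split = c(0.6, 0.2, 0.2), seed = 9)
  vols_of <- function(d, role) unique(vapply(d[[role]], function(p)
    p$provenance$volume, ""))
  for (role in c("train", "val", "test"))
    expect_identical(vols_of(ds1, role), vols_of(ds2, role))
  expect_length(intersect(vols_of(ds1, "train"), vols_of(ds1, "val")), 0)
  expect_length(intersect(vols_of(ds1, "train"), vols_of(ds1, "test")), 0)
  expect_error(make_dataset(vols, spec, split = c(0.8, 0.3, 0.2)), "split")
  # frame 1 carries the manual (uncorrupted) mask
  e <- vols[[1]]
  e$pseudo_masks[1, , ] <- 0L   # corrupt the pseudo mask of frame 1 only
  ds3 <- make_dataset(list(e), spec, split = c(1, 0, 0), seed = 1)
  first <- Filter(function(p) p$provenance$frame == 1L, ds3$train)
  w <- attr(first[[1]]$noisy, "window")
  expect_equal(first[[1]]$label,
               extract_patches(e$manual_mask + 0, spec)[[1]],
               ignore_attr = TRUE)
  # soft labels are consistent with the stored label patch
  p <- ds3$train[[5]]
  expect_equal(apply(p$soft_label, c(1, 2), which.max) - 1L,
               unclass(p$label), ignore_attr = TRUE)
})
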
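# PSNR/SSIM and the segmentation overlap metrics against closed forms and
# brute-force oracles.

test_that("PSNR reproduces its closed forms and monotonicity", {
  y <- matrix(runif(64), 8)
  expect_equal(psnr(y, y), Inf)
  expect_equal(psnr(y, y + 0.1), 20, tolerance = 1e-9)
  # direct formula on a random pair
  set.seed(41)
  z <- matrix(runif(64), 8)
  expect_equal(psnr(y, z), 10 * log10(1 / mean((y - z)^2)),
               tolerance = 1e-9)
  # strictly decreasing with independent noise amplitude
  noise <- matrix(rnorm(64), 8)
  p <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a)
    psnr(y, y + a * noise), 0)
  expect_true(all(diff(p) < 0))
  expect_error(psnr(numeric(0), numeric(0)), "empty")
})

test_that("SSIM special cases hold in both modes", {
  set.seed(42)
  y <- matrix(runif(16 * 16), 16)
  for (w in c("gaussian", "global"))
    expect_equal(ssim(y, y, ssim_config(window = w)), 1, tolerance = 1e-9)
  # equal constants: stabilizers prevent 0/0
  cst <- matrix(0.5, 16, 16)
  expect_equal(ssim(cst, cst), 1)
  # anti-correlated about mid-range: negative global SSIM on a ramp
  ramp <- matrix(seq(0, 1, length.out = 256), 16)
  expect_lt(ssim(ramp, 1 - ramp, ssim_config(window = "global")), 0)
  # windowed SSIM with a full-image uniform window equals global SSIM
  z <- matrix(runif(11 * 11), 11)
  zz <- z + 0.05 * matrix(rnorm(121), 11)
  got_w <- ssim(z, zz, ssim_config(window = "gaussian", window_size = 11,
                                   sigma = 1e6))   # effectively uniform
  got_g <- ssim(z, zz, ssim_config(window = "global"))
  expect_equal(got_w, got_g, tolerance = 1e-6)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "smaller")
})

test_that("windowed SSIM matches a per-window direct computation", {
  set.seed(43)
  y <- matrix(runif(14 * 13), 14)
  z <- pmin(pmax(y + 0.1 * matrix(rnorm(14 * 13), 14), 0), 1)
  cfg <- ssim_config()
  w <- 11L; half <- 5L
  k <- dnorm(seq(-half, half), sd = 1.5); k <- k / sum(k)
  K2 <- outer(k, k)
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- c()
  for (i in 1:(14 - w + 1)) for (j in 1:(13 - w + 1)) {
    wy <- y[i:(i + w - 1), j:(j + w - 1)]
    wz <- z[i:(i + w - 1), j:(j + w - 1)]
    m1 <- sum(K2 * wy); m2 <- sum(K2 * wz)
    v1 <- sum(K2 * wy^2) - m1^2; v2 <- sum(K2 * wz^2) - m2^2
    cv <- sum(K2 * wy * wz) - m1 * m2
    vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
                ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
  }
  expect_equal(ssim(y, z, cfg), mean(vals), tolerance = 1e-10)
})

test_that("confusion counts match a brute-force per-pixel tally", {
  set.seed(44)
  K <- 3L
  pred <- matrix(sample(0:2, 64, TRUE), 8)
  ref <- matrix(sample(0:2, 64, TRUE), 8)
  cm <- confusion(pred, ref, K)
  for (k in 0:(K - 1)) {
    expect_equal(cm$TP[k + 1], sum(pred == k & ref == k))
    expect_equal(cm$FP[k + 1], sum(pred == k & ref != k))
    expect_equal(cm$FN[k + 1], sum(pred != k & ref == k))
  }
  expect_equal(cm$TP + cm$FN, as.integer(tabulate(ref + 1L, K)))
  # perfect and maximally wrong masks
  cmp <- confusion(ref, ref, K)
  expect_true(all(cmp$FP == 0) && all(cmp$FN == 0))
  cmw <- confusion((ref + 1L) %% K, ref, K)
  expect_true(all(cmw$TP == 0))
  expect_error(confusion(pred + 5L, ref, K), "range")
})

test_that("mDice and mIoU match hand tallies and mDice >= mIoU always", {
  # two-class 2x2 toy: pred (0,0,1,1), ref (0,1,1,1)
  cm <- confusion(matrix(c(0L, 0L, 1L, 1L), 1), matrix(c(0L, 1L, 1L, 1L), 1),
                  K = 2L)
  expect_equal(mdice(cm), (2 / 3 + 4 / 5) / 2)   # 11/15
  expect_equal(miou(cm), (1 / 2 + 2 / 3) / 2)
  # absent classes contribute 1
  cm0 <- confusion(matrix(0L, 2, 2), matrix(0L, 2, 2), K = 3L)
  expect_equal(mdice(cm0), 1)
  expect_equal(miou(cm0), 1)
  set.seed(45)
  for (i in 1:50) {
    p <- matrix(sample(0:2, 36, TRUE), 6)
    r <- matrix(sample(0:2, 36, TRUE), 6)
    cm <- confusion(p, r, 3L)
    expect_gte(mdice(cm), miou(cm))
  }
})

test_that("dataset evaluation aggregates as mean +/- sample sd", {
  # one image: sd is 0
  pairs1 <- list(list(target = matrix(0, 12, 12), label = matrix(0L, 4, 4)))
  outs1 <- list(list(denoised = matrix(0.1, 12, 12),
                     mask = matrix(0L, 4, 4)))
  r1 <- evaluate_dataset(pairs1, outs1)
  expect_equal(r1$sd, rep(0, nrow(r1)))
  expect_equal(r1$mean[r1$metric == "PSNR"], 20, tolerance = 1e-9)
  # two images engineered to PSNR 20 and 30: mean 25, sd 7.071
  pairs2 <- list(list(target = matrix(0, 12, 12)),
                 list(target = matrix(0, 12, 12)))
  outs2 <- list(list(denoised = matrix(0.1, 12, 12)),
                list(denoised = matrix(sqrt(0.001), 12, 12)))
  r2 <- evaluate_dataset(pairs2, outs2)
  expect_equal(r2$mean[r2$metric == "PSNR"], 25, tolerance = 1e-9)
  expect_equal(r2$sd[r2$metric == "PSNR"], sqrt(50), tolerance = 1e-4)
  expect_equal(r2$n[r2$metric == "PSNR"], 2L)
  # aggregation equals direct recomputation from the per-image values
  per <- attr(r2, "per_image")
  expect_equal(r2$mean[r2$metric == "PSNR"], mean(per$PSNR))
  expect_error(evaluate_dataset(list(), list()), "empty")
})
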
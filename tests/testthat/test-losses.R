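# Closed-form values of the denoising and segmentation losses, the content
# term against a hand-composed oracle, and the optimizer-step sanity check.

test_that("denoising loss reproduces its closed forms", {
  cfg0 <- loss_config(beta = 0, feature_extractor = feature_extractor("off"))
  I <- matrix(runif(16), 4)
  expect_equal(denoise_loss(I, I, cfg0), 0)
  # 2 x 2 patches differing by 0.1 everywhere: 4 * 0.01 = 0.04
  a <- matrix(0.5, 2, 2)
  expect_equal(denoise_loss(a, a + 0.1, cfg0), 0.04, tolerance = 1e-12)
  # alpha scales the MSE term
  cfg2 <- loss_config(alpha = 3, beta = 0,
                      feature_extractor = feature_extractor("off"))
  expect_equal(denoise_loss(a, a + 0.1, cfg2), 0.12, tolerance = 1e-12)
  expect_error(denoise_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("surrogate content loss matches a hand-composed feature oracle", {
  set.seed(31)
  fe <- feature_extractor(seed = 5)
  cfg <- loss_config(alpha = 1, beta = 0.01, feature_extractor = fe)
  I <- matrix(runif(64), 8)
  O <- matrix(runif(64), 8)
  phi <- function(img) {
    x <- array(img, c(8, 8, 1, 1))
    h <- gelu_ref(brute_conv(x, fe$params$conv1$W, fe$params$conv1$b, 1L))
    gelu_ref(brute_conv(h, fe$params$conv2$W, fe$params$conv2$b, 2L))
  }
  want <- sum((I - O)^2) + 0.01 * sum((phi(I) - phi(O))^2)
  expect_equal(denoise_loss(I, O, cfg), want, tolerance = 1e-5)
  # and the analytic gradient of the full denoising loss is correct
  g <- esdm:::denoise_loss_grad(array(I, c(8, 8, 1, 1)),
                                array(O, c(8, 8, 1, 1)), cfg)
  expect_equal(g$value, want, tolerance = 1e-5)
  fd <- num_grad(function(z) esdm:::denoise_loss_grad(
    array(I, c(8, 8, 1, 1)), z, cfg)$value,
    array(O, c(8, 8, 1, 1)), h = 1e-6)
  expect_lt(max_rel_err(g$dout, fd), 1e-4)
})

test_that("segmentation loss reproduces its closed forms", {
  H <- 4L; W <- 3L; K <- 3L
  soft <- encode_soft_labels(matrix(sample(0:2, H * W, TRUE), H, W), 0.95, K)
  unif <- array(1 / 3, c(H, W, K))
  # uniform prediction: soft weights sum to 1, so the loss is ln 3 per pixel
  expect_equal(seg_loss(unif, soft), log(3), tolerance = 1e-12)
  # prediction equal to the soft label: the entropy of (0.95, 0.025, 0.025)
  ent <- -(0.95 * log(0.95) + 2 * 0.025 * log(0.025))
  expect_equal(seg_loss(soft, soft), ent, tolerance = 1e-12)
  # single pixel, hand arithmetic
  p1 <- array(c(0.8, 0.1, 0.1), c(1, 1, 3))
  y1 <- array(c(0.95, 0.025, 0.025), c(1, 1, 3))
  expect_equal(seg_loss(p1, y1),
               -(0.95 * log(0.8) + 0.025 * log(0.1) + 0.025 * log(0.1)),
               tolerance = 1e-12)
  expect_error(seg_loss(-p1, y1), "negative")
  # the expected loss is minimized when the prediction equals the soft label
  set.seed(32)
  for (i in 1:20) {
    q <- runif(3); q <- q / sum(q)
    expect_gte(seg_loss(array(q, c(1, 1, 3)), y1), seg_loss(y1, y1))
  }
})

test_that("the combined loss is the plain sum of its terms", {
  expect_equal(combined_loss(0, 0), 0)
  expect_equal(combined_loss(1.25, 0.5), 1.75)
  # disabling a decoder zeroes exactly that term
  set.seed(33)
  entry <- phantom_entry(seed = 11, n_frames = 2)
  ds <- make_dataset(list(entry), crop_spec(32, 32, 0), split = c(1, 0, 0))
  b <- esdm:::pairs_to_batch(ds$train, 1:2, 3L)
  lc <- loss_config(feature_extractor = feature_extractor("off"), beta = 0)
  both <- esdm:::esdm_loss_grads(esdm_model(tiny_config(), 1), b, lc,
                                 want_grads = FALSE)
  den <- esdm:::esdm_loss_grads(
    esdm_model(tiny_config(enable_seg_decoder = FALSE), 1), b, lc,
    want_grads = FALSE)
  seg <- esdm:::esdm_loss_grads(
    esdm_model(tiny_config(enable_denoise_decoder = FALSE), 1), b, lc,
    want_grads = FALSE)
  expect_equal(den$Lseg, 0)
  expect_equal(seg$LD, 0)
  expect_equal(both$Lc, both$LD + both$Lseg)
})

test_that("one small optimizer step decreases the combined loss on a fixed batch", {
  set.seed(34)
  entry <- phantom_entry(seed = 12, n_frames = 2)
  ds <- make_dataset(list(entry), crop_spec(32, 32, 0), split = c(1, 0, 0))
  b <- esdm:::pairs_to_batch(ds$train, 1:2, 3L)
  lc <- loss_config()
  m0 <- esdm_model(tiny_config(), init_seed = 2)
  r0 <- esdm:::esdm_loss_grads(m0, b, lc)
  # a gradient step decreases the loss once the step is small enough
  decreased <- FALSE
  for (lr in 10^-(4:8)) {
    m <- m0
    for (nm in names(r0$grads))
      m$params[[nm]] <- m$params[[nm]] - lr * r0$grads[[nm]]
    r1 <- esdm:::esdm_loss_grads(m, b, lc, want_grads = FALSE)
    if (r1$Lc < r0$Lc) { decreased <- TRUE; break }
  }
  expect_true(decreased)
})
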
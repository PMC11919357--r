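# The network building blocks against hand-built oracles, the shape and
# determinism contracts of every architecture variant, and the parameter
# accounting.

test_that("Q/K/V projection with identity weights flattens the input row-major", {
  set.seed(21)
  H <- 4L; W <- 3L; C <- 2L
  x <- array(rnorm(H * W * C), c(H, W, C))
  proj <- sct_projection_params(C, seed = 1)
  ident <- list(pw = list(W = diag(C), b = numeric(C)),
                dw = list(W = array(0, c(3, 3, C)), b = numeric(C)))
  ident$dw$W[2, 2, ] <- 1   # centred delta kernel
  proj$q <- ident; proj$k <- ident; proj$v <- ident
  s <- sct_qkv_projection(x, proj)
  flat <- matrix(0, H * W, C)
  for (h in seq_len(H)) for (w in seq_len(W))
    flat[(h - 1L) * W + w, ] <- x[h, w, ]   # row-major token order
  expect_equal(s$Q, flat)
  expect_equal(s$K, flat)
  expect_equal(s$V, flat)
})

test_that("Q/K/V projection matches a direct convolution oracle", {
  set.seed(22)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  proj <- sct_projection_params(2L, seed = 3)
  s <- sct_qkv_projection(x, proj)
  xa <- array(x, c(4, 4, 2, 1))
  for (nm in c("q", "k", "v")) {
    p <- proj[[nm]]
    Wc <- array(0, c(1, 1, 2, 2)); Wc[1, 1, , ] <- p$pw$W
    h1 <- brute_conv(xa, Wc, p$pw$b, 1L)
    h2 <- brute_dwconv(h1, p$dw$W, p$dw$b)
    flat <- matrix(0, 16, 2)
    for (h in 1:4) for (w in 1:4) flat[(h - 1) * 4 + w, ] <- h2[h, w, , 1]
    expect_lt(max_rel_err(s[[toupper(substr(nm, 1, 1))]], flat), 1e-6)
  }
})

test_that("constant input gives constant Q/K/V away from the borders", {
  x <- array(0.6, c(5, 5, 3))
  s <- sct_qkv_projection(x, sct_projection_params(3L, seed = 4))
  interior <- as.vector(outer(2:4, 2:4, function(h, w) (h - 1L) * 5L + w))
  for (m in s) {
    sub <- m[interior, , drop = FALSE]
    expect_lt(max(abs(sweep(sub, 2, sub[1, ]))), 1e-12)
  }
})

test_that("multi-head self-attention obeys its closed-form special cases", {
  set.seed(23)
  # single token: attention weight 1, output equals (projected) V
  Q <- matrix(rnorm(4), 1); K <- matrix(rnorm(4), 1); V <- matrix(rnorm(4), 1)
  out <- multi_head_self_attention(Q, K, V, heads = 2L)
  expect_equal(unclass(out), V, ignore_attr = TRUE)
  # identical keys: uniform attention = per-head row-mean of V
  Tn <- 6L; C <- 4L
  Q2 <- matrix(rnorm(Tn * C), Tn)
  K2 <- matrix(rep(rnorm(C), each = Tn), Tn)
  V2 <- matrix(rnorm(Tn * C), Tn)
  out2 <- multi_head_self_attention(Q2, K2, V2, heads = 2L)
  expect_equal(unclass(out2),
               matrix(rep(colMeans(V2), each = Tn), Tn),
               tolerance = 1e-12, ignore_attr = TRUE)
  # two tokens, one head, hand-computed softmax((QK')/sqrt(2)) V
  Q3 <- matrix(c(1, 0, 0.5, -1), 2); K3 <- matrix(c(0.2, 1, -0.3, 0.4), 2)
  V3 <- matrix(c(1, 2, 3, 4), 2)
  S <- Q3 %*% t(K3) / sqrt(2)
  A <- exp(S) / rowSums(exp(S))
  expect_equal(unclass(multi_head_self_attention(Q3, K3, V3, heads = 1L)),
               A %*% V3, tolerance = 1e-12, ignore_attr = TRUE)
  # attention rows always sum to one
  att <- attr(multi_head_self_attention(Q2, K2, V2, heads = 2L), "attention")
  expect_lt(max(abs(apply(att, c(1, 3), sum) - 1)), 1e-5)
  expect_gte(min(att), 0)
  expect_error(multi_head_self_attention(Q2, K2, V2, heads = 3L),
               "divisible")
})

test_that("DW-FFN matches its composed-convolution oracle and contracts", {
  set.seed(24)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  p <- dw_ffn_params(2L, seed = 5)
  got <- dw_ffn(x, p)
  expect_equal(dim(got), dim(x))
  xa <- array(x, c(4, 4, 2, 1))
  W1 <- array(0, c(1, 1, 2, 8)); W1[1, 1, , ] <- p$pw1$W
  W2 <- array(0, c(1, 1, 8, 2)); W2[1, 1, , ] <- p$pw2$W
  want <- brute_conv(gelu_ref(brute_dwconv(brute_conv(xa, W1, p$pw1$b),
                                           p$dw$W, p$dw$b)),
                     W2, p$pw2$b)
  expect_lt(max_rel_err(got, want[, , , 1]), 1e-6)
  # zero input with zero biases maps to zero
  p0 <- p
  p0$pw1$b[] <- 0; p0$dw$b[] <- 0; p0$pw2$b[] <- 0
  expect_equal(max(abs(dw_ffn(array(0, c(3, 3, 2)), p0))), 0)
})

test_that("SE block gates lie in (0,1) and match a hand-composed oracle", {
  set.seed(25)
  x <- array(rnorm(5 * 4 * 8), c(5, 4, 8))
  p <- se_block_params(8L, seed = 6)
  got <- se_block(x, p)
  gate <- attr(got, "gate")
  expect_true(all(gate > 0 & gate < 1))
  expect_true(all(abs(got) <= abs(x) + 1e-12))
  g <- apply(x, 3, mean)
  z <- as.vector(t(p$W1) %*% g + p$b1)
  a <- z * pnorm(z)
  u <- as.vector(t(p$W2) %*% a + p$b2)
  want <- x * rep(1 / (1 + exp(-u)), each = 20)
  expect_lt(max_rel_err(unclass(got), want), 1e-6)
  # zero input with zero biases: gate 0.5, output 0
  p0 <- p; p0$b1[] <- 0; p0$b2[] <- 0
  out0 <- se_block(array(0, c(3, 3, 8)), p0)
  expect_equal(attr(out0, "gate"), rep(0.5, 8))
  expect_equal(max(abs(out0)), 0)
  expect_error(se_block_params(4L, reduction = 8L), "reduction")
})

test_that("linear decoder block is a per-pixel operator matching its oracle", {
  set.seed(26)
  x <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  p <- linear_decoder_params(4L, seed = 7)
  got <- linear_decoder_block(x, p)
  expect_equal(dim(got), dim(x))
  ln_ref <- function(v, g, b) {
    mu <- mean(v); s <- sqrt(mean((v - mu)^2) + 1e-5)
    (v - mu) / s * g + b
  }
  for (h in 1:2) for (w in 1:2) {
    v <- x[h, w, ]
    want <- as.vector(t(p$lp2$W) %*%
                        gelu_ref(ln_ref(as.vector(t(p$lp1$W) %*% v + p$lp1$b),
                                        p$ln$gamma, p$ln$beta)) + p$lp2$b)
    expect_lt(max_rel_err(got[h, w, ], want), 1e-6)
  }
  # permuting pixel positions permutes outputs identically
  xp <- x[, 2:1, , drop = FALSE]
  expect_equal(unclass(linear_decoder_block(xp, p)),
               unclass(got[, 2:1, , drop = FALSE]))
  expect_error(linear_decoder_block(array(0, c(2, 2, 3)),
                                    linear_decoder_params(4L)), "even")
})

test_that("every architecture variant honours its forward shape contract", {
  set.seed(27)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  variants <- list(
    list(),
    list(enable_denoise_decoder = FALSE),
    list(enable_seg_decoder = FALSE),
    list(use_se = FALSE),
    list(use_skip = FALSE, use_se = FALSE))
  for (v in variants) {
    cfg <- do.call(esdm_config, c(v, list(
      filter_sizes = c(8L, 16L, 32L, 64L, 64L), sct_counts = c(1L, 1L, 1L),
      heads = c(2L, 2L, 2L), input_shape = c(64L, 64L, 1L))))
    m <- esdm_model(cfg, init_seed = 1)
    out <- esdm:::forward_esdm(m, x)
    if (cfg$enable_denoise_decoder)
      expect_equal(dim(out$denoised), c(64L, 64L, 1L, 2L))
    else expect_null(out$denoised)
    if (cfg$enable_seg_decoder) {
      expect_equal(dim(out$logits), c(64L, 64L, 3L, 2L))
      expect_true(all(is.finite(out$logits)))
    } else expect_null(out$logits)
  }
  expect_error(esdm_config(enable_denoise_decoder = FALSE,
                           enable_seg_decoder = FALSE), "decoder")
  expect_error(esdm_config(input_shape = c(100L, 100L, 1L)), "divisible")
  expect_error(esdm_config(heads = c(3L, 8L, 8L)), "divisible")
})

test_that("forward pass is deterministic given fixed weights and input", {
  set.seed(28)
  m <- esdm_model(tiny_config(), init_seed = 9)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(esdm:::forward_esdm(m, x), esdm:::forward_esdm(m, x))
  m2 <- esdm_model(tiny_config(), init_seed = 9)
  expect_identical(m$params, m2$params)
})

test_that("parameter accounting is additive across components and variants", {
  count <- function(...) count_parameters(
    esdm_model(esdm_config(...)))$trainable_parameters
  multi <- count_parameters(esdm_model(esdm_config()))
  expect_equal(sum(unlist(multi$per_component)), multi$trainable_parameters)
  seg_only <- count(enable_denoise_decoder = FALSE)
  recon_only <- count(enable_seg_decoder = FALSE)
  # seg-only omits all denoising weights, so it is strictly smaller
  expect_lt(seg_only, multi$trainable_parameters)
  # multi-task = denoise-only + the segmentation decoder, exactly
  expect_identical(multi$trainable_parameters - recon_only,
                   multi$per_component$seg_decoder)
  # SE gates add exactly their own weights (ablation delta)
  no_se <- count(use_se = FALSE)
  expect_identical(multi$trainable_parameters - no_se, 22300L)
})
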
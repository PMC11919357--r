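# The efficient segmentation-denoising network (ESDM): a shared five-stage
# encoder (two strided conv blocks, then three separable-convolutional-
# transformer stages), a deconvolution denoising decoder whose skip
# connections are gated by squeeze-and-excitation blocks, and a lightweight
# bilinear + linear-projection segmentation decoder.

#' Model configuration
#'
#' Defines an ESDM build: the per-stage filter sizes, the number of SCT
#' (separable convolutional transformer) blocks and attention heads in stages
#' 3-5, the decoder/fusion ablation flags and the number of segmentation
#' classes.  The defaults reproduce the full multi-task network; the ablation
#' variants (single-task, no squeeze-and-excitation, no skip connections,
#' scaled filter sizes) are all reachable through these arguments alone.
#'
#' @param filter_sizes Integer vector of five per-stage channel counts
#'   (default `c(32, 64, 128, 256, 256)`).
#' @param sct_counts Number of SCT blocks in stages 3-5 (default `c(1, 2, 2)`).
#' @param heads Attention heads in stages 3-5 (default `c(4, 8, 8)`); each
#'   stage's channel count must be divisible by its head count.
#' @param input_shape `c(H, W, channels)`; H and W must be divisible by 32
#'   (the total downsampling factor of the five encoder stages).
#' @param enable_denoise_decoder,enable_seg_decoder Decoder flags; at least
#'   one must be `TRUE`.
#' @param use_skip Fuse encoder features into the denoising decoder through
#'   skip connections (projection + addition).
#' @param use_se Gate each skip connection with a squeeze-and-excitation
#'   block (only meaningful when `use_skip` is `TRUE`).
#' @param n_classes Number of segmentation classes (default 3: background,
#'   epithelium, stroma).
#' @return An object of class `esdm_config`.
#' @export
esdm_config <- function(filter_sizes = c(32L, 64L, 128L, 256L, 256L),
                        sct_counts = c(1L, 2L, 2L),
                        heads = c(4L, 8L, 8L),
                        input_shape = c(256L, 256L, 1L),
                        enable_denoise_decoder = TRUE,
                        enable_seg_decoder = TRUE,
                        use_skip = TRUE,
                        use_se = TRUE,
                        n_classes = 3L) {
  filter_sizes <- as.integer(filter_sizes)
  sct_counts <- as.integer(sct_counts)
  heads <- as.integer(heads)
  input_shape <- as.integer(input_shape)
  stopifnot(length(filter_sizes) == 5L, all(filter_sizes > 0L),
            length(sct_counts) == 3L, all(sct_counts >= 1L),
            length(heads) == 3L, all(heads >= 1L),
            length(input_shape) == 3L, n_classes >= 2L)
  if (any(filter_sizes[3:5] %% heads != 0L))
    stop("stage channel counts ", paste(filter_sizes[3:5], collapse = "/"),
         " must be divisible by their head counts ",
         paste(heads, collapse = "/"))
  if (any(input_shape[1:2] %% 32L != 0L))
    stop("input height and width must be divisible by 32 (got ",
         input_shape[1L], " x ", input_shape[2L], ")")
  if (!enable_denoise_decoder && !enable_seg_decoder)
    stop("at least one decoder must be enabled")
  if (filter_sizes[1L] %% 2L != 0L)
    stop("the first filter size must be even")
  if (use_skip && use_se && filter_sizes[1L] < 8L)
    stop("squeeze-and-excitation with reduction 8 needs filter sizes >= 8")
  structure(list(filter_sizes = filter_sizes, sct_counts = sct_counts,
                 heads = heads, input_shape = input_shape,
                 enable_denoise_decoder = enable_denoise_decoder,
                 enable_seg_decoder = enable_seg_decoder,
                 use_skip = use_skip, use_se = use_se,
                 n_classes = as.integer(n_classes)),
            class = "esdm_config")
}

# decoder stage channel plans derived from the filter sizes
esdm_plan <- function(cfg) {
  f <- cfg$filter_sizes
  list(dch = c(f[4L], f[4L], f[3L], f[2L], f[2L]),  # denoise decoder, coarse to fine
       enc_skip = c(f[4L], f[3L], f[2L], f[1L]),    # encoder features fused at stages 1-4
       sch = c(f[4L], f[3L], f[2L], f[2L], f[1L]))  # segmentation decoder widths
}

# ---- parameter construction ------------------------------------------------

esdm_init_params <- function(cfg) {
  f <- cfg$filter_sizes; K <- cfg$n_classes
  plan <- esdm_plan(cfg)
  P <- list()
  put <- function(prefix, vals) {
    for (nm in names(vals)) P[[paste0(prefix, ".", nm)]] <<- vals[[nm]]
  }
  conv_block <- function(pre, cin, cout) {
    c1 <- nn_init_conv(3L, cin, cout); c2 <- nn_init_conv(3L, cout, cout)
    l1 <- nn_init_ln(cout); l2 <- nn_init_ln(cout)
    put(pre, list(conv1.W = c1$W, conv1.b = c1$b,
                  ln1.gamma = l1$gamma, ln1.beta = l1$beta,
                  conv2.W = c2$W, conv2.b = c2$b,
                  ln2.gamma = l2$gamma, ln2.beta = l2$beta))
  }
  sct_block <- function(pre, C) {
    l1 <- nn_init_ln(C); l2 <- nn_init_ln(C)
    put(pre, list(ln1.gamma = l1$gamma, ln1.beta = l1$beta))
    for (s in c("q", "k", "v")) {
      pw <- nn_init_dense(C, C); dw <- nn_init_dw(3L, C)
      put(pre, stats::setNames(list(pw$W, pw$b, dw$W, dw$b),
                               paste0(s, c(".pw.W", ".pw.b", ".dw.W", ".dw.b"))))
    }
    pj <- nn_init_dense(C, C)
    f1 <- nn_init_dense(C, 4L * C); fd <- nn_init_dw(3L, 4L * C)
    f2 <- nn_init_dense(4L * C, C)
    put(pre, list(proj.W = pj$W, proj.b = pj$b,
                  ln2.gamma = l2$gamma, ln2.beta = l2$beta,
                  ffn.pw1.W = f1$W, ffn.pw1.b = f1$b,
                  ffn.dw.W = fd$W, ffn.dw.b = fd$b,
                  ffn.pw2.W = f2$W, ffn.pw2.b = f2$b))
  }
  # shared encoder
  conv_block("enc.stage1", cfg$input_shape[3L], f[1L])
  conv_block("enc.stage2", f[1L], f[2L])
  for (st in 3:5) {
    C <- f[st]
    em <- nn_init_conv(3L, f[st - 1L], C); el <- nn_init_ln(C)
    put(paste0("enc.stage", st, ".embed"),
        list(conv.W = em$W, conv.b = em$b,
             ln.gamma = el$gamma, ln.beta = el$beta))
    for (j in seq_len(cfg$sct_counts[st - 2L]))
      sct_block(paste0("enc.stage", st, ".block", j), C)
  }
  # denoising decoder
  if (cfg$enable_denoise_decoder) {
    prev <- f[5L]
    for (i in 1:5) {
      cout <- plan$dch[i]
      pre <- paste0("dec.stage", i)
      dc <- nn_init_deconv(3L, cout, prev); l1 <- nn_init_ln(cout)
      put(pre, list(deconv.W = dc$W, deconv.b = dc$b,
                    ln1.gamma = l1$gamma, ln1.beta = l1$beta))
      if (i <= 4L && cfg$use_skip) {
        ce <- plan$enc_skip[i]
        if (cfg$use_se) {
          cr <- max(1L, ce %/% 8L)
          s1 <- nn_init_dense(ce, cr); s2 <- nn_init_dense(cr, ce)
          put(pre, list(se.W1 = s1$W, se.b1 = s1$b,
                        se.W2 = s2$W, se.b2 = s2$b))
        }
        pj <- nn_init_dense(ce, cout)
        put(pre, list(proj.W = pj$W, proj.b = pj$b))
      }
      cv <- nn_init_conv(3L, cout, cout); l2 <- nn_init_ln(cout)
      put(pre, list(conv.W = cv$W, conv.b = cv$b,
                    ln2.gamma = l2$gamma, ln2.beta = l2$beta))
      prev <- cout
    }
    hd <- nn_init_conv(3L, plan$dch[5L], 1L)
    put("dec.head", list(W = hd$W, b = hd$b))
  }
  # segmentation decoder
  if (cfg$enable_seg_decoder) {
    prev <- f[5L]
    for (i in 1:5) {
      cout <- plan$sch[i]
      p1 <- nn_init_dense(prev, cout %/% 2L)
      ln <- nn_init_ln(cout %/% 2L)
      p2 <- nn_init_dense(cout %/% 2L, cout)
      put(paste0("seg.stage", i),
          list(lp1.W = p1$W, lp1.b = p1$b,
               ln.gamma = ln$gamma, ln.beta = ln$beta,
               lp2.W = p2$W, lp2.b = p2$b))
      prev <- cout
    }
    hd <- nn_init_conv(3L, plan$sch[5L], K)
    put("seg.head", list(W = hd$W, b = hd$b))
  }
  P
}

#' Build a segmentation-denoising model
#'
#' Instantiates the multi-task network described by an [esdm_config()] with
#' Glorot-uniform initial weights.  The returned object is untrained; fit it
#' with [esdm_train()] or inspect its complexity with [count_parameters()].
#'
#' @param config An [esdm_config()].
#' @param init_seed Integer seed for the weight initialization; identical
#'   seeds give bit-identical weights.
#' @return An object of class `esdm`.
#' @export
esdm_model <- function(config = esdm_config(), init_seed = 1L) {
  stopifnot(inherits(config, "esdm_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(init_seed))
  params <- esdm_init_params(config)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(params = params, config = config,
                 init_seed = as.integer(init_seed),
                 trained = FALSE, manifest = NULL),
            class = "esdm")
}

#' @rdname esdm_model
#' @export
build_model <- function(config = esdm_config(), init_seed = 1L) {
  esdm_model(config, init_seed)
}

# ---- forward pass ----------------------------------------------------------

fwd_convblock <- function(x, P, pre, keep) {
  c1 <- nn_conv_fwd(x, P[[paste0(pre, ".conv1.W")]],
                    P[[paste0(pre, ".conv1.b")]], 2L, keep)
  l1 <- nn_ln_fwd(c1$y, P[[paste0(pre, ".ln1.gamma")]],
                  P[[paste0(pre, ".ln1.beta")]], keep = keep)
  g1 <- nn_gelu_fwd(l1$y, keep)
  c2 <- nn_conv_fwd(g1$y, P[[paste0(pre, ".conv2.W")]],
                    P[[paste0(pre, ".conv2.b")]], 1L, keep)
  l2 <- nn_ln_fwd(c2$y, P[[paste0(pre, ".ln2.gamma")]],
                  P[[paste0(pre, ".ln2.beta")]], keep = keep)
  g2 <- nn_gelu_fwd(l2$y, keep)
  list(y = g2$y, cache = if (keep) list(c1 = c1$cache, l1 = l1$cache,
                                        g1 = g1$cache, c2 = c2$cache,
                                        l2 = l2$cache, g2 = g2$cache))
}

bwd_convblock <- function(dy, P, pre, cache, acc) {
  d <- nn_gelu_bwd(dy, cache$g2)
  lb <- nn_ln_bwd(d, cache$l2)
  acc(paste0(pre, ".ln2.gamma"), lb$dgamma)
  acc(paste0(pre, ".ln2.beta"), lb$dbeta)
  cb <- nn_conv_bwd(lb$dx, cache$c2)
  acc(paste0(pre, ".conv2.W"), cb$dW); acc(paste0(pre, ".conv2.b"), cb$db)
  d <- nn_gelu_bwd(cb$dx, cache$g1)
  lb <- nn_ln_bwd(d, cache$l1)
  acc(paste0(pre, ".ln1.gamma"), lb$dgamma)
  acc(paste0(pre, ".ln1.beta"), lb$dbeta)
  cb <- nn_conv_bwd(lb$dx, cache$c1)
  acc(paste0(pre, ".conv1.W"), cb$dW); acc(paste0(pre, ".conv1.b"), cb$db)
  cb$dx
}

fwd_sct <- function(x, P, pre, heads, keep) {
  g <- function(s) P[[paste0(pre, ".", s)]]
  l1 <- nn_ln_fwd(x, g("ln1.gamma"), g("ln1.beta"), keep = keep)
  br <- list()
  seqs <- list()
  for (s in c("q", "k", "v")) {
    pw <- nn_pw_fwd(l1$y, g(paste0(s, ".pw.W")), g(paste0(s, ".pw.b")), keep)
    dw <- nn_dwconv_fwd(pw$y, g(paste0(s, ".dw.W")), g(paste0(s, ".dw.b")),
                        keep = keep)
    br[[s]] <- list(pw = pw$cache, dw = dw$cache)
    seqs[[s]] <- dw$y
  }
  at <- nn_attn_fwd(seqs$q, seqs$k, seqs$v, heads, keep)
  pj <- nn_pw_fwd(at$y, g("proj.W"), g("proj.b"), keep)
  x2 <- x + pj$y
  l2 <- nn_ln_fwd(x2, g("ln2.gamma"), g("ln2.beta"), keep = keep)
  f1 <- nn_pw_fwd(l2$y, g("ffn.pw1.W"), g("ffn.pw1.b"), keep)
  fd <- nn_dwconv_fwd(f1$y, g("ffn.dw.W"), g("ffn.dw.b"), keep = keep)
  fg <- nn_gelu_fwd(fd$y, keep)
  f2 <- nn_pw_fwd(fg$y, g("ffn.pw2.W"), g("ffn.pw2.b"), keep)
  list(y = x2 + f2$y,
       cache = if (keep) list(l1 = l1$cache, br = br, at = at$cache,
                              pj = pj$cache, l2 = l2$cache, f1 = f1$cache,
                              fd = fd$cache, fg = fg$cache, f2 = f2$cache))
}

bwd_sct <- function(dy, P, pre, cache, acc) {
  nm <- function(s) paste0(pre, ".", s)
  f2b <- nn_pw_bwd(dy, cache$f2)
  acc(nm("ffn.pw2.W"), f2b$dW); acc(nm("ffn.pw2.b"), f2b$db)
  dg <- nn_gelu_bwd(f2b$dx, cache$fg)
  fdb <- nn_dwconv_bwd(dg, cache$fd)
  acc(nm("ffn.dw.W"), fdb$dW); acc(nm("ffn.dw.b"), fdb$db)
  f1b <- nn_pw_bwd(fdb$dx, cache$f1)
  acc(nm("ffn.pw1.W"), f1b$dW); acc(nm("ffn.pw1.b"), f1b$db)
  l2b <- nn_ln_bwd(f1b$dx, cache$l2)
  acc(nm("ln2.gamma"), l2b$dgamma); acc(nm("ln2.beta"), l2b$dbeta)
  dx2 <- dy + l2b$dx
  pjb <- nn_pw_bwd(dx2, cache$pj)
  acc(nm("proj.W"), pjb$dW); acc(nm("proj.b"), pjb$db)
  ab <- nn_attn_bwd(pjb$dx, cache$at)
  dl1 <- 0
  for (s in c("q", "k", "v")) {
    dseq <- ab[[paste0("d", s)]]
    dwb <- nn_dwconv_bwd(dseq, cache$br[[s]]$dw)
    acc(nm(paste0(s, ".dw.W")), dwb$dW)
    acc(nm(paste0(s, ".dw.b")), dwb$db)
    pwb <- nn_pw_bwd(dwb$dx, cache$br[[s]]$pw)
    acc(nm(paste0(s, ".pw.W")), pwb$dW)
    acc(nm(paste0(s, ".pw.b")), pwb$db)
    dl1 <- dl1 + pwb$dx
  }
  l1b <- nn_ln_bwd(dl1, cache$l1)
  acc(nm("ln1.gamma"), l1b$dgamma); acc(nm("ln1.beta"), l1b$dbeta)
  dx2 + l1b$dx
}

#' Forward pass of the network
#'
#' @param model An `esdm` object.
#' @param x Input batch: an `H x W x N` or `H x W x 1 x N` array of
#'   grayscale intensities.
#' @param train Keep the intermediate activations needed for a backward pass.
#' @return A list with `denoised` (`H x W x 1 x N`, linear output),
#'   `logits` (`H x W x K x N`) and, when `train = TRUE`, `cache`.
#' @keywords internal
forward_esdm <- function(model, x, train = FALSE) {
  cfg <- model$config; P <- model$params
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3L])
  if (is.null(dim(x)) && is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  keep <- train
  cache <- list()
  s1 <- fwd_convblock(x, P, "enc.stage1", keep)
  s2 <- fwd_convblock(s1$y, P, "enc.stage2", keep)
  cache$s1 <- s1$cache; cache$s2 <- s2$cache
  e <- s2$y
  enc_out <- list()
  cache$st <- list()
  for (st in 3:5) {
    pre <- paste0("enc.stage", st)
    em <- nn_conv_fwd(e, P[[paste0(pre, ".embed.conv.W")]],
                      P[[paste0(pre, ".embed.conv.b")]], 2L, keep)
    el <- nn_ln_fwd(em$y, P[[paste0(pre, ".embed.ln.gamma")]],
                    P[[paste0(pre, ".embed.ln.beta")]], keep = keep)
    e <- el$y
    blocks <- list()
    for (j in seq_len(cfg$sct_counts[st - 2L])) {
      bl <- fwd_sct(e, P, paste0(pre, ".block", j), cfg$heads[st - 2L], keep)
      e <- bl$y
      blocks[[j]] <- bl$cache
    }
    cache$st[[st - 2L]] <- list(em = em$cache, el = el$cache, blocks = blocks)
    enc_out[[st - 2L]] <- e
  }
  skips <- list(s1$y, s2$y, enc_out[[1L]], enc_out[[2L]])
  b5 <- enc_out[[3L]]

  denoised <- NULL
  if (cfg$enable_denoise_decoder) {
    plan <- esdm_plan(cfg)
    d <- b5
    cache$dec <- list()
    for (i in 1:5) {
      pre <- paste0("dec.stage", i)
      dc <- nn_deconv_fwd(d, P[[paste0(pre, ".deconv.W")]],
                          P[[paste0(pre, ".deconv.b")]], 2L, keep)
      l1 <- nn_ln_fwd(dc$y, P[[paste0(pre, ".ln1.gamma")]],
                      P[[paste0(pre, ".ln1.beta")]], keep = keep)
      g1 <- nn_gelu_fwd(l1$y, keep)
      d <- g1$y
      sc <- NULL
      if (i <= 4L && cfg$use_skip) {
        s_enc <- skips[[5L - i]]
        sc <- list()
        if (cfg$use_se) {
          se <- nn_se_fwd(s_enc, P[[paste0(pre, ".se.W1")]],
                          P[[paste0(pre, ".se.b1")]],
                          P[[paste0(pre, ".se.W2")]],
                          P[[paste0(pre, ".se.b2")]], keep)
          sc$se <- se$cache
          s_enc <- se$y
        }
        pj <- nn_pw_fwd(s_enc, P[[paste0(pre, ".proj.W")]],
                        P[[paste0(pre, ".proj.b")]], keep)
        sc$pj <- pj$cache
        d <- d + pj$y
      }
      cv <- nn_conv_fwd(d, P[[paste0(pre, ".conv.W")]],
                        P[[paste0(pre, ".conv.b")]], 1L, keep)
      l2 <- nn_ln_fwd(cv$y, P[[paste0(pre, ".ln2.gamma")]],
                      P[[paste0(pre, ".ln2.beta")]], keep = keep)
      g2 <- nn_gelu_fwd(l2$y, keep)
      d <- g2$y
      cache$dec[[i]] <- list(dc = dc$cache, l1 = l1$cache, g1 = g1$cache,
                             sc = sc, cv = cv$cache, l2 = l2$cache,
                             g2 = g2$cache)
    }
    hd <- nn_conv_fwd(d, P[["dec.head.W"]], P[["dec.head.b"]], 1L, keep)
    cache$dec_head <- hd$cache
    denoised <- hd$y
  }

  logits <- NULL
  if (cfg$enable_seg_decoder) {
    g <- b5
    cache$seg <- list()
    for (i in 1:5) {
      pre <- paste0("seg.stage", i)
      up <- nn_up2_fwd(g, keep)
      p1 <- nn_pw_fwd(up$y, P[[paste0(pre, ".lp1.W")]],
                      P[[paste0(pre, ".lp1.b")]], keep)
      ln <- nn_ln_fwd(p1$y, P[[paste0(pre, ".ln.gamma")]],
                      P[[paste0(pre, ".ln.beta")]], keep = keep)
      ga <- nn_gelu_fwd(ln$y, keep)
      p2 <- nn_pw_fwd(ga$y, P[[paste0(pre, ".lp2.W")]],
                      P[[paste0(pre, ".lp2.b")]], keep)
      g <- p2$y
      cache$seg[[i]] <- list(up = up$cache, p1 = p1$cache, ln = ln$cache,
                             ga = ga$cache, p2 = p2$cache)
    }
    hd <- nn_conv_fwd(g, P[["seg.head.W"]], P[["seg.head.b"]], 1L, keep)
    cache$seg_head <- hd$cache
    logits <- hd$y
  }
  list(denoised = denoised, logits = logits,
       cache = if (train) cache)
}

#' Backward pass: gradients of a scalar loss with respect to all weights
#'
#' @param model An `esdm` object.
#' @param cache Cache from `forward_esdm(..., train = TRUE)`.
#' @param dden Gradient w.r.t. the denoised output (or `NULL`).
#' @param dlogits Gradient w.r.t. the segmentation logits (or `NULL`).
#' @return Named list of gradients matching `model$params`.
#' @keywords internal
backward_esdm <- function(model, cache, dden = NULL, dlogits = NULL) {
  cfg <- model$config; P <- model$params
  genv <- new.env(parent = emptyenv())
  acc <- function(name, val) {
    cur <- genv[[name]]
    genv[[name]] <- if (is.null(cur)) val else cur + val
  }
  db5 <- 0
  dskips <- list(0, 0, 0, 0)

  if (cfg$enable_seg_decoder && !is.null(dlogits)) {
    hb <- nn_conv_bwd(dlogits, cache$seg_head)
    acc("seg.head.W", hb$dW); acc("seg.head.b", hb$db)
    dg <- hb$dx
    for (i in 5:1) {
      pre <- paste0("seg.stage", i)
      cc <- cache$seg[[i]]
      p2b <- nn_pw_bwd(dg, cc$p2)
      acc(paste0(pre, ".lp2.W"), p2b$dW); acc(paste0(pre, ".lp2.b"), p2b$db)
      dga <- nn_gelu_bwd(p2b$dx, cc$ga)
      lnb <- nn_ln_bwd(dga, cc$ln)
      acc(paste0(pre, ".ln.gamma"), lnb$dgamma)
      acc(paste0(pre, ".ln.beta"), lnb$dbeta)
      p1b <- nn_pw_bwd(lnb$dx, cc$p1)
      acc(paste0(pre, ".lp1.W"), p1b$dW); acc(paste0(pre, ".lp1.b"), p1b$db)
      dg <- nn_up2_bwd(p1b$dx, cc$up)
    }
    db5 <- db5 + dg
  }

  if (cfg$enable_denoise_decoder && !is.null(dden)) {
    hb <- nn_conv_bwd(dden, cache$dec_head)
    acc("dec.head.W", hb$dW); acc("dec.head.b", hb$db)
    dd <- hb$dx
    for (i in 5:1) {
      pre <- paste0("dec.stage", i)
      cc <- cache$dec[[i]]
      d2 <- nn_gelu_bwd(dd, cc$g2)
      l2b <- nn_ln_bwd(d2, cc$l2)
      acc(paste0(pre, ".ln2.gamma"), l2b$dgamma)
      acc(paste0(pre, ".ln2.beta"), l2b$dbeta)
      cvb <- nn_conv_bwd(l2b$dx, cc$cv)
      acc(paste0(pre, ".conv.W"), cvb$dW); acc(paste0(pre, ".conv.b"), cvb$db)
      dd <- cvb$dx
      if (!is.null(cc$sc)) {
        pjb <- nn_pw_bwd(dd, cc$sc$pj)
        acc(paste0(pre, ".proj.W"), pjb$dW)
        acc(paste0(pre, ".proj.b"), pjb$db)
        dskip <- pjb$dx
        if (!is.null(cc$sc$se)) {
          seb <- nn_se_bwd(dskip, cc$sc$se)
          acc(paste0(pre, ".se.W1"), seb$dW1); acc(paste0(pre, ".se.b1"), seb$db1)
          acc(paste0(pre, ".se.W2"), seb$dW2); acc(paste0(pre, ".se.b2"), seb$db2)
          dskip <- seb$dx
        }
        dskips[[5L - i]] <- dskips[[5L - i]] + dskip
      }
      d1 <- nn_gelu_bwd(dd, cc$g1)
      l1b <- nn_ln_bwd(d1, cc$l1)
      acc(paste0(pre, ".ln1.gamma"), l1b$dgamma)
      acc(paste0(pre, ".ln1.beta"), l1b$dbeta)
      dcb <- nn_deconv_bwd(l1b$dx, cc$dc)
      acc(paste0(pre, ".deconv.W"), dcb$dW)
      acc(paste0(pre, ".deconv.b"), dcb$db)
      dd <- dcb$dx
    }
    db5 <- db5 + dd
  }

  # encoder backward: stage 5 input is the stage-4 output (also skip 4), etc.
  de <- db5
  for (st in 5:3) {
    pre <- paste0("enc.stage", st)
    cc <- cache$st[[st - 2L]]
    for (j in rev(seq_along(cc$blocks)))
      de <- bwd_sct(de, P, paste0(pre, ".block", j), cc$blocks[[j]], acc)
    elb <- nn_ln_bwd(de, cc$el)
    acc(paste0(pre, ".embed.ln.gamma"), elb$dgamma)
    acc(paste0(pre, ".embed.ln.beta"), elb$dbeta)
    emb <- nn_conv_bwd(elb$dx, cc$em)
    acc(paste0(pre, ".embed.conv.W"), emb$dW)
    acc(paste0(pre, ".embed.conv.b"), emb$db)
    de <- emb$dx
    if (st > 3L) de <- de + dskips[[st - 1L]]  # skip from stage (st-1) output
  }
  ds2 <- de + dskips[[2L]]
  ds1 <- bwd_convblock(ds2, P, "enc.stage2", cache$s2, acc) + dskips[[1L]]
  bwd_convblock(ds1, P, "enc.stage1", cache$s1, acc)
  grads <- as.list(genv)
  grads[names(model$params)[!names(model$params) %in% names(grads)]] <- NULL
  grads
}

# ---- complexity ------------------------------------------------------------

esdm_component_of <- function(name) {
  if (startsWith(name, "enc.")) "encoder"
  else if (startsWith(name, "dec.")) "denoise_decoder"
  else "seg_decoder"
}

# multiply-accumulate count of one forward pass
esdm_macs <- function(cfg) {
  f <- cfg$filter_sizes; K <- cfg$n_classes
  H <- cfg$input_shape[1L]; W <- cfg$input_shape[2L]
  plan <- esdm_plan(cfg)
  conv <- function(k, cin, cout, h, w) k * k * cin * cout * h * w
  dwm <- function(k, c, h, w) k * k * c * h * w
  enc <- 0
  hh <- H; ww <- W
  cin <- cfg$input_shape[3L]
  for (st in 1:2) {
    hh <- hh %/% 2L; ww <- ww %/% 2L
    enc <- enc + conv(3, cin, f[st], hh, ww) + conv(3, f[st], f[st], hh, ww)
    cin <- f[st]
  }
  for (st in 3:5) {
    hh <- hh %/% 2L; ww <- ww %/% 2L
    C <- f[st]
    enc <- enc + conv(3, cin, C, hh, ww)
    Tn <- hh * ww
    per_block <- 3 * (C * C * Tn + dwm(3, C, hh, ww)) +  # QKV projections
      2 * Tn * Tn * C +                                  # QK' and AV
      C * C * Tn +                                       # output projection
      4 * C * C * Tn + dwm(3, 4 * C, hh, ww) + 4 * C * C * Tn  # DW-FFN
    enc <- enc + cfg$sct_counts[st - 2L] * per_block
    cin <- C
  }
  den <- 0
  if (cfg$enable_denoise_decoder) {
    prev <- f[5L]
    hh <- H %/% 32L; ww <- W %/% 32L
    for (i in 1:5) {
      hh <- hh * 2L; ww <- ww * 2L
      cout <- plan$dch[i]
      den <- den + conv(3, prev, cout, hh, ww)
      if (i <= 4L && cfg$use_skip) {
        ce <- plan$enc_skip[i]
        if (cfg$use_se) den <- den + 2 * ce * max(1L, ce %/% 8L)
        den <- den + ce * cout * hh * ww
      }
      den <- den + conv(3, cout, cout, hh, ww)
      prev <- cout
    }
    den <- den + conv(3, plan$dch[5L], 1, H, W)
  }
  seg <- 0
  if (cfg$enable_seg_decoder) {
    prev <- f[5L]
    hh <- H %/% 32L; ww <- W %/% 32L
    for (i in 1:5) {
      hh <- hh * 2L; ww <- ww * 2L
      cout <- plan$sch[i]
      seg <- seg + 4 * prev * hh * ww +                 # bilinear interpolation
        prev * (cout %/% 2L) * hh * ww + (cout %/% 2L) * cout * hh * ww
      prev <- cout
    }
    seg <- seg + conv(3, plan$sch[5L], K, H, W)
  }
  list(encoder = enc, denoise_decoder = den, seg_decoder = seg,
       total = enc + den + seg)
}

#' Count trainable parameters and estimate complexity
#'
#' Tallies every trainable weight of the model, broken down into shared
#' encoder, denoising decoder (including skip projections and
#' squeeze-and-excitation gates) and segmentation decoder, and estimates the
#' multiply-accumulate (MAC) count of one forward pass at the configured
#' input shape.  FLOPs are reported as two floating-point operations per MAC;
#' this convention is stated in the report.
#'
#' @param model An `esdm` object.
#' @return An object of class `esdm_complexity`: a list with
#'   `trainable_parameters`, `millions`, `per_component`, `macs`, `flops`,
#'   `flops_convention` and `input_shape`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "esdm"))
  sizes <- vapply(model$params, length, integer(1L))
  comp <- vapply(names(sizes), esdm_component_of, character(1L))
  per <- tapply(sizes, comp, sum)
  per <- as.list(per[order(match(names(per), c("encoder", "denoise_decoder",
                                               "seg_decoder")))])
  total <- sum(sizes)
  macs <- esdm_macs(model$config)
  structure(list(trainable_parameters = total,
                 millions = round(total / 1e6, 3L),
                 per_component = per,
                 macs = macs$total,
                 flops = 2 * macs$total,
                 macs_per_component = macs[c("encoder", "denoise_decoder",
                                             "seg_decoder")],
                 flops_convention = "1 multiply-add = 2 FLOPs",
                 input_shape = model$config$input_shape),
            class = "esdm_complexity")
}

#' @export
print.esdm_complexity <- function(x, ...) {
  cat("Model complexity (input ",
      paste(x$input_shape, collapse = " x "), ")\n", sep = "")
  cat(sprintf("  trainable parameters: %s (%.3f M)\n",
              format(x$trainable_parameters, big.mark = ","), x$millions))
  for (nm in names(x$per_component))
    cat(sprintf("    %-16s %s\n", nm,
                format(x$per_component[[nm]], big.mark = ",")))
  cat(sprintf("  MACs: %.2f G; FLOPs: %.2f G (%s)\n",
              x$macs / 1e9, x$flops / 1e9, x$flops_convention))
  invisible(x)
}

#' @export
print.esdm_config <- function(x, ...) {
  cat("ESDM configuration\n")
  cat("  filter sizes:", paste(x$filter_sizes, collapse = ", "), "\n")
  cat("  SCT blocks (stages 3-5):", paste(x$sct_counts, collapse = ", "),
      "with heads", paste(x$heads, collapse = ", "), "\n")
  cat("  input:", paste(x$input_shape, collapse = " x "),
      "| classes:", x$n_classes, "\n")
  cat("  decoders:",
      if (x$enable_denoise_decoder) "denoising" else NULL,
      if (x$enable_seg_decoder) "segmentation" else NULL, "\n")
  cat("  skip connections:", x$use_skip, "| SE gating:", x$use_se, "\n")
  invisible(x)
}

#' @export
print.esdm <- function(x, ...) {
  cat(if (x$trained) "Trained" else "Untrained",
      "segmentation-denoising model\n")
  print(x$config)
  cp <- count_parameters(x)
  cat(sprintf("  %.3f M trainable parameters\n", cp$millions))
  if (!is.null(x$manifest) && length(x$manifest$trajectory$epoch)) {
    tr <- x$manifest$trajectory
    cat(sprintf("  trained %d epochs; best validation loss %.5f (epoch %d)\n",
                max(tr$epoch), x$manifest$best_val_loss,
                x$manifest$best_epoch))
  }
  invisible(x)
}

#' @export
summary.esdm <- function(object, ...) {
  print(object)
  print(count_parameters(object))
  invisible(object)
}

#' @export
coef.esdm <- function(object, ...) object$params
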
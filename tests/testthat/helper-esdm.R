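# Shared fixtures: tiny model configurations, small phantoms, numeric
# gradients and brute-force convolution oracles (independent nested-loop
# implementations used to cross-check the vectorized code).

tiny_config <- function(...) {
  esdm_config(filter_sizes = c(8L, 8L, 8L, 8L, 8L),
              sct_counts = c(1L, 1L, 1L), heads = c(2L, 2L, 2L),
              input_shape = c(32L, 32L, 1L), ...)
}

small_phantom_config <- function(seed = 1L, ...) {
  defaults <- list(width = 64L, depth = 64L, n_frames = 4L,
                   n_repetitions = 4L, surface_depth_mean = 12,
                   epithelium_thickness_mean = 20, boundary_amplitude = 2,
                   boundary_smoothness = 10, seed = seed)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# one training-volume entry for make_dataset(), built from a phantom
phantom_entry <- function(seed = 1L, n_frames = 4L, jitter = 2,
                          flip_rate = 0.02, ...) {
  ph <- generate_phantom(small_phantom_config(seed, n_frames = n_frames, ...))
  teacher <- teacher_oracle(jitter = jitter, flip_rate = flip_rate,
                            seed = seed)
  avg <- frame_average(ph$volume)
  Fn <- dim(ph$masks$labels)[1L]
  pseudo <- array(0L, dim(ph$masks$labels))
  for (f in seq_len(Fn))
    pseudo[f, , ] <- pseudo_label(teacher, ph$masks$labels[f, , ],
                                  avg[f, , ], frame_index = f)
  list(noisy = ph$volume, averaged = avg, pseudo_masks = pseudo,
       manual_mask = ph$masks$labels[1L, , ], id = paste0("phantom", seed),
       phantom = ph)
}

# central-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

max_rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))

# direct nested-loop 2D convolution, same padding, stride 1 or 2
brute_conv <- function(x, W, b, stride = 1L) {
  d <- dim(x); k <- dim(W)[1L]; Co <- dim(W)[4L]
  Ho <- ceiling(d[1L] / stride); Wo <- ceiling(d[2L] / stride)
  padh <- if (stride == 1L) (k - 1L) %/% 2L else
    max((Ho - 1L) * stride + k - d[1L], 0L) %/% 2L
  y <- array(0, c(Ho, Wo, Co, d[4L]))
  for (n in seq_len(d[4L])) for (co in seq_len(Co))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      s <- b[co]
      for (ci in seq_len(d[3L])) for (dy in seq_len(k)) for (dx in seq_len(k)) {
        hh <- (ho - 1L) * stride - padh + dy
        ww <- (wo - 1L) * stride - padh + dx
        if (hh >= 1L && hh <= d[1L] && ww >= 1L && ww <= d[2L])
          s <- s + x[hh, ww, ci, n] * W[dy, dx, ci, co]
      }
      y[ho, wo, co, n] <- s
    }
  y
}

# direct depth-wise 3x3 convolution, stride 1, same padding
brute_dwconv <- function(x, W, b) {
  d <- dim(x)
  y <- array(0, d)
  for (n in seq_len(d[4L])) for (c in seq_len(d[3L]))
    for (h in seq_len(d[1L])) for (w in seq_len(d[2L])) {
      s <- b[c]
      for (dy in 1:3) for (dx in 1:3) {
        hh <- h + dy - 2L; ww <- w + dx - 2L
        if (hh >= 1L && hh <= d[1L] && ww >= 1L && ww <= d[2L])
          s <- s + x[hh, ww, c, n] * W[dy, dx, c]
      }
      y[h, w, c, n] <- s
    }
  y
}

gelu_ref <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))

rand_arr <- function(...) array(rnorm(prod(c(...))), c(...))
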
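# The speckle phantom: determinism, degenerate noise, geometry, the
# thickness oracle and the 1/NR frame-averaging variance law.

test_that("identical seeds give bit-identical phantoms", {
  a <- generate_phantom(small_phantom_config(seed = 42))
  b <- generate_phantom(small_phantom_config(seed = 42))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$masks$labels, b$masks$labels)
  c <- generate_phantom(small_phantom_config(seed = 43))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("infinite speckle shape collapses every repetition onto the noise-free image", {
  ph <- generate_phantom(small_phantom_config(seed = 1,
                                              speckle_shape = Inf))
  for (f in 1:2) for (r in seq_len(dim(ph$volume$data)[2]))
    expect_equal(ph$volume$data[f, r, , ], ph$noise_free[f, , ])
})

test_that("flat boundaries give the configured epithelium pixel count on every A-line", {
  ph <- generate_phantom(small_phantom_config(
    seed = 2, boundary_amplitude = 0, epithelium_thickness_mean = 40,
    depth = 96))
  counts <- apply(ph$masks$labels == 1L, 1, colSums)
  expect_true(all(counts == 40L))
  # and the thickness oracle agrees
  expect_true(all(true_thickness_profile(ph$masks) == 40))
})

test_that("thickness oracle equals a brute-force per-column count on random boundaries", {
  ph <- generate_phantom(small_phantom_config(seed = 3,
                                              boundary_amplitude = 4))
  prof <- true_thickness_profile(ph$masks)
  d <- dim(ph$masks$labels)
  for (f in seq_len(d[1])) for (x in seq_len(d[3])) {
    n <- 0L
    for (z in seq_len(d[2])) if (ph$masks$labels[f, z, x] == 1L) n <- n + 1L
    expect_equal(prof[f, x], if (n > 0L) n else NA_real_)
  }
  # boundary curves reproduce the label transitions exactly
  for (f in seq_len(d[1])) {
    cur <- ph$masks$boundary_curves[[f]]
    expect_equal(colSums(ph$masks$labels[f, , ] == 0L),
                 as.numeric(cur$surface))
    expect_equal(colSums(ph$masks$labels[f, , ] != 2L),
                 as.numeric(cur$interface))
  }
})

test_that("a mask without epithelium yields an all-missing profile", {
  labels <- array(0L, c(1, 8, 6))
  labels[1, 5:8, ] <- 2L
  prof <- true_thickness_profile(layer_mask_volume(labels))
  expect_true(all(is.na(prof)))
  expect_true(is.nan(mean(prof, na.rm = FALSE)) || is.na(mean(prof)))
})

test_that("label transitions coincide with reflectivity transitions of the noise-free image", {
  ph <- generate_phantom(small_phantom_config(seed = 4, noise_floor = 0,
                                              attenuation = c(0, 0, 0)))
  refl <- small_phantom_config()$layer_reflectivity
  for (f in 1:2) {
    img <- ph$noise_free[f, , ]
    lab <- ph$masks$labels[f, , ]
    expect_equal(img, matrix(as.numeric(refl[lab + 1L]), nrow(img)))
  }
})

test_that("pixel variance of the NR-repetition mean follows the 1/NR speckle law", {
  # low reflectivity keeps clipping negligible so the gamma law is clean
  cfg <- phantom_config(width = 128, depth = 128, n_frames = 1,
                        n_repetitions = 32, surface_depth_mean = 12,
                        epithelium_thickness_mean = 40,
                        boundary_amplitude = 0, boundary_smoothness = 10,
                        layer_reflectivity = c(0.05, 0.15, 0.25),
                        attenuation = c(0, 0, 0), speckle_shape = 4,
                        noise_floor = 0, seed = 7)
  ph <- generate_phantom(cfg)
  reps <- ph$volume$data[1, , , ]            # 32 x Z x X
  tissue <- ph$masks$labels[1, , ] > 0L      # >= 1e4 tissue pixels
  expect_gt(sum(tissue), 1e4)
  v <- 1 / cfg$speckle_shape
  i0 <- ph$noise_free[1, , ]
  # single-repetition pixel variance matches v * I0^2 within 10%
  pixvar <- apply(reps, c(2, 3), var)
  expect_lt(abs(mean(pixvar[tissue]) / mean((v * i0^2)[tissue]) - 1), 0.1)
  # variance of the r-repetition mean scales as 1/r
  base <- mean(apply(reps[1:8, , ], c(2, 3), var)[tissue])
  for (r in c(2, 4, 8)) {
    groups <- matrix(seq_len(32), nrow = r)   # disjoint groups of r reps
    means <- apply(groups, 2, function(g) apply(reps[g, , ], c(2, 3), mean))
    dim(means) <- c(dim(i0), ncol(groups))
    vr <- mean(apply(means, c(1, 2), var)[tissue])
    expect_lt(abs(vr / (base / r) - 1), 0.1)
  }
})

test_that("geometrically infeasible configurations are rejected", {
  expect_error(phantom_config(depth = 64, surface_depth_mean = 40,
                              epithelium_thickness_mean = 30))
  expect_error(generate_phantom(small_phantom_config(
    boundary_amplitude = 30)), "boundaries")
})
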
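test_that("median filter: constants, isolated impulses, and agreement with a direct median", {
  # constant plane unchanged
  const <- fluorescence_stack(array(7, c(2, 8, 8)))
  expect_equal(median_filter_3x3(const)$voxels, const$voxels)

  # single isolated impulse in a constant plane is replaced by the constant
  v <- array(5, c(1, 9, 9)); v[1, 4, 6] <- 1000
  f <- median_filter_3x3(fluorescence_stack(v))
  expect_true(all(f$voxels == 5))

  # oracle: brute-force median over each 3x3 window with edge-replicated padding
  set.seed(7)
  m <- matrix(runif(20 * 24), 20, 24)
  f2 <- median_filter_3x3(array(m, c(1, 20, 24)))$voxels[1, , ]
  mp <- m[c(1, 1:20, 20), c(1, 1:24, 24)]
  ref <- matrix(0, 20, 24)
  for (i in 1:20) for (j in 1:24) ref[i, j] <- median(mp[i:(i + 2), j:(j + 2)])
  expect_equal(f2, ref)

  expect_error(median_filter_3x3(array(1, c(4, 2, 8))), class = "otc_invalid_input")
})

test_that("median filter reduces impulse-noise error against the clean phantom", {
  ph <- generate_fluorescence_stack(
    stack_phantom_spec(c(8, 48, 48), n_nuclei = 15, n_vessels = 2,
                       impulse_fraction = 0.01, background = 100, seed = 21))
  mae_before <- mean(abs(ph$nuclei$voxels - ph$nuclei_clean$voxels))
  filtered <- median_filter_3x3(ph$nuclei)
  mae_after <- mean(abs(filtered$voxels - ph$nuclei_clean$voxels))
  expect_lt(mae_after, mae_before)

  # idempotence on an impulse-corrupted constant volume
  v <- array(50, c(2, 32, 32))
  set.seed(3)
  idx <- sample(length(v), 10)
  v[idx] <- 5000
  once <- median_filter_3x3(fluorescence_stack(v))
  twice <- median_filter_3x3(once)
  expect_equal(twice$voxels, once$voxels)
})

test_that("destriping: neutral on stripe-free planes, kills the stripe band, keeps the mean", {
  # constant plane: energy only at DC, unchanged up to FFT roundoff
  const <- fluorescence_stack(array(40, c(2, 16, 16)))
  out <- remove_stripes(const, destripe_params("x", 2, 1))
  expect_lt(max(abs(out$voxels - 40)) / 40, 1e-6)

  ph <- generate_fluorescence_stack(
    stack_phantom_spec(c(6, 64, 64), n_nuclei = 10, n_vessels = 2,
                       stripe_axis = "x", stripe_amplitude = 0.2,
                       stripe_period_px = 8, background = 100, seed = 13))
  par <- destripe_params("x", 2, 1)
  out2 <- remove_stripes(ph$nuclei, par)
  for (z in 1:6) {
    before <- stripe_band_energy(ph$nuclei$voxels[z, , ], "x", 2)
    after <- stripe_band_energy(out2$voxels[z, , ], "x", 2)
    expect_lt(after, 0.1 * before)   # >= 90% band-energy reduction
    m0 <- mean(ph$nuclei$voxels[z, , ])
    expect_lt(abs(mean(out2$voxels[z, , ]) - m0) / m0, 0.005)  # mean preserved
  }

  # idempotence at damping 1 (on a phantom where clipping never engages:
  # stripes on a constant positive background)
  ph_c <- generate_fluorescence_stack(
    stack_phantom_spec(c(2, 64, 64), n_nuclei = 0, n_vessels = 0,
                       stripe_axis = "x", stripe_amplitude = 0.2,
                       background = 100, seed = 5))
  once <- remove_stripes(ph_c$nuclei, par)
  again <- remove_stripes(once, par)
  expect_lt(max(abs(again$voxels - once$voxels)) / max(once$voxels), 1e-6)

  # y-axis stripes are handled by the transposed notch
  ph_y <- generate_fluorescence_stack(
    stack_phantom_spec(c(2, 64, 64), n_nuclei = 5, stripe_axis = "y",
                       stripe_amplitude = 0.3, background = 80, seed = 4))
  out_y <- remove_stripes(ph_y$nuclei, destripe_params("y", 2, 1))
  expect_lt(stripe_band_energy(out_y$voxels[1, , ], "y", 2),
            0.1 * stripe_band_energy(ph_y$nuclei$voxels[1, , ], "y", 2))

  # shape preserved, values finite and nonnegative
  expect_equal(dim(out2$voxels), dim(ph$nuclei$voxels))
  expect_true(all(is.finite(out2$voxels)) && all(out2$voxels >= 0))
})

test_that("linear contrast adjustment maps the chosen percentiles to the output range", {
  v <- array(seq(0, 100, length.out = 4 * 5 * 5), c(4, 5, 5))
  st <- fluorescence_stack(v)

  # (0, 100): pure max-normalization
  full <- adjust_contrast_linear(st, 0, 100)
  expect_equal(full$voxels, v / 100, tolerance = 1e-12)

  # values at or above the median saturate when high = 50
  half <- adjust_contrast_linear(st, 0, 50)
  med <- unname(quantile(v, 0.5))
  expect_true(all(half$voxels[v >= med] == 1))
  expect_true(all(half$voxels[v < med] < 1))

  # custom output maximum for 16-bit export
  scaled <- adjust_contrast_linear(st, 0, 100, max_out = 65535)
  expect_equal(max(scaled$voxels), 65535)

  expect_error(adjust_contrast_linear(fluorescence_stack(array(3, c(2, 4, 4)))),
               class = "otc_degenerate_range")
  expect_error(adjust_contrast_linear(st, 50, 50), class = "otc_invalid_input")
})

test_that("maximum-intensity projection matches the brute-force per-ray maximum", {
  # identical planes: projection along z is that plane
  plane <- matrix(runif(6 * 7), 6, 7)
  st <- fluorescence_stack(array(rep(plane, each = 4), c(4, 6, 7)))
  expect_equal(max_intensity_projection(st, "z"), plane)

  # one-hot voxel
  v <- array(0, c(3, 5, 6)); v[2, 4, 5] <- 9
  mz <- max_intensity_projection(v, "z")
  expect_equal(which(mz != 0), 4L + (5L - 1L) * 5L)  # (row 4, col 5) of a 5 x 6 matrix
  expect_equal(mz[4, 5], 9)

  # random volume vs explicit loops, all three axes
  set.seed(8)
  r <- array(runif(4 * 5 * 6), c(4, 5, 6))
  for (ax in 1:3) {
    got <- max_intensity_projection(r, ax)
    other <- setdiff(1:3, ax)
    ref <- matrix(0, dim(r)[other[1]], dim(r)[other[2]])
    for (i in seq_len(dim(r)[other[1]])) for (j in seq_len(dim(r)[other[2]])) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[other[1]]] <- i; idx[[other[2]]] <- j
      ref[i, j] <- max(do.call(`[`, c(list(r), idx)))
    }
    expect_equal(got, ref)
  }

  # vessel phantom: projection nonzero exactly where a tube crosses the ray
  ph <- generate_fluorescence_stack(
    stack_phantom_spec(c(8, 32, 32), n_nuclei = 0, n_vessels = 2, seed = 6))
  proj <- max_intensity_projection(ph$vessels_clean, "z")
  brute <- apply(ph$vessels_clean$voxels, c(2, 3), max)
  expect_equal(proj, brute)
  expect_true(any(proj > 0))
})

test_that("process_stack applies median -> destripe -> contrast in order", {
  ph <- generate_fluorescence_stack(
    stack_phantom_spec(c(4, 32, 32), n_nuclei = 8, stripe_amplitude = 0.2,
                       impulse_fraction = 0.01, background = 60, seed = 17))
  manual <- adjust_contrast_linear(
    remove_stripes(median_filter_3x3(ph$nuclei), destripe_params("x")),
    1, 99.8)
  piped <- process_stack(ph$nuclei, median = TRUE,
                         destripe = destripe_params("x"), contrast = c(1, 99.8))
  expect_equal(piped$voxels, manual$voxels)
})
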
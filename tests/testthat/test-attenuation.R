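test_that("region_mu matches the closed-form inversion and handles identity", {
  # identical images: mu = 0 whatever L
  img <- matrix(runif(64 * 64, 50, 150), 64, 64)
  pair <- transmittance_pair(img, img, thickness_mm = 3.7)
  expect_equal(region_mu(pair, region_spec(0, 0, 64, 64))$mu, 0)

  # uniform blank 200, sample 200 e^-3, L = 1.5 -> mu = 2
  pair2 <- transmittance_pair(matrix(200, 10, 10), matrix(200 * exp(-3), 10, 10), 1.5)
  expect_equal(region_mu(pair2, region_spec(2, 3, 4, 5))$mu, 2, tolerance = 1e-12)

  # noise-free mu = 0 phantom at L = 2
  p0 <- clean_pair(mu = 0, L = 2, illum = 100)
  expect_lt(abs(region_mu(p0, region_spec(5, 5, 20, 20))$mu), 1e-12)
})

test_that("region_mu agrees with a brute-force per-pixel computation on random regions", {
  set.seed(42)
  p <- noisy_pair(h = 96, w = 120, mu = 1.2, L = 2, seed = 9)
  for (i in 1:100) {
    rh <- sample(1:40, 1); rw <- sample(1:40, 1)
    r0 <- sample(0:(96 - rh), 1); c0 <- sample(0:(120 - rw), 1)
    # independent oracle: explicit loops over the region pixels
    sb <- 0; ss <- 0
    for (dr in seq_len(rh)) for (dc in seq_len(rw)) {
      sb <- sb + p$blank_image[r0 + dr, c0 + dc]
      ss <- ss + p$sample_image[r0 + dr, c0 + dc]
    }
    expected <- log((sb / (rh * rw)) / (ss / (rh * rw))) / p$thickness_mm
    got <- region_mu(p, region_spec(r0, c0, rh, rw))
    expect_equal(got$mu, expected, tolerance = 1e-12)
    expect_equal(got$mean_blank, sb / (rh * rw), tolerance = 1e-12)
  }
})

test_that("region_mu error contracts: bounds and degenerate regions", {
  p <- clean_pair()
  expect_error(region_mu(p, region_spec(60, 0, 10, 10)), class = "otc_region_out_of_bounds")
  expect_error(region_mu(p, region_spec(0, 60, 10, 10)), class = "otc_region_out_of_bounds")
  dark <- transmittance_pair(matrix(100, 8, 8), matrix(0, 8, 8), 1)
  expect_error(region_mu(dark, region_spec(0, 0, 8, 8)), class = "otc_degenerate_region")
})

test_that("sample_regions: sizes from the fraction, bounds, determinism, rounding", {
  # 1000 x 1000 at defaults: three 150 x 150 regions inside bounds
  regs <- with(list(), {set.seed(1); sample_regions(1000, 1000, protocol_params())})
  expect_length(regs, 3)
  for (r in regs) {
    expect_equal(r$height_px, 150L)
    expect_equal(r$width_px, 150L)
    expect_true(r$row_origin >= 0 && r$row_origin + 150 <= 1000)
    expect_true(r$col_origin >= 0 && r$col_origin + 150 <= 1000)
  }

  # half-up rounding with a 1 px floor: 10 px * 0.15 -> 2 px
  set.seed(2)
  r10 <- sample_regions(10, 10, protocol_params())[[1]]
  expect_equal(r10$height_px, 2L)
  expect_equal(r10$width_px, 2L)
  set.seed(2)
  r3 <- sample_regions(3, 3, protocol_params())[[1]]  # 0.45 px rounds to 0 -> floor 1
  expect_equal(r3$height_px, 1L)

  # area mode: side = sqrt(0.15) of each dimension
  set.seed(3)
  ra <- sample_regions(1000, 1000, protocol_params(fraction_mode = "area"))[[1]]
  expect_equal(ra$height_px, as.integer(floor(sqrt(0.15) * 1000 + 0.5)))

  # determinism under a fixed RNG state
  set.seed(99); a <- sample_regions(500, 400, protocol_params())
  set.seed(99); b <- sample_regions(500, 400, protocol_params())
  expect_identical(a, b)

  # image smaller than one region
  expect_no_error(sample_regions(4, 4, protocol_params(region_fraction = 1.0)))
  expect_error(sample_regions(0, 10, protocol_params()), class = "otc_invalid_input")
})

test_that("run_protocol yields the hierarchical count: regions x runs x images", {
  pairs <- lapply(1:3, function(i) clean_pair(seed = i, sample_id = "s1"))
  s <- run_protocol(pairs, protocol_params(seed = 4))
  expect_equal(s$n_measurements, 135L)            # 3 x 15 x 3
  expect_equal(nrow(s$measurements), 135L)
  expect_equal(s$mu_mean, mean(s$measurements$mu))
  expect_equal(s$mu_sem, sd(s$measurements$mu) / sqrt(135))
  expect_setequal(unique(s$measurements$image_index), 0:2)
  expect_setequal(unique(s$measurements$run_index), 0:14)

  # single-measurement degenerate case: sem = 0 by the n = 1 convention
  one <- run_protocol(clean_pair(), protocol_params(regions_per_run = 1, runs_per_image = 1))
  expect_equal(one$n_measurements, 1L)
  expect_equal(one$mu_mean, one$measurements$mu[1])
  expect_equal(one$mu_sem, 0)

  # non-default counts propagate multiplicatively
  s2 <- run_protocol(pairs[1:2], protocol_params(regions_per_run = 2, runs_per_image = 5))
  expect_equal(s2$n_measurements, 2L * 5L * 2L)
})

test_that("noise-free protocol recovers the true attenuation to 1e-9 for any seed", {
  pairs <- lapply(1:3, function(i) clean_pair(mu = 2, L = 1.5, vignette = 0.2,
                                              seed = i, sample_id = "s"))
  for (seed in c(1, 77, 123456)) {
    s <- run_protocol(pairs, protocol_params(seed = seed))
    expect_rel_equal(s$mu_mean, 2, 1e-9)
    expect_true(all(abs(s$measurements$mu - 2) < 2e-9))
  }
})

test_that("protocol invariances: intensity scale, thickness, ordering", {
  p <- noisy_pair(h = 128, w = 128, mu = 1, L = 2, seed = 3, sample_id = "s")
  base <- run_protocol(p, protocol_params(seed = 8))

  # multiplying both images by c > 0 leaves every mu unchanged
  p_scaled <- transmittance_pair(p$blank_image * 3.7, p$sample_image * 3.7,
                                 p$thickness_mm, "s", p$condition)
  s_scaled <- run_protocol(p_scaled, protocol_params(seed = 8))
  expect_equal(s_scaled$measurements$mu, base$measurements$mu, tolerance = 1e-12)

  # replacing L by 2L halves every mu exactly
  p_thick <- transmittance_pair(p$blank_image, p$sample_image,
                                2 * p$thickness_mm, "s", p$condition)
  s_thick <- run_protocol(p_thick, protocol_params(seed = 8))
  expect_equal(s_thick$measurements$mu, base$measurements$mu / 2, tolerance = 1e-12)

  # noise-free phantoms differing only in mu_true order their estimates
  lo <- run_protocol(clean_pair(mu = 0.8, sample_id = "a"), protocol_params(seed = 2))
  hi <- run_protocol(clean_pair(mu = 1.1, sample_id = "a"), protocol_params(seed = 2))
  expect_gt(hi$mu_mean, lo$mu_mean)
})

test_that("run_protocol is reproducible end to end and stable to added images", {
  pairs <- lapply(1:3, function(i) noisy_pair(h = 64, w = 64, seed = i, sample_id = "s"))
  a <- run_protocol(pairs, protocol_params(seed = 10))
  b <- run_protocol(pairs, protocol_params(seed = 10))
  expect_identical(a$measurements, b$measurements)

  # image substreams: dropping the last image leaves earlier draws intact
  ab <- run_protocol(pairs[1:2], protocol_params(seed = 10))
  expect_identical(ab$measurements,
                   a$measurements[a$measurements$image_index < 2, ])
})

test_that("run_protocol validates its inputs", {
  p1 <- clean_pair(sample_id = "a")
  p2 <- clean_pair(sample_id = "b")
  expect_error(run_protocol(list(p1, p2)), class = "otc_invalid_input")
  expect_error(run_protocol(list()), class = "otc_invalid_input")
  # all-dark image: every region degenerate -> protocol failure naming the image
  dark <- transmittance_pair(matrix(100, 32, 32), matrix(0, 32, 32), 1, "dark")
  expect_error(run_protocol(dark, protocol_params(seed = 1)),
               class = "otc_protocol_failure")
  expect_error(run_protocol(dark, protocol_params(seed = 1)), "dark")
})
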
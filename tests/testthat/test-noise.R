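# Noise magnitude, the radial NPS estimator, unit-area normalization, and
# dose-ratio percentages.

test_that("noise magnitude handles the degenerate and trivial cases", {
  st <- generate_stack(uniform_spec(n_slices = 3L,
                                    grid = test_grid(128L, 50)))
  r <- noise_magnitude(st, 64L)
  expect_equal(r$mean_sd_hu, 0)
  expect_equal(r$se_hu, 0)
  one <- generate_stack(uniform_spec(sigma = 5, n_slices = 1L,
                                     grid = test_grid(128L, 50)))
  expect_true(is.na(noise_magnitude(one, 64L)$se_hu))
  expect_error(noise_magnitude(one, 256L), "fit")
})

test_that("white-noise SD is recovered within the concentration bound", {
  st <- generate_stack(uniform_spec(sigma = 15.4, n_slices = 20L,
                                    seed = 51L))
  r <- noise_magnitude(st, 128L)
  expect_equal(r$mean_sd_hu, 15.4, tolerance = 0.02)
  expect_gt(r$se_hu, 0)
})

test_that("noise magnitude is invariant to a constant HU offset", {
  st <- generate_stack(uniform_spec(sigma = 10, n_slices = 5L, seed = 52L,
                                    grid = test_grid(128L, 50)))
  shifted <- image_stack(st$data + 100, st$pixel_spacing,
                         st$slice_thickness)
  expect_equal(noise_magnitude(shifted, 64L)$per_slice_sd,
               noise_magnitude(st, 64L)$per_slice_sd, tolerance = 1e-12)
})

test_that("white noise gives a flat radial NPS at sigma^2 * spacing^2", {
  sigma <- 18
  sp <- chunked_white_nps(sigma, 64L, 100L, 2L, seed0 = 60L)
  expected <- sigma^2 * sp$pixel_spacing^2
  # mean level across bins
  expect_equal(stats::weighted.mean(sp$nps, sp$counts), expected,
               tolerance = 0.01)
  # per-bin flatness where the Monte Carlo error is small
  well <- sp$counts >= 48L
  expect_lt(max(abs(sp$nps[well] / expected - 1)), 0.05)
  # Parseval: 2-D integral equals the pooled ROI variance
  expect_equal(sp$nps_2d_integral / sp$variance, 1, tolerance = 0.02)
})

test_that("radial binning conserves the total off-DC power exactly", {
  st <- white_stack(10, 64L, 5L, seed = 61L)
  sp <- compute_nps(st, 64L)
  df <- 1 / (64 * sp$pixel_spacing)
  expect_equal(sum(sp$nps * sp$counts) * df^2, sp$nps_2d_integral,
               tolerance = 1e-12)
  expect_true(all(sp$nps >= 0))
  expect_equal(sp$frequencies, sort(sp$frequencies))
})

test_that("a shaped noise texture round-trips through the estimator", {
  curve <- data.frame(frequency = seq(0, 1.3, by = 0.05))
  curve$value <- exp(-(curve$frequency / 0.45)^2)
  g <- test_grid(64L, 25)
  spec <- phantom_spec(g, noise = noise_model(14, "target_nps",
                                              target_curve = curve,
                                              seed = 62L),
                       n_slices = 150L, body_diameter_mm = 20)
  # pure-noise stack: strip the scene so only the texture is analyzed
  st <- generate_stack(spec)
  scene <- render_noiseless_slice(spec)
  st$data <- st$data - as.vector(scene)
  sp <- compute_nps(st, 64L)
  target <- stats::approx(curve$frequency, curve$value,
                          xout = sp$frequencies, rule = 2)$y
  well <- sp$counts >= 24L & target > 0.05
  ratio <- sp$nps[well] / target[well]
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.10)
})

test_that("normalized NPS integrates to one and is scale invariant", {
  sp <- compute_nps(white_stack(12, 64L, 100L, seed = 63L), 64L)
  expect_equal(phantomiq:::trapz(sp$frequencies, sp$normalized_nps), 1,
               tolerance = 1e-6)
  # idempotence
  twice <- normalize_nps(normalize_nps(sp))
  expect_equal(twice$normalized_nps, sp$normalized_nps, tolerance = 1e-12)
  # doubling sigma leaves the normalized shape unchanged within MC error
  sp2 <- compute_nps(white_stack(24, 64L, 100L, seed = 64L), 64L)
  well <- sp$counts >= 48L
  expect_lt(max(abs(sp2$normalized_nps[well] - sp$normalized_nps[well]) /
                  mean(sp$normalized_nps[well])), 0.1)
})

test_that("a synthetic flat spectrum normalizes to 1 / bandwidth", {
  sp <- compute_nps(white_stack(10, 64L, 2L, seed = 65L), 64L)
  sp$nps <- rep(2.5, length(sp$nps))  # impose exact flatness
  flat <- normalize_nps(sp)
  bw <- max(sp$frequencies) - min(sp$frequencies)
  expect_equal(flat$normalized_nps, rep(1 / bw, length(sp$nps)),
               tolerance = 1e-12)
})

test_that("a zero-noise stack yields a degenerate spectrum, not a division", {
  st <- generate_stack(uniform_spec(n_slices = 2L,
                                    grid = test_grid(128L, 50)))
  expect_warning(sp <- compute_nps(st, 64L), "degenerate|undefined")
  expect_true(all(sp$nps < 1e-15))
  expect_true(sp$degenerate)
  expect_true(all(is.na(sp$normalized_nps)))
  expect_error(normalize_nps(sp), "zero")
})

test_that("detrending removes a shading plane before the spectrum", {
  n <- 64L
  ramp <- outer(seq_len(n), seq_len(n), function(r, c_) 0.5 * r - 0.2 * c_)
  st <- white_stack(8, n, 4L, seed = 66L)
  st$data <- st$data + as.vector(ramp)
  flat <- compute_nps(st, n, detrend = "plane")
  biased <- compute_nps(st, n, detrend = "mean")
  expect_equal(flat$variance, 64, tolerance = 0.05)  # sigma^2 restored
  # mean detrending leaves the ramp variance (0.29 * var of the lattice
  # coordinate) on top of the noise
  ramp_var <- (0.5^2 + 0.2^2) * (n^2 - 1) / 12
  expect_equal(biased$variance, 64 + ramp_var, tolerance = 0.05)
})

test_that("dose ratios reproduce the printed percentages half-up", {
  expect_identical(dose_ratio_percent(15.6, 10.2)$percent, 153L)
  expect_identical(dose_ratio_percent(26.6, 10.2)$percent, 261L)
  expect_identical(dose_ratio_percent(16.9, 15.4)$percent, 110L)
  expect_identical(dose_ratio_percent(16.7, 15.4)$percent, 108L)
  expect_identical(dose_ratio_percent(7.3, 7.3)$percent, 100L)
  expect_identical(dose_ratio_percent(1.235, 1)$percent, 124L)  # half-up
  expect_error(dose_ratio_percent(10, 0), "> 0")
})
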
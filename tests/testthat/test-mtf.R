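# Circular-edge MTF chain: signal averaging, centre estimation, ESF/LSF
# closed forms, and f50/f10 recovery against the Gaussian ground truth.

test_that("signal averaging returns the scene and obeys the variance law", {
  g <- test_grid(128L, 50)
  st <- generate_stack(uniform_spec(n_slices = 4L, grid = g))
  expect_identical(signal_average(st), st$data[, , 1])
  # +c / -c cancellation
  scene <- render_noiseless_slice(uniform_spec(grid = g))
  two <- image_stack(array(c(scene + 7, scene - 7),
                           dim = c(dim(scene), 2L)), g$pixel_spacing)
  expect_equal(signal_average(two), scene, tolerance = 1e-12)
  # residual noise after averaging 50 slices of sigma = 20
  st <- generate_stack(uniform_spec(sigma = 20, n_slices = 50L, seed = 71L,
                                    grid = g))
  resid <- signal_average(st) - scene
  idx <- 33:96
  expect_equal(stats::sd(resid[idx, idx]), 20 / sqrt(50), tolerance = 0.05)
})

test_that("disk centres are recovered to sub-pixel accuracy", {
  g <- test_grid()
  true_ctr <- c(5.13, -3.71)
  img <- render_noiseless_slice(disk_spec(990, center = true_ctr,
                                          blur = 0.3))
  est <- estimate_disk_center(img, g$pixel_spacing, c(4.5, -3), 12)
  expect_lt(max(abs(est - true_ctr)), 0.05 * g$pixel_spacing)
  # exactly centred disk: symmetry gives the centre to numerical precision
  img0 <- render_noiseless_slice(disk_spec(990, center = c(0, 0)))
  est0 <- estimate_disk_center(img0, g$pixel_spacing, c(0.4, -0.4), 12)
  expect_lt(max(abs(est0)), 1e-9)
  # a pure-noise window must be refused, not mislocated
  noise_img <- matrix(stats::rnorm(256^2), 256, 256)
  expect_error(estimate_disk_center(noise_img, g$pixel_spacing, c(0, 0),
                                    12),
               "contrast")
})

test_that("the radial ESF follows the blurred-edge closed form", {
  sig <- 0.3
  ctr <- c(5.13, -3.71)
  spec <- disk_spec(990, center = ctr, blur = sig)
  img <- render_noiseless_slice(spec)
  esf <- radial_esf(img, spec$grid$pixel_spacing, ctr, 6)
  expect_gte(max(esf$positions), 3)
  expect_lte(min(esf$positions), -3)
  # the rendered edge is the Gaussian edge averaged over the pixel
  # aperture: box(width = pixel) convolved with Phi, via the closed form
  # integral of Phi, G(z) = z Phi(z) + phi(z)
  dx <- spec$grid$pixel_spacing
  G <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
  # curvature of the circular edge shifts the apparent edge inward by
  # sigma^2 / (2 R) (normal limit of the Rice distribution)
  p <- esf$positions + sig^2 / (2 * 6)
  model <- 990 * (sig / dx) *
    (G((-p + dx / 2) / sig) - G((-p - dx / 2) / sig))
  expect_lt(max(abs(esf$values - model)), 0.01 * 990)
  # half-amplitude at the true edge
  at0 <- stats::approx(esf$positions, esf$values, xout = 0)$y
  expect_lt(abs(at0 - 495), 0.02 * 990)
})

test_that("a sharp disk's ESF transitions within about one pixel", {
  ctr <- c(5.13, -3.71)
  spec <- disk_spec(990, center = ctr, blur = 0)
  img <- render_noiseless_slice(spec)
  esf <- radial_esf(img, spec$grid$pixel_spacing, ctr, 6)
  dx <- spec$grid$pixel_spacing
  expect_true(all(esf$values[esf$positions < -dx] > 0.95 * 990))
  expect_true(all(abs(esf$values[esf$positions > dx]) < 0.05 * 990))
})

test_that("ESF differentiation matches its closed forms", {
  # linear ramp -> constant LSF
  ramp <- structure(list(positions = seq(-3, 3, 0.1),
                         values = 50 * seq(-3, 3, 0.1), bin_width = 0.1),
                    class = "edge_spread_function")
  lsf <- esf_to_lsf(ramp)
  expect_equal(lsf$values, rep(50, length(lsf$values)), tolerance = 1e-9)
  # Gaussian CDF -> Gaussian LSF with the same sigma
  pos <- seq(-3, 3, 0.02)
  gcdf <- structure(list(positions = pos,
                         values = 990 * stats::pnorm(-pos / 0.3),
                         bin_width = 0.02),
                    class = "edge_spread_function")
  lsf <- esf_to_lsf(gcdf)
  w <- lsf$values / sum(lsf$values)
  mu <- sum(w * lsf$positions)
  s <- sqrt(sum(w * (lsf$positions - mu)^2))
  expect_equal(s, 0.3, tolerance = 0.02)
  expect_gt(sum(lsf$values) * lsf$bin_width, 0)  # oriented positive
  # flat ESF is flagged as degenerate
  flat <- structure(list(positions = pos, values = rep(5, length(pos)),
                         bin_width = 0.02),
                    class = "edge_spread_function")
  expect_error(esf_to_lsf(flat), "flat")
})

test_that("a Gaussian LSF transforms to the Gaussian MTF closed form", {
  h <- 0.0390625
  pos <- seq(-5, 5, h)
  lsf <- structure(list(positions = pos,
                        values = stats::dnorm(pos, sd = 0.3),
                        bin_width = h),
                   class = "line_spread_function")
  m <- lsf_to_mtf(lsf)
  expect_equal(m$f50, gauss_mtf_freq(0.5, 0.3), tolerance = 0.02)
  expect_equal(m$f10, gauss_mtf_freq(0.1, 0.3), tolerance = 0.02)
  expect_equal(m$mtf[1], 1)
  # curve matches exp(-2 pi^2 sigma^2 f^2) through the bulk
  keep <- m$frequencies <= 1.5
  expect_lt(max(abs(m$mtf[keep] -
                      exp(-2 * pi^2 * 0.09 * m$frequencies[keep]^2))),
            0.01)
})

test_that("an impulse LSF has unit MTF and a flat curve", {
  v <- rep(0, 101); v[51] <- 1
  m <- lsf_to_mtf(v, bin_width = 0.05, taper = "none", baseline = FALSE,
                  derivative_correction = FALSE)
  expect_true(all(abs(m$mtf - 1) < 1e-9))
  expect_true(is.na(m$f50))
})

test_that("crossing readout interpolates linearly and exactly at samples", {
  expect_equal(mtf_crossing(c(0, 0.62), c(1, 0.5), 0.5), 0.62)
  expect_equal(mtf_crossing(c(0, 1, 2), c(1, 0.6, 0.2), 0.4), 1.5)
  expect_true(is.na(mtf_crossing(c(0, 1), c(1, 0.8), 0.5)))
  # first downward crossing wins when noise lobes re-cross the level
  expect_equal(mtf_crossing(c(0, 1, 2, 3, 4), c(1, 0.4, 0.6, 0.3, 0.1),
                            0.5),
               (1 - 0.5) / (1 - 0.4))  # in the first segment, not the third
})

test_that("zero-integral LSFs are rejected", {
  expect_error(lsf_to_mtf(c(-1, 0, 1), bin_width = 0.1, baseline = FALSE),
               "integral")
})

test_that("f50 and f10 recover the Gaussian blur ground truth", {
  ctr <- c(5.13, -3.71)
  for (sig in c(0.2, 0.3, 0.5)) {
    spec <- disk_spec(990, center = ctr, blur = sig)
    m <- disk_mtf(render_noiseless_slice(spec), spec$grid$pixel_spacing,
                  radius = 6, approx_center = c(4.8, -3.4))
    expect_equal(m$f50, gauss_mtf_freq(0.5, sig), tolerance = 0.02,
                 label = sprintf("f50 at sigma %.1f", sig))
    expect_equal(m$f10, gauss_mtf_freq(0.1, sig), tolerance = 0.02,
                 label = sprintf("f10 at sigma %.1f", sig))
    expect_gt(m$f10, m$f50)
  }
})

test_that("doubling the blur halves the readout frequencies", {
  ctr <- c(5.13, -3.71)
  run <- function(sig) {
    spec <- disk_spec(990, center = ctr, blur = sig)
    disk_mtf(render_noiseless_slice(spec), spec$grid$pixel_spacing,
             radius = 6, center = ctr)
  }
  a <- run(0.25); b <- run(0.5)
  expect_equal(a$f50 / b$f50, 2, tolerance = 0.03)
  expect_equal(a$f10 / b$f10, 2, tolerance = 0.03)
})

test_that("the MTF is invariant to the disk contrast", {
  ctr <- c(5.13, -3.71)
  run <- function(hu) {
    spec <- disk_spec(hu, center = ctr, blur = 0.3)
    disk_mtf(render_noiseless_slice(spec), spec$grid$pixel_spacing,
             radius = 6, center = ctr)
  }
  hi <- run(990); lo <- run(99)
  expect_lt(max(abs(hi$mtf - lo$mtf)), 1e-6)
  expect_equal(hi$f50, lo$f50, tolerance = 1e-9)
})

test_that("replicate handling reports the across-replicate dispersion", {
  ctr <- c(5.13, -3.71)
  spec <- disk_spec(990, center = ctr, blur = 0.3)
  st <- generate_stack(spec)
  same <- mtf_with_replicates(list(st, st, st), radius = 6, center = ctr)
  expect_equal(same$f50_se, 0)
  expect_equal(same$f10_se, 0)
  single <- mtf_with_replicates(st, radius = 6, center = ctr)
  expect_true(is.na(single$f50_se))
  expect_false(is.na(single$f50))
})

test_that("signal averaging keeps the noisy readout near the noiseless one", {
  ctr <- c(5.13, -3.71)
  noiseless <- disk_mtf(render_noiseless_slice(disk_spec(990, center = ctr,
                                                         blur = 0.3)),
                        test_grid()$pixel_spacing, radius = 6, center = ctr)
  st <- generate_stack(disk_spec(990, center = ctr, blur = 0.3, sigma = 15,
                                 n_slices = 50L, seed = 81L))
  noisy <- disk_mtf(signal_average(st), st$pixel_spacing, radius = 6,
                    center = ctr)
  expect_equal(noisy$f50, noiseless$f50, tolerance = 0.03)
  expect_gt(noisy$f10, noisy$f50)
})

test_that("the Hann taper option biases a wide LSF upward (why Tukey)", {
  ctr <- c(5.13, -3.71)
  spec <- disk_spec(990, center = ctr, blur = 0.5)
  img <- render_noiseless_slice(spec)
  tk <- disk_mtf(img, spec$grid$pixel_spacing, radius = 6, center = ctr)
  hn <- disk_mtf(img, spec$grid$pixel_spacing, radius = 6, center = ctr,
                 taper = "hann")
  expect_gt(hn$f50, tk$f50)  # envelope narrows the LSF, inflating f50
})
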
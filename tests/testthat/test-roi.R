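# Rotated line-ROI measurements: sampling exactness, CT-number recovery,
# and attenuation-profile geometry.

test_that("a constant field samples to its value at every angle", {
  img <- matrix(120, 64, 64)
  for (ang in c(0, 17.3, 90, 245)) {
    p <- sample_line_profile(img, 0.5, c(1.2, -3.4), ang, 27L)
    expect_equal(p, rep(120, 27))
  }
})

test_that("axis-aligned sampling at lattice points is exact", {
  n <- 64L
  img <- matrix(stats::rnorm(n * n), n, n)
  dx <- 0.5
  # center on the pixel at row 32, col 32: x = (32 - 32.5) * dx, y likewise
  ctr <- c((32 - (n + 1) / 2) * dx, ((n + 1) / 2 - 32) * dx)
  p <- sample_line_profile(img, dx, ctr, 0, 11L)
  expect_equal(p, img[32, 32 + (-5:5)], tolerance = 1e-12)
  p90 <- sample_line_profile(img, dx, ctr, 90, 11L)
  expect_equal(p90, img[32 - (-5:5), 32], tolerance = 1e-12)
})

test_that("a linear ramp yields an arithmetic profile with slope cos(angle)", {
  n <- 128L
  dx <- 100 / 256
  xs <- (seq_len(n) - (n + 1) / 2) * dx
  img <- matrix(xs, n, n, byrow = TRUE)  # I(x, y) = x
  for (ang in c(0, 30, 135)) {
    p <- sample_line_profile(img, dx, c(0.7, 1.1), ang, 21L)
    steps <- diff(p)
    expect_equal(steps, rep(dx * cos(ang * pi / 180), 20),
                 tolerance = 1e-9)
  }
})

test_that("lines exiting the image are rejected", {
  img <- matrix(0, 32, 32)
  expect_error(sample_line_profile(img, 0.5, c(7, 0), 0, 27L), "bounds")
})

test_that("line ROI spec enforces its geometry invariants", {
  expect_error(line_roi_spec(26L), "odd")
  expect_error(line_roi_spec(27L, n_angles = 400L, angle_step = 1),
               "360")
  expect_silent(line_roi_spec(51L))
})

test_that("noiseless insert CT numbers are recovered to 0.5 HU", {
  for (hu in c(120, -35)) {
    st <- generate_stack(disk_spec(hu))
    r <- measure_ct_number(st, c(5.13, -3.71))
    expect_lt(abs(r$mean_hu - hu), 0.5)
  }
})

test_that("noisy CT-number mean and dispersion follow the sampling model", {
  st <- generate_stack(disk_spec(340, sigma = 16, n_slices = 10L,
                                 seed = 21L))
  ctr <- c(5.13, -3.71)
  # nearest-neighbour sampling reads actual pixels: grand SD ~ sigma
  rn <- measure_ct_number(st, ctr, method = "nearest")
  expect_lt(abs(rn$mean_hu - 340), 1)
  expect_equal(rn$sd_hu, 16, tolerance = 0.1)
  # bilinear sampling attenuates per-sample noise by the known factor
  # sqrt(E[((1-fr)^2 + fr^2) * ((1-fc)^2 + fc^2)]) for the sampled fractions
  rb <- measure_ct_number(st, ctr)
  cc <- phantomiq:::.line_coords(dim(st$data)[1], st$pixel_spacing, ctr,
                                 0:359, 27L)
  fr <- cc$row - floor(cc$row); fc <- cc$col - floor(cc$col)
  att <- sqrt(mean(((1 - fr)^2 + fr^2) * ((1 - fc)^2 + fc^2)))
  expect_lt(abs(rb$mean_hu - 340), 1)
  expect_equal(rb$sd_hu, 16 * att, tolerance = 0.1)
})

test_that("the sensitometry preset recovers all nominal insert values", {
  sens <- catphan_presets("sensitometry", grid_spec(512L, 200),
                          noise = noise_model(15, seed = 31L),
                          n_slices = 10L)
  st <- generate_stack(sens)
  for (ins in sens$inserts[1:3]) {
    r <- measure_ct_number(st, ins$center, insert_label = ins$label)
    # noise-determined bound: ~600 independent pixels per slice x 10 slices
    expect_lt(abs(r$mean_hu - ins$contrast_hu), 1,
              label = sprintf("CT number of '%s'", ins$label))
  }
})

test_that("the mean APC shows the disk plateau with a sharp edge", {
  st <- generate_stack(disk_spec(120))
  a <- measure_apc(st, c(5.13, -3.71))
  inside <- abs(a$positions) < 6 - st$pixel_spacing
  outside <- abs(a$positions) > 6 + st$pixel_spacing
  expect_true(all(abs(a$mean_profile[inside] - 120) < 1.5))
  expect_true(all(abs(a$mean_profile[outside]) < 1.5))
  # away from the edge the zero-noise profiles agree across angles;
  # bilinear interpolation breaks exact rotational symmetry at the edge
  off_edge <- abs(abs(a$positions) - 6) > 1
  expect_true(all(a$sd_profile[off_edge] < 1))
  expect_equal(a$positions, -rev(a$positions))
  expect_equal(a$n_profiles, 360L)
})

test_that("a blurred APC crosses half amplitude at the true edge radius", {
  st <- generate_stack(disk_spec(120, blur = 0.5))
  a <- measure_apc(st, c(5.13, -3.71))
  for (side in c(-6, 6)) {
    v <- stats::approx(a$positions, a$mean_profile, xout = side)$y
    expect_lt(abs(v - 60), 0.02 * 120,
              label = sprintf("APC at %+d mm", side))
  }
})

test_that("per-angle profiles of a symmetric scene match the mean profile", {
  spec <- disk_spec(120, center = c(0.13, -0.29), blur = 0.6)
  st <- generate_stack(spec)
  prof <- phantomiq:::.all_profiles(st, c(0.13, -0.29), line_roi_spec(51L))
  mean_prof <- rowMeans(prof[, , 1])
  dev <- sweep(prof[, , 1], 1, mean_prof)
  # interpolation error concentrates where the profile bends; stay off the
  # steepest half-millimetre around the edge
  off_edge <- abs(abs(st$pixel_spacing *
                        (seq_len(51) - 26)) - 6) > 0.5
  expect_lt(max(abs(dev[off_edge, ])), 0.01 * 120)
})

test_that("averaging more profiles shrinks the mean-profile error as 1/sqrt(n)", {
  truth <- measure_apc(generate_stack(disk_spec(120)), c(5.13, -3.71))
  sq_err <- function(n_slices, seed) {
    a <- measure_apc(generate_stack(disk_spec(120, sigma = 25,
                                              n_slices = n_slices,
                                              seed = seed)),
                     c(5.13, -3.71))
    mean((a$mean_profile - truth$mean_profile)^2)
  }
  # pool several seeds: nearby line samples overlap, so the per-position
  # errors are strongly correlated and a single realization is noisy
  seeds <- c(41L, 42L, 43L)
  rms1 <- sqrt(mean(vapply(seeds, function(s) sq_err(1L, s), numeric(1))))
  rms16 <- sqrt(mean(vapply(seeds, function(s) sq_err(16L, s),
                            numeric(1))))
  ratio <- rms1 / rms16   # factor-16 profiles: ratio ~ 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})
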
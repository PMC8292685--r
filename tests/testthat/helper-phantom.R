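# Shared fixtures: small grids that keep the standard 0.390625 mm pixel
# spacing of the full-size 1024 px / 400 mm reconstruction.

test_grid <- function(n = 256L, fov = 100) grid_spec(n, fov)

# uniform body filling most of a small grid
uniform_spec <- function(sigma = 0, n_slices = 1L, seed = 1L,
                         texture = "white", grid = test_grid(),
                         body = 0.8 * grid$field_of_view, ...) {
  phantom_spec(grid, noise = noise_model(sigma, texture, seed = seed, ...),
               n_slices = n_slices, body_diameter_mm = body)
}

# single off-lattice disk (generic sub-pixel phase) on a small grid
disk_spec <- function(contrast, diameter = 12, center = c(5.13, -3.71),
                      blur = 0, sigma = 0, n_slices = 1L, seed = 1L,
                      grid = test_grid()) {
  phantom_spec(grid,
               inserts = list(disk_insert(center, diameter, contrast,
                                          "disk")),
               blur_sigma_mm = blur,
               noise = noise_model(sigma, seed = seed),
               n_slices = n_slices,
               body_diameter_mm = 0.8 * grid$field_of_view)
}

# frequency at which a Gaussian MTF of width sigma falls to level p
gauss_mtf_freq <- function(p, sigma) sqrt(log(1 / p) / (2 * pi^2 * sigma^2))

# pure white-noise stack built directly (no scene), for estimator-only tests
white_stack <- function(sigma, n, n_slices, seed,
                        pixel_spacing = 100 / 256) {
  withr::with_seed(seed, {
    image_stack(array(stats::rnorm(n * n * n_slices, sd = sigma),
                      dim = c(n, n, n_slices)),
                pixel_spacing = pixel_spacing)
  })
}

# average spectra computed over equal-size chunks of slices (memory cap)
chunked_white_nps <- function(sigma, n, slices_per_chunk, n_chunks, seed0,
                              roi_size = n, pixel_spacing = 100 / 256) {
  sps <- lapply(seq_len(n_chunks), function(k) {
    compute_nps(white_stack(sigma, n, slices_per_chunk, seed0 + k,
                            pixel_spacing = pixel_spacing),
                roi_size = roi_size)
  })
  sp <- sps[[1]]
  sp$nps <- Reduce(`+`, lapply(sps, `[[`, "nps")) / n_chunks
  sp$variance <- mean(vapply(sps, `[[`, numeric(1), "variance"))
  sp$nps_2d_integral <- mean(vapply(sps, `[[`, numeric(1),
                                    "nps_2d_integral"))
  sp$n_realizations <- n_chunks * slices_per_chunk
  normalize_nps(sp)
}
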
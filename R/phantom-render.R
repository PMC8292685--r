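# Rendering of noiseless scenes and synthesis of noisy slice stacks.
#
# A rendered pixel is the average of the continuous scene over the pixel
# aperture. Gaussian edge blur is applied analytically to the continuous
# scene before sampling: the blurred indicator of a disk of radius R has the
# exact closed form P(chi2_2(ncp = (d/sigma)^2) <= (R/sigma)^2) at distance d
# from the disk centre. Rendering the blur this way (rather than discretely
# convolving the rasterized image) keeps the scene's true MTF exactly
# Gaussian x pixel aperture, with no aliasing of the sharp-edge spectrum.

# coverage profile of a (possibly blurred) disk as a function of the distance
# from its centre
.disk_profile <- function(d, radius, sigma) {
  if (sigma <= 0) return(as.numeric(d <= radius))
  b <- radius / sigma
  if (b > 50) {
    # large-disk asymptote of the exact form below (the Rice distribution's
    # normal limit): a Gaussian edge shifted inward by the curvature term
    # sigma^2 / (2 d), which also restores exact area conservation;
    # pchisq's noncentral series gets expensive at this scale
    return(stats::pnorm((radius - d - sigma^2 / (2 * pmax(d, sigma))) /
                          sigma))
  }
  stats::pchisq(b^2, df = 2, ncp = (d / sigma)^2)
}

# N x N matrix of per-pixel aperture-averaged coverage of one disk
.disk_coverage <- function(grid, center, radius, sigma, supersample = NULL) {
  n <- grid$matrix_size
  dx <- grid$pixel_spacing
  xs <- pixel_x(n, dx)
  ys <- pixel_y(n, dx)
  # distance from disk centre for every pixel centre
  d <- sqrt(outer(ys - center[2], xs - center[1],
                  function(a, b) a^2 + b^2))
  half_diag <- dx * sqrt(2) / 2
  band <- if (sigma > 0) 5 * sigma + half_diag + dx else half_diag
  cov <- matrix(0, n, n)
  cov[d <= radius - band] <- 1
  idx <- which(abs(d - radius) < band)
  if (!length(idx)) return(cov)
  ss <- supersample %||% (if (sigma > 0) 16L else 64L)
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * dx
  # pixel-centre coordinates of band pixels
  px <- xs[(idx - 1L) %/% n + 1L]
  py <- ys[(idx - 1L) %% n + 1L]
  acc <- numeric(length(idx))
  if (sigma > 0) {
    # tabulate the smooth profile once, then interpolate at subpixel radii
    dd <- seq(max(0, radius - band - dx), radius + band + dx, by = 0.02 * dx)
    pp <- .disk_profile(dd, radius, sigma)
    for (oy in off) {
      for (ox in off) {
        dk <- sqrt((px + ox - center[1])^2 + (py + oy - center[2])^2)
        acc <- acc + stats::approx(dd, pp, xout = dk, rule = 2)$y
      }
    }
  } else {
    r2 <- radius^2
    for (oy in off) {
      for (ox in off) {
        acc <- acc + ((px + ox - center[1])^2 + (py + oy - center[2])^2 <= r2)
      }
    }
  }
  cov[idx] <- acc / ss^2
  cov
}

#' Render the noiseless slice of a phantom specification
#'
#' Produces the 2-D HU image of the phantom scene: air (-1000 HU) outside the
#' body disk, `background_hu` inside it, plus each insert's contrast. Disk
#' edges are anti-aliased by averaging the scene over the pixel aperture
#' (supersampled area fraction); a positive `blur_sigma_mm` blurs the
#' continuous scene with an isotropic Gaussian before sampling, so the
#' rendered scene's MTF is exactly the Gaussian closed form times the
#' pixel-aperture term.
#'
#' @param spec a [phantom_spec()].
#' @return `matrix_size` x `matrix_size` numeric matrix of CT numbers (HU),
#'   row = image row (top first), column = image column (left first).
#' @examples
#' spec <- phantom_spec(grid_spec(128, 50), inserts = list(
#'   disk_insert(c(0, 0), 12, 120, "acrylic")), body_diameter_mm = 40)
#' img <- render_noiseless_slice(spec)
#' img[64, 64]   # 120 at the disk centre
#' @export
render_noiseless_slice <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a phantom_spec", call. = FALSE)
  }
  grid <- spec$grid
  img <- matrix(-1000, grid$matrix_size, grid$matrix_size)
  img <- img + (spec$background_hu + 1000) *
    .disk_coverage(grid, c(0, 0), spec$body_diameter_mm / 2,
                   spec$blur_sigma_mm)
  for (ins in spec$inserts) {
    img <- img + ins$contrast_hu *
      .disk_coverage(grid, ins$center, ins$diameter / 2, spec$blur_sigma_mm)
  }
  img
}

# one N x N noise realization; `prep` carries the precomputed filter/scale
.noise_prep <- function(noise, grid) {
  n <- grid$matrix_size
  if (noise$texture == "white" || noise$sigma_hu == 0) {
    return(list(kind = "white", scale = noise$sigma_hu))
  }
  f <- fft_freq(n, grid$pixel_spacing)
  f2 <- outer(f^2, f^2, "+")
  H <- switch(noise$texture,
    gaussian_lowpass =
      exp(-2 * pi^2 * noise$correlation_length_mm^2 * f2),
    target_nps = {
      v <- stats::approx(noise$target_curve$frequency,
                         noise$target_curve$value,
                         xout = sqrt(f2), rule = 2)$y
      h <- sqrt(pmax(v, 0))
      h[1] <- 0  # keep realizations zero-mean
      matrix(h, n, n)
    }
  )
  ms <- mean(H^2)
  if (ms <= 0) stop("noise filter has no passband", call. = FALSE)
  list(kind = "filtered", H = H, scale = noise$sigma_hu / sqrt(ms))
}

.noise_slice <- function(prep, n) {
  if (prep$scale == 0) return(matrix(0, n, n))
  w <- matrix(stats::rnorm(n * n), n, n)
  if (prep$kind == "white") return(prep$scale * w)
  prep$scale * Re(stats::fft(stats::fft(w) * prep$H, inverse = TRUE)) / n^2
}

#' Generate a noisy slice stack from a phantom specification
#'
#' Renders the noiseless scene once and adds an independent noise realization
#' per slice according to the spec's [noise_model()]. For correlated textures
#' the white field is filtered in the frequency domain (square root of the
#' target spectrum) and rescaled deterministically so the per-pixel SD equals
#' `sigma_hu` in expectation. Identical (spec, seed) pairs reproduce
#' bit-identical stacks.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional integer overriding the seed stored in the noise model.
#' @return an [image_stack()].
#' @export
generate_stack <- function(spec, seed = NULL) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a phantom_spec", call. = FALSE)
  }
  grid <- spec$grid
  n <- grid$matrix_size
  scene <- render_noiseless_slice(spec)
  prep <- .noise_prep(spec$noise, grid)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed %||% spec$noise$seed)
  data <- array(0, dim = c(n, n, spec$n_slices))
  for (k in seq_len(spec$n_slices)) {
    data[, , k] <- scene + .noise_slice(prep, n)
  }
  image_stack(data, pixel_spacing = grid$pixel_spacing,
              slice_thickness = grid$slice_thickness)
}
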
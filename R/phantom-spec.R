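# Declarative phantom descriptions: grid geometry, disk inserts, noise model,
# and the composite phantom specification that drives the renderer.

#' Reconstruction grid geometry
#'
#' Describes the reconstructed image grid. The pixel spacing is always derived
#' as `field_of_view / matrix_size`, so the default 1024-pixel, 400-mm grid
#' has a spacing of exactly 0.390625 mm.
#'
#' @param matrix_size pixels per image side (integer, >= 64).
#' @param field_of_view reconstructed field of view in mm.
#' @param slice_thickness nominal slice thickness in mm.
#' @return a `grid_spec` object.
#' @examples
#' g <- grid_spec()
#' g$pixel_spacing  # 0.390625
#' @export
grid_spec <- function(matrix_size = 1024L, field_of_view = 400,
                      slice_thickness = 0.5) {
  matrix_size <- as.integer(matrix_size)
  if (is.na(matrix_size) || matrix_size < 64L) {
    stop("`matrix_size` must be an integer >= 64", call. = FALSE)
  }
  stopifnot_scalar(field_of_view, "field_of_view", positive = TRUE)
  stopifnot_scalar(slice_thickness, "slice_thickness", positive = TRUE)
  structure(
    list(
      matrix_size = matrix_size,
      field_of_view = field_of_view,
      pixel_spacing = field_of_view / matrix_size,
      slice_thickness = slice_thickness
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, FOV %g mm (%g mm/px), slice %g mm\n",
              x$matrix_size, x$matrix_size, x$field_of_view,
              x$pixel_spacing, x$slice_thickness))
  invisible(x)
}

#' Disk insert
#'
#' A circular insert added to the uniform phantom body. Coordinates are in mm
#' from the image centre (x right, y up); `contrast_hu` is the CT-number
#' offset of the insert relative to the phantom background.
#'
#' @param center length-2 numeric, (x, y) in mm.
#' @param diameter disk diameter in mm (> 0).
#' @param contrast_hu CT-number contrast over the background (HU).
#' @param label free-text identifier used in reports and error messages.
#' @return a `disk_insert` object.
#' @export
disk_insert <- function(center, diameter, contrast_hu, label = "insert") {
  if (!is.numeric(center) || length(center) != 2L || any(!is.finite(center))) {
    stop("`center` must be a finite (x, y) pair in mm", call. = FALSE)
  }
  stopifnot_scalar(diameter, "diameter", positive = TRUE)
  stopifnot_scalar(contrast_hu, "contrast_hu")
  structure(
    list(center = as.numeric(center), diameter = diameter,
         contrast_hu = contrast_hu, label = as.character(label)),
    class = "disk_insert"
  )
}

#' Noise model
#'
#' Per-slice stochastic noise added to the noiseless scene. `sigma_hu` is the
#' target per-pixel standard deviation; the texture is either uncorrelated
#' (`"white"`), low-pass Gaussian-correlated with a correlation length in mm
#' (`"gaussian_lowpass"`), or shaped to a user-supplied radial noise power
#' spectrum (`"target_nps"`, a data frame with columns `frequency` in
#' cycles/mm and `value` >= 0). Identical (spec, seed) pairs reproduce
#' bit-identical stacks.
#'
#' @param sigma_hu target per-pixel noise SD in HU (>= 0).
#' @param texture one of `"white"`, `"gaussian_lowpass"`, `"target_nps"`.
#' @param correlation_length_mm correlation length for `"gaussian_lowpass"`.
#' @param target_curve data frame (`frequency`, `value`) for `"target_nps"`.
#' @param seed integer RNG seed.
#' @return a `noise_model` object.
#' @export
noise_model <- function(sigma_hu = 0,
                        texture = c("white", "gaussian_lowpass", "target_nps"),
                        correlation_length_mm = NULL,
                        target_curve = NULL,
                        seed = 1L) {
  texture <- match.arg(texture)
  stopifnot_scalar(sigma_hu, "sigma_hu")
  if (sigma_hu < 0) stop("`sigma_hu` must be >= 0", call. = FALSE)
  if (texture == "gaussian_lowpass") {
    if (is.null(correlation_length_mm)) {
      stop("gaussian_lowpass texture needs `correlation_length_mm`",
           call. = FALSE)
    }
    stopifnot_scalar(correlation_length_mm, "correlation_length_mm",
                     positive = TRUE)
  }
  if (texture == "target_nps") {
    if (!is.data.frame(target_curve) ||
        !all(c("frequency", "value") %in% names(target_curve))) {
      stop("target_nps texture needs `target_curve` with columns ",
           "`frequency` and `value`", call. = FALSE)
    }
    if (any(target_curve$value < 0)) {
      stop("`target_curve$value` must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(sigma_hu = sigma_hu, texture = texture,
         correlation_length_mm = correlation_length_mm,
         target_curve = target_curve, seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Phantom specification
#'
#' The complete ground-truth record for a synthetic slice stack: grid,
#' uniform body, disk inserts, isotropic Gaussian edge blur, and noise model.
#' The true in-plane MTF of the rendered scene is
#' `exp(-2 * pi^2 * blur_sigma_mm^2 * f^2)` multiplied by the pixel-aperture
#' term; recovery tests compare against that closed form.
#'
#' @param grid a [grid_spec()].
#' @param background_hu CT number of the uniform phantom body (HU).
#' @param inserts list of [disk_insert()] objects.
#' @param blur_sigma_mm SD of the isotropic Gaussian point-spread (mm, >= 0).
#' @param noise a [noise_model()].
#' @param n_slices number of slices to generate (>= 1).
#' @param body_diameter_mm diameter of the phantom body disk (mm); pixels
#'   outside the body read -1000 HU (air).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid = grid_spec(), background_hu = 0,
                         inserts = list(), blur_sigma_mm = 0,
                         noise = noise_model(0), n_slices = 1L,
                         body_diameter_mm = 200) {
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec",
                                         call. = FALSE)
  stopifnot_scalar(background_hu, "background_hu")
  stopifnot_scalar(blur_sigma_mm, "blur_sigma_mm")
  if (blur_sigma_mm < 0) stop("`blur_sigma_mm` must be >= 0", call. = FALSE)
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model",
                                            call. = FALSE)
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L) stop("`n_slices` must be >= 1",
                                             call. = FALSE)
  stopifnot_scalar(body_diameter_mm, "body_diameter_mm", positive = TRUE)
  if (body_diameter_mm > grid$field_of_view) {
    stop("phantom body exceeds the field of view", call. = FALSE)
  }
  if (!is.list(inserts) || (length(inserts) &&
                            !all(vapply(inserts, inherits, TRUE,
                                        "disk_insert")))) {
    stop("`inserts` must be a list of disk_insert objects", call. = FALSE)
  }
  half_fov <- grid$field_of_view / 2
  for (ins in inserts) {
    if (sqrt(sum(ins$center^2)) + ins$diameter / 2 > half_fov) {
      stop(sprintf("insert '%s' does not lie fully within the field of view",
                   ins$label), call. = FALSE)
    }
  }
  structure(
    list(grid = grid, background_hu = background_hu, inserts = inserts,
         blur_sigma_mm = blur_sigma_mm, noise = noise, n_slices = n_slices,
         body_diameter_mm = body_diameter_mm),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> body %g mm @ %g HU, %d insert(s), blur %g mm,\n",
    x$body_diameter_mm, x$background_hu, length(x$inserts), x$blur_sigma_mm))
  cat(sprintf("  noise %g HU (%s), %d slice(s), grid %d px / %g mm FOV\n",
              x$noise$sigma_hu, x$noise$texture, x$n_slices,
              x$grid$matrix_size, x$grid$field_of_view))
  invisible(x)
}

#' Catphan-style module presets
#'
#' Ready-made phantom specifications emulating the three quality-assurance
#' modules used by abdominal CT phantom protocols:
#'
#' * `"sensitometry"`: three 12-mm disks at 340, 120 and -35 HU contrast at
#'   the 9, 11 and 1 o'clock positions of the insert circle, plus a 990-HU
#'   high-contrast disk (7 o'clock) for the circular-edge MTF measurement.
#' * `"uniformity"`: the uniform body with no inserts (noise/NPS module).
#' * `"low_contrast"`: nine disks with diameters 15, 9, 8, 7, 6, 5, 4, 3 and
#'   2 mm at the 1.0% contrast level. The HU meaning of "1.0% contrast" is a
#'   convention, not a physical constant; it is exposed as
#'   `hu_per_percent` and defaults to 10 HU per 1% (a 100-HU scale), i.e.
#'   10 HU above the local background.
#'
#' @param module one of `"sensitometry"`, `"uniformity"`, `"low_contrast"`.
#' @param grid a [grid_spec()].
#' @param noise a [noise_model()]; default is 15.4-HU white noise, a typical
#'   abdominal-protocol noise level.
#' @param blur_sigma_mm Gaussian edge blur in mm (default 0.3, a typical
#'   body-kernel point-spread width).
#' @param n_slices slices per stack (default 50, matching the sequential-image
#'   averaging convention of the measurements).
#' @param insert_circle_radius_mm radius of the circle the sensitometry
#'   inserts sit on (mm).
#' @param low_contrast_radius_mm radius of the low-contrast disk circle (mm).
#' @param contrast_percent nominal low-contrast level in percent.
#' @param hu_per_percent HU corresponding to 1% contrast.
#' @param body_diameter_mm phantom body diameter (mm).
#' @param background_hu body CT number (HU).
#' @return a `phantom_spec`.
#' @examples
#' spec <- catphan_presets("sensitometry", grid_spec(256, 200))
#' vapply(spec$inserts, `[[`, numeric(1), "contrast_hu")
#' @export
catphan_presets <- function(module = c("sensitometry", "uniformity",
                                       "low_contrast"),
                            grid = grid_spec(),
                            noise = noise_model(15.4, "white", seed = 1L),
                            blur_sigma_mm = 0.3,
                            n_slices = 50L,
                            insert_circle_radius_mm = 58.5,
                            low_contrast_radius_mm = 50,
                            contrast_percent = 1.0,
                            hu_per_percent = 10,
                            body_diameter_mm = 200,
                            background_hu = 0) {
  module <- match.arg(module)
  clock_xy <- function(hour, r) {
    a <- hour * 30 * pi / 180  # clockwise from 12 o'clock
    c(r * sin(a), r * cos(a))
  }
  inserts <- switch(
    module,
    uniformity = list(),
    sensitometry = {
      r <- insert_circle_radius_mm
      list(
        disk_insert(clock_xy(9, r), 12, 340, "high"),
        disk_insert(clock_xy(11, r), 12, 120, "moderate"),
        disk_insert(clock_xy(1, r), 12, -35, "low"),
        disk_insert(clock_xy(7, r), 12, 990, "mtf")
      )
    },
    low_contrast = {
      d <- c(15, 9, 8, 7, 6, 5, 4, 3, 2)
      contrast <- contrast_percent * hu_per_percent
      lapply(seq_along(d), function(i) {
        disk_insert(clock_xy(12 * (i - 1) / length(d), low_contrast_radius_mm),
                    d[i], contrast, sprintf("lc_%gmm", d[i]))
      })
    }
  )
  phantom_spec(grid = grid, background_hu = background_hu, inserts = inserts,
               blur_sigma_mm = blur_sigma_mm, noise = noise,
               n_slices = n_slices, body_diameter_mm = body_diameter_mm)
}
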
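# Rotated line-ROI measurements: insert CT numbers from short line profiles
# swept through 360 degrees, and attenuation profile curves (APCs) from
# longer ones. The line is always centred on the object centre and sampled
# at one pixel spacing per step.

#' Line ROI specification
#'
#' Geometry of the rotated line region of interest. The default 27-pixel line
#' (about +-5 mm at the standard 0.390625 mm spacing) is the CT-number ROI;
#' a 51-pixel line (about +-10 mm) is the attenuation-profile ROI.
#'
#' @param length_pixels odd number of samples along the line.
#' @param n_angles number of rotation steps.
#' @param angle_step step between rotations in degrees.
#' @return a `line_roi_spec` object.
#' @export
line_roi_spec <- function(length_pixels = 27L, n_angles = 360L,
                          angle_step = 1.0) {
  length_pixels <- as.integer(length_pixels)
  n_angles <- as.integer(n_angles)
  if (length_pixels < 3L || length_pixels %% 2L == 0L) {
    stop("`length_pixels` must be an odd integer >= 3 so the line is ",
         "centred on the object centre", call. = FALSE)
  }
  if (n_angles < 1L) stop("`n_angles` must be >= 1", call. = FALSE)
  stopifnot_scalar(angle_step, "angle_step", positive = TRUE)
  if (n_angles * angle_step > 360 + 1e-9) {
    stop("`n_angles * angle_step` must not exceed 360 degrees", call. = FALSE)
  }
  structure(list(length_pixels = length_pixels, n_angles = n_angles,
                 angle_step = angle_step), class = "line_roi_spec")
}

# fractional (row, col) coordinates (1-based) of line samples for all angles;
# returns list(row, col) matrices [length_pixels x n_angles]
.line_coords <- function(n, pixel_spacing, center, angles_deg,
                         length_pixels) {
  offs <- (seq_len(length_pixels) - (length_pixels + 1) / 2) * pixel_spacing
  th <- angles_deg * pi / 180
  x <- center[1] + outer(offs, cos(th))
  y <- center[2] + outer(offs, sin(th))
  list(row = (n + 1) / 2 - y / pixel_spacing,
       col = x / pixel_spacing + (n + 1) / 2)
}

# bilinear (or nearest-neighbour) sampling at fractional coordinates
.sample_image <- function(image, row, col, method = "bilinear") {
  n <- nrow(image)
  if (method == "nearest") {
    r <- round(row); c <- round(col)
    if (any(r < 1 | r > n | c < 1 | c > n)) {
      stop("line ROI exits the image bounds", call. = FALSE)
    }
    out <- image[cbind(as.vector(r), as.vector(c))]
  } else {
    r0 <- floor(row); c0 <- floor(col)
    if (any(r0 < 1 | r0 + 1 > n | c0 < 1 | c0 + 1 > n)) {
      stop("line ROI exits the image bounds", call. = FALSE)
    }
    fr <- as.vector(row - r0); fc <- as.vector(col - c0)
    r0 <- as.vector(r0); c0 <- as.vector(c0)
    out <- image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      image[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
      image[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
      image[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  }
  if (!is.null(dim(row))) dim(out) <- dim(row)
  out
}

#' Sample a line profile through an image
#'
#' Samples `length_pixels` points spaced one pixel apart along the direction
#' `angle`, centred on `center`, by bilinear interpolation (or
#' nearest-neighbour). Values are ordered from the negative to the positive
#' end of the line.
#'
#' @param image 2-D HU matrix.
#' @param pixel_spacing mm per pixel.
#' @param center (x, y) in mm from the image centre.
#' @param angle line direction in degrees (0 = +x, counter-clockwise).
#' @param length_pixels number of samples (odd).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return numeric vector of HU values.
#' @export
sample_line_profile <- function(image, pixel_spacing, center, angle,
                                length_pixels = 27L,
                                method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  cc <- .line_coords(nrow(image), pixel_spacing, center, angle,
                     as.integer(length_pixels))
  as.vector(.sample_image(image, cc$row, cc$col, method))
}

# all profiles of a stack: array [length_pixels, n_angles, n_slices]
.all_profiles <- function(stack, center, roi, method = "bilinear") {
  angles <- (seq_len(roi$n_angles) - 1) * roi$angle_step
  cc <- .line_coords(dim(stack$data)[1], stack$pixel_spacing, center,
                     angles, roi$length_pixels)
  ns <- n_slices(stack)
  out <- array(0, dim = c(roi$length_pixels, roi$n_angles, ns))
  for (k in seq_len(ns)) {
    out[, , k] <- .sample_image(stack$data[, , k], cc$row, cc$col, method)
  }
  out
}

#' Measure an insert's CT number with rotated line ROIs
#'
#' Sweeps the line ROI through `n_angles` rotations about the object centre
#' on every slice and pools all samples. `mean_hu` is the grand mean;
#' `sd_hu` is by default the grand (pooled per-sample) SD, whose magnitude is
#' comparable to the image noise level. The SD of the per-angle profile
#' means is also reported (`sd_angle_means`) for the alternative convention.
#'
#' @param stack an [image_stack()].
#' @param center insert centre, (x, y) mm.
#' @param roi a [line_roi_spec()]; default 27 pixels x 360 angles.
#' @param insert_label label carried into reports.
#' @param method interpolation passed to [sample_line_profile()].
#' @return a `ct_number_result`: `mean_hu`, `sd_hu`, `sd_angle_means`,
#'   `n_samples`, `insert_label`.
#' @export
measure_ct_number <- function(stack, center, roi = line_roi_spec(27L),
                              insert_label = "insert",
                              method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (!inherits(stack, "image_stack")) {
    stop("`stack` must be an image_stack", call. = FALSE)
  }
  prof <- .all_profiles(stack, center, roi, method)
  angle_means <- apply(prof, c(2, 3), mean)
  structure(
    list(mean_hu = mean(prof),
         sd_hu = stats::sd(as.vector(prof)),
         sd_angle_means = stats::sd(as.vector(angle_means)),
         n_samples = length(prof),
         insert_label = insert_label),
    class = "ct_number_result"
  )
}

#' @export
print.ct_number_result <- function(x, ...) {
  cat(sprintf("<ct_number_result> %s: %.1f +- %.1f HU (n = %d)\n",
              x$insert_label, x$mean_hu, x$sd_hu, x$n_samples))
  invisible(x)
}

#' Measure the mean attenuation profile curve of an insert
#'
#' Records the line profile at every rotation angle on every slice and
#' averages position-wise, so a centred disk appears as a plateau around
#' position 0 with the background beyond its radius.
#'
#' @inheritParams measure_ct_number
#' @param roi a [line_roi_spec()]; default 51 pixels x 360 angles.
#' @return a `radial_profile_result`: `positions` (signed mm from the
#'   centre), `mean_profile`, `sd_profile`, `n_profiles`.
#' @export
measure_apc <- function(stack, center, roi = line_roi_spec(51L),
                        insert_label = "insert",
                        method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (!inherits(stack, "image_stack")) {
    stop("`stack` must be an image_stack", call. = FALSE)
  }
  prof <- .all_profiles(stack, center, roi, method)
  L <- roi$length_pixels
  flat <- matrix(prof, nrow = L)  # positions x (angles * slices)
  structure(
    list(positions = (seq_len(L) - (L + 1) / 2) * stack$pixel_spacing,
         mean_profile = rowMeans(flat),
         sd_profile = apply(flat, 1, stats::sd),
         n_profiles = ncol(flat),
         insert_label = insert_label),
    class = "radial_profile_result"
  )
}

#' @export
print.radial_profile_result <- function(x, ...) {
  cat(sprintf(
    "<radial_profile_result> %s: %d positions over [%.2f, %.2f] mm, %d profiles\n",
    x$insert_label, length(x$positions), min(x$positions), max(x$positions),
    x$n_profiles))
  invisible(x)
}

#' Export a radial profile as a data frame
#' @param x a `radial_profile_result`.
#' @param ... unused.
#' @return data frame with `position_mm`, `mean_hu`, `sd_hu`.
#' @export
as.data.frame.radial_profile_result <- function(x, ...) {
  data.frame(position_mm = x$positions, mean_hu = x$mean_profile,
             sd_hu = x$sd_profile)
}
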
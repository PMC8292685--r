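# In-plane MTF by the circular-edge (disk) method: signal averaging, radial
# edge-spread function around the disk boundary, differentiation to the
# line-spread function, Fourier transform to the MTF, and f50/f10 readout.

#' Signal-average a stack
#'
#' Pixel-wise mean across slices, used to suppress noise before edge
#' analysis (residual noise falls as `1/sqrt(n_slices)`).
#'
#' @param stack an [image_stack()].
#' @return 2-D HU matrix.
#' @export
signal_average <- function(stack) {
  if (!inherits(stack, "image_stack")) {
    stop("`stack` must be an image_stack", call. = FALSE)
  }
  if (n_slices(stack) == 0L) stop("empty stack", call. = FALSE)
  rowMeans(stack$data, dims = 2)
}

#' Estimate a disk centre by intensity-weighted centroid
#'
#' Background is estimated from an annulus outside 1.2 x the nominal radius;
#' the centroid of (image - background) is taken over a window of 1.5 x the
#' nominal diameter. Windows containing no usable disk contrast (contrast
#' energy indistinguishable from the background fluctuation) are rejected.
#'
#' @param image 2-D HU matrix.
#' @param pixel_spacing mm per pixel.
#' @param approx_center nominal (x, y) centre in mm.
#' @param approx_diameter nominal diameter in mm.
#' @return refined (x, y) centre in mm.
#' @export
estimate_disk_center <- function(image, pixel_spacing, approx_center,
                                 approx_diameter) {
  stopifnot_scalar(approx_diameter, "approx_diameter", positive = TRUE)
  n <- nrow(image)
  xs <- pixel_x(n, pixel_spacing)
  ys <- pixel_y(n, pixel_spacing)
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  d <- sqrt((X - approx_center[1])^2 + (Y - approx_center[2])^2)
  win <- 0.75 * approx_diameter
  if (approx_center[1] - win < min(xs) || approx_center[1] + win > max(xs) ||
      approx_center[2] - win < min(ys) || approx_center[2] + win > max(ys)) {
    stop("centroid window exits the image", call. = FALSE)
  }
  bg_idx <- d > 0.6 * approx_diameter & d <= win
  in_idx <- d <= 0.6 * approx_diameter
  bg <- mean(image[bg_idx])
  w <- image[in_idx] - bg
  # reject windows whose summed contrast could plausibly be pure background
  # fluctuation; the variance of sum(w) includes the background-estimate
  # term n^2/n_bg because bg is itself estimated from the annulus
  n_in <- sum(in_idx)
  sd_stat <- stats::sd(image[bg_idx]) * sqrt(n_in + n_in^2 / sum(bg_idx))
  if (abs(sum(w)) <= 3 * sd_stat) {
    stop("no detectable disk contrast in the centroid window", call. = FALSE)
  }
  c(sum(X[in_idx] * w), sum(Y[in_idx] * w)) / sum(w)
}

#' Radial edge-spread function of a disk
#'
#' Every pixel in the annulus `nominal_radius +- half_range_mm` contributes
#' the pair (signed distance from the nominal edge, HU value). Samples are
#' grouped into radial bins of `bin_width`; each bin is summarized by the
#' mean of its distances and the mean of its values, and the scatter of bin
#' centroids is linearly interpolated onto the regular position grid (this
#' also fills empty bins). Using the centroid distance rather than the bin
#' centre removes the within-bin position bias that the steep edge slope
#' would otherwise turn into high-frequency ripple. Negative positions are
#' inside the disk.
#'
#' @param image 2-D HU matrix (typically a signal average).
#' @param pixel_spacing mm per pixel.
#' @param center disk centre, (x, y) mm.
#' @param nominal_radius disk radius in mm.
#' @param bin_width radial bin width in mm (default 0.1 pixel).
#' @param half_range_mm half-width of the annulus (mm, >= 3).
#' @return an `edge_spread_function`: `positions`, `values`, `bin_width`,
#'   `n_per_bin`.
#' @export
radial_esf <- function(image, pixel_spacing, center, nominal_radius,
                       bin_width = 0.1 * pixel_spacing, half_range_mm = 5) {
  stopifnot_scalar(nominal_radius, "nominal_radius", positive = TRUE)
  if (half_range_mm < 3) {
    stop("`half_range_mm` must cover at least +-3 mm around the edge",
         call. = FALSE)
  }
  n <- nrow(image)
  half_img <- (n / 2) * pixel_spacing
  if (max(abs(center)) + nominal_radius + half_range_mm > half_img) {
    stop("edge annulus exits the image", call. = FALSE)
  }
  xs <- pixel_x(n, pixel_spacing)
  ys <- pixel_y(n, pixel_spacing)
  d <- sqrt(outer((ys - center[2])^2, (xs - center[1])^2, "+")) -
    nominal_radius
  sel <- abs(d) <= half_range_mm & d > -nominal_radius
  b <- as.integer(round(d[sel] / bin_width))
  v <- image[sel]
  sums <- rowsum(v, b)
  dsums <- rowsum(d[sel], b)
  cnts <- rowsum(rep(1L, length(b)), b)
  kb <- as.integer(rownames(sums))
  ord <- order(kb)
  kb <- kb[ord]
  mean_v <- (sums / cnts)[ord]
  mean_d <- (dsums / cnts)[ord]
  bins <- seq.int(min(kb), max(kb))
  vals <- stats::approx(mean_d, mean_v, xout = bins * bin_width,
                        rule = 2)$y
  npb <- integer(length(bins))
  npb[match(kb, bins)] <- as.integer(cnts[ord])
  structure(
    list(positions = bins * bin_width, values = vals,
         bin_width = bin_width, n_per_bin = npb),
    class = "edge_spread_function"
  )
}

#' @export
print.edge_spread_function <- function(x, ...) {
  cat(sprintf(
    "<edge_spread_function> %d bins of %.4f mm over [%.2f, %.2f] mm\n",
    length(x$positions), x$bin_width, min(x$positions), max(x$positions)))
  invisible(x)
}

# tail levels of an ESF (first/last `frac` of bins)
.esf_tails <- function(esf, frac = 0.1) {
  m <- length(esf$values)
  nt <- max(3L, round(frac * m))
  list(inside = mean(esf$values[seq_len(nt)]),
       outside = mean(esf$values[seq.int(m - nt + 1L, m)]))
}

# signed position where the ESF first crosses half amplitude (linear interp);
# used to refine the nominal radius once
.esf_half_crossing <- function(esf) {
  tails <- .esf_tails(esf)
  half <- (tails$inside + tails$outside) / 2
  v <- esf$values - half
  falling <- tails$inside > tails$outside
  s <- if (falling) v else -v
  i <- which(s[-length(s)] >= 0 & s[-1] < 0)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  x0 <- esf$positions[i]
  x0 + s[i] / (s[i] - s[i + 1]) * esf$bin_width
}

#' Differentiate an edge-spread function into a line-spread function
#'
#' Central differences on the binned ESF, oriented so the LSF integrates to
#' the positive contrast magnitude. The two end bins are dropped. A flat ESF
#' (no edge) is rejected.
#'
#' @param esf an `edge_spread_function`.
#' @param smooth apply a light 1-2-1 binomial smoothing to the ESF first
#'   (off by default).
#' @return a `line_spread_function`: `positions`, `values`, `bin_width`.
#' @export
esf_to_lsf <- function(esf, smooth = FALSE) {
  if (!inherits(esf, "edge_spread_function")) {
    stop("`esf` must be an edge_spread_function", call. = FALSE)
  }
  v <- esf$values
  m <- length(v)
  if (m < 5L) stop("ESF has too few samples to differentiate", call. = FALSE)
  if (isTRUE(smooth)) {
    v <- c(v[1], (v[-c(m - 1L, m)] + 2 * v[-c(1L, m)] + v[-c(1L, 2L)]) / 4,
           v[m])
  }
  h <- esf$bin_width
  lsf <- (v[-(1:2)] - v[seq_len(m - 2L)]) / (2 * h)
  if (all(abs(lsf) < 1e-12)) {
    stop("flat ESF: no edge to differentiate", call. = FALSE)
  }
  if (sum(lsf) < 0) lsf <- -lsf
  structure(
    list(positions = esf$positions[-c(1L, m)], values = lsf, bin_width = h),
    class = "line_spread_function"
  )
}

#' Transform a line-spread function into an MTF with f50/f10 readout
#'
#' The LSF is baseline-corrected (mean of the outer tails subtracted),
#' tapered, zero-padded and Fourier-transformed; the modulus is corrected
#' for the known transfer of the central-difference derivative and, when
#' `aperture_mm` is given, divided by the pixel-aperture term
#' `sinc(pi * f * aperture_mm)` so the readout refers to the pre-sampling
#' scene MTF. The curve is normalized to 1 at zero frequency. `f50` and
#' `f10` are located at the first downward crossing of 0.5 and 0.1 by linear
#' interpolation.
#'
#' The default taper is a Tukey window with `tukey_alpha = 0.5`: its flat
#' central half leaves a well-contained LSF untouched, whereas a full Hann
#' taper multiplies the LSF core by its envelope and biases the readout
#' upward by several percent. Hann remains available for comparison.
#'
#' @param lsf a `line_spread_function` (or numeric vector with `bin_width`).
#' @param bin_width sample spacing in mm (taken from `lsf` if absent).
#' @param taper `"tukey"` (default), `"hann"` or `"none"`.
#' @param tukey_alpha tapered fraction of the Tukey window.
#' @param baseline subtract the tail baseline (default TRUE).
#' @param aperture_mm pixel-aperture width to deconvolve, or `NULL`.
#' @param derivative_correction divide by the central-difference transfer
#'   `sinc(2 pi f h)`; applies when the LSF came from [esf_to_lsf()]
#'   (default TRUE). Disable for an LSF that was not obtained by finite
#'   differences.
#' @param pad_factor zero-padding factor for a smooth curve.
#' @param max_frequency truncate the reported curve (cycles/mm); default
#'   half the sampling frequency of the binned LSF, further capped at
#'   `0.9 / aperture_mm` when the aperture correction is active (beyond
#'   that the correction denominator approaches its zero and the corrected
#'   values carry no information).
#' @return an `mtf_result`: `frequencies`, `mtf`, `f50`, `f10`, `f50_se`,
#'   `f10_se` (SEs are `NA` for a single estimate).
#' @export
lsf_to_mtf <- function(lsf, bin_width = NULL,
                       taper = c("tukey", "hann", "none"),
                       tukey_alpha = 0.5, baseline = TRUE,
                       aperture_mm = NULL, derivative_correction = TRUE,
                       pad_factor = 8L, max_frequency = NULL) {
  taper <- match.arg(taper)
  if (inherits(lsf, "line_spread_function")) {
    v <- lsf$values
    h <- bin_width %||% lsf$bin_width
  } else {
    v <- as.numeric(lsf)
    h <- bin_width
  }
  if (is.null(h)) stop("`bin_width` is required", call. = FALSE)
  m <- length(v)
  if (isTRUE(baseline)) {
    nt <- max(3L, round(0.1 * m))
    v <- v - mean(c(v[seq_len(nt)], v[seq.int(m - nt + 1L, m)]))
  }
  if (abs(sum(v)) < 1e-12 * max(abs(v), 1e-300)) {
    stop("LSF has zero integral; MTF undefined", call. = FALSE)
  }
  w <- switch(taper,
              tukey = tukey_window(m, tukey_alpha),
              hann = hann_window(m),
              none = rep(1, m))
  v <- v * w
  np <- 2^ceiling(log2(max(pad_factor * m, m)))
  M <- Mod(stats::fft(c(v, rep(0, np - m))))
  fr <- (seq_len(np) - 1) / (np * h)
  fmax <- max_frequency %||%
    min(0.5 / h, if (is.null(aperture_mm)) Inf else 0.9 / aperture_mm)
  keep <- fr <= fmax
  M <- M[keep]
  fr <- fr[keep]
  if (isTRUE(derivative_correction)) {
    # transfer of the central-difference derivative
    M <- M / sinc(2 * pi * fr * h)
  }
  if (!is.null(aperture_mm)) {
    M <- M / pmax(sinc(pi * fr * aperture_mm), 0.05)
  }
  M <- M / M[1]
  mtf_result(frequencies = fr, mtf = M)
}

#' Construct an MTF result with interpolated f50/f10 readout
#'
#' @param frequencies cycles/mm, starting at 0.
#' @param mtf MTF samples, 1 at zero frequency.
#' @param f50_se,f10_se across-replicate standard errors (optional).
#' @return an `mtf_result`.
#' @export
mtf_result <- function(frequencies, mtf, f50_se = NA_real_,
                       f10_se = NA_real_) {
  structure(
    list(frequencies = frequencies, mtf = mtf,
         f50 = mtf_crossing(frequencies, mtf, 0.5),
         f10 = mtf_crossing(frequencies, mtf, 0.1),
         f50_se = f50_se, f10_se = f10_se),
    class = "mtf_result"
  )
}

#' Frequency of the first downward crossing of an MTF level
#'
#' @param frequencies cycles/mm.
#' @param mtf MTF samples.
#' @param level threshold in (0, 1).
#' @return interpolated frequency, or `NA` if the curve never falls below
#'   `level`.
#' @export
mtf_crossing <- function(frequencies, mtf, level) {
  i <- which(mtf[-length(mtf)] >= level & mtf[-1] <= level &
               mtf[-length(mtf)] > mtf[-1])
  if (!length(i)) {
    at <- which(mtf == level)
    return(if (length(at)) frequencies[at[1]] else NA_real_)
  }
  i <- i[1]
  frequencies[i] + (mtf[i] - level) / (mtf[i] - mtf[i + 1]) *
    (frequencies[i + 1] - frequencies[i])
}

#' @export
print.mtf_result <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.na(v)) return("n/a")
    if (is.na(se)) sprintf("%.3f", v) else sprintf("%.3f (SE %.4f)", v, se)
  }
  cat(sprintf("<mtf_result> f50 = %s, f10 = %s cycles/mm\n",
              fmt(x$f50, x$f50_se), fmt(x$f10, x$f10_se)))
  invisible(x)
}

#' Export an MTF curve as a data frame
#' @param x an `mtf_result`.
#' @param ... unused.
#' @return data frame with `frequency`, `mtf`.
#' @export
as.data.frame.mtf_result <- function(x, ...) {
  data.frame(frequency = x$frequencies, mtf = x$mtf)
}

#' Full circular-edge MTF chain on one image
#'
#' Convenience wrapper: optional centroid refinement of the disk centre, a
#' provisional ESF whose half-amplitude crossing refines the nominal radius
#' once, then the final ESF -> LSF -> MTF chain.
#'
#' @param image 2-D HU matrix (typically a signal average).
#' @param pixel_spacing mm per pixel.
#' @param radius nominal disk radius in mm.
#' @param center known (x, y) centre in mm, or `NULL` to estimate it from
#'   `approx_center`.
#' @param approx_center starting point for the centroid search.
#' @param refine_center estimate the centre by centroid (default TRUE when
#'   `center` is NULL).
#' @param refine_radius refine the radius at the provisional half-amplitude
#'   crossing (default TRUE).
#' @param aperture_mm pixel-aperture deconvolution width; defaults to
#'   `pixel_spacing` (set `NULL` to disable).
#' @param ... further arguments to [radial_esf()] and [lsf_to_mtf()]
#'   (`bin_width`, `half_range_mm`, `taper`, `tukey_alpha`, `baseline`,
#'   `pad_factor`, `max_frequency`, `smooth`).
#' @return an `mtf_result` with the final `edge_spread_function` attached as
#'   attribute `"esf"`.
#' @export
disk_mtf <- function(image, pixel_spacing, radius, center = NULL,
                     approx_center = c(0, 0), refine_center = is.null(center),
                     refine_radius = TRUE, aperture_mm = pixel_spacing,
                     ...) {
  dots <- list(...)
  esf_args <- dots[names(dots) %in% c("bin_width", "half_range_mm")]
  mtf_args <- dots[names(dots) %in% c("taper", "tukey_alpha", "baseline",
                                      "derivative_correction",
                                      "pad_factor", "max_frequency")]
  smooth <- isTRUE(dots$smooth)
  if (is.null(center)) {
    center <- if (refine_center) {
      estimate_disk_center(image, pixel_spacing, approx_center, 2 * radius)
    } else {
      approx_center
    }
  }
  esf <- do.call(radial_esf, c(list(image, pixel_spacing, center, radius),
                               esf_args))
  if (isTRUE(refine_radius)) {
    shift <- .esf_half_crossing(esf)
    if (is.finite(shift) && abs(shift) < pixel_spacing) {
      radius <- radius + shift
      esf <- do.call(radial_esf,
                     c(list(image, pixel_spacing, center, radius), esf_args))
    }
  }
  lsf <- esf_to_lsf(esf, smooth = smooth)
  res <- do.call(lsf_to_mtf, c(list(lsf, aperture_mm = aperture_mm),
                               mtf_args))
  attr(res, "esf") <- esf
  res
}

#' Circular-edge MTF with replicate stacks
#'
#' Runs the full disk-method chain on the signal average of each replicate
#' stack and reports the mean MTF curve with the across-replicate standard
#' errors of f50 and f10 (the replicate emulation of repeated
#' signal-averaged reconstructions). With a single replicate the SEs are
#' reported absent.
#'
#' @param stacks list of [image_stack()] replicates.
#' @param radius nominal disk radius in mm.
#' @param center known (x, y) centre in mm, or `NULL` to estimate per
#'   replicate.
#' @param ... passed to [disk_mtf()].
#' @return an `mtf_result`; `f50`/`f10` are the means of the per-replicate
#'   readouts.
#' @export
mtf_with_replicates <- function(stacks, radius, center = NULL, ...) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  if (!length(stacks)) stop("need at least one replicate stack",
                            call. = FALSE)
  runs <- lapply(stacks, function(s) {
    disk_mtf(signal_average(s), s$pixel_spacing, radius, center = center,
             ...)
  })
  f50s <- vapply(runs, `[[`, numeric(1), "f50")
  f10s <- vapply(runs, `[[`, numeric(1), "f10")
  nrep <- length(runs)
  curve <- Reduce(`+`, lapply(runs, `[[`, "mtf")) / nrep
  res <- structure(
    list(frequencies = runs[[1]]$frequencies,
         mtf = curve,
         f50 = mean(f50s), f10 = mean(f10s),
         f50_se = if (nrep >= 2L) stats::sd(f50s) / sqrt(nrep) else NA_real_,
         f10_se = if (nrep >= 2L) stats::sd(f10s) / sqrt(nrep) else NA_real_,
         f50_replicates = f50s, f10_replicates = f10s),
    class = "mtf_result"
  )
  res
}
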
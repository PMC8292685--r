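# Noise magnitude, the radial-frequency noise power spectrum, and dose-ratio
# percentages.

# centred square ROI indices
.center_roi_index <- function(n, roi_size) {
  if (roi_size > n) {
    stop(sprintf("ROI of %d px does not fit a %d px image", roi_size, n),
         call. = FALSE)
  }
  lo <- floor((n - roi_size) / 2) + 1L
  seq.int(lo, lo + roi_size - 1L)
}

#' Image noise magnitude
#'
#' The standard deviation of the CT number inside a centred square ROI,
#' computed per slice and averaged. The standard error is the SD of the
#' per-slice SDs divided by `sqrt(n_slices)`; with a single slice it is
#' reported as `NA` (not zero).
#'
#' @param stack an [image_stack()].
#' @param roi_size ROI side in pixels (default 256).
#' @return a `noise_result`: `mean_sd_hu`, `se_hu`, `per_slice_sd`,
#'   `n_slices`, `roi_size`.
#' @export
noise_magnitude <- function(stack, roi_size = 256L) {
  if (!inherits(stack, "image_stack")) {
    stop("`stack` must be an image_stack", call. = FALSE)
  }
  idx <- .center_roi_index(dim(stack$data)[1], as.integer(roi_size))
  ns <- n_slices(stack)
  per_slice <- vapply(seq_len(ns), function(k) {
    stats::sd(stack$data[idx, idx, k])
  }, numeric(1))
  structure(
    list(mean_sd_hu = mean(per_slice),
         se_hu = if (ns >= 2L) stats::sd(per_slice) / sqrt(ns) else NA_real_,
         per_slice_sd = per_slice,
         n_slices = ns,
         roi_size = as.integer(roi_size)),
    class = "noise_result"
  )
}

#' @export
print.noise_result <- function(x, ...) {
  cat(sprintf("<noise_result> %.2f HU (SE %s), %d slice(s), %d px ROI\n",
              x$mean_sd_hu,
              if (is.na(x$se_hu)) "n/a" else sprintf("%.3f", x$se_hu),
              x$n_slices, x$roi_size))
  invisible(x)
}

# remove the detrend surface from one ROI
.detrend_roi <- function(roi, mode) {
  if (mode == "mean") return(roi - mean(roi))
  # first-order plane fit; row/col coordinates are orthogonal and centred,
  # so the coefficients are simple projections
  n <- nrow(roi); m <- ncol(roi)
  r <- seq_len(n) - (n + 1) / 2
  c_ <- seq_len(m) - (m + 1) / 2
  a <- mean(roi)
  br <- sum(rowSums(roi) * r) / (sum(r^2) * m)
  bc <- sum(colSums(roi) * c_) / (sum(c_^2) * n)
  roi - (a + outer(r, rep(1, m)) * br + outer(rep(1, n), c_) * bc)
}

#' Noise power spectrum by the radial frequency method
#'
#' For each slice the centred square ROI is extracted, detrended, and its
#' periodogram `|DFT|^2 * pixel_spacing^2 / roi_size^2` (units HU^2 mm^2)
#' accumulated. The slice-averaged 2-D spectrum is collapsed onto a 1-D
#' radial-frequency axis: each 2-D sample is assigned to the bin nearest its
#' Euclidean frequency norm, with bin width equal to the DFT frequency
#' spacing `1 / (roi_size * pixel_spacing)`; the zero-frequency sample is
#' excluded and empty bins are dropped. The unit-area normalized curve is
#' attached (all-zero spectra are flagged degenerate instead of divided by
#' zero).
#'
#' @param stack an [image_stack()].
#' @param roi_size ROI side in pixels (default 256).
#' @param detrend `"mean"` (subtract the ROI mean, default) or `"plane"`
#'   (subtract a first-order plane fit).
#' @return a `spectrum_result`: `frequencies` (cycles/mm), `nps`,
#'   `normalized_nps`, `counts` (2-D samples per bin), `n_realizations`,
#'   `variance` (pooled detrended ROI variance), `nps_2d_integral`,
#'   `pixel_spacing`, `roi_size`, `degenerate`.
#' @export
compute_nps <- function(stack, roi_size = 256L,
                        detrend = c("mean", "plane")) {
  detrend <- match.arg(detrend)
  if (!inherits(stack, "image_stack")) {
    stop("`stack` must be an image_stack", call. = FALSE)
  }
  roi_size <- as.integer(roi_size)
  idx <- .center_roi_index(dim(stack$data)[1], roi_size)
  dx <- stack$pixel_spacing
  ns <- n_slices(stack)
  acc <- matrix(0, roi_size, roi_size)
  var_acc <- 0
  for (k in seq_len(ns)) {
    roi <- .detrend_roi(stack$data[idx, idx, k], detrend)
    acc <- acc + Mod(stats::fft(roi))^2
    var_acc <- var_acc + sum(roi^2) / (length(roi) - 1L)
  }
  p2d <- acc / ns * dx^2 / roi_size^2
  variance <- var_acc / ns

  df <- 1 / (roi_size * dx)
  f1 <- fft_freq(roi_size, dx)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  bin <- as.integer(round(fr / df))
  keep <- bin > 0L
  sums <- tapply(p2d[keep], bin[keep], sum)
  counts <- tapply(bin[keep], bin[keep], length)
  kbin <- as.integer(names(sums))
  ord <- order(kbin)
  kbin <- kbin[ord]
  nps <- as.numeric(sums[ord]) / as.numeric(counts[ord])
  res <- structure(
    list(frequencies = kbin * df,
         nps = nps,
         normalized_nps = NULL,
         counts = as.integer(counts[ord]),
         n_realizations = ns,
         variance = variance,
         nps_2d_integral = sum(p2d[bin > 0L]) * df^2,
         pixel_spacing = dx,
         roi_size = roi_size,
         degenerate = FALSE),
    class = "spectrum_result"
  )
  auc <- trapz(res$frequencies, res$nps)
  if (auc > 0) {
    res$normalized_nps <- res$nps / auc
  } else {
    res$degenerate <- TRUE
    res$normalized_nps <- rep(NA_real_, length(res$nps))
    warning("all-zero noise power spectrum; normalized curve is undefined",
            call. = FALSE)
  }
  res
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(
    "<spectrum_result> %d radial bins to %.3f cycles/mm, %d realization(s)\n",
    length(x$frequencies), max(x$frequencies), x$n_realizations))
  cat(sprintf("  2-D integral %.3f HU^2 (ROI variance %.3f HU^2)%s\n",
              x$nps_2d_integral, x$variance,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Normalize a noise power spectrum to unit area
#'
#' Divides the NPS by its trapezoidal area under the curve so the normalized
#' spectrum integrates to 1; the operation is idempotent.
#'
#' @param spectrum a `spectrum_result`.
#' @return the spectrum with `normalized_nps` set.
#' @export
normalize_nps <- function(spectrum) {
  if (!inherits(spectrum, "spectrum_result")) {
    stop("`spectrum` must be a spectrum_result", call. = FALSE)
  }
  auc <- trapz(spectrum$frequencies, spectrum$nps)
  if (auc <= 0) {
    stop("area under the NPS curve is zero; cannot normalize", call. = FALSE)
  }
  spectrum$normalized_nps <- spectrum$nps / auc
  spectrum$degenerate <- FALSE
  spectrum
}

#' Export a spectrum as a data frame
#' @param x a `spectrum_result`.
#' @param ... unused.
#' @return data frame with `frequency`, `nps`, `normalized_nps`.
#' @export
as.data.frame.spectrum_result <- function(x, ...) {
  data.frame(frequency = x$frequencies, nps = x$nps,
             normalized_nps = x$normalized_nps)
}

#' Noise ratio between two conditions as an integer percentage
#'
#' `round(100 * test / reference)` with half-up rounding, the convention
#' under which the printed noise pairs (15.6 vs 10.2 HU and 16.9 vs 15.4 HU)
#' reproduce 153% and 110%.
#'
#' @param test_sd_hu noise SD of the test condition (HU).
#' @param reference_sd_hu noise SD of the reference condition (HU, > 0).
#' @return a `dose_ratio_result`: `percent`, `test_sd_hu`,
#'   `reference_sd_hu`.
#' @examples
#' dose_ratio_percent(15.6, 10.2)$percent  # 153
#' @export
dose_ratio_percent <- function(test_sd_hu, reference_sd_hu) {
  stopifnot_scalar(test_sd_hu, "test_sd_hu")
  stopifnot_scalar(reference_sd_hu, "reference_sd_hu", positive = TRUE)
  structure(
    list(percent = as.integer(round_half_up(100 * test_sd_hu /
                                              reference_sd_hu)),
         test_sd_hu = test_sd_hu,
         reference_sd_hu = reference_sd_hu),
    class = "dose_ratio_result"
  )
}

#' @export
print.dose_ratio_result <- function(x, ...) {
  cat(sprintf("<dose_ratio_result> %d%% (%.1f vs %.1f HU)\n",
              x$percent, x$test_sd_hu, x$reference_sd_hu))
  invisible(x)
}
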
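# Low-contrast detectability support: Cohen's kappa for the two-reader
# agreement analysis, and a clearly-labelled model-observer surrogate for the
# minimum detectable diameter. The surrogate is a non-prewhitening matched
# filter with a Rose-type threshold; it does not reproduce human readings.

#' Two-rater rating table
#'
#' @param rater_a,rater_b category per item (equal length).
#' @param items optional item identifiers.
#' @param categories ordered vector of permissible categories; defaults to
#'   the sorted union of the observed ratings.
#' @return a `rating_table` object.
#' @export
rating_table <- function(rater_a, rater_b, items = NULL, categories = NULL) {
  if (length(rater_a) != length(rater_b)) {
    stop("`rater_a` and `rater_b` must have the same length", call. = FALSE)
  }
  if (length(rater_a) < 2L) stop("need at least 2 rated items",
                                 call. = FALSE)
  categories <- categories %||% sort(unique(c(rater_a, rater_b)))
  if (!all(c(rater_a, rater_b) %in% categories)) {
    bad <- setdiff(unique(c(rater_a, rater_b)), categories)
    stop(sprintf("ratings outside `categories`: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(items = items %||% seq_along(rater_a),
         rater_a = rater_a, rater_b = rater_b, categories = categories),
    class = "rating_table"
  )
}

#' Read a two-rater rating table from CSV
#'
#' Expects columns `item`, `rater_a`, `rater_b` (extra columns ignored).
#' @param path CSV file.
#' @param categories optional category order.
#' @return a [rating_table()].
#' @export
read_rating_table <- function(path, categories = NULL) {
  d <- utils::read.csv(path)
  need <- c("rater_a", "rater_b")
  if (!all(need %in% names(d))) {
    stop(sprintf("'%s' must have columns rater_a and rater_b", path),
         call. = FALSE)
  }
  rating_table(d$rater_a, d$rater_b, items = d$item,
               categories = categories)
}

#' Agreement band for a kappa value
#'
#' The conventional interpretation scale on the kappa value rounded to two
#' decimals: 0.01-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate,
#' 0.61-0.80 substantial, 0.81-1.00 almost perfect; below 0.01 is "poor".
#'
#' @param kappa numeric kappa value(s).
#' @return character band(s).
#' @examples
#' kappa_band(0.713)  # "substantial"
#' @export
kappa_band <- function(kappa) {
  k <- round(kappa, 2)
  cut(k, breaks = c(-Inf, 0.005, 0.205, 0.405, 0.605, 0.805, Inf),
      labels = c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect")) |> as.character()
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement from the cross-tabulation of the two rating
#' vectors: `kappa = (po - pe) / (1 - pe)` with observed agreement `po` and
#' expected-by-chance agreement `pe` from the table margins. Unweighted by
#' default; linear or quadratic weights over the ordered categories are
#' available. When the expected agreement equals 1 the kappa is undefined
#' and flagged.
#'
#' @param ratings a [rating_table()] (or a data frame with columns
#'   `rater_a`, `rater_b`).
#' @param weights `"none"` (default), `"linear"` or `"quadratic"`.
#' @return a `kappa_result`: `kappa`, `observed_agreement`,
#'   `expected_agreement`, `band`, `table`, `undefined`.
#' @examples
#' cohens_kappa(rating_table(c(1, 2, 1, 2), c(1, 1, 2, 2)))$kappa  # 0
#' @export
cohens_kappa <- function(ratings, weights = c("none", "linear",
                                              "quadratic")) {
  weights <- match.arg(weights)
  if (is.data.frame(ratings)) {
    ratings <- rating_table(ratings$rater_a, ratings$rater_b,
                            items = ratings$item)
  }
  if (!inherits(ratings, "rating_table")) {
    stop("`ratings` must be a rating_table", call. = FALSE)
  }
  lev <- ratings$categories
  a <- factor(ratings$rater_a, levels = lev)
  b <- factor(ratings$rater_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  q <- length(lev)
  W <- if (weights == "none") {
    diag(q)
  } else {
    d <- abs(outer(seq_len(q), seq_len(q), "-")) / max(q - 1L, 1L)
    if (weights == "linear") 1 - d else 1 - d^2
  }
  po <- sum(W * p)
  pe <- sum(W * outer(rowSums(p), colSums(p)))
  undefined <- abs(1 - pe) < 1e-12
  kappa <- if (undefined) NA_real_ else (po - pe) / (1 - pe)
  structure(
    list(kappa = kappa,
         observed_agreement = po,
         expected_agreement = pe,
         band = if (undefined) NA_character_ else kappa_band(kappa),
         table = tab,
         weights = weights,
         undefined = undefined),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined) {
    cat("<kappa_result> undefined (expected agreement = 1)\n")
  } else {
    cat(sprintf(
      "<kappa_result> kappa = %.3f (%s); observed %.3f, expected %.3f\n",
      x$kappa, x$band, x$observed_agreement, x$expected_agreement))
  }
  invisible(x)
}

#' Non-prewhitening matched-filter SNR for a disk signal
#'
#' Template SNR of a uniform disk of the given diameter and contrast against
#' white noise of the given per-pixel SD:
#' `SNR = (contrast / noise_sd) * sqrt(pi * diameter^2 / 4) / pixel_spacing`.
#' This is a white-noise approximation; when a measured noise power spectrum
#' is supplied the variance term is instead weighted by the NPS over the
#' disk template spectrum (non-prewhitening observer with correlated noise).
#'
#' @param diameter disk diameter in mm.
#' @param contrast_hu disk contrast in HU.
#' @param noise_sd_hu per-pixel noise SD in HU.
#' @param pixel_spacing mm per pixel.
#' @param nps optional `spectrum_result` describing the noise texture.
#' @return unitless SNR.
#' @examples
#' npw_disk_snr(6, 10, 15.4, 0.390625)  # ~8.84
#' @export
npw_disk_snr <- function(diameter, contrast_hu, noise_sd_hu, pixel_spacing,
                         nps = NULL) {
  stopifnot_scalar(diameter, "diameter", positive = TRUE)
  stopifnot_scalar(contrast_hu, "contrast_hu", positive = TRUE)
  stopifnot_scalar(noise_sd_hu, "noise_sd_hu", positive = TRUE)
  stopifnot_scalar(pixel_spacing, "pixel_spacing", positive = TRUE)
  if (is.null(nps)) {
    return((contrast_hu / noise_sd_hu) * sqrt(pi * diameter^2 / 4) /
             pixel_spacing)
  }
  if (!inherits(nps, "spectrum_result")) {
    stop("`nps` must be a spectrum_result", call. = FALSE)
  }
  # disk template spectrum (Airy pattern): W(f) = C * A * 2 J1(x)/x,
  # x = pi * d * f; radial integrals 2 pi f df over the measured axis
  f <- nps$frequencies
  x <- pi * diameter * f
  W2 <- (contrast_hu * pi * diameter^2 / 4)^2 *
    ifelse(x < 1e-9, 1, (2 * besselJ(x, 1) / x))^2
  # rescale the measured NPS so its 2-D integral matches the requested
  # noise variance (texture from `nps`, magnitude from `noise_sd_hu`)
  scale <- noise_sd_hu^2 / nps$nps_2d_integral
  num <- trapz(f, 2 * pi * f * W2)
  den <- trapz(f, 2 * pi * f * W2 * nps$nps * scale)
  if (den <= 0) stop("degenerate NPS: zero template-weighted power",
                     call. = FALSE)
  num / sqrt(den)
}

#' Minimum detectable diameter under the model-observer surrogate
#'
#' Evaluates the non-prewhitening SNR for each candidate diameter and
#' reports the smallest one whose SNR reaches the decision threshold
#' (Rose-type criterion, default 5). The result is monotone: lowering the
#' noise never increases the minimum detectable diameter.
#'
#' @param contrast_hu disk contrast in HU.
#' @param noise_sd_hu per-pixel noise SD in HU.
#' @param pixel_spacing mm per pixel.
#' @param diameters candidate ladder in mm, descending (default the
#'   15..2 mm low-contrast ladder).
#' @param threshold decision SNR.
#' @param nps optional `spectrum_result` for correlated noise.
#' @return a `detectability_estimate`: `min_detectable_diameter` (`NA` when
#'   none qualifies), `per_diameter_snr`, `threshold`, `label`.
#' @export
min_detectable_diameter <- function(contrast_hu, noise_sd_hu, pixel_spacing,
                                    diameters = c(15, 9, 8, 7, 6, 5, 4, 3,
                                                  2),
                                    threshold = 5.0, nps = NULL) {
  if (!length(diameters)) stop("`diameters` must be non-empty",
                               call. = FALSE)
  if (is.unsorted(rev(diameters), strictly = TRUE)) {
    stop("`diameters` must be strictly descending", call. = FALSE)
  }
  snr <- vapply(diameters, npw_disk_snr, numeric(1),
                contrast_hu = contrast_hu, noise_sd_hu = noise_sd_hu,
                pixel_spacing = pixel_spacing, nps = nps)
  names(snr) <- sprintf("%g", diameters)
  ok <- snr >= threshold
  mdd <- if (any(ok)) min(diameters[ok]) else NA_real_
  structure(
    list(min_detectable_diameter = mdd,
         per_diameter_snr = snr,
         threshold = threshold,
         label = if (is.na(mdd)) "none detectable" else
           sprintf("%g mm", mdd)),
    class = "detectability_estimate"
  )
}

#' @export
print.detectability_estimate <- function(x, ...) {
  cat(sprintf(
    "<detectability_estimate> minimum detectable diameter: %s (SNR threshold %g)\n",
    x$label, x$threshold))
  invisible(x)
}
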
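# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DFT sample frequencies
#'
#' Frequencies (cycles per unit of `spacing`) associated with the output of
#' [stats::fft()] for `n` samples, in FFT order (non-negative first, then
#' negative).
#' @param n number of samples.
#' @param spacing sample spacing.
#' @return numeric vector of length `n`.
#' @keywords internal
#' @noRd
fft_freq <- function(n, spacing) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  k / (n * spacing)
}

# trapezoidal integral of y over x (x strictly increasing)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# round half away from zero (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

# sin(x)/x with the removable singularity filled
sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)

# Tukey (tapered cosine) window; alpha = total tapered fraction
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  e <- alpha / 2
  if (e > 0) {
    lo <- t < e
    hi <- t > 1 - e
    w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / e - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1) / e + 1)))
  }
  w
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# physical x (mm, right-positive) of each column centre / y (mm, up-positive)
# of each row centre; origin at image centre
pixel_x <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing
pixel_y <- function(n, spacing) ((n + 1) / 2 - seq_len(n)) * spacing

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
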
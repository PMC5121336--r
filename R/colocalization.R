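#' Pearson colocalization coefficient
#'
#' Pearson correlation of two channels' pixel intensities over a mask.
#'
#' @param channel_a,channel_b numeric matrices of identical dimensions.
#' @param mask logical matrix of the same dimensions selecting pixels
#'   (default: all).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_colocalization <- function(channel_a, channel_b, mask = NULL) {
  stopifnot(all(dim(channel_a) == dim(channel_b)))
  if (is.null(mask)) mask <- array(TRUE, dim(channel_a))
  stopifnot(all(dim(mask) == dim(channel_a)))
  a <- channel_a[mask]; b <- channel_b[mask]
  if (length(a) < 2L) stop("pearson_colocalization: mask selects < 2 pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("pearson_colocalization: zero-variance channel; correlation undefined")
  }
  stats::cor(a, b)
}

#' Manders colocalization coefficients
#'
#' `M1` is the fraction of channel A's total intensity found in pixels where
#' channel B exceeds its threshold; `M2` is the symmetric quantity for
#' channel B over channel A's thresholded pixels.
#'
#' @param channel_a,channel_b numeric matrices of identical dimensions,
#'   non-negative.
#' @param threshold_a,threshold_b intensity thresholds (default 0: any
#'   strictly positive pixel counts as occupied).
#' @return named numeric vector `c(M1 = ..., M2 = ...)`, each in `[0, 1]`.
#' @export
manders_coefficients <- function(channel_a, channel_b, threshold_a = 0,
                                 threshold_b = 0) {
  stopifnot(all(dim(channel_a) == dim(channel_b)),
            threshold_a >= 0, threshold_b >= 0)
  sa <- sum(channel_a); sb <- sum(channel_b)
  if (sa == 0 || sb == 0) {
    stop("manders_coefficients: all-zero channel")
  }
  c(M1 = sum(channel_a[channel_b > threshold_b]) / sa,
    M2 = sum(channel_b[channel_a > threshold_a]) / sb)
}
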
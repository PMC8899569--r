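#' Fraction cleaved from T7E1 gel densitometry
#'
#' The fraction cleaved is the total relative density of the cleavage bands
#' divided by the sum of the relative densities of the cleavage and uncut
#' bands.
#'
#' @param cleaved_band_densities nonnegative relative densities of the
#'   cleavage bands (one or more).
#' @param uncut_density nonnegative relative density of the uncut band.
#' @return proportion in `[0, 1]`.
#' @examples
#' fractionCleaved(c(0.3, 0.45), 0.25)  # 0.75
#' @export
fractionCleaved <- function(cleaved_band_densities, uncut_density) {
  d <- c(cleaved_band_densities, uncut_density)
  if (length(cleaved_band_densities) < 1L) stop("at least one cleavage band required")
  if (any(!is.finite(d)) || any(d < 0)) stop("densities must be finite and nonnegative")
  tot <- sum(d)
  if (tot == 0) stop("all band densities are zero; fraction cleaved undefined")
  sum(cleaved_band_densities) / tot
}

#' Variant frequency from the fraction cleaved
#'
#' Converts a T7E1 cleaved fraction into a variant frequency via
#' `100 * (1 - sqrt(1 - f))`: under random reannealing, a variant at
#' frequency p/100 produces mismatched (cleavable) heteroduplexes with
#' probability `1 - (1 - p/100)^2`. Monotone increasing on `[0, 1]`.
#'
#' Inputs within 1e-12 of the bounds are clipped (floating-point noise);
#' anything further outside `[0, 1]` is an error, never a silent clip.
#'
#' @param fraction_cleaved proportion(s) in `[0, 1]`; vectorized.
#' @return variant frequency in percent.
#' @examples
#' t7e1VariantFrequency(0.75)  # 50
#' @export
t7e1VariantFrequency <- function(fraction_cleaved) {
  f <- fraction_cleaved
  if (any(!is.finite(f))) stop("fraction cleaved must be finite")
  eps <- 1e-12
  if (any(f < -eps | f > 1 + eps)) {
    stop("fraction cleaved must lie in [0, 1]")
  }
  f <- pmin(pmax(f, 0), 1)
  100 * (1 - sqrt(1 - f))
}
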
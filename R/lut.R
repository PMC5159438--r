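#' Eight-bin pseudocolor intensity lookup table
#'
#' The fixed calibration scale used to score ISH signal intensity. Each of the
#' 256 gray index positions of an 8-bit image (0 = strongest signal, 255 =
#' white background) falls into one of eight bins; each bin carries a display
#' color and an integer intensity scale running from 7 ("very very high"
#' expression, red, index 0--31) down to 0 ("no signal", black, index
#' 192--255). The four strongest bins span 32 index positions each, the two
#' weak-signal bins 16 each, and the no-signal bin the top 64.
#'
#' @return A data frame with one row per bin and columns `lo`, `hi` (inclusive
#'   integer index bounds), `scale` (7 to 0), `label`, and `r`, `g`, `b`
#'   (display color, 0--255).
#' @examples
#' intensity_lut()
#' @export
intensity_lut <- function() {
  data.frame(
    lo    = c(0L, 32L, 64L, 96L, 128L, 160L, 176L, 192L),
    hi    = c(31L, 63L, 95L, 127L, 159L, 175L, 191L, 255L),
    scale = 7:0,
    label = c("very very high", "very high", "high", "medium",
              "low", "very low", "very very low", "no signal"),
    r = c(255L, 255L, 255L, 255L,   0L,   0L,   0L, 0L),
    g = c(  0L, 124L, 190L, 255L, 255L, 123L,   0L, 0L),
    b = c(  0L,   0L,   0L,   0L,   0L, 255L, 255L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Four-level density bins
#'
#' Classifies the percent density Np (signal pixels as a percentage of the
#' Nissl-positive reference pixels in the same ROI) into the density scale D:
#' 1 = sparse (0--5\%), 2 = scattered (5--20\%), 3 = medium (20--70\%),
#' 4 = high/wide-spread (>70\%). Bins are half-open `[lo, hi)`; the last bin
#' is closed at 100.
#'
#' @return A data frame with columns `lo`, `hi` (percent), `scale`, `label`.
#' @export
density_bins <- function() {
  data.frame(
    lo = c(0, 5, 20, 70),
    hi = c(5, 20, 70, 100),
    scale = 1:4,
    label = c("sparse", "scattered", "medium", "high/wide-spread"),
    stringsAsFactors = FALSE
  )
}

validate_lut <- function(lut) {
  stopifnot(is.data.frame(lut),
            all(c("lo", "hi", "scale", "r", "g", "b") %in% names(lut)))
  if (nrow(lut) != 8L)
    stop("intensity LUT must have exactly 8 bins")
  if (any(lut$lo[-1] != lut$hi[-nrow(lut)] + 1L) || lut$lo[1] != 0L ||
      lut$hi[nrow(lut)] != 255L)
    stop("intensity LUT bins must partition [0, 255] with no gap or overlap")
  if (any(diff(lut$scale) != -1L) || lut$scale[1] != 7L)
    stop("intensity LUT scales must decrease strictly from 7 to 0")
  invisible(lut)
}

validate_density_bins <- function(bins) {
  stopifnot(is.data.frame(bins), all(c("lo", "hi", "scale") %in% names(bins)))
  if (bins$lo[1] != 0 || bins$hi[nrow(bins)] != 100 ||
      any(bins$lo[-1] != bins$hi[-nrow(bins)]))
    stop("density bins must partition [0, 100]")
  if (any(diff(bins$scale) <= 0))
    stop("density scales must be increasing")
  invisible(bins)
}

#' Intensity scale of a mean gray value
#'
#' Looks up the intensity scale L (7 to 0) of a mean gray value on the 0--255
#' 8-bit scale. A value falls in the bin whose half-open float interval
#' `[lo, hi + 1)` contains it; 255 maps to the last ("no signal") bin.
#'
#' @param mean_gray Numeric vector of mean gray values in \[0, 255\].
#' @param lut Intensity lookup table, by default [intensity_lut()].
#' @return Integer vector of intensity scales in 0--7.
#' @examples
#' intensity_scale(169.18) # 2
#' intensity_scale(0)      # 7
#' @export
intensity_scale <- function(mean_gray, lut = intensity_lut()) {
  validate_lut(lut)
  if (!is.numeric(mean_gray) || anyNA(mean_gray))
    stop("mean_gray must be numeric and non-missing")
  if (any(mean_gray < 0 | mean_gray > 255))
    stop("mean_gray out of range [0, 255]")
  # half-open [lo, hi + 1); findInterval on the left edges does exactly this
  idx <- findInterval(mean_gray, lut$lo)
  lut$scale[idx]
}

#' Density scale of a percent density
#'
#' Looks up the density scale D (1 to 4) of a percent density Np. Bins are
#' half-open `[lo, hi)`; the last bin is closed so that 100 maps to scale 4.
#'
#' @param np Numeric vector of percent densities in \[0, 100\].
#' @param bins Density bins, by default [density_bins()].
#' @return Integer vector of density scales in 1--4.
#' @examples
#' density_scale(47.76) # 3
#' @export
density_scale <- function(np, bins = density_bins()) {
  validate_density_bins(bins)
  if (!is.numeric(np) || anyNA(np))
    stop("np must be numeric and non-missing")
  if (any(np < 0 | np > 100))
    stop("np out of range [0, 100]")
  idx <- findInterval(np, bins$lo, rightmost.closed = FALSE)
  idx[np >= bins$hi[nrow(bins)]] <- nrow(bins)
  bins$scale[idx]
}

#' Pseudocolor rendering of an 8-bit image
#'
#' Maps every pixel to the display color of its LUT bin. This is a
#' visualization aid only: the underlying gray values, which all scoring
#' operates on, are untouched.
#'
#' @param img Integer matrix of gray values in \[0, 255\].
#' @param lut Intensity lookup table.
#' @return An `height x width x 3` integer array of RGB values in 0--255.
#' @export
apply_pseudocolor <- function(img, lut = intensity_lut()) {
  img <- as_gray8(img)
  validate_lut(lut)
  idx <- findInterval(as.vector(img), lut$lo)
  out <- array(0L, dim = c(nrow(img), ncol(img), 3L))
  out[, , 1] <- lut$r[idx]
  out[, , 2] <- lut$g[idx]
  out[, , 3] <- lut$b[idx]
  out
}
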
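#' Expressing-pixel mask of an ROI
#'
#' A pixel counts as expressing when it lies inside the requested ROI and its
#' gray value is below `background_threshold` (default 192, the start of the
#' LUT's "no signal" bin: index positions 192--255 correspond to background).
#'
#' @param img Integer gray matrix in \[0, 255\].
#' @param roi A [region_mask()] of the same shape.
#' @param label Integer ROI label present in `roi`.
#' @param background_threshold Gray values `>=` this are background
#'   (default 192).
#' @return Logical matrix, `TRUE` where the pixel expresses.
#' @export
expressing_pixel_mask <- function(img, roi, label, background_threshold = 192) {
  img <- as_gray8(img)
  stopifnot(inherits(roi, "region_mask"))
  if (!all(dim(img) == dim(roi$labels)))
    stop("image and region mask shapes differ")
  if (!any(roi$labels == label))
    stop("label ", label, " not present in region mask")
  roi$labels == label & img < background_threshold
}

#' Mean gray value over expressing pixels
#'
#' @param img Integer gray matrix.
#' @param mask Logical matrix of the same shape (e.g. from
#'   [expressing_pixel_mask()]).
#' @return Mean of the gray values where `mask` is `TRUE`, or `NA_real_` with
#'   a warning when the mask is empty (no signal; the caller records L = 0).
#' @export
mean_gray_expressing <- function(img, mask) {
  img <- as_gray8(img)
  if (!is.logical(mask) || !all(dim(img) == dim(mask)))
    stop("mask must be a logical matrix matching the image shape")
  if (!any(mask)) {
    warning("no expressing pixels in mask; region has no signal")
    return(NA_real_)
  }
  mean(img[mask])
}

#' Count positively expressing pixels in an ROI
#'
#' The count is the number of `TRUE` pixels in the expressing mask. With
#' `watershed = TRUE` touching signal blobs are split before blob statistics
#' are computed (requires the EBImage package); splitting never changes the
#' pixel count, which is returned either way, with the number of blobs
#' attached as attribute `"n_blobs"`.
#'
#' @inheritParams expressing_pixel_mask
#' @param watershed Also report the number of split signal blobs.
#' @return Integer pixel count (with attribute `n_blobs` when
#'   `watershed = TRUE`).
#' @export
count_positive_pixels <- function(img, roi, label, background_threshold = 192,
                                  watershed = FALSE) {
  m <- expressing_pixel_mask(img, roi, label, background_threshold)
  n <- sum(m)
  if (watershed) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("watershed blob statistics require the EBImage package")
    lab <- if (n > 0)
      EBImage::watershed(EBImage::distmap(EBImage::Image(m * 1)))
    else m * 0
    attr(n, "n_blobs") <- length(setdiff(unique(as.vector(EBImage::imageData(lab))), 0))
  }
  n
}

#' Percent density of signal relative to the Nissl reference
#'
#' Np = 100 x (n_signal / pixel_area) / (n_reference / pixel_area). The pixel
#' area (the smallest pixel, 0.17 square micrometers) cancels analytically
#' and is kept only as the documented calibration constant; the result is
#' capped at 100.
#'
#' @param n_signal Signal pixel count in the ROI of the ISH image.
#' @param n_reference Positive pixel count in the same ROI of the Nissl image.
#' @param pixel_area Area of one pixel in square micrometers (default 0.17).
#' @return Percent density in \[0, 100\].
#' @examples
#' density_percent(25, 100) # 25
#' @export
density_percent <- function(n_signal, n_reference, pixel_area = 0.17) {
  if (any(n_reference == 0))
    stop("undefined density: reference (Nissl) pixel count is zero")
  if (any(n_signal < 0) || any(n_reference < 0) || pixel_area <= 0)
    stop("pixel counts must be non-negative and pixel_area positive")
  np <- 100 * (n_signal / pixel_area) / (n_reference / pixel_area)
  pmin(np, 100)
}

#' Expression factor from per-section (L, D) pairs
#'
#' E is the mean over sections of the per-section product L_i x D_i
#' (`"mean_of_products"`, the canonical form; the worked-example formula
#' (L1 D1 + L2 D2 + L3 D3) / 3). The alternative reading, product of the two
#' per-plane averages mean(L) x mean(D), coincides when D is constant across
#' sections and is exposed as `method = "product_of_means"`.
#'
#' @param pairs A list of length-2 numeric vectors `c(L, D)` or a two-column
#'   matrix; L in 0--7, D in 1--4 (or 0 for a no-signal section).
#' @param method Averaging form, see above.
#' @return The expression factor E, a number in \[0, 28\].
#' @examples
#' expression_factor(list(c(2, 3), c(2, 3), c(1, 3))) # 5
#' @export
expression_factor <- function(pairs,
                              method = c("mean_of_products", "product_of_means")) {
  method <- match.arg(method)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (!is.matrix(pairs) || ncol(pairs) != 2L || nrow(pairs) < 1L)
    stop("pairs must be a non-empty list of (L, D) pairs")
  L <- pairs[, 1]; D <- pairs[, 2]
  if (any(L < 0 | L > 7) || any(D < 0 | D > 4))
    stop("L must lie in 0-7 and D in 0-4")
  if (method == "mean_of_products") mean(L * D) else mean(L) * mean(D)
}

#' Category of an expression factor
#'
#' E = 0 is "none"; otherwise lower-inclusive half-open bins:
#' (0, 6) very low, \[6, 11) low, \[11, 17) moderate, \[17, 22) high,
#' \[22, 28\] very high.
#'
#' @param E Numeric vector of expression factors in \[0, 28\].
#' @return Character vector of categories.
#' @examples
#' categorize_expression(c(0, 5, 12, 28))
#' @export
categorize_expression <- function(E) {
  if (any(E < 0 | E > 28) || anyNA(E))
    stop("E out of range [0, 28]")
  out <- character(length(E))
  out[E == 0] <- "none"
  out[E > 0 & E < 6] <- "very low"
  out[E >= 6 & E < 11] <- "low"
  out[E >= 11 & E < 17] <- "moderate"
  out[E >= 17 & E < 22] <- "high"
  out[E >= 22] <- "very high"
  out
}

#' Score one ISH/Nissl section pair for one ROI
#'
#' @inheritParams expressing_pixel_mask
#' @param nissl Matched Nissl reference image (same mask).
#' @param lut,dbins Calibration scales.
#' @return One-row data frame with `mean_gray`, `L`, `n_signal`,
#'   `n_reference`, `Np`, `D`.
#' @keywords internal
score_section <- function(img, nissl, roi, label, background_threshold = 192,
                          lut = intensity_lut(), dbins = density_bins()) {
  m <- expressing_pixel_mask(img, roi, label, background_threshold)
  n_ref <- sum(expressing_pixel_mask(nissl, roi, label, background_threshold))
  if (!any(m)) {
    return(data.frame(mean_gray = NA_real_, L = 0L, n_signal = 0L,
                      n_reference = n_ref, Np = 0, D = 0L))
  }
  mg <- mean(img[m])
  n_sig <- sum(m)
  np <- density_percent(n_sig, n_ref)
  data.frame(mean_gray = mg, L = intensity_scale(mg, lut),
             n_signal = n_sig, n_reference = n_ref,
             Np = np, D = density_scale(np, dbins))
}

#' Score a gene in one ROI over the sections of one sagittal plane
#'
#' Runs the full scoring schema over 1 or more (typically 2--3) matched
#' ISH/Nissl section pairs in one plane: per section the expressing-pixel
#' mask, mean gray value and intensity scale L, the signal and Nissl pixel
#' counts, percent density Np and density scale D; then the expression
#' factor E (mean over sections of L_i x D_i) and its category. A section
#' with no expressing pixels contributes (L, D) = (0, 0).
#'
#' @param ish_images List of gray matrices (the ISH sections of one plane).
#' @param nissl_images List of matched Nissl gray matrices, same length.
#' @param roi Shared [region_mask()].
#' @param label ROI label to score.
#' @param gene Gene symbol.
#' @param plane One of `"lateral"`, `"parasagittal"`, `"midsagittal"`.
#' @param background_threshold Gray cutoff for expressing pixels.
#' @param lut,dbins Calibration scales.
#' @param method Averaging form passed to [expression_factor()].
#' @return An object of class `region_expression`: gene, region, plane, the
#'   per-section score table, E and category.
#' @export
score_gene_region <- function(ish_images, nissl_images, roi, label, gene,
                              plane = c("parasagittal", "lateral", "midsagittal"),
                              background_threshold = 192,
                              lut = intensity_lut(), dbins = density_bins(),
                              method = "mean_of_products") {
  plane <- match.arg(plane)
  if (!is.list(ish_images)) ish_images <- list(ish_images)
  if (!is.list(nissl_images)) nissl_images <- list(nissl_images)
  if (length(ish_images) < 1L)
    stop("at least one ISH section is required")
  if (length(nissl_images) != length(ish_images))
    stop("every ISH section needs a matched Nissl image")
  stopifnot(inherits(roi, "region_mask"))
  if (!any(roi$labels == label))
    stop("label ", label, " not present in region mask")

  sections <- do.call(rbind, lapply(seq_along(ish_images), function(i) {
    s <- score_section(ish_images[[i]], nissl_images[[i]], roi, label,
                       background_threshold, lut, dbins)
    cbind(section = i, s)
  }))
  E <- expression_factor(as.matrix(sections[, c("L", "D")]), method = method)
  structure(
    list(gene = gene,
         region = unname(roi$names[[as.character(label)]]),
         region_label = as.integer(label),
         plane = plane,
         sections = sections,
         E = E,
         category = categorize_expression(E)),
    class = "region_expression")
}

#' @export
print.region_expression <- function(x, ...) {
  cat(sprintf("%s in %s (%s plane): E = %.3g [%s]\n",
              x$gene, x$region, x$plane, x$E, x$category))
  print(x$sections, row.names = FALSE)
  invisible(x)
}

#' Flatten region_expression records to the per-section score table
#'
#' @param records A `region_expression` or a list of them.
#' @return Data frame with columns gene, region, plane, section_id,
#'   mean_gray, L, n_signal, n_reference, Np, D, E, category.
#' @export
scores_table <- function(records) {
  if (inherits(records, "region_expression")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    data.frame(gene = r$gene, region = r$region, plane = r$plane,
               section_id = r$sections$section,
               mean_gray = r$sections$mean_gray, L = r$sections$L,
               n_signal = r$sections$n_signal,
               n_reference = r$sections$n_reference,
               Np = r$sections$Np, D = r$sections$D,
               E = r$E, category = r$category,
               stringsAsFactors = FALSE)
  }))
}

#' Write per-section scores as TSV
#'
#' @param records A `region_expression` or list of them.
#' @param path Output TSV.
#' @export
write_scores <- function(records, path) {
  utils::write.table(scores_table(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
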
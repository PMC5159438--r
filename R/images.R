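#' Validate / coerce an 8-bit grayscale image
#'
#' @param x Numeric matrix with values in \[0, 255\].
#' @return An integer matrix of gray values.
#' @keywords internal
as_gray8 <- function(x) {
  if (length(x) == 0) stop("empty image")
  if (is.array(x) && length(dim(x)) == 3L) return(to_gray8(x))
  if (!is.matrix(x)) stop("image must be a matrix of gray values")
  if (anyNA(x) || any(x < 0 | x > 255))
    stop("gray values must lie in [0, 255]")
  storage.mode(x) <- "integer"
  x
}

#' Convert an RGB or grayscale raster to an 8-bit gray image
#'
#' RGB input is collapsed to gray as the unweighted mean of the three
#' channels, rounded half-up and clipped to \[0, 255\] (the default
#' conversion of common image tools); grayscale input passes through
#' unchanged. An optional luminance weighting (0.299, 0.587, 0.114) is
#' available.
#'
#' @param image Either a gray matrix or an `h x w x 3` (or `h x w x 4`,
#'   alpha ignored) array, channel values in 0--255.
#' @param weights `"mean"` (default) or `"luminance"`.
#' @return Integer matrix of gray values in \[0, 255\].
#' @examples
#' to_gray8(array(c(30, 60, 90), dim = c(1, 1, 3))) # 60
#' @export
to_gray8 <- function(image, weights = c("mean", "luminance")) {
  weights <- match.arg(weights)
  if (length(image) == 0) stop("empty image")
  if (is.matrix(image)) return(as_gray8(image))
  d <- dim(image)
  if (length(d) != 3L || !d[3] %in% c(3L, 4L))
    stop("image must be a gray matrix or an RGB(A) array")
  if (anyNA(image) || any(image < 0 | image > 255))
    stop("channel values must lie in [0, 255]")
  w <- if (weights == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  g <- image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3]
  g <- floor(g + 0.5)                      # round half-up
  g[g < 0] <- 0; g[g > 255] <- 255
  m <- matrix(as.integer(g), d[1], d[2])
  m
}

#' Region-of-interest label mask
#'
#' Binds pixels of a section image to named anatomical ROIs. `labels` is an
#' integer matrix of the same shape as the paired image, 0 meaning outside
#' any ROI; `names` maps each nonzero label to an anatomical acronym.
#'
#' @param labels Integer matrix of non-negative labels.
#' @param names Named character vector: `names(names)` are the label numbers
#'   as strings, values the region names (e.g. `"CTX-L5"`).
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(labels, names) {
  if (!is.matrix(labels) || anyNA(labels) || any(labels < 0))
    stop("labels must be a matrix of non-negative integers")
  storage.mode(labels) <- "integer"
  used <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!all(as.character(used) %in% base::names(names)))
    stop("every nonzero label needs a name: missing ",
         paste(setdiff(as.character(used), base::names(names)), collapse = ", "))
  structure(list(labels = labels, names = names), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  used <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat("region_mask:", nrow(x$labels), "x", ncol(x$labels), "pixels,",
      length(used), "ROI(s)\n")
  for (l in used)
    cat(sprintf("  %3d  %-12s %d px\n", l, x$names[[as.character(l)]],
                sum(x$labels == l)))
  invisible(x)
}

## ---- image / mask file IO ----------------------------------------------

#' Read an 8-bit grayscale (or RGB) PNG image
#'
#' @param path PNG file.
#' @return Integer gray matrix (RGB files are converted via [to_gray8()]).
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  to_gray8(if (is.matrix(x)) round(x * 255) else x * 255)
}

#' Write an 8-bit grayscale PNG image
#'
#' @param img Integer gray matrix in \[0, 255\].
#' @param path Output file.
#' @export
write_gray_png <- function(img, path) {
  img <- as_gray8(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a region mask from a label PNG and a label,name CSV
#'
#' The PNG stores the integer label of each pixel as its 8-bit gray value
#' (so at most 255 ROIs); the CSV has columns `label` and `name`.
#'
#' @param mask_path Label image (PNG).
#' @param labels_path Two-column CSV mapping label to region name.
#' @return A [region_mask()].
#' @export
read_region_mask <- function(mask_path, labels_path) {
  m <- png::readPNG(mask_path)
  if (!is.matrix(m)) m <- to_gray8(m * 255) else m <- round(m * 255)
  tab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(tab)))
    stop("labels file needs columns 'label' and 'name'")
  nm <- stats::setNames(as.character(tab$name), as.character(tab$label))
  region_mask(matrix(as.integer(m), nrow(m), ncol(m)), nm)
}

#' Write a region mask as a label PNG plus a label,name CSV
#'
#' @param mask A [region_mask()].
#' @param mask_path,labels_path Output files.
#' @export
write_region_mask <- function(mask, mask_path, labels_path) {
  stopifnot(inherits(mask, "region_mask"))
  if (max(mask$labels) > 255) stop("label PNG supports at most 255 ROIs")
  png::writePNG(mask$labels / 255, mask_path)
  utils::write.csv(
    data.frame(label = as.integer(names(mask$names)),
               name = unname(mask$names)),
    labels_path, row.names = FALSE, quote = FALSE)
  invisible(mask_path)
}
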
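#' Assemble region_expression records into a gene x region matrix
#'
#' One row per gene, one column per region. Several records for the same
#' (gene, region) — e.g. different planes — are averaged. Cells with no
#' record are set to `fill` and flagged in the `"filled"` attribute.
#' Conflicting categories among duplicates raise a warning, not an error.
#'
#' @param records A `region_expression` or a list of them.
#' @param fill Value for missing cells (default 0).
#' @return Numeric matrix (genes x regions) with attribute `filled`, a
#'   logical matrix marking cells that received `fill`.
#' @export
build_matrix <- function(records, fill = 0) {
  if (inherits(records, "region_expression")) records <- list(records)
  if (length(records) < 1L) stop("no records")
  genes <- unique(vapply(records, `[[`, "", "gene"))
  regions <- unique(vapply(records, `[[`, "", "region"))
  m <- matrix(NA_real_, length(genes), length(regions),
              dimnames = list(genes, regions))
  cats <- matrix(NA_character_, length(genes), length(regions))
  n <- matrix(0L, length(genes), length(regions))
  for (r in records) {
    i <- match(r$gene, genes); j <- match(r$region, regions)
    m[i, j] <- if (n[i, j] == 0L) r$E else m[i, j] + r$E
    n[i, j] <- n[i, j] + 1L
    if (!is.na(cats[i, j]) && cats[i, j] != r$category)
      warning(sprintf("conflicting categories for %s / %s: %s vs %s",
                      r$gene, r$region, cats[i, j], r$category))
    cats[i, j] <- r$category
  }
  m[n > 0] <- m[n > 0] / n[n > 0]
  filled <- n == 0L
  m[filled] <- fill
  attr(m, "filled") <- filled
  m
}

#' Hierarchically cluster one axis of an expression matrix
#'
#' Agglomerative average-linkage clustering of the genes (rows) or regions
#' (columns), under Euclidean distance (default) or one-minus-Pearson
#' correlation distance. The merge sequence of [stats::hclust()] is
#' deterministic for a given input ordering; with exactly tied merge
#' heights the earlier-indexed pair is merged first, so labels sorted
#' lexicographically give a reproducible tree.
#'
#' @param mat Numeric matrix (genes x regions).
#' @param axis `"genes"` (rows) or `"regions"` (columns).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage Agglomeration method, default `"average"`.
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_axis <- function(mat, axis = c("genes", "regions"),
                         metric = c("euclidean", "correlation"),
                         linkage = "average") {
  axis <- match.arg(axis); metric <- match.arg(metric)
  x <- if (axis == "genes") mat else t(mat)
  if (nrow(x) < 2L) stop("need at least 2 items on the clustered axis")
  d <- if (metric == "euclidean") {
    stats::dist(x)
  } else {
    v <- apply(x, 1, stats::var)
    if (any(v == 0))
      stop("constant row(s) under correlation metric: ",
           paste(rownames(x)[v == 0], collapse = ", "))
    stats::as.dist(1 - stats::cor(t(x)))
  }
  stats::hclust(d, method = linkage)
}

#' Export a clustered heatmap: reordered matrix, dendrograms, image
#'
#' Writes `<prefix>_matrix.tsv` (matrix reordered to the dendrogram leaf
#' orders), `<prefix>_genes.nwk` / `<prefix>_regions.nwk` (Newick trees with
#' branch lengths) and `<prefix>_heatmap.png`. The PNG is rendered directly
#' from the cell values (low-to-high mapped through a white-to-red ramp) so
#' re-export from identical inputs is byte-identical.
#'
#' @param mat Genes x regions matrix.
#' @param row_dendro,col_dendro [stats::hclust] trees for rows and columns,
#'   or `NULL` to keep an axis unordered.
#' @param prefix Output path prefix (non-empty).
#' @param cell_px Pixel size of one heatmap cell (default 12).
#' @return Invisibly, the paths written.
#' @export
export_heatmap <- function(mat, row_dendro, col_dendro, prefix, cell_px = 12) {
  if (!is.character(prefix) || length(prefix) != 1L || !nzchar(prefix))
    stop("empty output prefix")
  check <- function(hc, labs, what) {
    if (is.null(hc)) return(seq_along(labs))
    if (!inherits(hc, "hclust") || length(hc$order) != length(labs) ||
        !setequal(hc$labels, labs))
      stop("dendrogram does not match matrix ", what)
    match(hc$labels[hc$order], labs)
  }
  ro <- check(row_dendro, rownames(mat), "rows")
  co <- check(col_dendro, colnames(mat), "columns")
  m <- mat[ro, co, drop = FALSE]

  paths <- paste0(prefix, c("_matrix.tsv", "_genes.nwk", "_regions.nwk",
                            "_heatmap.png"))
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(row_dendro)) ape::write.tree(ape::as.phylo(row_dendro), paths[2])
  if (!is.null(col_dendro)) ape::write.tree(ape::as.phylo(col_dendro), paths[3])

  rng <- range(m)
  z <- if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
  ramp <- grDevices::colorRamp(c("white", "yellow", "red"))
  rgb01 <- ramp(as.vector(z)) / 255
  img <- array(0, dim = c(nrow(m), ncol(m), 3))
  img[, , 1] <- rgb01[, 1]; img[, , 2] <- rgb01[, 2]; img[, , 3] <- rgb01[, 3]
  big <- img[rep(seq_len(nrow(m)), each = cell_px),
             rep(seq_len(ncol(m)), each = cell_px), , drop = FALSE]
  png::writePNG(big, paths[4])
  invisible(paths)
}
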
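#' Pearson correlation matrix of a gene x sample matrix
#'
#' @param X Numeric matrix, genes in rows, samples (brain structures) in
#'   columns; at least 3 samples.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(X) {
  if (!is.matrix(X) || ncol(X) < 3L)
    stop("need a genes x samples matrix with at least 3 samples")
  v <- apply(X, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(X)[v == 0], collapse = ", "))
  r <- stats::cor(t(X))
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Raises correlations to the soft-threshold power beta to obtain connection
#' strengths: unsigned `a = |r|^beta`, signed `a = ((1 + r)/2)^beta`. The
#' diagonal is fixed to 0 so connectivity sums run over partners only.
#'
#' @param cor_mat Correlation matrix, entries in \[-1, 1\].
#' @param beta Soft-threshold power, > 0 (default 6, the conventional
#'   unsigned default; see [pick_soft_threshold()] for a scale-free fit
#'   scan).
#' @param signed Use the signed transform.
#' @return Symmetric adjacency matrix in \[0, 1\] with `beta` and `signed`
#'   attached as attributes.
#' @export
adjacency <- function(cor_mat, beta = 6, signed = FALSE) {
  if (beta <= 0) stop("beta must be positive")
  if (any(abs(cor_mat) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  a <- if (signed) ((1 + cor_mat) / 2)^beta else abs(cor_mat)^beta
  diag(a) <- 0
  structure(a, beta = beta, signed = signed)
}

#' Topological overlap matrix
#'
#' Standard unsigned topological overlap of a weighted adjacency:
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (u != i, j; guaranteed by the zero diagonal) and
#' `k_i = sum_u a_iu`. The diagonal is set to 1. TOM measures how much two
#' genes share the same network neighborhood in addition to their direct
#' connection; `1 - tom` is the clustering dissimilarity.
#'
#' @param adj Adjacency matrix from [adjacency()] (zero diagonal, \[0, 1\]).
#' @return Symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
tom <- function(adj) {
  a <- unclass(adj)
  if (!isSymmetric(a, tol = 1e-10)) stop("adjacency must be symmetric")
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  denom[denom < 1e-12] <- 1e-12
  t_ <- (L + a) / denom
  diag(t_) <- 1
  # symmetrize away float asymmetry from the matrix product
  (t_ + t(t_)) / 2
}

#' Scale-free topology fit scan over candidate soft-threshold powers
#'
#' For each power, computes the weighted connectivity distribution and the
#' R-squared of the log10(frequency) ~ log10(k) linear fit over connectivity
#' bins (signed negatively when the slope is positive, i.e. not scale-free).
#' Reported for guidance only; nothing is enforced.
#'
#' @param cor_mat Correlation matrix.
#' @param powers Candidate powers (default 1:12).
#' @param signed Signed adjacency.
#' @param n_bins Connectivity histogram bins (default 10).
#' @return Data frame with `power`, `fit_r2`, `slope`, `mean_k`.
#' @export
pick_soft_threshold <- function(cor_mat, powers = 1:12, signed = FALSE,
                                n_bins = 10) {
  out <- lapply(powers, function(b) {
    k <- rowSums(adjacency(cor_mat, beta = b, signed = signed))
    cut_k <- cut(k, breaks = n_bins)
    dk <- tapply(k, cut_k, mean)
    pk <- tapply(k, cut_k, length) / length(k)
    ok <- !is.na(dk) & dk > 0
    if (sum(ok) < 3)
      return(data.frame(power = b, fit_r2 = NA_real_, slope = NA_real_,
                        mean_k = mean(k)))
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    r2 <- summary(fit)$r.squared
    sl <- stats::coef(fit)[2]
    data.frame(power = b, fit_r2 = -sign(sl) * r2, slope = sl,
               mean_k = mean(k))
  })
  do.call(rbind, out)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage clustering of the dissimilarity `1 - tom`, followed by a
#' static cut: join heights are rescaled to \[0, 1\] and the tree is cut at
#' rescaled height `1 - cut_height`, i.e. `cut_height` is the top fraction
#' of the join-height range regarded as between-module structure. Clusters
#' smaller than `min_size` become "unassigned" (label 0). When the
#' expression matrix `X` is supplied, modules whose eigengenes correlate
#' above `merge_kme` are merged iteratively. Module ids are assigned by
#' decreasing size (ties by first gene index), so labeling is deterministic.
#'
#' @param tom_mat TOM matrix from [tom()].
#' @param cut_height Top fraction of the rescaled join-height range cut away
#'   (default 0.25).
#' @param min_size Minimum module size (default 16).
#' @param merge_kme Eigengene correlation above which modules merge
#'   (default 0.8); only applied when `X` is given.
#' @param X Optional genes x samples matrix (same genes) for eigengene
#'   merging.
#' @return Object of class `module_partition`: integer labels named by gene
#'   (0 = unassigned), the dendrogram, and the cut parameters.
#' @export
detect_modules <- function(tom_mat, cut_height = 0.25, min_size = 16,
                           merge_kme = 0.8, X = NULL) {
  if (cut_height <= 0 || cut_height >= 1) stop("cut_height must be in (0, 1)")
  if (min_size < 2) stop("min_size must be at least 2")
  genes <- rownames(tom_mat)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom_mat)))
  d <- 1 - tom_mat
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  hmin <- min(hc$height); hmax <- max(hc$height)
  cut_at <- hmin + (1 - cut_height) * (hmax - hmin)
  raw <- stats::cutree(hc, h = cut_at)

  tab <- table(raw)
  labels <- integer(length(raw))
  big <- as.integer(names(tab)[tab >= min_size])
  for (b in big) labels[raw == b] <- b

  if (!is.null(X) && length(setdiff(unique(labels), 0L)) > 1L) {
    repeat {
      mods <- setdiff(sort(unique(labels)), 0L)
      if (length(mods) < 2L) break
      me <- sapply(mods, function(m)
        module_eigengene(X, genes[labels == m])$values)
      cc <- stats::cor(me)
      diag(cc) <- 0
      if (max(cc) <= merge_kme) break
      ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      labels[labels == mods[ij[2]]] <- mods[ij[1]]
    }
  }

  # relabel 1..K by decreasing size, ties by first member index
  mods <- setdiff(unique(labels), 0L)
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(labels == m), 0L)
    firsts <- vapply(mods, function(m) which(labels == m)[1], 0L)
    ord <- order(-sizes, firsts)
    new <- integer(length(labels))
    for (i in seq_along(ord)) new[labels == mods[ord[i]]] <- i
    labels <- new
  } else {
    warning("all genes unassigned at this cut")
  }
  names(labels) <- genes
  structure(list(labels = labels, dendrogram = hc,
                 params = list(cut_height = cut_height, min_size = min_size,
                               merge_kme = merge_kme)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(factor(x$labels))
  cat("module_partition:", length(x$labels), "genes,",
      sum(names(tab) != "0"), "module(s)\n")
  print(tab)
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the per-gene standardized member submatrix
#' across samples: the unit-norm sample profile that explains the largest
#' share of the module's expression variance. The sign is oriented so the
#' mean correlation with the member genes is non-negative.
#'
#' @param X Genes x samples matrix.
#' @param members Character vector of member gene names (rows of `X`).
#' @return Object of class `eigengene`: `values` (per-sample, unit norm),
#'   `var_explained`, `members`.
#' @export
module_eigengene <- function(X, members) {
  if (length(members) < 1L) stop("module needs at least one member")
  missing <- setdiff(members, rownames(X))
  if (length(missing))
    stop("member gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  Xs <- t(scale(t(X[members, , drop = FALSE])))   # per-gene standardization
  e <- eigen(crossprod(Xs), symmetric = TRUE)
  v <- e$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  cors <- as.vector(stats::cor(t(Xs), v))
  if (mean(cors) < 0) v <- -v
  structure(list(values = stats::setNames(v, colnames(X)),
                 var_explained = e$values[1] / sum(pmax(e$values, 0)),
                 members = members),
            class = "eigengene")
}

#' @export
print.eigengene <- function(x, ...) {
  cat(sprintf("eigengene of %d gene(s), %.1f%% variance explained\n",
              length(x$members), 100 * x$var_explained))
  invisible(x)
}

#' Module membership (kME) with p-values
#'
#' kME is the absolute Pearson correlation between each gene's expression
#' profile and each module eigengene, on a 0--1 scale. The p-value is the
#' two-sided t-transform of the correlation with n - 2 degrees of freedom.
#' Raw p-values are reported by default; `adjust = "BH"` applies
#' Benjamini-Hochberg per eigengene.
#'
#' @param X Genes x samples matrix (>= 3 samples).
#' @param eigengenes A single `eigengene` or a named list of them.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with `gene`, `module`, `kME`, `p_value`. Zero-variance
#'   genes get `NA` kME and are flagged in column `flagged`.
#' @export
kme <- function(X, eigengenes, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (ncol(X) < 3L) stop("need at least 3 samples")
  if (inherits(eigengenes, "eigengene")) eigengenes <- list(`1` = eigengenes)
  if (is.null(names(eigengenes)))
    names(eigengenes) <- seq_along(eigengenes)
  n <- ncol(X)
  v <- apply(X, 1, stats::var)
  out <- do.call(rbind, lapply(names(eigengenes), function(m) {
    eg <- eigengenes[[m]]$values
    r <- suppressWarnings(as.vector(stats::cor(t(X), eg)))
    r[v == 0] <- NA_real_
    k <- abs(r)
    tt <- k * sqrt((n - 2) / pmax(1 - k^2, .Machine$double.eps))
    p <- 2 * stats::pt(-tt, df = n - 2)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    if (adjust == "BH") p <- stats::p.adjust(p, "BH")
    data.frame(gene = rownames(X), module = m, kME = k, p_value = p,
               flagged = v == 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Intramodular connectivity and hub ranking
#'
#' kIM of a gene is the sum of its adjacency weights to the other genes of
#' its own module; the highest-kIM genes of each module are its hubs.
#' Unassigned genes get `NA`.
#'
#' @param adj Adjacency matrix (zero diagonal).
#' @param partition A `module_partition` (or integer label vector named by
#'   gene) covering the adjacency's genes.
#' @return Data frame with `gene`, `module`, `kIM`, and `hub_rank` (rank by
#'   decreasing kIM within module, ties broken by gene label).
#' @export
intramodular_connectivity <- function(adj, partition) {
  labels <- if (inherits(partition, "module_partition")) partition$labels
            else partition
  genes <- rownames(adj)
  if (is.null(genes)) genes <- names(labels)
  if (!setequal(genes, names(labels)))
    stop("partition does not cover the adjacency genes")
  labels <- labels[genes]
  kim <- rep(NA_real_, length(genes))
  for (m in setdiff(unique(labels), 0L)) {
    idx <- which(labels == m)
    kim[idx] <- rowSums(adj[idx, idx, drop = FALSE])
  }
  out <- data.frame(gene = genes, module = as.integer(labels), kIM = kim,
                    hub_rank = NA_integer_, stringsAsFactors = FALSE)
  for (m in setdiff(unique(labels), 0L)) {
    idx <- which(out$module == m)
    ord <- order(-out$kIM[idx], out$gene[idx])   # ties broken by gene label
    out$hub_rank[idx[ord]] <- seq_along(idx)
  }
  out
}

#' Hub genes per module
#'
#' @param connectivity Output of [intramodular_connectivity()].
#' @param k Number of hubs per module (default 5).
#' @return Data frame of the top-`k` genes per module by kIM.
#' @export
top_hubs <- function(connectivity, k = 5) {
  out <- connectivity[!is.na(connectivity$kIM) & connectivity$hub_rank <= k, ]
  out[order(out$module, out$hub_rank), ]
}

#' Node and edge betweenness of a module network
#'
#' Builds the weighted graph of a module (edges kept where the similarity
#' weight exceeds `edge_threshold`), with edge length `1 - weight`, and
#' computes shortest-path node and edge betweenness with standard
#' accumulation over all source-target pairs. Disconnected graphs are
#' allowed; betweenness is then per component.
#'
#' @param w Similarity matrix (adjacency or TOM) with gene dimnames.
#' @param members Gene names of the module.
#' @param edge_threshold Minimum weight for an edge (default 0, keep all
#'   positive-weight edges).
#' @return List with `nodes` (gene, betweenness) and `edges` (gene_a,
#'   gene_b, weight, edge_betweenness) data frames.
#' @export
module_betweenness <- function(w, members, edge_threshold = 0) {
  sub <- w[members, members, drop = FALSE]
  diag(sub) <- 0
  sub[sub <= edge_threshold] <- 0
  if (all(sub == 0)) stop("thresholded module graph has no edges")
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE)
  len <- 1 - igraph::E(g)$weight
  len[len <= 0] <- .Machine$double.eps
  nb <- igraph::betweenness(g, weights = len)
  eb <- igraph::edge_betweenness(g, weights = len)
  ends <- igraph::as_edgelist(g)
  list(nodes = data.frame(gene = names(nb), betweenness = unname(nb),
                          stringsAsFactors = FALSE),
       edges = data.frame(gene_a = ends[, 1], gene_b = ends[, 2],
                          weight = igraph::E(g)$weight,
                          edge_betweenness = eb, stringsAsFactors = FALSE))
}

#' Weighted co-expression module analysis of a gene x sample matrix
#'
#' The one-call pipeline: Pearson correlation, soft-threshold adjacency,
#' topological overlap, module detection (static cut + minimum size +
#' eigengene merging), module eigengenes, kME with p-values, and
#' intramodular connectivity. Per-gene standardization (z-scoring across
#' samples) is applied by default; note Pearson correlation is invariant to
#' it, so it affects only the stored matrix and eigengene scale.
#'
#' @param X Genes x samples numeric matrix with gene rownames.
#' @param beta Soft-threshold power (default 6).
#' @param signed Signed network (default unsigned).
#' @param cut_height,min_size,merge_kme Module detection parameters, see
#'   [detect_modules()].
#' @param standardize Z-score each gene across samples first (default TRUE).
#' @return Object of class `coexpr_fit` with elements `X`, `cor`,
#'   `adjacency`, `tom`, `partition`, `eigengenes`, `kme`, `connectivity`
#'   and `params`.
#' @export
coexpr_modules <- function(X, beta = 6, signed = FALSE, cut_height = 0.25,
                           min_size = 16, merge_kme = 0.8,
                           standardize = TRUE) {
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  if (standardize) X <- t(scale(t(X)))
  r <- correlation_matrix(X)
  a <- adjacency(r, beta = beta, signed = signed)
  tm <- tom(a)
  part <- detect_modules(tm, cut_height = cut_height, min_size = min_size,
                         merge_kme = merge_kme, X = X)
  mods <- setdiff(sort(unique(part$labels)), 0L)
  egs <- stats::setNames(
    lapply(mods, function(m)
      module_eigengene(X, names(part$labels)[part$labels == m])),
    mods)
  kme_tab <- if (length(egs)) kme(X, egs) else NULL
  conn <- intramodular_connectivity(a, part)
  structure(list(X = X, cor = r, adjacency = a, tom = tm, partition = part,
                 eigengenes = egs, kme = kme_tab, connectivity = conn,
                 params = list(beta = beta, signed = signed,
                               cut_height = cut_height, min_size = min_size,
                               merge_kme = merge_kme,
                               standardize = standardize)),
            class = "coexpr_fit")
}

#' @export
print.coexpr_fit <- function(x, ...) {
  tab <- table(x$partition$labels)
  mods <- names(tab)[names(tab) != "0"]
  cat(sprintf("coexpr_fit: %d genes x %d samples, beta = %g (%s)\n",
              nrow(x$X), ncol(x$X), x$params$beta,
              if (x$params$signed) "signed" else "unsigned"))
  cat(sprintf("%d module(s) of sizes %s; %d unassigned\n",
              length(mods),
              paste(sort(as.integer(tab[mods]), decreasing = TRUE),
                    collapse = ", "),
              if ("0" %in% names(tab)) tab[["0"]] else 0L))
  invisible(x)
}

#' @export
summary.coexpr_fit <- function(object, ...) {
  print(object)
  for (m in names(object$eigengenes)) {
    eg <- object$eigengenes[[m]]
    km <- object$kme[object$kme$module == m &
                     object$kme$gene %in% eg$members, ]
    cat(sprintf("  module %s: %d genes, var explained %.2f, mean kME %.2f\n",
                m, length(eg$members), eg$var_explained, mean(km$kME)))
  }
  invisible(object)
}

#' @export
plot.coexpr_fit <- function(x, ...) {
  hc <- x$partition$dendrogram
  labs <- x$partition$labels[hc$labels]
  graphics::par(mfrow = c(2, 1), mar = c(0.5, 4, 2, 1))
  plot(hc, labels = FALSE, hang = -1, main = "Gene dendrogram (1 - TOM)",
       xlab = "", sub = "", ...)
  cols <- c("grey", grDevices::hcl.colors(max(1, max(labs)), "Dark 3"))
  graphics::par(mar = c(2, 4, 0.5, 1))
  graphics::image(matrix(seq_along(hc$order), ncol = 1),
                  col = cols[labs[hc$order] + 1L], axes = FALSE,
                  ylab = "module")
  invisible(x)
}
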
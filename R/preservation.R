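#' Permutation Z-summary module preservation between two networks
#'
#' Tests whether modules defined in a reference gene x sample matrix retain
#' their network properties in a test matrix. Gene sets are intersected by
#' exact name; modules with fewer than 3 genes after intersection are
#' skipped with a warning. For each remaining reference module, two observed
#' statistics are computed in the test network:
#'
#' * density: the mean within-module adjacency;
#' * connectivity: the Pearson correlation between the reference and test
#'   intramodular connectivity (kIM) vectors over the module genes.
#'
#' The permutation null draws `n_perm` random gene sets of the same size
#' from the test network (seeded) and evaluates the same statistics on each.
#' `Z = (observed - null mean) / null sd` per statistic, and
#' `Z_summary = (Z_density + Z_connectivity) / 2`. A statistic whose null
#' standard deviation collapses below 1e-8 (e.g. the connectivity statistic
#' when reference and test data are identical, where every correlation is
#' exactly 1) is flagged `NA` and excluded from the mean. Conventional
#' reading: `Z_summary < 2` no evidence of preservation, 2--10 weak to
#' moderate, `> 10` strong.
#'
#' @param X_ref,X_test Genes x samples matrices with gene rownames.
#' @param partition_ref A `module_partition` (or named integer label vector)
#'   on the reference genes.
#' @param beta,signed Adjacency parameters (default unsigned, beta = 6).
#' @param n_perm Number of permutations, >= 50 (default 200).
#' @param seed RNG seed for the permutation draws.
#' @return Object of class `module_preservation`: a data frame with one row
#'   per module (`module`, `size`, `Z_density`, `Z_connectivity`,
#'   `Z_summary`, `n_perm`, `seed`) plus per-module null summaries in the
#'   `"nulls"` attribute.
#' @export
zsummary <- function(X_ref, X_test, partition_ref, beta = 6, signed = FALSE,
                     n_perm = 200, seed = 1) {
  labels <- if (inherits(partition_ref, "module_partition"))
    partition_ref$labels else partition_ref
  if (n_perm < 50) stop("n_perm must be at least 50")
  common <- intersect(intersect(rownames(X_ref), rownames(X_test)),
                      names(labels))
  dropped <- length(union(rownames(X_ref), rownames(X_test))) - length(common)
  if (dropped > 0)
    message(dropped, " gene(s) outside the ref/test intersection dropped")
  if (length(common) < 4L) stop("too few shared genes between networks")
  X_ref <- X_ref[common, , drop = FALSE]
  X_test <- X_test[common, , drop = FALSE]
  labels <- labels[common]

  a_ref <- adjacency(correlation_matrix(X_ref), beta = beta, signed = signed)
  a_test <- adjacency(correlation_matrix(X_test), beta = beta, signed = signed)
  n <- length(common)

  kim_in <- function(a, idx) rowSums(a[idx, idx, drop = FALSE])
  density_of <- function(a, idx)
    mean(a[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
  stat_pair <- function(idx) {
    c(density = density_of(a_test, idx),
      connectivity = suppressWarnings(
        stats::cor(kim_in(a_ref, idx), kim_in(a_test, idx))))
  }

  mods <- setdiff(sort(unique(labels)), 0L)
  keep <- mods[vapply(mods, function(m) sum(labels == m) >= 3L, TRUE)]
  if (length(keep) < length(mods))
    warning("module(s) smaller than 3 after gene intersection skipped: ",
            paste(setdiff(mods, keep), collapse = ", "))

  set.seed(seed)
  rows <- list(); nulls <- list()
  for (m in keep) {
    idx <- which(labels == m)
    obs <- stat_pair(idx)
    null <- matrix(NA_real_, n_perm, 2,
                   dimnames = list(NULL, c("density", "connectivity")))
    for (p in seq_len(n_perm))
      null[p, ] <- stat_pair(sample.int(n, length(idx)))
    mu <- colMeans(null); sdv <- apply(null, 2, stats::sd)
    z <- (obs - mu) / sdv
    z[sdv < 1e-8] <- NA_real_            # degenerate null, flagged
    if (anyNA(z))
      warning("module ", m, ": zero null sd for ",
              paste(names(z)[is.na(z)], collapse = ", "),
              "; statistic flagged and excluded from Z_summary")
    rows[[as.character(m)]] <- data.frame(
      module = m, size = length(idx),
      Z_density = unname(z["density"]),
      Z_connectivity = unname(z["connectivity"]),
      Z_summary = mean(z, na.rm = TRUE),
      n_perm = n_perm, seed = seed)
    nulls[[as.character(m)]] <- data.frame(
      statistic = colnames(null), observed = unname(obs),
      null_mean = unname(mu), null_sd = unname(sdv))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, nulls = nulls, class = c("module_preservation", "data.frame"))
}

#' @export
print.module_preservation <- function(x, ...) {
  cat("Permutation module preservation (", x$n_perm[1], " permutations)\n",
      sep = "")
  df <- as.data.frame(x)
  df$evidence <- cut(df$Z_summary, c(-Inf, 2, 10, Inf),
                     labels = c("none", "weak-moderate", "strong"))
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a preservation report as TSV
#'
#' @param report A `module_preservation` object.
#' @param path Output TSV.
#' @export
write_preservation <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
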
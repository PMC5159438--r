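# Independent oracles used across tests. Deliberately naive: definitions
# transcribed literally, no shared code with the implementation.

# Topological overlap by element-wise loops over the definition.
bf_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  out <- matrix(1, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Average-linkage agglomeration by exhaustive pair search on the definition
# (mean pairwise distance between clusters); returns the sorted merge heights.
bf_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; bh <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  sort(heights)
}

# Random symmetric adjacency in [0, 1] with zero diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# Fixture spec for round-trip scoring tests: ROIs of 10,000 px with planted
# (p, mu) drawn from bin interiors (mu at least 3 gray levels from any LUT
# bin edge; sigma 2 keeps mu +/- 3 sigma inside the bin's safety margin).
roundtrip_spec <- function(seed) {
  mus <- c(15, 47, 80, 112, 144, 167, 184)   # interiors of scales 7..1
  ps <- c(0, 0.03, 0.10, 0.30, 0.60, 0.85)
  set.seed(1000 + seed)
  ish_fixture_spec(
    rois = data.frame(
      label = 1:3, name = c("R1", "R2", "R3"),
      row0 = 21, col0 = c(11, 131, 251), h = 100, w = 100,
      p = sample(ps, 3, replace = TRUE),
      mu = sample(mus, 3, replace = TRUE), sigma = 2),
    seed = seed)
}
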
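test_that("correlation_matrix matches hand-computed Pearson on a toy", {
  X <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(2, 4, 6, 8),
             g3 = c(4, 3, 2, 1))
  r <- correlation_matrix(X)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["g1", "g2"], 1)
  expect_equal(r["g1", "g3"], -1)
  # definition oracle for a non-trivial pair
  X2 <- rbind(a = c(1, 3, 2, 5), b = c(2, 1, 4, 3), c = c(5, 5, 1, 2))
  r2 <- correlation_matrix(X2)
  orc <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  expect_equal(r2["a", "b"], orc(X2["a", ], X2["b", ]))
  expect_equal(r2["a", "c"], orc(X2["a", ], X2["c", ]))
  expect_error(correlation_matrix(rbind(g1 = c(1, 1, 1), g2 = 1:3)), "g1")
  expect_error(correlation_matrix(X[, 1:2]), "3 samples")
})

test_that("adjacency applies the soft-threshold transforms", {
  r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 1, -0.5, 1, 1), 3)
  a <- adjacency(r, beta = 2)
  expect_equal(a[1, 2], 0.25)
  expect_equal(a[1, 3], 0.25)      # unsigned: |-0.5|^2
  expect_equal(unname(diag(a)), rep(0, 3))
  s <- adjacency(r, beta = 2, signed = TRUE)
  expect_equal(s[1, 3], 0.0625)    # ((1 - 0.5)/2)^2
  expect_equal(s[2, 3], 1)
  expect_error(adjacency(r, beta = 0), "positive")
})

test_that("tom matches the hand-evaluated formula and a brute-force oracle", {
  # two genes fully connected
  a2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(tom(a2)[1, 2], 1)
  # 3-node toy, all pairs 0.5: (0.25 + 0.5)/(1 + 1 - 0.5) = 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  t3 <- tom(a3)
  expect_equal(t3[1, 2], 0.5)
  expect_equal(unname(diag(t3)), rep(1, 3))
  # brute-force equivalence on random 8-gene adjacencies
  for (seed in 1:5) {
    a <- random_adjacency(8, seed)
    expect_lt(max(abs(tom(a) - bf_tom(a))), 1e-10)
    expect_lt(max(abs(tom(a) - t(tom(a)))), 1e-12)   # symmetric
  }
})

test_that("tom dominates its pairwise lower bound", {
  a <- random_adjacency(10, 99)
  k <- rowSums(a)
  lower <- a / (outer(k, k, pmin) + 1 - a)
  tm <- tom(a)
  off <- upper.tri(a)
  expect_true(all(tm[off] >= lower[off] - 1e-12))
})

test_that("module eigengene agrees with an SVD oracle up to sign", {
  set.seed(21)
  X <- matrix(rnorm(10 * 15), 10, dimnames = list(paste0("g", 1:10), NULL))
  eg <- module_eigengene(X, rownames(X))
  Xs <- t(scale(t(X)))
  sv <- svd(Xs)
  v1 <- sv$v[, 1]
  flip <- if (sum(eg$values * v1) < 0) -1 else 1
  expect_lt(max(abs(eg$values - flip * v1)), 1e-8)
  expect_equal(eg$var_explained, sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_equal(sum(eg$values^2), 1)                      # unit norm
  expect_gte(mean(cor(t(Xs), eg$values)), 0)             # sign orientation

  # degenerate modules
  e1 <- module_eigengene(X, "g1")
  expect_equal(abs(cor(X["g1", ], e1$values)), 1)
  X2 <- rbind(a = X[1, ], b = X[1, ])
  e2 <- module_eigengene(X2, c("a", "b"))
  expect_equal(abs(cor(X2["a", ], e2$values)), 1)
  expect_equal(e2$var_explained, 1)
  expect_error(module_eigengene(X, "nope"), "absent")
})

test_that("kme returns |cor| with t-transform p-values", {
  set.seed(4)
  X <- matrix(rnorm(5 * 10), 5, dimnames = list(paste0("g", 1:5), NULL))
  eg <- module_eigengene(X, c("g1", "g2", "g3"))
  km <- kme(X, list(`1` = eg))
  expect_true(all(km$kME >= 0 & km$kME <= 1))
  expect_true(all(km$p_value > 0 & km$p_value <= 1))
  # p-values agree with cor.test as independent check
  for (g in rownames(X)) {
    ct <- cor.test(X[g, ], eg$values)
    expect_equal(km$p_value[km$gene == g], ct$p.value, tolerance = 1e-12)
  }
  # gene identical to the eigengene
  X2 <- rbind(X, e = eg$values)
  km2 <- kme(X2, list(`1` = eg))
  expect_equal(km2$kME[km2$gene == "e"], 1)
  # constructed orthogonal gene
  resid <- stats::residuals(lm(rnorm(10) ~ eg$values))
  X3 <- rbind(X, o = resid)
  km3 <- kme(X3, list(`1` = eg))
  expect_equal(km3$kME[km3$gene == "o"], 0, tolerance = 1e-12)
})

test_that("intramodular connectivity sums within-module adjacency", {
  # star: center g1 connected (weight 1) to 4 leaves, leaves unconnected
  a <- matrix(0, 5, 5, dimnames = rep(list(paste0("g", 1:5)), 2))
  a["g1", 2:5] <- 1; a[2:5, "g1"] <- 1
  part <- setNames(rep(1L, 5), rownames(a))
  ic <- intramodular_connectivity(a, part)
  expect_equal(ic$kIM[ic$gene == "g1"], 4)
  expect_equal(ic$kIM[ic$gene != "g1"], rep(1, 4))
  expect_equal(ic$hub_rank[ic$gene == "g1"], 1L)
  # handshake identity: sum kIM = 2 x total within-module edge weight
  b <- random_adjacency(6, 7)
  dimnames(b) <- rep(list(paste0("g", 1:6)), 2)
  part2 <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), rownames(b))
  ic2 <- intramodular_connectivity(b, part2)
  w_within <- sum(b[1:3, 1:3][upper.tri(b[1:3, 1:3])]) +
    sum(b[4:6, 4:6][upper.tri(b[4:6, 4:6])])
  expect_equal(sum(ic2$kIM), 2 * w_within)
  # brute-force sums on a 5-gene toy
  c5 <- random_adjacency(5, 11); dimnames(c5) <- rep(list(paste0("g", 1:5)), 2)
  p5 <- setNames(rep(1L, 5), rownames(c5))
  ic5 <- intramodular_connectivity(c5, p5)
  for (i in 1:5)
    expect_equal(ic5$kIM[i], sum(c5[i, -i]))
  expect_equal(nrow(top_hubs(ic2, k = 2)), 4)
})

test_that("betweenness matches pair enumeration on canonical graphs", {
  nm <- function(n) rep(list(paste0("g", seq_len(n))), 2)
  # complete triangle, equal weights: no intermediaries
  tri <- matrix(0.5, 3, 3, dimnames = nm(3)); diag(tri) <- 0
  bt <- module_betweenness(tri, rownames(tri))
  expect_equal(bt$nodes$betweenness, rep(0, 3))
  # path g1 - g2 - g3: middle carries the single g1-g3 shortest path
  pth <- matrix(0, 3, 3, dimnames = nm(3))
  pth[1, 2] <- pth[2, 1] <- pth[2, 3] <- pth[3, 2] <- 0.5
  bp <- module_betweenness(pth, rownames(pth))
  expect_equal(bp$nodes$betweenness[bp$nodes$gene == "g2"], 1)
  expect_equal(sum(bp$nodes$betweenness), 1)
  # star of 5: center carries all 6 leaf pairs
  st <- matrix(0, 5, 5, dimnames = nm(5))
  st[1, 2:5] <- st[2:5, 1] <- 0.5
  bs <- module_betweenness(st, rownames(st))
  expect_equal(bs$nodes$betweenness[bs$nodes$gene == "g1"], 6)
  # edge betweenness of the path: each edge carries 2 pairs
  expect_equal(sort(bp$edges$edge_betweenness), c(2, 2))
  expect_error(module_betweenness(matrix(0, 2, 2, dimnames = nm(2)),
                                  c("g1", "g2")), "no edges")
})

test_that("detect_modules separates planted blocks and rejects noise", {
  # two planted blocks, within ~ 1, between ~ 0
  n <- 10
  tm <- diag(n) * 0
  tm[1:5, 1:5] <- 0.95; tm[6:10, 6:10] <- 0.95
  tm[1:5, 6:10] <- 0.02; tm[6:10, 1:5] <- 0.02
  diag(tm) <- 1
  rownames(tm) <- colnames(tm) <- paste0("g", 1:n)
  part <- detect_modules(tm, cut_height = 0.25, min_size = 2)
  expect_equal(length(setdiff(unique(part$labels), 0L)), 2)
  expect_equal(sum(part$labels == 0), 0)
  expect_equal(length(unique(part$labels[1:5])), 1)
  expect_equal(length(unique(part$labels[6:10])), 1)

  # pure noise at a strict cut: everything unassigned
  set.seed(5)
  noise <- matrix(rnorm(100 * 60), 100,
                  dimnames = list(sprintf("n%03d", 1:100), NULL))
  tm_n <- tom(adjacency(correlation_matrix(noise), beta = 6))
  expect_warning(pn <- detect_modules(tm_n, cut_height = 0.2, min_size = 5),
                 "unassigned")
  expect_true(all(pn$labels == 0))
})

test_that("module recovery on the planted fixture is essentially exact", {
  skip_if_not_installed("mclust")
  fx <- gen_coexpr_fixture(coexpr_fixture_spec(seed = 1))
  fit <- coexpr_modules(fx$X)
  ari <- mclust::adjustedRandIndex(fit$partition$labels, fx$labels)
  expect_gte(ari, 0.9)
  # recovered sizes echo the planted 16/40/70
  sizes <- sort(as.integer(table(fit$partition$labels[fit$partition$labels > 0])))
  expect_equal(sizes, c(16L, 40L, 70L))
})

test_that("coexpr_fit methods print and plot without error", {
  fx <- gen_coexpr_fixture(coexpr_fixture_spec(sizes = c(8, 10), n_noise = 5,
                                               n_samples = 20, seed = 2))
  fit <- coexpr_modules(fx$X, min_size = 5)
  expect_output(print(fit), "coexpr_fit")
  expect_output(summary(fit), "module")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  expect_s3_class(fit$partition, "module_partition")
})

test_that("soft-threshold scan reports a fit per candidate power", {
  fx <- gen_coexpr_fixture(coexpr_fixture_spec(seed = 3))
  sc <- pick_soft_threshold(correlation_matrix(fx$X), powers = c(2, 6, 10))
  expect_equal(sc$power, c(2, 6, 10))
  expect_true(all(is.finite(sc$mean_k)))
  expect_true(all(abs(sc$fit_r2) <= 1, na.rm = TRUE))
})
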
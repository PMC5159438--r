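#' Specification for a synthetic ISH fixture
#'
#' Describes a synthetic brain-section triplet (ISH image, Nissl reference,
#' region mask) with planted ground truth: each rectangular ROI receives an
#' exact number of signal pixels, `round(p * area)`, at uniformly placed
#' positions, with signal gray levels drawn from N(mu, sigma) clipped to
#' \[0, 191\]; all other pixels come from the background gray range. Signal
#' pixels are placed by exact count rather than per-pixel Bernoulli draws so
#' density recovery is deterministic. The Nissl image marks every ROI pixel
#' as positive (gray < 192).
#'
#' @param width,height Image size in pixels.
#' @param rois Data frame with columns `label`, `name`, `row0`, `col0`
#'   (top-left corner, 1-based), `h`, `w` (rectangle size), `p` (signal
#'   fraction in \[0, 1\]), `mu` (signal gray mean in \[0, 191\]), `sigma`
#'   (signal gray sd). Rectangles must be disjoint and inside the image, and
#'   `mu +/- 3 sigma` must stay inside \[0, 191\].
#' @param background Inclusive gray range of background pixels (default
#'   200--255).
#' @param seed RNG seed.
#' @return Object of class `ish_fixture_spec`.
#' @export
ish_fixture_spec <- function(width = 360, height = 140,
                             rois = data.frame(
                               label = 1:3,
                               name = c("CTX-L5", "HIP-DG", "CB-GCL"),
                               row0 = c(21, 21, 21), col0 = c(11, 131, 251),
                               h = 100, w = 100,
                               p = c(0.30, 0.60, 0.03),
                               mu = c(168, 110, 40), sigma = 2),
                             background = c(200, 255), seed = 1) {
  stopifnot(width > 0, height > 0, nrow(rois) >= 1)
  need <- c("label", "name", "row0", "col0", "h", "w", "p", "mu", "sigma")
  if (!all(need %in% names(rois)))
    stop("rois needs columns ", paste(need, collapse = ", "))
  if (any(rois$p < 0 | rois$p > 1)) stop("signal fraction p must lie in [0, 1]")
  if (any(rois$mu - 3 * rois$sigma < 0 | rois$mu + 3 * rois$sigma > 191))
    stop("mu +/- 3 sigma must stay inside [0, 191]")
  if (any(rois$row0 < 1 | rois$col0 < 1 |
          rois$row0 + rois$h - 1 > height | rois$col0 + rois$w - 1 > width))
    stop("ROI rectangle outside image")
  if (background[1] < 192 || background[2] > 255)
    stop("background range must lie inside [192, 255]")
  # disjointness
  cover <- matrix(0L, height, width)
  for (i in seq_len(nrow(rois))) {
    rr <- rois$row0[i]:(rois$row0[i] + rois$h[i] - 1)
    cc <- rois$col0[i]:(rois$col0[i] + rois$w[i] - 1)
    cover[rr, cc] <- cover[rr, cc] + 1L
  }
  if (any(cover > 1L)) stop("overlapping ROIs")
  structure(list(width = width, height = height, rois = rois,
                 background = background, seed = seed),
            class = "ish_fixture_spec")
}

#' Generate a synthetic ISH/Nissl/mask fixture with planted truth
#'
#' @param spec An [ish_fixture_spec()].
#' @return List with `ish` and `nissl` gray matrices, `mask` (a
#'   [region_mask()]), and `truth`, a data frame of the planted per-ROI
#'   ground truth (`p`, `mu`, exact signal count, expected Np, L, D, E and
#'   category).
#' @examples
#' fx <- gen_ish_fixture(ish_fixture_spec(seed = 7))
#' fx$truth
#' @export
gen_ish_fixture <- function(spec) {
  stopifnot(inherits(spec, "ish_fixture_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  bg <- spec$background
  rand_bg <- function(n) sample(bg[1]:bg[2], n, replace = TRUE)
  ish <- matrix(rand_bg(h * w), h, w)
  nissl <- matrix(rand_bg(h * w), h, w)
  labels <- matrix(0L, h, w)
  truth <- list()
  for (i in seq_len(nrow(spec$rois))) {
    r <- spec$rois[i, ]
    rr <- r$row0:(r$row0 + r$h - 1); cc <- r$col0:(r$col0 + r$w - 1)
    labels[rr, cc] <- r$label
    area <- r$h * r$w
    ns <- round(r$p * area)
    block <- matrix(rand_bg(area), r$h, r$w)  # non-signal ROI pixels
    if (ns > 0) {
      pos <- sample.int(area, ns)
      grays <- pmin(pmax(round(stats::rnorm(ns, r$mu, r$sigma)), 0), 191)
      block[pos] <- grays
    }
    ish[rr, cc] <- block
    nissl[rr, cc] <- matrix(sample(80:150, area, replace = TRUE), r$h, r$w)
    np <- 100 * ns / area
    L <- if (ns == 0) 0L else intensity_scale(r$mu)
    D <- if (ns == 0) 0L else density_scale(np)
    truth[[i]] <- data.frame(label = r$label, name = r$name, p = r$p,
                             mu = r$mu, area = area, n_signal = ns,
                             expected_Np = np, expected_L = L, expected_D = D,
                             expected_E = L * D,
                             expected_category = categorize_expression(L * D),
                             stringsAsFactors = FALSE)
  }
  storage.mode(ish) <- "integer"
  storage.mode(nissl) <- "integer"
  mask <- region_mask(labels,
                      stats::setNames(as.character(spec$rois$name),
                                      as.character(spec$rois$label)))
  list(ish = ish, nissl = nissl, mask = mask, truth = do.call(rbind, truth))
}

#' Specification for a synthetic co-expression fixture
#'
#' Gene x sample matrices with planted correlated modules: per module a
#' latent factor u over samples, member genes
#' `g = sqrt(rho) u + sqrt(1 - rho) * noise_sd * eps` with independent
#' standard-normal eps, and pure-noise genes besides. The expected pairwise
#' within-module correlation is `rho` (at `noise_sd = 1`). Defaults mirror a
#' small brain-region network: module sizes 16, 40 and 70 (the reported
#' module-size range), 50 additional noise genes (a ~180-gene network), 60
#' samples, within-module correlation 0.8.
#'
#' @param sizes Module sizes, each >= 2.
#' @param n_noise Number of pure-noise genes.
#' @param n_samples Number of samples (brain structures), >= 3.
#' @param rho Within-module correlation, in \[0, 1).
#' @param noise_sd Standard deviation of the idiosyncratic noise.
#' @param seed RNG seed.
#' @return Object of class `coexpr_fixture_spec`.
#' @export
coexpr_fixture_spec <- function(sizes = c(16, 40, 70), n_noise = 50,
                                n_samples = 60, rho = 0.8, noise_sd = 1,
                                seed = 1) {
  if (any(sizes < 2)) stop("module sizes must be at least 2")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (n_samples < 3) stop("need at least 3 samples")
  structure(list(sizes = sizes, n_noise = n_noise, n_samples = n_samples,
                 rho = rho, noise_sd = noise_sd, seed = seed),
            class = "coexpr_fixture_spec")
}

draw_coexpr <- function(spec) {
  n_genes <- sum(spec$sizes) + spec$n_noise
  X <- matrix(0, n_genes, spec$n_samples)
  labels <- integer(n_genes)
  row <- 1L
  for (m in seq_along(spec$sizes)) {
    u <- stats::rnorm(spec$n_samples)
    for (g in seq_len(spec$sizes[m])) {
      X[row, ] <- sqrt(spec$rho) * u +
        sqrt(1 - spec$rho) * spec$noise_sd * stats::rnorm(spec$n_samples)
      labels[row] <- m
      row <- row + 1L
    }
  }
  if (spec$n_noise > 0) {
    idx <- row:(row + spec$n_noise - 1L)
    X[idx, ] <- matrix(spec$noise_sd * stats::rnorm(spec$n_noise * spec$n_samples),
                       spec$n_noise)
  }
  rownames(X) <- sprintf("g%03d", seq_len(n_genes))
  colnames(X) <- sprintf("S%02d", seq_len(spec$n_samples))
  names(labels) <- rownames(X)
  list(X = X, labels = labels)
}

#' Generate a gene x sample matrix with planted modules
#'
#' @param spec A [coexpr_fixture_spec()].
#' @return List with `X` (genes x samples) and `labels` (named integer
#'   vector of true module ids, 0 for noise genes).
#' @export
gen_coexpr_fixture <- function(spec = coexpr_fixture_spec()) {
  stopifnot(inherits(spec, "coexpr_fixture_spec"))
  set.seed(spec$seed)
  draw_coexpr(spec)
}

#' Generate a reference/test matrix pair for preservation testing
#'
#' Both matrices are drawn independently from the same spec (same module
#' membership, fresh latent factors and noise); optionally the genes of one
#' module are replaced by pure noise in the test matrix, destroying its
#' co-expression there while the labels (from the reference) are unchanged.
#'
#' @param spec A [coexpr_fixture_spec()].
#' @param scramble_module Module id to scramble in the test matrix, or
#'   `NULL` for none.
#' @return List with `X_ref`, `X_test` and `labels`.
#' @export
gen_preservation_pair <- function(spec = coexpr_fixture_spec(),
                                  scramble_module = NULL) {
  stopifnot(inherits(spec, "coexpr_fixture_spec"))
  set.seed(spec$seed)
  ref <- draw_coexpr(spec)
  test <- draw_coexpr(spec)
  if (!is.null(scramble_module)) {
    if (!scramble_module %in% seq_along(spec$sizes))
      stop("unknown module id: ", scramble_module)
    idx <- which(ref$labels == scramble_module)
    test$X[idx, ] <- matrix(
      spec$noise_sd * stats::rnorm(length(idx) * spec$n_samples), length(idx))
  }
  list(X_ref = ref$X, X_test = test$X, labels = ref$labels)
}
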
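---
title: "From ISH sections to co-expression modules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ISH sections to co-expression modules: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ishnet)
```

## What the package computes

`ishnet` implements two connected analyses for spatial gene-expression data
in the brain.

The first converts in situ hybridization (ISH) section images into a
semi-quantitative per-region **expression factor**. ISH is not quantitative
in the copy-number sense: signal darkness reflects transcript abundance only
ordinally, and faint-but-real signal is easily lost in binary expression
masks. The scoring schema therefore classifies each region of interest (ROI)
on two ordinal axes — how *dark* the expressing pixels are (intensity scale
L) and how much of the region expresses at all (density scale D) — and
combines them into a single factor E.

The second analysis takes gene-by-sample expression matrices (samples being
brain structures) and builds a weighted co-expression network: Pearson
correlation, soft-threshold adjacency, topological overlap, module
detection, module eigengenes and membership (kME), intramodular connectivity
and hubs, and a permutation Z statistic for module preservation between two
data sets.

Synthetic-data generators plant ground truth for both halves, so the whole
pipeline is testable end to end without any atlas download.

## The scoring schema

### Intensity scale L

Images are reduced to 8-bit grayscale (0 = strongest signal, 255 = white
background; RGB input is averaged over channels, unweighted by default as in
common image tools, with luminance weighting available). A fixed eight-bin
lookup table partitions the 256 index positions:

```{r}
intensity_lut()
```

The four strong bins are 32 index positions wide, the two weak-signal bins
16 each — deliberately finer so that weak expression is still resolved — and
the top 64 positions are background. The pseudocolor rendering
(`apply_pseudocolor()`) exists purely to make this binning visible; scoring
always reads the underlying gray values, and a test asserts that rendering
never perturbs scores.

Within an ROI, the *expressing* pixels are those with gray value below the
background threshold (default 192, the start of the no-signal bin; the
threshold is a parameter because the choice of cutoff applied before
averaging is a convention, not a measurement). L is the LUT scale of the
mean gray value of those pixels. Bin lookup uses half-open float intervals
`[lo, hi + 1)` with 255 assigned to the last bin, so every value in
[0, 255] has exactly one scale: a mean gray of 169.18 falls in the 160–175
bin and scores L = 2.

### Density scale D

Density measures how widespread expression is: the number of expressing
pixels in the ISH image divided by the number of positive pixels of the
matched Nissl (pan-cellular) stain in the same ROI, as a percentage,

\[
N_p = 100 \cdot \frac{n_\mathrm{signal}/A}{n_\mathrm{Nissl}/A},
\]

where \(A\) = 0.17 µm² is the area of the smallest pixel. \(A\) cancels
analytically — a property tested explicitly — and is retained only as the
documented calibration constant. Np is capped at 100 (signal and Nissl are
different images, so the raw ratio can exceed 1). D bins Np as 1 (0–5 %,
sparse), 2 (5–20 %, scattered), 3 (20–70 %, medium), 4 (> 70 %,
wide-spread), half-open bins with the last closed: 47.76 % scores D = 3.

### Expression factor E and categories

Each of the 2–3 good-quality sections per sagittal plane yields one (L, D)
pair; the expression factor is the mean of the per-section products,

\[
E = \frac{1}{n}\sum_{i=1}^{n} L_i D_i , \qquad 0 \le E \le 28 .
\]

The alternative reading — product of the two per-plane averages,
\(\bar L \times \bar D\) — coincides whenever D is constant across sections
(as in the worked example (2,3), (2,3), (1,3) → E = 5) and is exposed as
`method = "product_of_means"`; the mean-of-products form is the default
because it is the form the worked example actually evaluates. E = 0 is
reported as "none"; positive E falls into lower-inclusive bins
(0, 6) very low, [6, 11) low, [11, 17) moderate, [17, 22) high,
[22, 28] very high. The strict inequalities of the verbal definition leave
the boundary points 6, 11, 17, 22 (and Np = 5, 20, 70) unassigned;
lower-inclusive half-open bins make both functions total and deterministic,
which matters more for a pipeline than the unknowable original convention.

Scoring is fully deterministic: there is no RNG anywhere in this module.

```{r}
score <- expression_factor(list(c(2, 3), c(2, 3), c(1, 3)))
c(E = score, category = categorize_expression(score))
```

Multi-plane combination (lateral / parasagittal / midsagittal) is reported
per plane; how planes were merged into single per-structure values in the
original heatmaps is not documented, so `build_matrix()` simply averages
all records for a (gene, region) cell and flags cells that had none.

## Gene-by-region matrices and heatmaps

`build_matrix()` assembles scored records into a genes × regions matrix;
`cluster_axis()` clusters either axis with average linkage under Euclidean
(default) or correlation distance — no metric is canonical for
semi-quantitative scores, and Euclidean linkage on raw E is the more
conservative default since E is already on a common bounded scale; z-scoring
per gene is available as a flag. `export_heatmap()` writes the reordered
matrix, Newick trees with branch lengths, and a PNG rendered directly from
cell values so identical inputs give byte-identical files. Average-linkage
heights are verified against an exhaustive agglomeration oracle on small
matrices, and clustering is permutation-equivariant in its merge-height
multiset.

## The co-expression network

For a genes × samples matrix \(X\) (at least 3 samples; zero-variance genes
are an error by name), the network is built as

* correlation \(r_{ij}\) (Pearson);
* adjacency \(a_{ij} = |r_{ij}|^\beta\) (unsigned, default) or
  \(((1+r_{ij})/2)^\beta\) (signed), diagonal fixed to 0. The default
  \(\beta = 6\) is the conventional unsigned choice;
  `pick_soft_threshold()` reports the scale-free-fit R² over a power scan
  but nothing is enforced;
* topological overlap
  \(\mathrm{tom}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 -
  a_{ij})\) with \(\ell_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}\) and
  \(k_i = \sum_u a_{iu}\); diagonal 1. The source analyses name TOM without
  printing a formula; this is the standard unsigned form of the framework
  they build on, and it is verified in tests against a brute-force
  element-wise oracle to 1e-10.

Per-gene standardization before analysis is offered (default on) although
Pearson correlation is invariant to it; it affects only the stored matrix
and the eigengene scale.

### Module detection

Modules are cut from the average-linkage tree of \(1 - \mathrm{tom}\). Join
heights are rescaled to [0, 1] and the tree is cut at rescaled height
\(1 - \texttt{cut\_height}\): `cut_height` (default 0.25) is the top
fraction of the join-height range treated as between-module structure. This
from-the-top reading follows the static-cut idiom of established network
tools, which cut near the top of the tree; cutting at the *bottom* quarter
of the range instead would slice through within-module joins whenever
modules are internally heterogeneous (on the planted default fixture it
splits a 40-gene module and unassigns the 16-gene one). Clusters smaller
than `min_size` (default 16, the smallest module size the motivating
analysis reports) are unassigned; modules whose eigengenes correlate above
`merge_kme` (default 0.8) are merged iteratively; final ids are assigned by
decreasing size, so labeling is deterministic. Dynamic tree cut is out of
scope.

### Eigengenes, kME, hubs, betweenness

The module eigengene is the first principal component across samples of the
per-gene standardized member submatrix (computed via the eigendecomposition
of the sample-by-sample cross-product; tests require agreement with an
independent SVD to 1e-8 up to sign), unit norm, sign-oriented so the mean
correlation with members is non-negative. kME is the absolute correlation
of each gene with each eigengene; p-values use the two-sided t-transform
with n − 2 degrees of freedom and are reported raw by default
(Benjamini–Hochberg by flag, since the motivating analysis reports raw
values). Intramodular connectivity kIM sums a gene's adjacency to its
module partners; the top-kIM genes are the module hubs. Module networks can
be exported with shortest-path node and edge betweenness (edge length
\(1 - w\)), computed per component when the thresholded graph is
disconnected.

### Permutation preservation (Z summary)

Given a reference partition and a test matrix, each module of size ≥ 3
after name intersection is scored in the test network by

* **density**: mean within-module adjacency;
* **connectivity**: correlation between the reference and test kIM vectors
  over the module genes.

The null draws `n_perm` (default 200, minimum 50) random gene sets of equal
size from the test network and evaluates the same statistics;
\(Z = (\mathrm{obs} - \overline{\mathrm{null}})/\mathrm{sd}(\mathrm{null})\)
per statistic and \(Z_\mathrm{summary}\) is their mean. Conventional
reading: < 2 no evidence, 2–10 weak to moderate, > 10 strong. When the null
sd collapses (below 1e-8) the statistic is flagged `NA` and excluded from
the mean — this happens by construction for the connectivity statistic when
reference and test data are identical, where every null correlation is
exactly 1.

Two calibration facts, both asserted in the test suite, delimit what this
statistic can show on the synthetic fixtures:

1. A random gene set evaluated against its own permutation null yields
   per-statistic Zs that are approximately standard normal (mean within
   ±0.2, sd within [0.8, 1.2] over 200 seeded draws). \(Z_\mathrm{summary}\)
   itself is the mean of two positively correlated Zs, so its null sd is
   below 1 by design; calibration is therefore asserted per statistic.
2. The planted modules are *exchangeable*: every member loads on the latent
   factor with the same \(\sqrt{\rho}\), so there is no gene-specific hub
   structure for the connectivity statistic to recognize across two
   independent draws. Its observed value is then near 0 while the null —
   which scores the *same* random set in both networks and thus inherits
   the shared module-size signal — is strongly positive, driving
   \(Z_\mathrm{connectivity}\) far negative even for genuinely preserved
   modules. This is a property of homogeneous simulated modules, not of the
   statistic on real data, where hub structure is gene-specific and shared.
   Consequently the strong-preservation claim (> 10) is demonstrated in the
   self-preservation design (test = reference), where the degenerate
   connectivity null is flagged and the density Z carries the verdict,
   while the discrimination claim (scrambled module < 2) holds in every
   design. Small modules (16 genes) cannot reach Z > 10 even when perfectly
   preserved: the permutation sd of mean within-set adjacency is simply too
   large for 16-gene draws from a ~180-gene network.

## Synthetic data: what it emulates, what it does not

`gen_ish_fixture()` builds an ISH/Nissl/mask triplet per spec: within each
rectangular ROI exactly `round(p * area)` uniformly placed pixels receive
signal gray from N(µ, σ) clipped to [0, 191]; everything else comes from
the background range (default 200–255); the Nissl mate marks every ROI
pixel positive. Planting by exact count rather than per-pixel Bernoulli
draws makes density recovery deterministic — a sampling test becomes an
exact one. Clipping (rather than truncated resampling) is used for the gray
noise; its bias is negligible when µ is ≥ 3σ from the clip bounds, which
the spec validation enforces anyway. The round-trip contract — planted
(L, D, E, category) recovered exactly — holds for ROIs of ≥ 10,000 pixels
with µ at least 3 gray levels from any bin edge; the test suite runs it on
20 seeded fixtures. These images emulate the *scoring geometry* only: no
anatomy, no staining artifacts, no registration error, no illumination
gradients — so passing tests certify the arithmetic of the schema, not its
robustness to real histology.

`gen_coexpr_fixture()` plants modules as
\(g = \sqrt{\rho}\,u + \sqrt{1-\rho}\,\sigma_\varepsilon\,\varepsilon\)
with a fresh latent factor u per module, giving expected within-module
correlation ρ. Defaults — module sizes {16, 40, 70}, 50 noise genes,
60 samples, ρ = 0.8 — mirror a small brain-structure network of roughly 180
genes with modules spanning the reported 16–70 size range. Module recovery
on this default fixture is essentially exact (adjusted Rand ≥ 0.9,
asserted ≥ 0.9 in tests). `gen_preservation_pair()` draws reference and
test matrices independently from the same spec and can replace one module's
genes by pure noise in the test draw. What these fixtures do *not* emulate:
heteroskedastic noise, correlated noise genes, overlapping modules,
gene-specific loadings (see the preservation note above), batch structure,
or the donor-to-donor heterogeneity of real atlas data.

## Numerical and interface choices

* Bin lookups are half-open and total; all boundary points have a defined
  image (tested over full-domain grids for monotonicity).
* TOM denominators are guarded at 1e-12; the matrix is symmetrized to
  remove float asymmetry of the matrix product.
* kME p-values are clamped into (0, 1]; |r| = 1 maps to the smallest
  representable positive p rather than 0.
* All stochastic operations take explicit seeds and reproduce
  bit-identically; the CLI writes a JSON manifest (config echo, input
  checksums, seed, version) beside every output, so results are
  reproducible from the manifest alone.
* Problem sizes in the test suite are the generator defaults above
  (176-gene networks, 60 samples, 200 permutations, 20 image fixtures of
  three 10,000-pixel ROIs), chosen as the smallest sizes at which the
  planted structure is unambiguous.

## Known limitations

* The scoring schema is semi-quantitative by design; E values are ordinal
  summaries, not expression estimates, and comparisons across genes assume
  comparable probe behavior.
* The published density worked example is internally inconsistent (its
  pixel counts give 4.78 %, its printed density 47.76 %); the formula is
  implemented as written and the printed percentage anchors the
  density-scale tests.
* Z summary here is the mean of one density and one connectivity Z, a
  deliberate simplification of the multi-statistic composite in the
  established preservation framework; dynamic tree cut, GO enrichment and
  TF-binding prediction are out of scope.
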
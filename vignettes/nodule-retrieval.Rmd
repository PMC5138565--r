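---
title: "Hashing and cluster-pruned retrieval of lung nodule images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hashing and cluster-pruned retrieval of lung nodule images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulehash)
```

`nodulehash` retrieves lesion images that resemble a query lesion, using
compact binary codes learned from benign/malignant labels, and narrows each
search to a few feature-space clusters. This vignette is the package's own
account of the method: the model and its assumptions, the parameters that
matter, what the synthetic data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The retrieval model

**Representation.** An image enters the system as a pair (gray matrix in
[0, 1], binary lesion mask) with a benign (0) / malignant (1) label.
Features are computed from the lesion only — co-occurrence pairs, gray
statistics and signs are all restricted to mask pixels, because the lesion,
not the crop window, is the object of interest. The 104 components are, in
fixed order: gray mean/variance/entropy (f1–f3), the seven Hu invariant
moments of the mask (f4–f10), perimeter, area, maximum diameter,
rectangularity and roundness (f11–f15), calcification area/degree and
cavitary area/ratio (f16–f19), a boundary Fourier descriptor (f20), and
14 Haralick statistics of the gray-level co-occurrence matrix at four angles
together with their per-statistic mean and variance across angles
(f21–f104). Since these components mix pixel counts, probabilities and
unbounded moments, every downstream distance (clustering, kernel, pruning)
operates on z-scores from a standardizer fitted once on the training set;
queries are standardized with the training parameters and never re-fitted.

**Partitioning.** The training matrix is clustered by normalized spectral
clustering: Gaussian similarity $W_{ij} = \exp(-\lVert x_i - x_j\rVert^2 /
2\delta^2)$, normalized Laplacian $L = D^{-1/2}(D - W)D^{-1/2}$, the $k$
eigenvectors of $L$ with smallest eigenvalues row-normalized and clustered
by k-means with 10 restarts. Two choices here were open and are package
decisions: the embedding follows the Ng–Jordan–Weiss recipe (as many
eigenvectors as clusters, rows normalized to unit length), and cluster
centers are the mean *standardized feature vectors* of each cluster rather
than eigenspace centroids — query pruning measures $\lVert q - \mu_i
\rVert^2$ on the query's features, which are never embedded, so the centers
must live in that space.

**Hashing.** Each of the $r$ hash functions is a sign-thresholded Gaussian
kernel expansion over $m$ anchor samples,
$h(x) = \mathrm{sgn}\big(\sum_j \kappa(x_{(j)}, x)\, a_j - b\big)$, with the
bias $b$ chosen so the pre-sign response has exact mean zero over the
training set (this balances each bit). The coefficients are supervised:
for $l$ labeled samples, with $S \in \{\pm 1\}^{l \times l}$ the
same/different-label matrix and $\bar K$ the mean-centered kernel matrix,
the code matrix is trained to satisfy
$\mathrm{sgn}(\bar K A)\,\mathrm{sgn}(\bar K A)^\top \approx r S$, i.e. the
inner product of two codes (equivalently $r - 2\cdot$Hamming distance)
approximates $+r$ for same-label pairs and $-r$ for different-label pairs.
The optimizer is the standard greedy KSH recipe — the source material for
this framework states the objective but not a procedure: per bit, a spectral
relaxation (top generalized eigenvector of the bit's residual objective)
initializes the coefficient column, tanh-smoothed gradient ascent refines
it (at most 500 iterations, stop at relative change $< 10^{-6}$), the
realized $\pm 1$ bit vector is subtracted from the residual target, and the
next bit starts from that residual. The per-bit residual norm is recorded as
the objective trace; the final residual equals, by construction, the direct
Frobenius evaluation of the trained objective, which the tests verify
independently.

**Retrieval and decision rule.** A query is featurized, standardized and
encoded; only the records in the $m_{\text{cand}}$ clusters with nearest
centers are scored. Candidates are ranked by code inner product
(descending), computed on packed bits as $r - 2\,\mathrm{popcount}(\oplus)$.
Inner products are coarse (integers in $[-r, r]$), so ties are common; the
decision rule resolves them by returning first the record whose cluster
center is closer to the query, reusing the distances already computed for
pruning. Beyond that the ranking falls back to ascending record id — a
package decision that makes the order total, so the pruned search can be
checked for *exact* equality against an exhaustive-search oracle. The
benign/malignant call on the query is a majority vote over the returned
labels; an exact tie is called malignant, the conservative branch for a
screening aid.

## Parameters and defaults

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `r` (bits) | 48 | code length; the headline operating point of the framework |
| `k` (clusters) | 35 | database partition count at archive scale; use ~`n/40` at desk scale |
| `m_candidates` | 8 | candidate clusters searched per query |
| `p` | 5 | neighbours returned / voting set size |
| `m_anchor` | `min(300, l/2)` | kernel anchors; must stay below `l` on small data |
| `l` | `min(1000, n)` | labeled samples in the supervision matrix |
| `sigma` | median anchor distance | kernel bandwidth, from a seeded subsample |
| `delta` | median pairwise distance | similarity bandwidth, seeded subsample of ≤ 200 |
| `k_levels` | 16 | GLCM / entropy gray quantization (equal-width bins on [0,1]) |
| `glcm_distance` | 1 | co-occurrence offset in pixels |
| `tau_cal`, `tau_cav` | 0.85, 0.15 | calcification / cavity thresholds on normalized gray |

The bandwidths follow the median heuristic because both kernels operate on
z-scored features whose pairwise distances concentrate; a fixed constant
would be arbitrary across datasets. The GLCM quantization and offset are
standard Haralick practice and exposed in `feature_config()`.

## The synthetic data generator

`generate_nodule()` draws a star-convex lesion whose boundary radius is
$R\,(1 + a \sum_{h=2}^{6} w_h \cos(h\theta + \phi_h))$ with seeded random
phases and normalized amplitudes, so the perturbation never exceeds the
amplitude $a < 1$ and the region is always one connected component. The
interior is filled with spatially smoothed Gaussian noise; with configurable
probability a small bright (≥ 0.9) calcification disk or dark (≤ 0.1) cavity
disk is stamped inside the mask. The benign class draws its boundary
amplitude and noise scale from the low end of the configured ranges
(amplitude fraction 0–0.3, noise fraction 0.10–0.35), the malignant class
from the high end (0.55–1.0 and 0.60–1.0): smooth round benign blobs versus
irregular rough malignant ones. These ranges were fixed once, to mirror the
qualitative radiological contrast the features are designed to detect —
roundness, Hu moments and the Fourier descriptor respond monotonically to
the irregularity knob, GLCM statistics to the noise scale.

What this emulates: the geometry/texture contrast between classes, mask
conventions, gray normalization, per-image seeds
(`hash(master_seed, index)`) for reproducible, extensible datasets. What it
does **not** emulate: acquisition physics (no Hounsfield units, dose or
reconstruction kernels), partial-volume blur at lesion boundaries,
juxtapleural and juxtavascular attachments, segmentation error, or
inter-reader label noise. The synthetic classes are therefore *much* more
separable than clinical data — held-out precision and accuracy saturate near
1.0 at desk scale. Passing tests consequently demonstrate that the pipeline
is implemented correctly (oracle equivalences, invariances, monotonicities,
above-chance learning), not that clinical accuracy figures would be
reproduced; those depend on the archive the framework is deployed on.

## Numerical choices and edge cases

* **Suspected misprints adopted as the standard forms.** The inverse
  difference moment is implemented with the conventional positive sign, and
  the Gaussian kernel with the squared norm in the exponent; the printed
  variants (negative IDM, unsquared norm) would respectively negate a
  homogeneity measure and define a Laplacian-like kernel at odds with its
  own name.
* **Entropies** use log base 2 throughout (bits), with $0 \log 0 = 0$; any
  fixed base only rescales one feature column and is absorbed by the
  standardizer.
* **Discrete geometry.** The perimeter is the traced Moore-neighbour contour
  length with diagonal steps weighted $\sqrt 2$, which keeps the roundness
  of a digital disk near 1 (naïve edge counting biases it low). The minimal
  rotated bounding rectangle is computed over pixel *corner* points by
  rotating calipers on the convex hull, so an axis-aligned filled square has
  rectangularity exactly 1. A single-pixel mask gets the perimeter of its
  unit square.
* **Fourier descriptor** = energy of boundary harmonics 2–8 after
  normalizing by harmonic 1: translation drops with the DC term, scale and
  rotation with the normalization, start point with the magnitudes.
* **Haralick degeneracies.** Correlation-type statistics return 0 when a
  marginal variance vanishes (constant image); the maximal correlation
  coefficient clamps its eigenvalue into [0, 1] before the square root.
* **Sign convention** `sgn(0) = +1` everywhere (encoding, packed bits), so
  codes are deterministic.
* **k-means restarts** are seeded; if a restart yields an empty cluster the
  partition is retried with an incremented seed, at most 5 times. `k = 1`
  and `k = n` short-circuit to the trivial partitions.
* **Zero-variance features** get unit scale in the standardizer, passing
  through centering unchanged instead of dividing by zero.
* **Ties beyond the decision rule** (equal inner product *and* equal cluster
  distance) order by ascending id, making every ranking a total order.
* **Self-queries.** When a test id collides with a database id, that record
  is excluded from that query's search (and logged); with disjoint ids a
  database image queried against its own database returns itself first at
  the maximal inner product, as expected.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so the
whole suite executes in minutes on one core while still exercising every
code path at realistic ratios: 400 training images (200 per class) with 100
held-out queries for the end-to-end runs (r = 48, k = 10, 4 candidate
clusters, p = 5), 200-image databases for the pruning-vs-exhaustive
equivalence checks, and 8-sample toys where exhaustive $2^8$ enumeration of
all possible bit vectors is feasible. Archive-scale defaults (k = 35,
m_anchor = 300, l = 1000) engage automatically once the training set is
large enough to support them.

## Known limitations

* Segmentation is an input, not a capability: masks must be provided.
* The eigendecompositions (Laplacian, per-bit relaxation) are dense;
  training cost grows as $O(n^2)$ memory and $O(l m^2 + m^3)$ per bit,
  appropriate for databases up to a few thousand images.
* Only the KSH backend is implemented; the code-database interface (packed
  codes + cluster ids + labels) is backend-agnostic, so alternative hashing
  schemes could be slotted in, but none are provided.
* The majority vote inherits retrieval's biases: with `p` even and a split
  vote the malignant call is deliberate, and with very unbalanced archives
  the vote reflects archive composition, not prevalence-corrected risk.
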
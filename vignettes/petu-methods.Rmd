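---
title: "Texture spectra from parallel-encoded texture units: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture spectra from parallel-encoded texture units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petu)
```

## The model

`petu` implements a statistical texture descriptor for binary images in the
texture-unit / texture-spectrum family (the family that also contains LBP
and CCR). An I×J observation window slides with stride 1 over a binary
image; at each fully interior placement the detected pattern is encoded
into a single integer, the *texture unit*, by reading each window row as a
binary number and summing the I row codes:

$$ k \;=\; \sum_{i=1}^{I} \sum_{j=0}^{J-1} a_{i,j}\, 2^{j}. $$

Two properties follow directly from this "parallel" (per-row) encoding and
drive everything else in the package:

1. **Dimensionality collapse.** The unit takes only
   $K(I,J) = I(2^J-1)+1$ values instead of $2^{IJ}$. A 5×5 window yields a
   156-dimensional spectrum; even 15×15 stays below half a million bins.
   This is what makes windows beyond 3×3 practical, in contrast to
   full-state encodings that overflow already at 4×4 or 5×5.
2. **Row-permutation invariance.** $k$ is a sum over rows, so any
   reordering of the rows of a pattern gives the same unit. The descriptor
   is therefore exactly invariant under vertical flips of the image — and
   *blind* to textures that differ only in vertical arrangement (see
   *Limitations*).

The normalized count vector $p_{I\times J}(k) = h(k)/P_p$ with
$P_p = (M-I+1)(N-J+1)$ is the *texture spectrum*, the feature vector used
by the entropy measure and the classifier.

**Texture information** is the Shannon entropy
$H = -\sum_k p(k)\log_2 p(k)$ (bits), with the usual $0\log 0 = 0$
convention, bounded by $\log_2 K$ with equality only for the equiprobable
spectrum. Since $\log_2 K$ grows with both window dimensions, window size
is the dial that trades computational cost against information capacity.

**Cost model.** Encoding one pattern costs $I\,J$ multiplications and
$I(J-1) + (I-1)$ additions, so a full histogram costs
$(M-I+1)(N-J+1)(2IJ-1)$ operations. The package reproduces this model
analytically (`count_operations()`) rather than measuring wall-clock time,
which is hardware-bound.

**Classifier.** Learning draws S random subimages per class, computes a
spectrum for each, and averages them into a class prototype
$p^c = \tfrac1S \sum_s p^{c,s}$; recognition averages P subimage spectra of
the test image and assigns the nearest prototype's label. Decisions are
tallied in a C×C confusion matrix and summarized as the efficiency
$\mathrm{Ef} = \sum \mathrm{diag}(M_c)/C \times 100$, i.e. the protocol
scores one test image per class.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| window I, J | pixels | — (user) | Controls K, entropy bound, and cost; 3×3–10×10 is the low-dimensional regime. |
| binarization threshold | intensity 0–255 | Otsu | Parameter-free global threshold maximizing between-class variance; pixels strictly above go white. |
| subimage size | pixels | — (user) | Must fit the class images and dominate the window; larger subimages mean less sampling noise. |
| S, P | count | 100 | Number of averaged subimage spectra in learning / recognition; variance of the averaged spectrum shrinks as 1/S. |
| distance | — | Euclidean | The minimum-distance rule does not pin a metric; Euclidean is the standard choice, Manhattan and χ² are provided because the choice is genuinely open. |
| seed | integer | — (user) | All sampling and synthesis is seeded; per-class and per-test-image streams are derived from it, so models and confusion matrices are bit-reproducible. |

## Numerical and convention choices

* **Bit order**: the leftmost pixel of a row is the least significant bit.
  Any fixed order gives an equivalent descriptor (it only relabels the k
  axis), but one must be fixed for counts to be comparable; this one is
  asserted in the worked examples of the test suite.
* **All-ones row**: encodes to $2^J - 1$, hence the maximum unit
  $I(2^J-1)$ and histogram length $I(2^J-1)+1$ — consistent with every
  closed-form K value the package asserts (22, 156, 379, 10,231, 229,363,
  491,506).
* **Boundary handling**: only fully interior placements, no padding —
  forced by the normalization denominator $(M-I+1)(N-J+1)$.
* **Thresholding ties**: intensity equal to the threshold maps to black
  (strict `>`). One convention had to be fixed; this one makes "raise the
  threshold" monotone (never creates white pixels).
* **Histogram storage**: sparse (occupied bins only) everywhere, with a
  dense `tabulate()` path available below $K \le 2^{22}$ as an independent
  counting route; the two are asserted identical. With 64-bit counts and
  sparse storage a 20×20 window ($K \approx 2.1\times10^7$) runs in
  ordinary memory — the descriptor itself has no overflow problem at that
  size, only dense implementations do.
* **Sub-3×3 windows** are permitted for testing and flagged
  (`subminimal = TRUE`), since the named dimensional regimes start at 3×3.
* **Classifier ties** (exactly equal distances) resolve to the first class
  in model order; deterministic given the model.
* **Entropy validation**: spectra must sum to 1 within $10^{-9}$ before
  entropy is computed; degenerate spectra give exactly $H = 0$.

## What the synthetic generator emulates — and what it does not

The image databases behind the descriptor's published applications
(industrial tile finishes, tree stems) are proprietary, so the package
ships seeded generators instead. `make_database()` produces C
pairwise-distinct binary classes from a fixed grid mixing four families:
Bernoulli fields (broad spectra), checkerboards and vertical stripes
(few-state periodic spectra), and thresholded smoothed-noise "blob" fields
(spatially correlated, natural-looking patches). Parameters are strided
across their ranges so even a 12-class database spans sparse-to-dense and
fine-to-coarse textures. This emulates the *statistical situation* of the
original databases — distinct stationary textures, subimage sampling,
train = test — and a green classification test establishes exactly that:
the pipeline separates well-separated stationary binary textures. It does
**not** establish robustness to uncontrolled lighting, scale or rotation
changes, non-stationarity, or binarization artifacts of real photographs.

Two degeneracies of the descriptor shaped the grid and are worth knowing
about as user-facing facts:

* Horizontal stripes of different widths can share one spectrum exactly
  (widths 1 and 2 coincide for any odd I), because only the *number* of
  white rows in a window matters for rows that are all-white/all-black.
* Diagonal stripes of width c collapse onto the cell-c checkerboard
  (width 1 is pixel-identical to it; width 2 has an identical 5×5
  spectrum).

The database grid therefore uses vertical stripes only, whose row codes
differ genuinely across widths.

The `hard = TRUE` variant exists to exercise the error paths and the
window-size trend. Classes differing only in Bernoulli *density* turn out
to be useless for this under a train-equals-test protocol: both stages read
the same fixed image, every window size estimates density equally well, so
the problem is either trivially separable or hopeless regardless of
window — no trend can appear. The hard variant instead fixes the density
(median threshold) and spaces classes by *correlation scale* (blob filter
radius in 0.15-pixel steps). Small windows cannot resolve neighborhood
structure beyond their own extent, larger ones can, which reproduces the
expected efficiency-vs-window-size degradation; the monotonicity test
asserts the 3×3 ≤ 5×5 trend on seed-averaged efficiencies, and the hard
suite deliberately uses small subimages (40×40, S = P = 10) because with
near-full-coverage sampling the sampling noise that makes the problem hard
would vanish.

## Known limitations

* **Binarization dependence**: the descriptor sees only the thresholded
  image; textures distinguished by gray-level structure that a global
  threshold destroys are out of reach, and no local/adaptive thresholding
  is provided.
* **Vertical-structure blindness**: row-permutation invariance discards
  all information about the vertical ordering of rows within the window.
* **No rotation invariance**: unlike rotation-invariant LBP variants, unit
  values change under 90° rotation (rows and columns play different roles).
* **Train = test protocol**: the shipped evaluation mirrors the
  one-test-image-per-class, same-images-in-both-stages protocol;
  generalization to held-out images is a different (harder) question the
  package does not claim to answer.
* **Image formats**: only the netpbm family (PBM/PGM/PPM) is read and
  written; no PNG/TIFF/JPEG decoder is bundled.
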
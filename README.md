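# petu — parallel-encoded texture units for binary-image classification

`petu` is an R package for statistical texture analysis of **binary images**
— thresholded photographs of manufactured surfaces (ceramic tile finishes),
tree bark, biological micrographs, or any raster where the texture survives
binarization. It targets the common industrial/field setting where a
classifier must be both accurate and cheap enough for task-specific
hardware.

## The descriptor

An observation window of I rows and J columns slides pixel by pixel over a
binary image s(m, n) ∈ {0, 1}. Each placement detects a pattern
P = (a_ij). Every row of P is read as a binary number (leftmost pixel =
least significant bit),

    c_i = Σ_{j=0}^{J−1} b_j 2^j ,   i = 1 … I,

and the I row codes are summed into a single **texture unit**

    k = c_1 + c_2 + … + c_I  ∈  [0, I(2^J − 1)].

Because the rows are coded independently ("in parallel") and then summed,
the 2^(I·J) possible patterns collapse onto only

    K(I, J) = I(2^J − 1) + 1

unit values — e.g. K = 22 for 3×3 and K = 10,231 for 10×10 (the
*low-dimensional* regime), K = 491,506 for 15×15 (*high-dimensional*).
Counting k over all (M−I+1)(N−J+1) placements and normalizing gives the
**texture spectrum** p_{I×J}(k), a probability vector used three ways:

* **Texture information**: Shannon entropy H = −Σ p(k) log2 p(k), bounded
  by log2 K — larger windows can carry more information.
* **Cost model**: computing the histogram takes
  (M−I+1)(N−J+1)(2IJ−1) multiplications and additions.
* **Classification**: a multi-class minimum-distance classifier. Learning
  averages the spectra of S randomly drawn subimages per class into a
  prototype p^c(k); recognition averages P subimage spectra of the test
  image and assigns the label of the nearest prototype (Euclidean by
  default; Manhattan and χ² available). Performance is reported as a C×C
  confusion matrix and the efficiency Ef = Σ diag(M_c)/C × 100.

## Worked example

```r
library(petu)

w <- petu_window(5, 5)
dimensional_space(w)
#> R^156 dimensional space (low region) for window 5 x 5

img <- make_texture("blob", rows = 300, cols = 300, radius = 2,
                    quantile = 0.5, seed = 7)
s <- texture_spectrum(img, w)
texture_entropy(s)
#> texture information H = 7.1184 bits (bound log2 K = 7.2854, K = 156)

count_operations(300, 300, w)
#> [1] 4293184

db  <- make_database(C = 12, rows = 300, cols = 300, seed = 42)
cfg <- sampling_config(150, 150, S = 100, P = 100, seed = 42)
model <- petu_learn(db, w, cfg)
cm <- petu_evaluate(model, db)
classification_efficiency(cm)
#> [1] 100
```

The blob texture fills all 156 histogram bins and sits near (but below) the
log2(156) ≈ 7.29-bit entropy bound; the 12 synthetic texture classes —
spread Bernoulli densities, stripe periods, checkerboard cells, blob
scales — are recovered perfectly by the 5×5 spectrum under the
train-equals-test, S = P = 100 protocol.

## Command line

A launcher script is installed at `inst/cli/petu.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/petu.R", package="petu"))') \
    ops --rows 300 --cols 300 --window 3 3
# 1509668
```

Subcommands: `info`, `ops`, `spectrum`, `entropy`, `synth`, `train`,
`classify` (with `--evaluate`). Images are read and written as portable
anymaps (PBM/PGM/PPM); grayscale input is binarized with a global
threshold, Otsu by default or `--binarize fixed --threshold T`.

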
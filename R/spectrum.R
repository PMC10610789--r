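#' Texture-unit histogram of a binary image
#'
#' Slides an I x J observation window pixel by pixel over the image (stride
#' 1, fully interior placements only, no padding) and counts how often each
#' texture unit k occurs. The number of placements is
#' Pp = (M - I + 1) * (N - J + 1), which is also the histogram total.
#'
#' The computation is vectorized: per-row binary codes are accumulated with
#' J shifted matrix additions, then units with I more; integer arithmetic in
#' doubles is exact here because k < 2^53 for any practical window. The
#' result is bit-identical to the naive per-placement encoding (this is
#' asserted by the test suite against a brute-force reference).
#'
#' Storage is sparse (only units that occur are kept), so large windows such
#' as 20 x 20 (K = 20,971,501) pose no memory problem. The `backend`
#' argument selects between two independent counting routes — a dense
#' `tabulate()` over all K bins (only allowed when K <= 2^22) and a sparse
#' unique/match aggregation — which must and do agree; `"auto"` picks by K.
#'
#' @param img binary matrix (values 0/1); rows are image lines.
#' @param w a [petu_window()] or `c(I, J)`; must fit inside `img`.
#' @param backend `"auto"`, `"dense"`, or `"sparse"` counting route.
#' @return An object of class `texture_histogram`: list with `window`, `K`,
#'   `Pp`, `M`, `N`, and parallel vectors `k` (sorted units with nonzero
#'   count) and `counts`.
#' @examples
#' img <- matrix(0, 8, 8)
#' h <- texture_histogram(img, petu_window(3, 3))
#' h$k       # 0
#' h$counts  # 36
#' @seealso [texture_spectrum()] for the normalized version.
#' @export
texture_histogram <- function(img, w, backend = c("auto", "dense", "sparse")) {
  backend <- match.arg(backend)
  w <- as_petu_window(w)
  img <- check_binary_image(img)
  M <- nrow(img); N <- ncol(img)
  if (w$I > M || w$J > N) {
    stop(sprintf("window %d x %d does not fit inside the %d x %d image",
                 w$I, w$J, M, N), call. = FALSE)
  }
  K <- window_K(w)
  units <- unit_field(img, w)
  if (backend == "auto") backend <- if (K <= 2^22) "dense" else "sparse"
  if (backend == "dense") {
    if (K > 2^22) {
      stop("dense backend restricted to K <= 2^22; use backend = \"sparse\"",
           call. = FALSE)
    }
    full <- tabulate(as.integer(units) + 1L, nbins = as.integer(K))
    nz <- which(full > 0L)
    k <- as.numeric(nz - 1L)
    counts <- as.numeric(full[nz])
  } else {
    u <- as.vector(units)
    k <- sort(unique(u))
    counts <- as.numeric(tabulate(match(u, k), nbins = length(k)))
  }
  structure(list(window = w, K = K, Pp = length(units), M = M, N = N,
                 k = k, counts = counts),
            class = "texture_histogram")
}

# Matrix of texture units, one per fully-interior window placement:
# (M - I + 1) x (N - J + 1), in doubles.
unit_field <- function(img, w) {
  M <- nrow(img); N <- ncol(img)
  I <- w$I; J <- w$J
  Np <- N - J + 1L
  Mp <- M - I + 1L
  # row codes: rc[m, n0] = sum_j img[m, n0 + j - 1] * 2^(j-1)
  rc <- matrix(0, M, Np)
  for (j in seq_len(J)) {
    rc <- rc + img[, j:(j + Np - 1L), drop = FALSE] * 2^(j - 1)
  }
  # units: u[m0, n0] = sum_i rc[m0 + i - 1, n0]
  u <- matrix(0, Mp, Np)
  for (i in seq_len(I)) {
    u <- u + rc[i:(i + Mp - 1L), , drop = FALSE]
  }
  u
}

#' Texture spectrum (normalized texture-unit histogram)
#'
#' The texture spectrum p(k) is the texture-unit histogram divided by the
#' total number of window placements Pp, giving a probability distribution
#' over the K = I*(2^J - 1) + 1 possible unit values. It is the feature
#' vector used throughout: for entropy measurement ([texture_entropy()]) and
#' as the per-class prototype in the classifier ([petu_learn()]).
#'
#' @param img binary matrix, or a `texture_histogram` (then `w` is ignored).
#' @param w a [petu_window()] or `c(I, J)`.
#' @param backend passed to [texture_histogram()].
#' @return An object of class `texture_spectrum`: list with `window`, `K`,
#'   `Pp`, and parallel vectors `k` and `p` (probabilities summing to 1).
#' @examples
#' chk <- make_texture("checkerboard", rows = 4, cols = 4, cell = 1)
#' s <- texture_spectrum(chk, c(3, 3))
#' setNames(s$p, s$k)  # units 9 and 12, probability 1/2 each
#' @export
texture_spectrum <- function(img, w = NULL, backend = "auto") {
  h <- if (inherits(img, "texture_histogram")) img
       else texture_histogram(img, w, backend = backend)
  new_texture_spectrum(h$k, h$counts / h$Pp, h$window, Pp = h$Pp)
}

# Low-level sparse constructor; k sorted, p the matching probabilities.
new_texture_spectrum <- function(k, p, window, Pp = NA_real_) {
  window <- as_petu_window(window)
  structure(list(window = window, K = window_K(window), Pp = Pp,
                 k = as.numeric(k), p = as.numeric(p)),
            class = "texture_spectrum")
}

#' Build a texture spectrum from explicit (unit, probability) pairs
#'
#' Mostly useful for constructing reference spectra in examples and tests
#' (e.g. a delta spectrum) without going through an image.
#'
#' @param k texture-unit values (distinct, within `[0, K - 1]`).
#' @param p probabilities for each unit; must be nonnegative and sum to 1
#'   within 1e-9.
#' @param w a [petu_window()] or `c(I, J)`.
#' @return A `texture_spectrum`.
#' @examples
#' as_texture_spectrum(k = c(9, 12), p = c(0.5, 0.5), w = c(3, 3))
#' @export
as_texture_spectrum <- function(k, p, w) {
  w <- as_petu_window(w)
  K <- window_K(w)
  if (length(k) != length(p)) stop("k and p must have equal length", call. = FALSE)
  if (anyDuplicated(k)) stop("unit values k must be distinct", call. = FALSE)
  if (any(k < 0) || any(k > K - 1) || any(k != floor(k))) {
    stop(sprintf("unit values must be integers in [0, %s]",
                 format(K - 1, big.mark = ",")), call. = FALSE)
  }
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (within 1e-9)", call. = FALSE)
  }
  o <- order(k)
  new_texture_spectrum(k[o], p[o], w)
}

#' @export
print.texture_histogram <- function(x, ...) {
  cat(sprintf("texture-unit histogram: window %d x %d, K = %s, Pp = %s, %d occupied bins\n",
              x$window$I, x$window$J, format(x$K, big.mark = ","),
              format(x$Pp, big.mark = ","), length(x$k)))
  invisible(x)
}

#' @export
print.texture_spectrum <- function(x, ...) {
  cat(sprintf("texture spectrum: window %d x %d, K = %s, %d occupied bins\n",
              x$window$I, x$window$J, format(x$K, big.mark = ","), length(x$k)))
  invisible(x)
}

#' Arithmetic operation count of the histogram computation
#'
#' Analytic cost model for computing the texture-unit histogram of an
#' M x N image with an I x J window. Per window placement the encoding
#' costs I*J multiplications plus I*(J - 1) additions for the row codes and
#' I - 1 additions for the unit sum, i.e. 2*I*J - 1 operations, over
#' (M - I + 1)*(N - J + 1) placements:
#'
#'   ops(M, N, I, J) = (M - I + 1) * (N - J + 1) * (2*I*J - 1)
#'
#' For a 300 x 300 image this gives 1,509,668 operations at 3 x 3 and
#' 63,089,839 at 20 x 20.
#'
#' @param M,N image rows and columns.
#' @param w a [petu_window()] or `c(I, J)`.
#' @return Total number of multiplications and additions (a double; exact
#'   integer arithmetic within 2^53).
#' @examples
#' count_operations(300, 300, c(3, 3))    # 1509668
#' count_operations(300, 300, c(20, 20))  # 63089839
#' @export
count_operations <- function(M, N, w) {
  w <- as_petu_window(w)
  if (length(M) != 1L || length(N) != 1L || M < 1 || N < 1 ||
      M != floor(M) || N != floor(N)) {
    stop("M and N must be positive integers", call. = FALSE)
  }
  if (w$I > M || w$J > N) {
    stop(sprintf("window %d x %d does not fit inside a %d x %d image",
                 w$I, w$J, M, N), call. = FALSE)
  }
  (M - w$I + 1) * (N - w$J + 1) * (2 * w$I * w$J - 1)
}
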
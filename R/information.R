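#' Texture information (Shannon entropy) of a spectrum
#'
#' Measures the amount of texture information carried by a texture spectrum
#' as its Shannon entropy in bits, H = -sum_k p(k) log2 p(k), with the
#' convention 0 * log2(0) = 0. H is bounded by log2(K), attained exactly
#' when all K unit values are equiprobable, so larger observation windows
#' (larger K) can carry more texture information.
#'
#' @param p a `texture_spectrum`, or a plain numeric probability vector
#'   (then `w` must be given so K is known).
#' @param w window, only used when `p` is a bare numeric vector.
#' @return An object of class `texture_information`: list with `H` (bits),
#'   `K`, and `H_max` = log2(K).
#' @examples
#' s <- as_texture_spectrum(k = c(9, 12), p = c(0.5, 0.5), w = c(3, 3))
#' texture_entropy(s)$H  # 1 bit
#' @seealso [max_entropy()] for the equiprobable bound alone.
#' @export
texture_entropy <- function(p, w = NULL) {
  if (inherits(p, "texture_spectrum")) {
    w <- p$window
    probs <- p$p
  } else if (is.numeric(p)) {
    if (is.null(w)) stop("w is required when p is a bare probability vector",
                         call. = FALSE)
    probs <- p
  } else {
    stop("p must be a texture_spectrum or a numeric probability vector",
         call. = FALSE)
  }
  w <- as_petu_window(w)
  if (any(probs < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("spectrum is not normalized: probabilities must sum to 1 within 1e-9",
         call. = FALSE)
  }
  pos <- probs[probs > 0]
  H <- -sum(pos * log2(pos))
  K <- window_K(w)
  structure(list(H = H, K = K, H_max = log2(K), window = w),
            class = "texture_information")
}

#' @export
print.texture_information <- function(x, ...) {
  cat(sprintf("texture information H = %.4f bits (bound log2 K = %.4f, K = %s)\n",
              x$H, x$H_max, format(x$K, big.mark = ",")))
  invisible(x)
}

#' Maximum texture information of a window
#'
#' Entropy of the equiprobable spectrum: log2(K) = log2(I*(2^J - 1) + 1)
#' bits. Strictly increasing in both I and J, which is the theoretical basis
#' for choosing larger observation windows when more texture information is
#' wanted.
#'
#' @param w a [petu_window()] or `c(I, J)`.
#' @return Upper bound on spectrum entropy, in bits.
#' @examples
#' max_entropy(c(3, 3))    # log2(22) ~ 4.459
#' max_entropy(c(10, 10))  # log2(10231) ~ 13.32
#' @export
max_entropy <- function(w) {
  log2(window_K(as_petu_window(w)))
}
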
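#' Observation window
#'
#' An observation window is the I-row, J-column region slid pixel by pixel
#' over a binary image. Each placement detects an I x J binary pattern that
#' is encoded into a single texture unit (see [texture_unit()]).
#'
#' Windows of any positive size are accepted. Sizes from 3 x 3 up to
#' 10 x 10 correspond to the low-dimensional regime of the descriptor
#' (histogram length K at most 10,231); larger windows are high-dimensional.
#' Windows smaller than 3 x 3 are permitted (they are convenient in tests)
#' but flagged by [dimensional_space()].
#'
#' @param I number of window rows (positive integer).
#' @param J number of window columns (positive integer).
#' @return An object of class `petu_window`: a list with elements `I` and `J`.
#' @examples
#' w <- petu_window(3, 3)
#' dimensional_space(w)$K  # 22
#' @export
petu_window <- function(I, J) {
  if (length(I) != 1L || length(J) != 1L ||
      !is.finite(I) || !is.finite(J) ||
      I < 1 || J < 1 || I != floor(I) || J != floor(J)) {
    stop("window dimensions I and J must be positive integers", call. = FALSE)
  }
  structure(list(I = as.integer(I), J = as.integer(J)), class = "petu_window")
}

#' @export
print.petu_window <- function(x, ...) {
  cat(sprintf("observation window %d x %d (K = %s)\n",
              x$I, x$J, format(window_K(x), big.mark = ",")))
  invisible(x)
}

# Accept petu_window or a length-2 vector c(I, J).
as_petu_window <- function(w) {
  if (inherits(w, "petu_window")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(petu_window(w[1], w[2]))
  stop("expected a petu_window or a length-2 numeric c(I, J)", call. = FALSE)
}

# Histogram length K = I * (2^J - 1) + 1. Doubles, not integers: K exceeds
# .Machine$integer.max already for J > 26 or so.
window_K <- function(w) {
  w <- as_petu_window(w)
  w$I * (2^w$J - 1) + 1
}
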
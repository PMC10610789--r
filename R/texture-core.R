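#' Binary-to-decimal code of one window row
#'
#' Reads a row of J bits as a binary number. The leftmost pixel of the row is
#' the least significant bit (b0), so `row_code(c(1, 0, 1))` is
#' 1*2^0 + 0*2^1 + 1*2^2 = 5. This orientation is a fixed convention: any
#' fixed bit order yields an equivalent descriptor (a relabeling of the
#' texture-unit axis), but one order must be chosen and documented.
#'
#' @param bits vector of 0/1 values (one window row, length J >= 1).
#' @return The row code, a number in `[0, 2^J - 1]`.
#' @examples
#' row_code(c(0, 0, 0))  # 0
#' row_code(c(1, 1, 1))  # 7
#' @seealso [texture_unit()]
#' @export
row_code <- function(bits) {
  bits <- check_bits(bits, "row")
  J <- length(bits)
  sum(bits * 2^(seq_len(J) - 1))
}

#' Parallel-encoded texture unit of a binary pattern
#'
#' Encodes an I x J binary pattern into a single integer by coding each row
#' independently with [row_code()] and summing the I row codes. The sum
#' collapses the 2^(I*J) distinct patterns onto I*(2^J - 1) + 1 unit values,
#' which is what keeps the texture spectrum low-dimensional for windows well
#' beyond 3 x 3. Because addition is commutative, the unit is invariant under
#' any permutation of the pattern's rows.
#'
#' @param pattern an I x J matrix (or vector for I = 1) of 0/1 values.
#' @return The texture unit k, an integer in `[0, I*(2^J - 1)]`.
#' @examples
#' texture_unit(matrix(0, 3, 3))  # 0
#' texture_unit(matrix(1, 3, 3))  # 21
#' texture_unit(rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 0)))  # 5 + 2 + 3 = 10
#' @export
texture_unit <- function(pattern) {
  if (!is.matrix(pattern)) {
    if (is.numeric(pattern) || is.logical(pattern)) {
      pattern <- matrix(pattern, nrow = 1L)
    } else {
      stop("pattern must be a 0/1 matrix", call. = FALSE)
    }
  }
  pattern <- check_bits(pattern, "pattern")
  J <- ncol(pattern)
  # row code per row, then sum: k = sum_i sum_j a_ij * 2^(j-1)
  sum(pattern %*% 2^(seq_len(J) - 1))
}

#' Dimensional space of the texture spectrum
#'
#' For an I x J window the texture-unit histogram has length
#' K(I, J) = I*(2^J - 1) + 1: K is linear in the number of rows I but
#' exponential in the number of columns J. Two operating regimes are
#' distinguished: the low-dimensional region, for windows from 3 x 3
#' (K = 22) up to 10 x 10 (K = 10,231), and the high-dimensional region for
#' anything larger. Windows with a side below 3 fall outside both regions;
#' they are reported as `low` with `subminimal = TRUE`.
#'
#' @param w a [petu_window()] or `c(I, J)`.
#' @return An object of class `petu_space`: list with `K` (histogram
#'   length), `region` (`"low"` or `"high"`), and `subminimal` (`TRUE` when
#'   the window is smaller than 3 x 3 in either dimension).
#' @examples
#' dimensional_space(petu_window(3, 3))    # K = 22, low
#' dimensional_space(petu_window(15, 15))  # K = 491506, high
#' @export
dimensional_space <- function(w) {
  w <- as_petu_window(w)
  K <- window_K(w)
  subminimal <- w$I < 3L || w$J < 3L
  region <- if (w$I > 10L || w$J > 10L) "high" else "low"
  if (subminimal && region == "low") {
    warning(sprintf("window %d x %d is smaller than 3 x 3; reported as the low-dimensional region by convention",
                    w$I, w$J), call. = FALSE)
  }
  structure(list(K = K, region = region, subminimal = subminimal,
                 window = w),
            class = "petu_space")
}

#' @export
print.petu_space <- function(x, ...) {
  cat(sprintf("R^%s dimensional space (%s region) for window %d x %d\n",
              format(x$K, big.mark = ","), x$region, x$window$I, x$window$J))
  invisible(x)
}

# Validate 0/1 content; returns numeric version of x.
check_bits <- function(x, what) {
  if (length(x) < 1L) stop(sprintf("%s must contain at least one bit", what),
                           call. = FALSE)
  if (is.logical(x)) x[] <- as.numeric(x)
  if (!is.numeric(x) || anyNA(x) || any(x != 0 & x != 1)) {
    stop(sprintf("%s must contain only 0/1 values", what), call. = FALSE)
  }
  x
}

# Validate an M x N binary image stored as a plain matrix.
check_binary_image <- function(img, arg = "img") {
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("%s must be a non-empty matrix", arg), call. = FALSE)
  }
  check_bits(img, sprintf("binary image %s", arg))
}
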
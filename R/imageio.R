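#' Read a raster image as a grayscale intensity matrix
#'
#' Reads portable anymap rasters — PBM (`P1`), PGM (`P2`/`P5`), PPM
#' (`P3`/`P6`) — and returns an M x N matrix of intensities in `[0, 255]`.
#' Color images are converted to luminance with the Rec.601 weights
#' (0.299 R + 0.587 G + 0.114 B). Bitmap (`P1`) pixels follow the netpbm
#' convention that 1 means black, so they map to intensity 0 and 0 to 255.
#' Samples on a non-255 `maxval` scale are rescaled to `[0, 255]`.
#'
#' Only the netpbm family is supported: no raster decoder for PNG/TIFF/JPEG
#' is available to this package, and the netpbm formats cover lossless
#' plain-text interchange. Convert other formats externally, e.g.
#' `pnmtopng` in reverse or Python's `imageio`.
#'
#' @param path path to a PBM/PGM/PPM file.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' writeLines(c("P2", "2 2", "255", "0 255", "0 255"), f)
#' read_image(f)
#' @seealso [binarize_global()], [write_pnm()]
#' @export
read_image <- function(path) {
  if (length(path) != 1L || !is.character(path)) {
    stop("path must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  magic <- tryCatch(readBin(path, "raw", n = 2L), error = function(e) raw(0))
  magic <- rawToChar(magic)
  if (!magic %in% c("P1", "P2", "P3", "P5", "P6")) {
    stop(sprintf("unsupported image format in '%s': expected a PBM/PGM/PPM (P1/P2/P3/P5/P6) raster",
                 path), call. = FALSE)
  }
  pnm <- read_pnm_raw(path, magic)
  px <- pnm$samples
  if (magic == "P1") {
    gray <- matrix(255 * (1 - px), pnm$height, pnm$width, byrow = TRUE)
  } else {
    if (pnm$maxval != 255) px <- px * (255 / pnm$maxval)
    if (pnm$channels == 3L) {
      dim(px) <- c(3L, pnm$width * pnm$height)
      px <- 0.299 * px[1L, ] + 0.587 * px[2L, ] + 0.114 * px[3L, ]
    }
    gray <- matrix(px, pnm$height, pnm$width, byrow = TRUE)
  }
  gray
}

# Parse header + samples of a netpbm file. Returns samples in file order
# (row-major, RGB interleaved for PPM).
read_pnm_raw <- function(path, magic) {
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  binary <- magic %in% c("P5", "P6")
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 2L)
  n_header <- if (magic == "P1") 2L else 3L  # bitmaps carry no maxval
  header <- integer(0)
  tok <- character(0)
  # single-byte scan so we stop exactly where binary samples begin
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (length(ch) == 0L) {
      stop(sprintf("truncated header in '%s'", path), call. = FALSE)
    }
    ch <- rawToChar(ch)
    if (ch == "#") {
      repeat {
        ch <- readBin(con, "raw", n = 1L)
        if (length(ch) == 0L || rawToChar(ch) == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- c(tok, ch)
    } else if (length(tok)) {
      header <- c(header, as.integer(paste(tok, collapse = "")))
      tok <- character(0)
      if (length(header) == n_header) break
    }
  }
  width <- header[1L]; height <- header[2L]
  maxval <- if (n_header == 3L) header[3L] else 1L
  n_samp <- width * height * channels
  if (width < 1L || height < 1L || maxval < 1L || maxval > 65535L) {
    stop(sprintf("invalid netpbm header in '%s'", path), call. = FALSE)
  }
  samples <- if (binary) {
    size <- if (maxval > 255L) 2L else 1L
    v <- readBin(con, "integer", n = n_samp, size = size, signed = FALSE,
                 endian = "big")
    if (length(v) < n_samp) {
      stop(sprintf("truncated pixel data in '%s'", path), call. = FALSE)
    }
    as.numeric(v)
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    txt <- gsub("#[^\n]*", " ", txt)
    v <- if (magic == "P1") {
      # P1 allows pixels without separators; treat every 0/1 digit as a pixel
      as.numeric(strsplit(gsub("[^01]", "", txt), "")[[1L]])
    } else {
      suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1L]]))
    }
    if (anyNA(v) || length(v) < n_samp) {
      stop(sprintf("malformed pixel data in '%s'", path), call. = FALSE)
    }
    v[seq_len(n_samp)]
  }
  if (any(samples < 0) || any(samples > maxval)) {
    stop(sprintf("pixel values outside [0, maxval] in '%s'", path),
         call. = FALSE)
  }
  list(width = width, height = height, maxval = maxval,
       channels = channels, samples = samples)
}

#' Write a matrix as a plain (ASCII) PGM image
#'
#' Binary 0/1 matrices are scaled to 0/255 on disk so the file renders as
#' black and white; matrices already in `[0, 255]` are written rounded.
#' Always emits the plain `P2` variant for portability and diffability.
#'
#' @param img numeric matrix, either 0/1 or intensities in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".pgm")
#' write_pnm(make_texture("checkerboard", 4, 4, cell = 2), f)
#' read_image(f)
#' @export
write_pnm <- function(img, path) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("img must be a numeric matrix", call. = FALSE)
  }
  if (any(img < 0) || any(img > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  vals <- round(img)
  if (all(vals %in% c(0, 1))) vals <- vals * 255
  lines <- c("P2", paste(ncol(img), nrow(img)), "255",
             apply(vals, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Otsu's global threshold
#'
#' Exhaustively scans integer thresholds t = 0..254 and returns the one
#' maximizing the between-class variance of the split into intensities
#' `<= t` and `> t` (ties resolved to the smallest t). This is the
#' parameter-free default used by [binarize_global()].
#'
#' @param img numeric matrix of intensities in `[0, 255]`.
#' @return Integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(img) {
  img <- check_gray_image(img)
  v <- round(as.vector(img))
  hist <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  p <- hist / n
  omega <- cumsum(p)                  # P(intensity <= t), t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  # between-class variance at each t = 0..254
  w0 <- omega[1:255]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 255L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[1:255][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  if (!any(valid)) return(0L)  # constant image: threshold is arbitrary
  which.max(sigma_b) - 1L
}

#' Binarize a grayscale image with a global threshold
#'
#' Maps each pixel to 1 (white) when its intensity strictly exceeds the
#' threshold and to 0 (black) otherwise; intensities equal to the threshold
#' therefore go to black. The threshold is either supplied (`method =
#' "fixed"`) or chosen by Otsu's between-class-variance criterion
#' (`method = "otsu"`, the default).
#'
#' @param img numeric matrix of intensities in `[0, 255]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold required for `"fixed"`, in `[0, 255]`; ignored for
#'   `"otsu"`.
#' @return Binary matrix of the same dimensions, with the chosen threshold
#'   in attribute `"threshold"`.
#' @examples
#' g <- rbind(c(10, 200), c(30, 240))
#' binarize_global(g, method = "fixed", threshold = 128)
#' @export
binarize_global <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  img <- check_gray_image(img)
  if (method == "fixed") {
    if (is.null(threshold)) {
      stop("method = \"fixed\" requires a threshold in [0, 255]", call. = FALSE)
    }
    if (length(threshold) != 1L || !is.finite(threshold) ||
        threshold < 0 || threshold > 255) {
      stop("threshold must be a single value in [0, 255]", call. = FALSE)
    }
  } else {
    threshold <- otsu_threshold(img)
  }
  out <- (img > threshold) * 1
  attr(out, "threshold") <- threshold
  out
}

check_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || nrow(img) < 1L || ncol(img) < 1L) {
    stop("expected a non-empty numeric intensity matrix", call. = FALSE)
  }
  if (anyNA(img) || any(img < 0) || any(img > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  img
}
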
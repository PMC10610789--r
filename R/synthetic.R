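#' Generate a synthetic binary texture
#'
#' Seeded generators for binary test textures, chosen to span the range of
#' spectrum shapes the descriptor can meet: `"bernoulli"` fields give broad
#' spectra, `"checkerboard"` and `"stripes"` give few-state periodic
#' spectra, and `"blob"` (a thresholded box-filtered noise field) gives
#' spatially correlated patches reminiscent of natural surface textures.
#'
#' @param kind one of `"bernoulli"`, `"checkerboard"`, `"stripes"`, `"blob"`.
#' @param rows,cols output size in pixels.
#' @param density for `"bernoulli"`: probability of a 1 at each pixel, in
#'   `[0, 1]`.
#' @param cell for `"checkerboard"`: cell side in pixels; the top-left cell
#'   is 1 (white).
#' @param width for `"stripes"`: stripe width in pixels (period 2 * width).
#' @param orientation for `"stripes"`: `"horizontal"`, `"vertical"`, or
#'   `"diagonal"`.
#' @param radius for `"blob"`: box-filter radius in pixels applied to a
#'   Bernoulli(0.5) field.
#' @param quantile for `"blob"`: quantile of the filtered field above which
#'   pixels become 1.
#' @param seed RNG seed for the random kinds (`NULL` uses the current
#'   stream); deterministic output for a fixed seed.
#' @return A `rows` x `cols` binary matrix.
#' @examples
#' make_texture("checkerboard", rows = 4, cols = 4, cell = 1)
#' make_texture("bernoulli", rows = 8, cols = 8, density = 0.3, seed = 1)
#' @export
make_texture <- function(kind = c("bernoulli", "checkerboard", "stripes", "blob"),
                         rows, cols, density = 0.5, cell = 4L, width = 4L,
                         orientation = c("horizontal", "vertical", "diagonal"),
                         radius = 2L, quantile = 0.5, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(rows >= 1, cols >= 1)
  rows <- as.integer(rows); cols <- as.integer(cols)
  gen <- switch(kind,
    bernoulli = {
      stopifnot(density >= 0, density <= 1)
      draw <- function() matrix(as.numeric(stats::runif(rows * cols) < density),
                                rows, cols)
      if (is.null(seed)) draw() else with_seed(seed, draw())
    },
    checkerboard = {
      stopifnot(cell >= 1)
      r <- floor((seq_len(rows) - 1) / cell)
      c <- floor((seq_len(cols) - 1) / cell)
      (outer(r, c, `+`) %% 2 == 0) * 1
    },
    stripes = {
      orientation <- match.arg(orientation)
      stopifnot(width >= 1)
      idx <- switch(orientation,
        horizontal = matrix(seq_len(rows) - 1, rows, cols),
        vertical   = matrix(seq_len(cols) - 1, rows, cols, byrow = TRUE),
        diagonal   = outer(seq_len(rows) - 1, seq_len(cols) - 1, `+`))
      (floor(idx / width) %% 2 == 0) * 1
    },
    blob = {
      stopifnot(radius >= 1, quantile >= 0, quantile <= 1)
      draw <- function() matrix(as.numeric(stats::runif(rows * cols) < 0.5),
                                rows, cols)
      field <- if (is.null(seed)) draw() else with_seed(seed, draw())
      # fractional radii blend the two neighboring box filters, giving a
      # continuum of correlation scales
      r0 <- floor(radius); fr <- radius - r0
      sm <- box_filter(field, r0)
      if (fr > 0) sm <- (1 - fr) * sm + fr * box_filter(field, r0 + 1)
      (sm > stats::quantile(sm, quantile)) * 1
    })
  storage.mode(gen) <- "double"
  gen
}

# Mean filter over the (2r+1)^2 neighborhood clipped to the image, via a
# padded integral image; O(rows * cols) regardless of r.
box_filter <- function(mat, r) {
  M <- nrow(mat); N <- ncol(mat)
  ii <- matrix(0, M + 1L, N + 1L)
  cs <- matrix(apply(mat, 2L, cumsum), M, N)  # cumulative sums down columns
  ii[-1L, -1L] <- matrix(t(apply(cs, 1L, cumsum)), M, N)  # then across rows

  r1 <- pmax(seq_len(M) - r, 1L); r2 <- pmin(seq_len(M) + r, M)
  c1 <- pmax(seq_len(N) - r, 1L); c2 <- pmin(seq_len(N) + r, N)
  sums <- ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
    ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  area <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / area
}

# Fixed parameter grid behind make_database: kinds interleaved so small C
# already mixes random, periodic, and correlated textures.
database_grid <- function() {
  specs <- list()
  dens <- seq(0.08, 0.92, length.out = 24)
  # visit densities in a strided order so even a small C spans the range
  dens <- dens[as.vector(t(matrix(1:24, nrow = 6)))]
  cells <- c(1:8, 10, 12, 15, 20)
  widths <- 1:8
  # only vertical stripes enter the grid: the texture unit is invariant
  # under row permutation, so horizontal stripes of different widths can
  # share one spectrum (widths 1 and 2 coincide for odd I), and diagonal
  # stripes of width c collapse onto the cell-c checkerboard (width 1 is
  # even pixel-identical to it). Vertical stripes change the row codes
  # themselves, so each width is a genuinely distinct class.
  bern <- lapply(dens, function(d) list(kind = "bernoulli", density = d))
  chk <- lapply(cells, function(s) list(kind = "checkerboard", cell = s))
  str <- lapply(widths, function(wd)
    list(kind = "stripes", width = wd, orientation = "vertical"))
  radii <- 1:6
  quants <- c(0.35, 0.65)
  blb <- unlist(lapply(radii, function(r) lapply(quants, function(q)
    list(kind = "blob", radius = r, quantile = q))), recursive = FALSE)
  pools <- list(bern, str, chk, blb)
  idx <- rep(0L, length(pools))
  while (any(idx < lengths(pools))) {
    for (pi in seq_along(pools)) {
      if (idx[pi] < length(pools[[pi]])) {
        idx[pi] <- idx[pi] + 1L
        specs[[length(specs) + 1L]] <- pools[[pi]][[idx[pi]]]
      }
    }
  }
  specs
}

#' Generate a synthetic multi-class texture database
#'
#' Produces C pairwise-distinct binary class images with labels
#' `"class_01"`, `"class_02"`, ... Deterministic for a fixed seed. The
#' default database draws classes from a fixed grid of generator settings
#' (spread Bernoulli densities, stripe widths and orientations,
#' checkerboard cells, blob radii), giving well-separated spectra: a
#' stand-in for a curated database of visually distinct surface textures.
#' The `hard = TRUE` variant instead uses blob fields at one fixed density
#' (median threshold) whose correlation scales differ only in steps of 0.15
#' pixels of filter radius — deliberately confusable classes that exercise
#' the classifier's error paths, especially at small observation windows.
#'
#' @param C number of classes (>= 2; at most the grid size, 56, for the
#'   default variant).
#' @param rows,cols class-image size in pixels.
#' @param seed integer seed; per-class seeds are derived from it.
#' @param hard generate the nearly-identical-density variant.
#' @return Named list of C binary matrices.
#' @examples
#' db <- make_database(C = 4, rows = 32, cols = 32, seed = 1)
#' names(db)
#' @export
make_database <- function(C, rows, cols, seed = 1L, hard = FALSE) {
  stopifnot(C >= 2, C == floor(C), rows >= 1, cols >= 1)
  C <- as.integer(C)
  specs <- if (hard) {
    # classes share one density (median threshold) and differ only in
    # correlation scale, in small steps: confusable at small windows, while
    # larger windows see enough of the neighborhood to separate them
    radii <- seq(1, by = 0.15, length.out = C)
    lapply(radii, function(r) list(kind = "blob", radius = r, quantile = 0.5))
  } else {
    grid <- database_grid()
    if (C > length(grid)) {
      stop(sprintf("C = %d exceeds the %d distinct generator settings available",
                   C, length(grid)), call. = FALSE)
    }
    grid[seq_len(C)]
  }
  db <- vector("list", C)
  names(db) <- sprintf("class_%02d", seq_len(C))
  for (ci in seq_len(C)) {
    args <- c(specs[[ci]], list(rows = rows, cols = cols,
                                seed = seed + 7919L * ci))
    db[[ci]] <- do.call(make_texture, args)
  }
  db
}
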
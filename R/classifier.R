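#' Sampling configuration for the subimage classifier
#'
#' Collects the subimage-sampling parameters of the multi-class classifier:
#' subimage size, the number S of subimages averaged into each class
#' prototype during learning, the number P averaged into the feature vector
#' of a test image during recognition, and the RNG seed that makes both
#' stages reproducible. Subimage corners are drawn uniformly with
#' replacement over all fully-interior positions, so subimages may overlap
#' (with S = 100 subimages of 150 x 150 from a 300 x 300 image they must).
#'
#' @param sub_rows,sub_cols subimage size in pixels.
#' @param S subimages per class in the learning stage.
#' @param P subimages per test image in the recognition stage.
#' @param seed integer RNG seed.
#' @return An object of class `petu_sampling`.
#' @examples
#' sampling_config(150, 150, S = 100, P = 100, seed = 42)
#' @export
sampling_config <- function(sub_rows, sub_cols, S = 100L, P = S, seed = 1L) {
  stopifnot(sub_rows >= 1, sub_cols >= 1, S >= 1, P >= 1)
  structure(list(sub_rows = as.integer(sub_rows),
                 sub_cols = as.integer(sub_cols),
                 S = as.integer(S), P = as.integer(P),
                 seed = as.integer(seed)),
            class = "petu_sampling")
}

# Run expr with a private, seeded RNG stream; global RNG state untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw random subimages from a binary image
#'
#' Top-left corners are drawn uniformly, with replacement, over all
#' positions at which the subimage is fully interior. Deterministic for a
#' fixed seed.
#'
#' @param img binary matrix.
#' @param sub_rows,sub_cols subimage size; must fit inside `img`.
#' @param count number of subimages to draw (0 gives an empty list).
#' @param seed integer RNG seed (`NULL` uses the current RNG stream).
#' @return List of `count` binary matrices of size `sub_rows` x `sub_cols`.
#' @examples
#' img <- make_texture("bernoulli", rows = 40, cols = 40, density = 0.5, seed = 7)
#' subs <- sample_subimages(img, 16, 16, count = 3, seed = 42)
#' @export
sample_subimages <- function(img, sub_rows, sub_cols, count, seed = NULL) {
  img <- check_binary_image(img)
  stopifnot(count >= 0, count == floor(count))
  M <- nrow(img); N <- ncol(img)
  if (sub_rows > M || sub_cols > N) {
    stop(sprintf("subimage %d x %d does not fit inside the %d x %d image",
                 sub_rows, sub_cols, M, N), call. = FALSE)
  }
  if (count == 0) return(list())
  draw <- function() {
    r0 <- sample.int(M - sub_rows + 1L, count, replace = TRUE)
    c0 <- sample.int(N - sub_cols + 1L, count, replace = TRUE)
    cbind(r0, c0)
  }
  corners <- if (is.null(seed)) draw() else with_seed(seed, draw())
  lapply(seq_len(count), function(s) {
    r0 <- corners[s, 1L]; c0 <- corners[s, 2L]
    img[r0:(r0 + sub_rows - 1L), c0:(c0 + sub_cols - 1L), drop = FALSE]
  })
}

# Arithmetic mean of sparse spectra sharing one window.
average_spectra <- function(spectra) {
  w <- spectra[[1L]]$window
  ks <- sort(unique(unlist(lapply(spectra, `[[`, "k"))))
  acc <- numeric(length(ks))
  for (s in spectra) acc[match(s$k, ks)] <- acc[match(s$k, ks)] + s$p
  new_texture_spectrum(ks, acc / length(spectra), w)
}

# Distance between two sparse spectra over the union of their supports.
spectrum_distance <- function(a, b, metric = c("euclidean", "manhattan", "chi2")) {
  metric <- match.arg(metric)
  ks <- sort(unique(c(a$k, b$k)))
  pa <- numeric(length(ks)); pa[match(a$k, ks)] <- a$p
  pb <- numeric(length(ks)); pb[match(b$k, ks)] <- b$p
  switch(metric,
    euclidean = sqrt(sum((pa - pb)^2)),
    manhattan = sum(abs(pa - pb)),
    chi2 = {
      s <- pa + pb
      d <- (pa - pb)^2
      sum(d[s > 0] / s[s > 0])
    })
}

#' Learn a multi-class prototype model
#'
#' Learning stage of the minimum-distance texture classifier. For each class
#' image, S subimages are drawn at random, the texture spectrum of each is
#' computed, and the class prototype is the arithmetic mean of those S
#' spectra (itself a probability distribution). Per-class sampling seeds are
#' derived deterministically from `cfg$seed`, so the whole model is
#' reproducible.
#'
#' @param class_images named list of binary matrices; names are the class
#'   labels and must be unique.
#' @param w a [petu_window()] or `c(I, J)`; must fit inside the subimages.
#' @param cfg a [sampling_config()].
#' @param distance distance metric used at recognition time:
#'   `"euclidean"` (default), `"manhattan"`, or `"chi2"`.
#' @return An object of class `petu_model` with per-class prototype spectra.
#' @examples
#' db <- make_database(C = 3, rows = 60, cols = 60, seed = 1)
#' cfg <- sampling_config(30, 30, S = 10, P = 10, seed = 5)
#' model <- petu_learn(db, w = c(3, 3), cfg = cfg)
#' @seealso [petu_classify()], [petu_evaluate()]
#' @export
petu_learn <- function(class_images, w, cfg,
                       distance = c("euclidean", "manhattan", "chi2")) {
  distance <- match.arg(distance)
  w <- as_petu_window(w)
  stopifnot(inherits(cfg, "petu_sampling"))
  labels <- names(class_images)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("class_images must be a named list (names are class labels)",
         call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("duplicate class labels", call. = FALSE)
  if (length(class_images) < 2L) {
    stop("at least 2 classes are required", call. = FALSE)
  }
  if (w$I > cfg$sub_rows || w$J > cfg$sub_cols) {
    stop("observation window does not fit inside the configured subimages",
         call. = FALSE)
  }
  prototypes <- vector("list", length(labels))
  names(prototypes) <- labels
  for (ci in seq_along(labels)) {
    subs <- sample_subimages(class_images[[ci]], cfg$sub_rows, cfg$sub_cols,
                             count = cfg$S, seed = cfg$seed + ci)
    prototypes[[ci]] <- average_spectra(
      lapply(subs, texture_spectrum, w = w))
  }
  structure(list(window = w, K = window_K(w), labels = labels,
                 prototypes = prototypes, distance = distance,
                 sampling = cfg),
            class = "petu_model")
}

#' @export
print.petu_model <- function(x, ...) {
  cat(sprintf("minimum-distance texture classifier: %d classes, window %d x %d, %s distance\n",
              length(x$labels), x$window$I, x$window$J, x$distance))
  cat(sprintf("  sampling: S = %d, P = %d, subimages %d x %d, seed %d\n",
              x$sampling$S, x$sampling$P, x$sampling$sub_rows,
              x$sampling$sub_cols, x$sampling$seed))
  invisible(x)
}

#' Classify a test image by minimum distance to the class prototypes
#'
#' Recognition stage: P subimages are drawn at random from the test image,
#' their spectra averaged into the test feature vector, and the label of the
#' prototype at minimum distance is returned. Ties are broken in favor of
#' the first class in model order.
#'
#' @param test_img binary matrix, at least as large as the configured
#'   subimage size.
#' @param model a `petu_model` from [petu_learn()].
#' @param seed RNG seed for the subimage draw; defaults to the model's
#'   sampling seed.
#' @return List with `label` (predicted class), `distances` (named vector,
#'   one distance per class), and `spectrum` (the averaged test spectrum).
#' @export
petu_classify <- function(test_img, model, seed = model$sampling$seed) {
  stopifnot(inherits(model, "petu_model"))
  cfg <- model$sampling
  subs <- sample_subimages(test_img, cfg$sub_rows, cfg$sub_cols,
                           count = cfg$P, seed = seed)
  test_spec <- average_spectra(lapply(subs, texture_spectrum, w = model$window))
  d <- vapply(model$prototypes, spectrum_distance, numeric(1),
              b = test_spec, metric = model$distance)
  list(label = model$labels[which.min(d)], distances = d,
       spectrum = test_spec)
}

#' Evaluate a model on labelled test images
#'
#' Classifies each test image and tallies the decisions in a C x C
#' confusion matrix: rows are the true (test) classes, columns the predicted
#' (prototype) classes; the main diagonal holds correct identifications.
#' Per-image recognition seeds are derived from the model's sampling seed,
#' so the matrix is reproducible.
#'
#' @param model a `petu_model`.
#' @param test_images named list of binary matrices; every name must be a
#'   label known to the model.
#' @return A `petu_confusion` object (an integer matrix with class labels
#'   as dimnames).
#' @examples
#' db <- make_database(C = 3, rows = 60, cols = 60, seed = 1)
#' cfg <- sampling_config(30, 30, S = 10, P = 10, seed = 5)
#' model <- petu_learn(db, w = c(3, 3), cfg = cfg)
#' cm <- petu_evaluate(model, db)
#' classification_efficiency(cm)
#' @export
petu_evaluate <- function(model, test_images) {
  stopifnot(inherits(model, "petu_model"))
  labels <- model$labels
  test_labels <- names(test_images)
  if (is.null(test_labels) || !all(test_labels %in% labels)) {
    stop("every test image label must be one of the model's class labels",
         call. = FALSE)
  }
  C <- length(labels)
  mc <- matrix(0L, C, C, dimnames = list(test = labels, predicted = labels))
  for (ti in seq_along(test_images)) {
    res <- petu_classify(test_images[[ti]], model,
                         seed = model$sampling$seed + 10000L + ti)
    mc[test_labels[ti], res$label] <- mc[test_labels[ti], res$label] + 1L
  }
  structure(mc, class = c("petu_confusion", "matrix", "array"))
}

#' @export
print.petu_confusion <- function(x, ...) {
  cat(sprintf("confusion matrix (%d classes), efficiency %.3f%%\n",
              nrow(x), classification_efficiency(x)))
  print(unclass(x))
  invisible(x)
}

#' Classification efficiency of a confusion matrix
#'
#' Percentage of correct decisions under the one-test-image-per-class
#' protocol: the sum of the main diagonal divided by the number of classes
#' C, times 100. A C x C identity matrix therefore scores 100%.
#'
#' @param mc a square confusion matrix (rows = test classes, columns =
#'   predicted classes).
#' @return Efficiency in percent.
#' @examples
#' classification_efficiency(diag(12))  # 100
#' @export
classification_efficiency <- function(mc) {
  if (!is.matrix(mc) || nrow(mc) != ncol(mc) || nrow(mc) < 1L) {
    stop("mc must be a square matrix", call. = FALSE)
  }
  sum(diag(mc)) / nrow(mc) * 100
}
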
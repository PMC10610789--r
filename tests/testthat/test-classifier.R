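small_db <- function(seed = 1) make_database(C = 4, rows = 60, cols = 60, seed = seed)
small_cfg <- function(seed = 5) sampling_config(24, 24, S = 8, P = 8, seed = seed)

test_that("sample_subimages draws interior subimages, reproducibly", {
  img <- make_texture("bernoulli", 50, 40, density = 0.5, seed = 3)
  subs <- sample_subimages(img, 20, 15, count = 10, seed = 42)
  expect_length(subs, 10)
  for (s in subs) expect_identical(dim(s), c(20L, 15L))
  subs2 <- sample_subimages(img, 20, 15, count = 10, seed = 42)
  expect_identical(subs, subs2)
  expect_identical(sample_subimages(img, 20, 15, count = 0, seed = 1), list())
  expect_error(sample_subimages(img, 60, 15, count = 1, seed = 1),
               "does not fit")
})

test_that("prototypes are means of subimage spectra and stay normalized", {
  db <- small_db()
  cfg <- sampling_config(24, 24, S = 1, P = 1, seed = 9)
  model <- petu_learn(db, c(3, 3), cfg)
  # S = 1: prototype equals that single subimage's spectrum
  sub <- sample_subimages(db[[1]], 24, 24, count = 1, seed = 9 + 1)[[1]]
  ref <- texture_spectrum(sub, c(3, 3))
  expect_equal(model$prototypes[[1]]$k, ref$k)
  expect_equal(model$prototypes[[1]]$p, ref$p, tolerance = 1e-12)
  model8 <- petu_learn(db, c(3, 3), small_cfg())
  for (pr in model8$prototypes) {
    expect_equal(sum(pr$p), 1, tolerance = 1e-9)
  }
})

test_that("averaging two delta spectra gives the half/half prototype", {
  a <- as_texture_spectrum(0, 1, c(3, 3))
  b <- as_texture_spectrum(21, 1, c(3, 3))
  avg <- petu:::average_spectra(list(a, b))
  expect_equal(stats::setNames(avg$p, avg$k), c("0" = 0.5, "21" = 0.5))
})

test_that("learn validates labels, class count, and window fit", {
  db <- small_db()
  unnamed <- unname(db)
  expect_error(petu_learn(unnamed, c(3, 3), small_cfg()), "named list")
  dup <- db; names(dup) <- c("a", "a", "b", "c")
  expect_error(petu_learn(dup, c(3, 3), small_cfg()), "duplicate")
  expect_error(petu_learn(db[1], c(3, 3), small_cfg()), "at least 2 classes")
  expect_error(petu_learn(db, c(30, 30), small_cfg()),
               "does not fit inside the configured subimages")
})

test_that("an exact prototype match classifies to that class at distance ~0", {
  db <- small_db()
  model <- petu_learn(db, c(3, 3), small_cfg())
  # feed a prototype back as the test spectrum by classifying its own class
  res <- petu_classify(db[[2]], model, seed = 77)
  expect_identical(res$label, "class_02")
  expect_equal(sum(res$spectrum$p), 1, tolerance = 1e-9)
  expect_identical(names(res$distances), model$labels)
})

test_that("evaluation is deterministic and permutation-consistent", {
  db <- small_db()
  model <- petu_learn(db, c(3, 3), small_cfg())
  cm1 <- petu_evaluate(model, db)
  cm2 <- petu_evaluate(model, db)
  expect_identical(cm1, cm2)
  expect_equal(rowSums(cm1), stats::setNames(rep(1, 4), names(db)))

  # permuting class order in model and test set together leaves Ef unchanged
  perm <- c(3, 1, 4, 2)
  model_p <- petu_learn(db[perm], c(3, 3), small_cfg())
  cm_p <- petu_evaluate(model_p, db[perm])
  expect_equal(classification_efficiency(cm_p),
               classification_efficiency(cm1))
})

test_that("evaluate rejects unknown test labels; empty test set is all-zero", {
  db <- small_db()
  model <- petu_learn(db, c(3, 3), small_cfg())
  stranger <- list(mystery = db[[1]])
  expect_error(petu_evaluate(model, stranger), "class labels")
  cm0 <- petu_evaluate(model, db[0])
  expect_true(all(cm0 == 0))
})

test_that("efficiency is the diagonal sum over the class count, in percent", {
  expect_equal(classification_efficiency(diag(12)), 100)
  expect_equal(classification_efficiency(matrix(0, 3, 3)), 0)
  m <- diag(33); diag(m)[29:33] <- 0; m[29, 1] <- 1
  expect_equal(classification_efficiency(m), 28 / 33 * 100)
  expect_error(classification_efficiency(matrix(0, 2, 3)), "square")
})

test_that("distance metrics behave as metrics on sparse spectra", {
  a <- as_texture_spectrum(c(0, 5), c(0.5, 0.5), c(3, 3))
  b <- as_texture_spectrum(c(5, 9), c(0.5, 0.5), c(3, 3))
  for (m in c("euclidean", "manhattan", "chi2")) {
    expect_equal(petu:::spectrum_distance(a, a, m), 0)
    expect_gt(petu:::spectrum_distance(a, b, m), 0)
    expect_equal(petu:::spectrum_distance(a, b, m),
                 petu:::spectrum_distance(b, a, m))
  }
  expect_equal(petu:::spectrum_distance(a, b, "euclidean"), sqrt(0.5))
  expect_equal(petu:::spectrum_distance(a, b, "manhattan"), 1)
  expect_equal(petu:::spectrum_distance(a, b, "chi2"), 1)
})

test_that("train=test protocol separates the easy database across seeds", {
  # scaled-down analogue of the full acceptance protocol (smaller images,
  # fewer subimages) so the routine suite stays fast
  for (sd in c(1, 2, 3)) {
    db <- make_database(C = 6, rows = 90, cols = 90, seed = sd)
    cfg <- sampling_config(45, 45, S = 20, P = 20, seed = sd)
    model <- petu_learn(db, c(5, 5), cfg)
    expect_equal(classification_efficiency(petu_evaluate(model, db)), 100)
  }
})
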
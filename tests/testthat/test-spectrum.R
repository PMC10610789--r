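test_that("histograms of constant and checkerboard images are exact", {
  h0 <- texture_histogram(matrix(0, 8, 8), c(3, 3))
  expect_equal(h0$k, 0)
  expect_equal(h0$counts, 36)
  expect_equal(h0$Pp, 36)

  h1 <- texture_histogram(matrix(1, 8, 8), c(3, 3))
  expect_equal(h1$k, 21)
  expect_equal(h1$counts, 36)

  chk <- make_texture("checkerboard", 4, 4, cell = 1)
  h <- texture_histogram(chk, c(3, 3))
  expect_equal(h$Pp, 4)
  expect_equal(stats::setNames(h$counts, h$k), c("9" = 2, "12" = 2))

  s <- texture_spectrum(chk, c(3, 3))
  expect_equal(stats::setNames(s$p, s$k), c("9" = 0.5, "12" = 0.5))
})

test_that("optimized histogram equals the naive per-placement oracle", {
  set.seed(101)
  cases <- list(c(5, 5, 1, 1), c(8, 8, 3, 3), c(12, 9, 2, 4),
                c(16, 16, 5, 5), c(31, 17, 4, 6), c(64, 64, 8, 8))
  for (cs in cases) {
    img <- random_binary(cs[1], cs[2])
    h <- texture_histogram(img, c(cs[3], cs[4]))
    ref <- naive_histogram(img, cs[3], cs[4])
    expect_identical(as.character(h$k), names(ref))
    expect_equal(h$counts, as.numeric(ref))
    expect_equal(sum(h$counts), (cs[1] - cs[3] + 1) * (cs[2] - cs[4] + 1))
  }
})

test_that("dense and sparse counting backends agree", {
  set.seed(7)
  img <- random_binary(40, 40, 0.3)
  for (w in list(c(3, 3), c(6, 4))) {
    hd <- texture_histogram(img, w, backend = "dense")
    hs <- texture_histogram(img, w, backend = "sparse")
    expect_identical(hd$k, hs$k)
    expect_identical(hd$counts, hs$counts)
  }
  expect_error(texture_histogram(img, c(20, 20), backend = "dense"),
               "restricted to K")
})

test_that("large windows use sparse storage without overflow", {
  set.seed(8)
  img <- random_binary(40, 40)
  h <- texture_histogram(img, c(20, 20))  # K = 20,971,501 > 2^22
  expect_equal(h$K, 20 * (2^20 - 1) + 1)
  expect_equal(sum(h$counts), 21^2)
  expect_true(all(h$k >= 0 & h$k <= h$K - 1))
})

test_that("spectra are normalized and vertical-flip invariant", {
  set.seed(21)
  for (rep in 1:5) {
    img <- random_binary(24, 30, runif(1, 0.2, 0.8))
    w <- c(sample(1:5, 1), sample(1:5, 1))
    s <- texture_spectrum(img, w)
    expect_equal(sum(s$p), 1, tolerance = 1e-12)
    flipped <- texture_histogram(img[nrow(img):1, ], w)
    h <- texture_histogram(img, w)
    expect_identical(h$k, flipped$k)
    expect_identical(h$counts, flipped$counts)
  }
})

test_that("as_texture_spectrum validates its inputs", {
  expect_error(as_texture_spectrum(c(0, 0), c(0.5, 0.5), c(3, 3)), "distinct")
  expect_error(as_texture_spectrum(c(0, 25), c(0.5, 0.5), c(3, 3)),
               "integers in")
  expect_error(as_texture_spectrum(c(0, 21), c(0.6, 0.5), c(3, 3)),
               "sum to 1")
  s <- as_texture_spectrum(c(21, 0), c(0.25, 0.75), c(3, 3))
  expect_equal(s$k, c(0, 21))  # sorted
  expect_equal(s$p, c(0.75, 0.25))
})

test_that("window larger than the image is rejected with both sizes named", {
  expect_error(texture_histogram(matrix(0, 4, 4), c(5, 3)),
               "5 x 3 does not fit inside the 4 x 4")
})

table1_ops <- c(
  1509668, 2734479, 4293184, 6178775, 8384292, 10902823, 13727504,
  16851519, 20268100, 23970527, 27952128, 32206279, 36726404, 41505975,
  46538512, 51817583, 57336804, 63089839)

test_that("count_operations reproduces all 18 cost-table rows at 300x300", {
  for (i in seq_along(3:20)) {
    d <- (3:20)[i]
    expect_equal(count_operations(300, 300, c(d, d)), table1_ops[i])
  }
  expect_equal(count_operations(3, 3, c(3, 3)), 17)  # single placement
  expect_error(count_operations(10, 10, c(11, 3)), "does not fit")
})
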
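test_that("filter banks load with the documented structure", {
  w <- load_wavelet("haar")
  expect_equal(w$dec_lo, c(1, 1) / sqrt(2))
  expect_equal(abs(w$dec_hi), c(1, 1) / sqrt(2))
  expect_error(load_wavelet("db3.5"), "unknown wavelet")
  expect_setequal(supported_wavelets(),
                  c("haar", "db2", "db4", "rbio2.4", "dmey"))

  # db2: orthonormality and one vanishing moment of the high-pass
  h <- load_wavelet("db2")$dec_lo
  expect_length(h, 4L)
  expect_equal(sum(h^2), 1, tolerance = 1e-8)
  expect_lt(abs(sum((-1)^(0:3) * (0:3) * h)), 1e-8)
})

test_that("orthogonal banks satisfy the quadrature-mirror relation", {
  for (wn in c("haar", "db2", "db4", "dmey")) {
    w <- load_wavelet(wn)
    expect_true(w$orthogonal)
    L <- length(w$dec_lo)
    qmf <- (-1)^(seq_len(L) - 1) * rev(w$dec_lo)
    # allow the global sign convention to differ
    expect_true(max(abs(w$dec_hi - qmf)) < 1e-8 ||
                  max(abs(w$dec_hi + qmf)) < 1e-8)
  }
  expect_false(load_wavelet("rbio2.4")$orthogonal)
})

test_that("single-level decomposition honors lengths and degenerate cases", {
  co <- dwt_single_level(c(1, 1, 1, 1), "haar", padding = "none")
  expect_equal(co$approx, c(sqrt(2), sqrt(2)))
  expect_equal(co$detail, c(0, 0), tolerance = 1e-12)

  # half the original data length without padding
  co50 <- dwt_single_level(rnorm(50), "haar", padding = "none")
  expect_length(co50$approx, 25L)
  expect_length(co50$detail, 25L)

  expect_error(dwt_single_level(rnorm(50), "dmey", padding = "none"),
               "symmetric")
  expect_error(dwt_single_level(rnorm(51), "haar", padding = "none"), "even")
})

test_that("coefficient lengths follow the per-mode formulas", {
  for (wn in supported_wavelets()) {
    L <- length(load_wavelet(wn)$dec_lo)
    for (n in 2:64) {
      co <- dwt_single_level(rnorm(n), wn, padding = "symmetric")
      expect_length(co$approx, (n + L - 1) %/% 2)
      expect_length(co$detail, (n + L - 1) %/% 2)
      if (n %% 2 == 0 && n >= L) {
        co0 <- dwt_single_level(rnorm(n), wn, padding = "none")
        expect_length(co0$approx, n %/% 2)
      }
    }
  }
})

test_that("symmetric-mode coefficients match the reference implementation", {
  set.seed(31)
  X <- matrix(rnorm(20 * 50), nrow = 20)
  for (wn in c("db4", "dmey", "rbio2.4")) {
    ours <- t(apply(X, 1, function(x) {
      co <- dwt_single_level(x, wn, padding = "symmetric")
      c(co$approx, co$detail)
    }))
    ref <- reference_dwt(X, wn, mode = "symmetric")
    expect_lt(max(abs(ours - ref)), 1e-8)
  }
})

test_that("round trips reconstruct the signal for every family", {
  expect_equal(idwt_single_level(
    dwt_single_level(c(1, 2, 3, 4), "haar", padding = "none"), "haar"),
    c(1, 2, 3, 4), tolerance = 1e-9)

  set.seed(32)
  x <- rnorm(50)
  for (wn in supported_wavelets()) {
    co <- dwt_single_level(x, wn, padding = "symmetric")
    expect_lt(max(abs(idwt_single_level(co, wn) - x)), 1e-8)
  }
  co <- dwt_single_level(x, "rbio2.4", padding = "none")
  expect_lt(max(abs(idwt_single_level(co, "rbio2.4") - x)), 1e-8)

  # zero coefficients reconstruct to the zero signal
  zc <- dwt_single_level(x, "haar", padding = "none")
  zc$approx[] <- 0; zc$detail[] <- 0
  expect_equal(idwt_single_level(zc, "haar"), rep(0, 50))

  expect_error(idwt_single_level(
    dwt_single_level(x, "haar"), "db2"), "mismatch")
})

test_that("orthogonal transforms conserve energy without padding", {
  set.seed(33)
  for (wn in c("haar", "db2", "db4")) {
    for (i in 1:10) {
      x <- rnorm(64)
      co <- dwt_single_level(x, wn, padding = "none")
      rel <- abs(sum(co$approx^2) + sum(co$detail^2) - sum(x^2)) / sum(x^2)
      expect_lt(rel, 1e-6)
    }
  }
  # dmey is a 62-tap FIR approximation of the Meyer wavelet; its filter bank
  # is near-orthogonal (sum of squared taps 1.0022), so energy is conserved
  # only to a few parts in a thousand
  for (i in 1:10) {
    x <- rnorm(64)
    co <- dwt_single_level(x, "dmey", padding = "none")
    rel <- abs(sum(co$approx^2) + sum(co$detail^2) - sum(x^2)) / sum(x^2)
    expect_lt(rel, 5e-3)
  }
})

test_that("feature tables concatenate cA and cD per segment in order", {
  set.seed(34)
  segs <- lapply(1:60, function(i) make_segment(rnorm(50), i %% 3))
  ft <- build_feature_table(segs, "haar", padding = "none")
  expect_identical(dim(ft$features), c(60L, 50L))
  expect_identical(ft$labels, vapply(segs, function(s) s$label, integer(1)))

  # dmey with symmetric padding: 2 * floor((50 + 61) / 2) = 110 features
  ftd <- build_feature_table(segs, "dmey")
  expect_identical(ncol(ftd$features), 110L)
  expect_identical(colnames(ftd$features)[1], "f0")

  # identical segments -> identical rows
  twins <- list(make_segment(segs[[1]]$values), make_segment(segs[[1]]$values))
  ft2 <- build_feature_table(twins, "db4")
  expect_identical(ft2$features[1, ], ft2$features[2, ])

  empty <- build_feature_table(list(), "haar")
  expect_identical(nrow(empty$features), 0L)
  expect_error(build_feature_table(list(make_segment(rnorm(50)),
                                        make_segment(rnorm(48))), "haar"),
               "same length")
})
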
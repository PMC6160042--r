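test_that("periodic symlet analysis matches the frozen external reference", {
  # helper-frozen-wavelet.R holds coefficients computed independently with
  # PyWavelets (sym10, periodization) for fixed random inputs.
  mine <- dwt1_features(pywt_x16)
  expect_equal(unname(mine), pywt_flat, tolerance = 1e-12)

  h <- wavelet_filter(10)
  lv <- faimspipe:::.dwt2_pyramid(pywt_X8, h)$levels[[1L]]
  expect_equal(lv$LL, pywt_cA, tolerance = 1e-12)
  expect_equal(lv$LH, pywt_cV, tolerance = 1e-12)
  expect_equal(lv$HL, pywt_cH, tolerance = 1e-12)
  expect_equal(lv$HH, pywt_cD, tolerance = 1e-12)
})

test_that("reshape_to_grid inverts the linearisation layout", {
  v <- linearise(toy_run())
  expect_equal(reshape_to_grid(v),
               matrix(c(1, 2, 5, 6, 3, 4, 7, 8), 2, byrow = TRUE))
  withr::with_seed(3, {
    run <- random_run("R", 1L, rows = 16L, cols = 7L)
  })
  g <- reshape_to_grid(linearise(run))
  expect_equal(g[, 1:7], unclass(run$positive), ignore_attr = TRUE)
  expect_equal(g[, 8:14], unclass(run$negative), ignore_attr = TRUE)
  expect_error(reshape_to_grid(1:7, rows = 2, cols = 2), "length")
})

test_that("crop_and_pad retains the window and zero-pads to a dyadic square", {
  g <- matrix(1, 512, 102)
  sq <- crop_and_pad(g, wavelet_spec(crop_rows = 512))
  expect_equal(dim(sq), c(512L, 512L))
  expect_true(all(sq[, 1:102] == 1))
  expect_true(all(sq[, 103:512] == 0))

  sq128 <- crop_and_pad(g, wavelet_spec(crop_rows = 128))
  expect_equal(dim(sq128), c(128L, 128L))
  expect_true(all(sq128[, 1:102] == 1) && all(sq128[, 103:128] == 0))

  off <- crop_and_pad(matrix(1:8, 8, 4),   # row i holds the value i
                      wavelet_spec(crop_rows = 4, crop_offset = 2))
  expect_equal(off[1:4, 1:4], matrix(3:6, 4, 4))

  expect_error(crop_and_pad(g, wavelet_spec(crop_rows = 512, crop_offset = 1)),
               "window")
  expect_true(all(crop_and_pad(matrix(0, 128, 102),
                               wavelet_spec(crop_rows = 128)) == 0))
})

test_that("2D feature count follows the closed form at every depth", {
  for (L in 1:6) {
    n_feat <- length(dwt2_features(matrix(rnorm(4^L), 2^L)))
    expect_identical(n_feat, as.integer(4 * (4^L - 1) / 3 + 1))
  }
  expect_length(dwt2_features(matrix(0, 2, 2)), 5L)
  expect_true(all(dwt2_features(matrix(0, 16, 16)) == 0))
  expect_error(dwt2_features(matrix(0, 4, 6)), "square")
  expect_error(dwt2_features(matrix(0, 6, 6)), "power of two")
})

test_that("the transform conserves energy, reconstructs, and is linear", {
  withr::with_seed(11, {
    for (side in c(8L, 16L, 32L)) {
      M <- matrix(rnorm(side^2), side)
      co <- dwt2_features(M)
      pyr <- faimspipe:::.dwt2_unflatten(co)
      energy <- sum(unlist(lapply(pyr$levels,
                                  function(l) c(l$LH, l$HL, l$HH)))^2) +
        pyr$smooth[1L, 1L]^2
      expect_equal(energy, sum(M^2), tolerance = 1e-10)
      expect_equal(idwt2(co), M, tolerance = 1e-10)
    }
    # linearity
    A <- matrix(rnorm(256), 16); B <- matrix(rnorm(256), 16)
    expect_equal(dwt2_features(2 * A - 3 * B),
                 2 * dwt2_features(A) - 3 * dwt2_features(B),
                 tolerance = 1e-10)
    # 1D perfect reconstruction of the padded input
    v <- rnorm(100)
    rec <- idwt1(dwt1_features(v))
    expect_equal(rec[1:100], v, tolerance = 1e-10)
    expect_equal(rec[101:128], rep(0, 28), tolerance = 1e-10)
  })
  expect_length(dwt1_features(rnorm(52224 / 16)), 4096L)  # pads to 2^J
  expect_true(all(dwt1_features(numeric(16)) == 0))
  expect_error(dwt1_features(numeric(0)), "empty")
})

test_that("feature support maps coefficients back to their region", {
  spec <- wavelet_spec(crop_rows = 32, vanishing_moments = 4)
  M <- matrix(0, 32, 32)
  M[9:12, 17:20] <- 1        # a compact bump
  co <- dwt2_features(M, spec)
  det <- co[!grepl("_LL_", names(co)) & names(co) != "W2_s"]
  top <- names(which.max(abs(det)))
  sup <- dwt2_feature_support(top, 32, spec)
  # the strongest detail coefficient's support must cover the bump
  expect_lte(sup$row_lo, 12)
  expect_gte(sup$row_hi, 9)
  expect_lte(sup$col_lo, 20)
  expect_gte(sup$col_hi, 17)
  # a redundant smooth-track coefficient has a well-defined support too
  sup2 <- dwt2_feature_support("W2_j3_LL_r3_c5", 32, spec)
  expect_true(sup2$row_lo >= 1 && sup2$row_hi <= 32)
  expect_identical(dwt2_feature_support("W2_s", 32, spec)$row_hi, 32L)
})

test_that("wavelet_table transforms every sample of a raw table", {
  fx <- small_cohort()
  tab <- build_table(fx$cohort$runs, 2L)
  spec <- wavelet_spec(crop_rows = 64)
  wt <- wavelet_table(tab, spec)
  expect_identical(attr(wt, "provenance"), "dwt2")
  expect_equal(nrow(wt), 20L)
  expect_equal(ncol(wt), as.integer(4 * (4^6 - 1) / 3 + 1))  # 64x64 depth 6
  # row 1 of the table equals a direct single-sample transform
  g <- reshape_to_grid(ft_values(tab)[1L, ], rows = 64, cols = 12)
  expect_equal(unname(ft_values(wt)[1L, ]),
               unname(dwt2_features(crop_and_pad(g, spec), spec)))
  # 1D mode matches per-sample transforms as well
  w1 <- wavelet_table(tab, wavelet_spec(mode = "dwt1"))
  expect_identical(attr(w1, "provenance"), "dwt1")
  expect_equal(unname(ft_values(w1)[1L, ]),
               unname(dwt1_features(ft_values(tab)[1L, ])))
  # mode none passes through
  expect_identical(wavelet_table(tab, wavelet_spec(mode = "none")), tab)
})
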
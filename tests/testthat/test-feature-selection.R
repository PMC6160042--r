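test_that("rank-sum p-values match exhaustive enumeration", {
  # hand-enumerable cases: C(4,2) = 6 rank assignments
  expect_equal(ranksum_p(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(ranksum_p(c(1, 4), c(2, 3)), 1)
  expect_equal(ranksum_p(c(3, 4), c(1, 2)), ranksum_p(c(1, 2), c(3, 4)))
  # random tie-free draws across small group sizes vs the enumeration oracle
  withr::with_seed(21, {
    for (na in c(2L, 3L, 5L)) {
      for (nb in c(2L, 4L, 6L)) {
        a <- rnorm(na); b <- rnorm(nb)
        expect_equal(ranksum_p(a, b), ranksum_enum(a, b), tolerance = 1e-12,
                     label = sprintf("exact p (na=%d, nb=%d)", na, nb))
      }
    }
  })
  expect_error(ranksum_p(numeric(0), 1), "non-empty")
})

test_that("large groups use the tie-corrected normal approximation", {
  withr::with_seed(22, {
    a <- round(rnorm(30), 1); b <- round(rnorm(28, 0.3), 1)  # ties likely
  })
  expect_equal(ranksum_p(a, b),
               stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
  # the vectorised per-feature screen agrees with the scalar version
  withr::with_seed(23, {
    X <- matrix(rnorm(60 * 50), 60)
    X[, 1:10] <- round(X[, 1:10], 1)
  })
  colnames(X) <- paste0("f", 1:50); rownames(X) <- paste0("s", 1:60)
  is_case <- rep(c(TRUE, FALSE), 30)
  pv <- faimspipe:::.ranksum_p_cols(X, is_case)
  pref <- apply(X, 2L, function(col) ranksum_p(col[is_case], col[!is_case]))
  expect_equal(unname(pv), unname(pref), tolerance = 1e-12)
})

test_that("sd_exclude retains exactly the above-threshold features", {
  X <- cbind(flat = rep(2, 6), spread = c(1, 2, 3, 4, 5, 6) / sd(1:6))
  rownames(X) <- paste0("s", 1:6)
  expect_identical(sd_exclude(X, 0), "spread")          # sd {0, 1} at sigma 0
  expect_identical(sd_exclude(X, 0.5), "spread")        # sd 1 > 0.5 retained
  expect_error(sd_exclude(X, 1.5), "lower")             # everything excluded
  expect_error(sd_exclude(X[1L, , drop = FALSE], 0), "2 samples")
})

test_that("filter_select keeps the lowest-p features with index tie-break", {
  withr::with_seed(30, {
    labels <- rep(c("case", "control"), each = 8L)
    X <- matrix(rnorm(16 * 5), 16)
    X[labels == "case", 4L] <- X[labels == "case", 4L] + 3   # strong feature
    X[labels == "case", 2L] <- X[labels == "case", 2L] + 1.2 # weaker one
  })
  dimnames(X) <- list(paste0("s", 1:16), paste0("f", 1:5))
  is_case <- labels == "case"
  p_oracle <- apply(X, 2L, function(col) ranksum_enum(col[is_case], col[!is_case]))
  sel <- filter_select(X, labels, nkeep = 2L)
  expect_identical(as.vector(sel), names(sort(p_oracle))[1:2])
  expect_equal(attr(sel, "p_value"), unname(sort(p_oracle))[1:2],
               tolerance = 1e-12)
  # nkeep >= feature count returns everything
  expect_setequal(as.vector(filter_select(X, labels, nkeep = 99L)),
                  colnames(X))
  # permuting columns selects the same feature set
  perm <- c(3L, 5L, 1L, 4L, 2L)
  expect_setequal(as.vector(filter_select(X[, perm], labels, nkeep = 2L)),
                  as.vector(sel))
  expect_error(filter_select(X, rep("case", 16L), 2L), "single class")
})

test_that("minimum filter p-value is calibrated against the Sidak form", {
  # with m independent null features, P(min p <= q) should be 1 - (1-q)^m
  m <- 15L; n_rep <- 150L; q <- 0.1
  withr::with_seed(31, {
    hits <- replicate(n_rep, {
      X <- matrix(rnorm(24 * m), 24)
      dimnames(X) <- list(paste0("s", 1:24), paste0("f", seq_len(m)))
      labels <- sample(rep(c("case", "control"), each = 12L))
      sel <- filter_select(X, labels, nkeep = 1L)
      attr(sel, "p_value") <= q
    })
  })
  expected <- 1 - (1 - q)^m
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_lt(abs(mean(hits) - expected), 4 * se + 0.02)
})

test_that("pca_reduce honours the variance threshold and training centring", {
  # collinear data: one true direction, but two components are always kept
  withr::with_seed(32, {
    t_tr <- rnorm(20); t_te <- rnorm(8)
  })
  line <- function(t) cbind(f1 = t, f2 = 2 * t, f3 = -t)
  tr <- line(t_tr); te <- line(t_te)
  rownames(tr) <- paste0("a", 1:20); rownames(te) <- paste0("b", 1:8)
  red <- pca_reduce(tr, te, selection_spec(use_pca = TRUE))
  expect_identical(colnames(red$train), c("PC1", "PC2"))
  expect_equal(unname(colMeans(ft_values(red$train))), c(0, 0),
               tolerance = 1e-12)

  # near-isotropic data needs all three components for 95%
  withr::with_seed(33, {
    iso <- matrix(rnorm(3000), 1000)
  })
  dimnames(iso) <- list(paste0("s", 1:1000), paste0("f", 1:3))
  ev <- eigen(stats::cov(iso))$values           # independent eigen oracle
  expect_lt(sum(ev[1:2]) / sum(ev), 0.95)
  red2 <- pca_reduce(iso[1:900, ], iso[901:1000, ],
                     selection_spec(use_pca = TRUE))
  expect_identical(ncol(ft_values(red2$train)), 3L)

  # test scores use training centring and loadings
  ctr <- colMeans(tr)
  rot <- stats::prcomp(tr)$rotation[, 1:2]
  manual <- scale(te, center = ctr, scale = FALSE) %*% rot
  expect_equal(abs(unname(ft_values(red$test))), abs(unname(manual)),
               tolerance = 1e-9)

  # retaining every component preserves pairwise distances
  withr::with_seed(34, {
    Y <- matrix(rnorm(60), 12, 5,
                dimnames = list(paste0("s", 1:12), paste0("f", 1:5)))
  })
  redY <- pca_reduce(Y, Y, selection_spec(use_pca = TRUE,
                                          pca_var_threshold = 1))
  expect_equal(as.matrix(dist(ft_values(redY$train))), as.matrix(dist(Y)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("stepwise search keeps informative features, drops collinear ones", {
  withr::with_seed(35, {
    n <- 80L
    labels <- rep(c("case", "control"), each = n / 2L)
    X <- matrix(rnorm(n * 8L), n)
    X[labels == "case", 3L] <- X[labels == "case", 3L] + 1.6
  })
  dimnames(X) <- list(sprintf("s%02d", 1:n), paste0("f", 1:8))
  sel <- suppressWarnings(
    stepwise_select(X, labels, selection_spec(method = "wrapper"), seed = 5L))
  expect_true("f3" %in% sel)

  # exhaustive best-subset AIC oracle also contains the planted feature
  y <- as.integer(labels == "case")
  best_aic <- Inf; best_set <- NULL
  for (k in 1:3) {
    for (set in utils::combn(8L, k, simplify = FALSE)) {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X[, set, drop = FALSE]), y,
                       family = stats::binomial()))
      aic <- fit$deviance + 2 * fit$rank
      if (aic < best_aic) { best_aic <- aic; best_set <- set }
    }
  }
  expect_true(3L %in% best_set)

  # an exact duplicate of a selected feature is never co-selected
  Xd <- cbind(X, f3copy = X[, 3L])
  seld <- suppressWarnings(
    stepwise_select(Xd, labels, selection_spec(method = "wrapper"), seed = 5L))
  expect_false(all(c("f3", "f3copy") %in% seld))
  expect_true(any(c("f3", "f3copy") %in% seld))

  expect_error(stepwise_select(X, labels,
                               selection_spec(method = "wrapper",
                                              wrapper_n_start = 0L)),
               "at least one")
})

test_that("stepwise search agrees with an established stepwise-AIC oracle", {
  withr::with_seed(36, {
    n <- 60L
    labels <- rep(c("case", "control"), each = n / 2L)
    X <- matrix(rnorm(n * 6L), n)
    X[labels == "case", 2L] <- X[labels == "case", 2L] + 1.4
  })
  dimnames(X) <- list(sprintf("s%02d", 1:n), paste0("f", 1:6))
  spec <- selection_spec(method = "wrapper", wrapper_n_start = 3L)
  mine <- suppressWarnings(stepwise_select(X, labels, spec, seed = 9L))

  start_idx <- sort(withr::with_seed(9L, sample.int(6L, 3L)))
  df <- data.frame(y = as.integer(labels == "case"), X)
  start_fml <- stats::reformulate(paste0("f", start_idx), "y")
  fit0 <- stats::glm(start_fml, stats::binomial, df)
  ref <- MASS::stepAIC(fit0, scope = list(
    lower = y ~ 1, upper = stats::reformulate(paste0("f", 1:6), "y")),
    direction = "both", trace = 0)
  expect_setequal(mine, attr(stats::terms(ref), "term.labels"))
})
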
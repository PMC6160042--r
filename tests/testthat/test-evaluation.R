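test_that("auc equals direct case-control pair counting", {
  expect_equal(auc(c("control", "control", "case", "case"),
                   c(0.1, 0.4, 0.3, 0.8)), 0.75)
  expect_equal(auc(rep(c("case", "control"), each = 5),
                   c(rep(1, 5), rep(0, 5))), 1)
  expect_equal(auc(rep(c("case", "control"), 5), rep(0.3, 10)), 0.5)
  withr::with_seed(50, {
    for (i in 1:30) {
      n <- sample(10:60, 1)
      labels <- sample(rep_len(c("case", "control"), n))
      p <- round(runif(n), sample(c(1, 2, 7), 1))  # some tie-rich cases
      expect_equal(auc(labels, p), auc_paircount(labels, p),
                   tolerance = 1e-12)
    }
    # complement property for tie-free scores
    p <- runif(40); labels <- sample(rep(c("case", "control"), 20))
    expect_equal(auc(labels, p) + auc(labels, -p), 1, tolerance = 1e-12)
  })
  expect_error(auc(rep("case", 4), runif(4)), "both classes")
})

test_that("auc and roc points agree with an established ROC implementation", {
  withr::with_seed(55, {
    labels <- sample(rep(c("case", "control"), c(26, 34)))
    p <- round(runif(60), 2)
  })
  ref <- suppressMessages(pROC::roc(response = labels, predictor = p,
                                    levels = c("control", "case"),
                                    direction = "<"))
  expect_equal(auc(labels, p), as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  # operating points match pROC's coordinates at every threshold
  rp <- roc_points(labels, p)
  co <- pROC::coords(ref, x = "all", transpose = FALSE)
  expect_equal(sort(rp$sensitivity), sort(co$sensitivity), tolerance = 1e-12)
  expect_equal(sort(rp$specificity), sort(co$specificity), tolerance = 1e-12)
})

test_that("bootstrap CI is seeded and degenerates correctly", {
  labels <- rep(c("case", "control"), each = 10)
  sep <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  expect_equal(bootstrap_ci(labels, sep, 200, seed = 1), c(1, 1))
  expect_equal(bootstrap_ci(labels, rep(0.4, 20), 200, seed = 1), c(0.5, 0.5))
  withr::with_seed(51, {
    p <- runif(20)
  })
  ci_a <- bootstrap_ci(labels, p, 500, seed = 7)
  expect_identical(ci_a, bootstrap_ci(labels, p, 500, seed = 7))
  # nested confidence levels give nested percentile intervals
  ci90 <- bootstrap_ci(labels, p, 500, seed = 7, conf = 0.90)
  expect_lte(ci_a[1], ci90[1])
  expect_gte(ci_a[2], ci90[2])
})

test_that("balance threshold maximises the Youden criterion", {
  # criterion is algebraically 2*(SE+SP-1)^2
  se <- runif(25); sp <- runif(25)
  expect_equal((se - 1 + sp)^2 + (sp - 1 + se)^2, 2 * (se + sp - 1)^2,
               tolerance = 1e-12)

  # constructed operating points exactly {(1,0), (0.8,0.9), (0,1)}
  labels <- rep(c("case", "control"), each = 10)
  p <- c(rep(0.8, 8), rep(0.1, 2), rep(0.1, 9), 0.8)
  bt <- balance_threshold(labels, p)
  expect_equal(bt$sensitivity, 0.8)
  expect_equal(bt$specificity, 0.9)

  # perfect separation reaches SE = SP = 1
  bt2 <- balance_threshold(labels, c(runif(10, 0.6, 1), runif(10, 0, 0.4)))
  expect_equal(bt2$sensitivity, 1)
  expect_equal(bt2$specificity, 1)

  # agreement with the exhaustive Youden scan on random instances
  withr::with_seed(52, {
    for (i in 1:30) {
      n <- sample(8:40, 1)
      labels_i <- sample(rep_len(c("case", "control"), n))
      p_i <- round(runif(n), 2)
      bt_i <- balance_threshold(labels_i, p_i)
      expect_equal(abs(bt_i$sensitivity + bt_i$specificity - 1),
                   youden_best(labels_i, p_i), tolerance = 1e-12)
    }
  })

  # symmetric tie: (0.9, 0.8) and (0.8, 0.9) share the criterion value;
  # the documented tie-break picks the higher-specificity point
  lab <- rep(c("case", "control"), each = 10)
  pt <- c(rep(0.9, 8), 0.4, 0.4, rep(0.1, 8), 0.6, 0.6)
  btt <- balance_threshold(lab, pt)
  expect_gte(btt$specificity, btt$sensitivity)
})

test_that("binomial CI matches Clopper-Pearson closed forms", {
  for (n in c(5L, 20L, 43L)) {
    ci0 <- binomial_ci(0L, n)
    expect_equal(ci0[1], 0)
    expect_equal(ci0[2], 1 - 0.025^(1 / n), tolerance = 1e-9)
    cin <- binomial_ci(n, n)
    expect_equal(cin[2], 1)
    expect_equal(cin[1], 0.025^(1 / n), tolerance = 1e-9)
  }
  ci <- binomial_ci(13L, 40L)
  expect_true(ci[1] <= 13 / 40 && 13 / 40 <= ci[2])
  expect_error(binomial_ci(2L, 0L), ">= 1")
  expect_error(binomial_ci(5L, 3L), "between")
})

test_that("roc_summary assembles consistent components", {
  withr::with_seed(53, {
    labels <- rep(c("case", "control"), c(12, 15))
    p <- plogis(rnorm(27, ifelse(labels == "case", 1, -1)))
  })
  s <- roc_summary(labels, p, n_boot = 300, seed = 2)
  expect_equal(s$auc, auc(labels, p))
  expect_true(s$auc_ci[1] <= s$auc && s$auc <= s$auc_ci[2])
  expect_true(s$sensitivity_ci[1] <= s$sensitivity &&
                s$sensitivity <= s$sensitivity_ci[2])
  expect_true(s$specificity_ci[1] <= s$specificity &&
                s$specificity <= s$specificity_ci[2])
  expect_identical(s$n_boot, 300)
  expect_output(print(s), "AUC")
})

test_that("demographic AUC reports orientation-corrected values", {
  labels <- rep(c("case", "control"), each = 8)
  high_in_case <- c(rnorm(8, 5), rnorm(8, 0))
  s1 <- demographic_auc(high_in_case, labels, n_boot = 100, seed = 1)
  expect_equal(s1$auc, auc(labels, high_in_case))
  expect_false(attr(s1, "flipped"))

  low_in_case <- -high_in_case
  expect_message(
    s2 <- demographic_auc(low_in_case, labels, n_boot = 100, seed = 1),
    "flipped")
  expect_true(attr(s2, "flipped"))
  expect_equal(s2$auc, max(auc(labels, low_in_case),
                           1 - auc(labels, low_in_case)))

  expect_warning(s3 <- demographic_auc(rep(1, 16), labels, n_boot = 50),
                 "constant")
  expect_equal(s3$auc, 0.5)

  # covariate identical to the label indicator is a perfect biomarker
  s4 <- demographic_auc(as.numeric(labels == "case"), labels, n_boot = 50,
                        seed = 1)
  expect_equal(s4$auc, 1)
})

test_that("compare_predictions is a symmetric rank-sum comparison", {
  expect_equal(compare_predictions(c(0.1, 0.2), c(0.8, 0.9)), 1 / 3)
  expect_equal(compare_predictions(c(0.8, 0.9), c(0.1, 0.2)), 1 / 3)
  same <- c(0.2, 0.5, 0.8)
  expect_equal(compare_predictions(same, same + 0), 1)
  ps <- prediction_set(c("a", "b"), c(0.1, 0.2), c(1L, 2L),
                       c("case", "control"), "slr")
  expect_equal(compare_predictions(ps, c(0.8, 0.9)), 1 / 3)
  expect_error(compare_predictions(numeric(0), c(0.5)), "empty")
})
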
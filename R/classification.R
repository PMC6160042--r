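# The five reference classifiers and the stratified 10-fold cross-validation
# harness.  All data-dependent selection (SD exclusion, filter/wrapper
# screening, PCA) happens strictly inside each fold on training rows only.

.model_kinds <- c("random_forest", "sparse_logistic", "svm_rbf",
                  "neural_net", "gaussian_process")

#' Classifier configuration
#'
#' Hyperparameter defaults follow the pipeline's reference settings:
#' random forest with 500 trees and per-feature importance; lasso-penalised
#' logistic regression with the penalty weight chosen by inner
#' cross-validated deviance; RBF-kernel SVM with kernel
#' `k(x, y) = exp(-sigma * ||x - y||^2)`, `sigma = 0.05`, cost 5 and Platt
#' probability calibration; a one-hidden-unit neural network trained by
#' resilient backpropagation with weight backtracking; and a binary Gaussian
#' process classifier on unscaled inputs with termination tolerance 0.01.
#'
#' @param kind One of `random_forest`, `sparse_logistic`, `svm_rbf`,
#'   `neural_net`, `gaussian_process`.
#' @param ... Hyperparameter overrides for the chosen kind.
#' @return A `model_spec` object.
#' @export
model_spec <- function(kind = .model_kinds, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    random_forest = list(ntree = 500L, importance = TRUE),
    sparse_logistic = list(alpha = 1, nfolds = 10L),
    svm_rbf = list(sigma = 0.05, C = 5, cross = 3L),
    neural_net = list(hidden = 1L, threshold = 0.01, stepmax = 10000L),
    gaussian_process = list(scaled = FALSE, tol = 0.01))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown ", kind, " hyperparameter(s): ",
         paste(unknown, collapse = ", "))
  }
  structure(list(kind = kind, params = utils::modifyList(defaults, over)),
            class = "model_spec")
}

#' The five default classifiers
#'
#' @return Named list of [model_spec()]s, one per classifier kind.
#' @export
default_models <- function() {
  stats::setNames(lapply(.model_kinds, model_spec), .model_kinds)
}

#' Cross-validation configuration
#'
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and all stochastic
#'   model fitting.
#' @param stratified Stratify folds by class (default TRUE).
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(k = 10L, seed = 1L, stratified = TRUE) {
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "cv_spec")
}

#' Stratified fold assignment
#'
#' Partitions samples into `k` near-equal folds.  Under stratification the
#' shuffled cases are dealt round-robin across folds, then the shuffled
#' controls continue the deal, so both total fold sizes and per-fold class
#' counts are within one sample of balance (115 samples in 10 folds give
#' training sets of exactly 103 or 104).  If any fold would leave a
#' single-class training set the draw is retried with a logged message.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify by class (default TRUE).
#' @return Integer vector of fold indices (1..k), one per sample.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  labels <- as_class_labels(labels)
  n <- length(labels)
  if (k < 2L || k > n) stop("k must be between 2 and the sample count")
  for (try in 0:4) {
    ord <- withr::with_seed(seed + try, {
      if (stratified) {
        c(sample(which(labels == "case")), sample(which(labels == "control")))
      } else {
        sample.int(n)
      }
    })
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[folds != f])) == 2L
    }, logical(1)))
    if (ok) {
      if (try > 0L) message("make_folds: redrew folds ", try, " time(s)")
      return(folds)
    }
  }
  stop("could not draw folds leaving both classes in every training set")
}

# ---- individual classifiers ------------------------------------------------

.fit_random_forest <- function(params, xtr, ytr, xte) {
  fit <- randomForest::randomForest(x = xtr, y = ytr, ntree = params$ntree,
                                    importance = params$importance)
  stats::predict(fit, xte, type = "prob")[, "case"]
}

.fit_sparse_logistic <- function(params, xtr, ytr, xte) {
  if (ncol(xtr) >= 2L) {
    nf <- max(3L, min(params$nfolds, nrow(xtr)))
    fit <- glmnet::cv.glmnet(xtr, ytr, family = "binomial",
                             alpha = params$alpha, nfolds = nf,
                             type.measure = "deviance")
    as.vector(stats::predict(fit, xte, s = "lambda.min", type = "response"))
  } else {
    # the lasso path needs >= 2 columns; a single screened feature gets a
    # plain logistic fit instead
    df <- data.frame(y = ytr, x = xtr[, 1L])
    fit <- suppressWarnings(stats::glm(y ~ x, stats::binomial, df))
    as.vector(stats::predict(fit, data.frame(x = xte[, 1L]),
                             type = "response"))
  }
}

.fit_svm_rbf <- function(params, xtr, ytr, xte) {
  fit <- kernlab::ksvm(xtr, ytr, kernel = "rbfdot",
                       kpar = list(sigma = params$sigma), C = params$C,
                       prob.model = TRUE, cross = params$cross)
  kernlab::predict(fit, xte, type = "probabilities")[, "case"]
}

.fit_gaussian_process <- function(params, xtr, ytr, xte) {
  # kernlab's automatic sigma estimation prints to stdout; keep fits quiet
  utils::capture.output(
    fit <- kernlab::gausspr(xtr, ytr, type = "classification",
                            scaled = params$scaled, tol = params$tol))
  kernlab::predict(fit, xte, type = "probabilities")[, "case"]
}

# Resilient backpropagation (RPROP+ with weight backtracking) for a
# one-hidden-layer logistic MLP trained on cross-entropy.  Converges when
# the largest absolute loss gradient drops below `threshold`; if the
# iteration cap is hit first the caller falls back to predicting the
# training prevalence.
.fit_rprop_net <- function(params, xtr, ytr, xte) {
  y <- as.numeric(ytr == "case")
  n <- nrow(xtr); p <- ncol(xtr); hdn <- params$hidden
  sigmoid <- function(z) 1 / (1 + exp(-z))
  n_w <- (p + 1L) * hdn + hdn + 1L
  w <- stats::rnorm(n_w, sd = 0.7)
  unpack <- function(w) {
    W1 <- matrix(w[seq_len(p * hdn)], p, hdn)
    b1 <- w[p * hdn + seq_len(hdn)]
    W2 <- w[(p + 1L) * hdn + seq_len(hdn)]
    b2 <- w[n_w]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  grad <- function(w) {
    pr <- unpack(w)
    z1 <- sweep(xtr %*% pr$W1, 2L, pr$b1, "+")
    a1 <- sigmoid(z1)
    ph <- sigmoid(as.vector(a1 %*% pr$W2) + pr$b2)
    d2 <- ph - y
    gW2 <- as.vector(crossprod(a1, d2))
    gb2 <- sum(d2)
    d1 <- (d2 %o% pr$W2) * a1 * (1 - a1)
    c(as.vector(crossprod(xtr, d1)), colSums(d1), gW2, gb2)
  }
  delta <- rep(0.1, n_w)
  g_prev <- numeric(n_w)
  dw_prev <- numeric(n_w)
  converged <- FALSE
  for (iter in seq_len(params$stepmax)) {
    g <- grad(w)
    if (any(!is.finite(g))) break
    if (max(abs(g)) < params$threshold) { converged <- TRUE; break }
    s <- sign(g) * sign(g_prev)
    up <- s > 0; down <- s < 0
    delta[up] <- pmin(delta[up] * 1.2, 50)
    delta[down] <- pmax(delta[down] * 0.5, 1e-6)
    dw <- -sign(g) * delta
    dw[down] <- -dw_prev[down]       # weight backtracking
    g[down] <- 0
    w <- w + dw
    g_prev <- g
    dw_prev <- dw
  }
  if (!converged) {
    warning("neural net did not converge; predicting training prevalence")
    return(rep(mean(y), nrow(xte)))
  }
  pr <- unpack(w)
  a1 <- sigmoid(sweep(xte %*% pr$W1, 2L, pr$b1, "+"))
  as.vector(sigmoid(as.vector(a1 %*% pr$W2) + pr$b2))
}

#' Fit one classifier and predict case probabilities
#'
#' @param spec A [model_spec()].
#' @param train_x,test_x Numeric feature matrices with matching columns.
#' @param train_y Training class labels (both classes must be present).
#' @return Numeric vector of case probabilities for the test rows,
#'   clipped to \\[0, 1\\].
#' @export
fit_predict <- function(spec, train_x, train_y, test_x) {
  stopifnot(inherits(spec, "model_spec"))
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (ncol(train_x) < 1L) stop("need at least one feature")
  if (!all(is.finite(train_x)) || !all(is.finite(test_x))) {
    stop("non-finite feature values")
  }
  train_y <- as_class_labels(train_y)
  if (length(unique(train_y)) < 2L) {
    stop("training labels contain a single class")
  }
  fn <- switch(spec$kind,
               random_forest = .fit_random_forest,
               sparse_logistic = .fit_sparse_logistic,
               svm_rbf = .fit_svm_rbf,
               neural_net = .fit_rprop_net,
               gaussian_process = .fit_gaussian_process)
  pmin(pmax(as.vector(fn(spec$params, train_x, train_y, test_x)), 0), 1)
}

#' Out-of-fold prediction container
#'
#' @param sample_id Sample identifiers.
#' @param probability Out-of-fold case probabilities in \\[0, 1\\].
#' @param fold Fold index in which each sample was held out.
#' @param label Observed class labels.
#' @param model Classifier kind that produced the probabilities.
#' @return A `prediction_set` data frame (columns `sample_id`,
#'   `probability`, `fold`, `label`) with a `model` attribute.
#' @export
prediction_set <- function(sample_id, probability, fold, label, model) {
  if (anyNA(probability) || any(probability < 0 | probability > 1)) {
    stop("probabilities must be in [0, 1] with every sample predicted once")
  }
  structure(data.frame(sample_id = as.character(sample_id),
                       probability = probability, fold = as.integer(fold),
                       label = as_class_labels(label)),
            model = model, class = c("prediction_set", "data.frame"))
}

#' Cross-validated out-of-fold predictions for a set of classifiers
#'
#' Partitions the samples into stratified folds, then within each fold (on
#' training rows only) applies SD exclusion, the configured feature
#' selection (filter / wrapper / embedded), optionally PCA, and fits every
#' classifier, collecting held-out case probabilities so each sample is
#' predicted exactly once.  When `use_pca` is set, the filter cap is the
#' training-set size before components are taken.
#'
#' @param table A [feature_table()] of all samples.
#' @param labels Class labels for the rows.
#' @param models Named list of [model_spec()]s (default all five).
#' @param selection A [selection_spec()].
#' @param cv A [cv_spec()].
#' @param always_include Optional [feature_table()] of covariates (e.g. the
#'   four demographics) appended to the selected features in every fold,
#'   exempt from selection.
#' @return Named list of [prediction_set()]s, one per model, with a
#'   `selection` attribute (data frame of per-fold selected features and
#'   p-values) and a `folds` attribute.
#' @export
cross_validate <- function(table, labels, models = default_models(),
                           selection = selection_spec(), cv = cv_spec(),
                           always_include = NULL) {
  labels <- as_class_labels(labels)
  X <- ft_values(table)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  if (anyNA(labels)) stop("all samples must be labelled")
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$kind, character(1))
  }
  folds <- make_folds(labels, cv$k, cv$seed, cv$stratified)
  extra <- NULL
  if (!is.null(always_include)) {
    extra <- ft_values(always_include)
    if (!identical(rownames(extra), rownames(X))) {
      extra <- extra[rownames(X), , drop = FALSE]
    }
  }
  prob <- matrix(NA_real_, n, length(models),
                 dimnames = list(rownames(X), names(models)))
  sel_report <- vector("list", cv$k)
  for (f in seq_len(cv$k)) {
    withr::with_seed(cv$seed + 7919L * f, {
      tr <- folds != f
      ltr <- labels[tr]
      keep <- sd_exclude(X[tr, , drop = FALSE], selection$sigma)
      Xtr_all <- X[tr, keep, drop = FALSE]
      pvals <- NULL
      ids <- switch(selection$method,
        filter = {
          nk <- if (selection$use_pca) min(sum(tr), length(keep)) else selection$nkeep
          sel <- filter_select(Xtr_all, ltr, nk)
          pvals <- attr(sel, "p_value")
          as.vector(sel)
        },
        wrapper = stepwise_select(Xtr_all, ltr, selection,
                                  seed = cv$seed + 7919L * f),
        embedded = keep)
      xtr <- Xtr_all[, ids, drop = FALSE]
      xte <- X[!tr, ids, drop = FALSE]
      if (selection$use_pca) {
        red <- pca_reduce(xtr, xte, selection)
        xtr <- ft_values(red$train)
        xte <- ft_values(red$test)
      }
      if (!is.null(extra)) {
        xtr <- cbind(xtr, extra[tr, , drop = FALSE])
        xte <- cbind(xte, extra[!tr, , drop = FALSE])
      }
      for (m in names(models)) {
        prob[!tr, m] <- fit_predict(models[[m]], xtr, ltr, xte)
      }
      sel_report[[f]] <- data.frame(
        fold = f, feature_id = ids,
        p_value = if (is.null(pvals)) NA_real_ else pvals)
    })
  }
  out <- lapply(names(models), function(m) {
    prediction_set(rownames(X), prob[, m], folds, labels, m)
  })
  names(out) <- names(models)
  attr(out, "selection") <- do.call(rbind, sel_report)
  attr(out, "folds") <- folds
  out
}

#' Average prediction probabilities across runs
#'
#' The probability ensemble: per-sample arithmetic mean of the case
#' probabilities predicted separately for each FAIMS run of the same
#' specimens.
#'
#' @param per_run List of [prediction_set()]s for the same samples and the
#'   same model.
#' @return A [prediction_set()] with averaged probabilities (fold indices
#'   are taken from the first set).
#' @export
probability_ensemble <- function(per_run) {
  if (!is.list(per_run) || length(per_run) < 2L) {
    stop("probability_ensemble needs at least two prediction sets")
  }
  ref <- per_run[[1L]]
  for (ps in per_run[-1L]) {
    if (!identical(ps$sample_id, ref$sample_id)) {
      stop("prediction sets are not aligned on sample_id")
    }
    if (!identical(attr(ps, "model"), attr(ref, "model"))) {
      stop("prediction sets come from different models")
    }
  }
  pm <- rowMeans(do.call(cbind, lapply(per_run, function(ps) ps$probability)))
  prediction_set(ref$sample_id, pm, ref$fold, ref$label, attr(ref, "model"))
}
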
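# Feature exclusion and selection: standard-deviation pre-filter, Wilcoxon
# rank-sum filter selection, PCA reduction and the stepwise-AIC wrapper
# comparison mode.  All data-dependent selection is meant to run inside
# cross-validation folds (see cross_validate()).

#' Feature-selection configuration
#'
#' @param sigma Standard-deviation exclusion threshold; features with sample
#'   SD not exceeding `sigma` are dropped before selection.  The default 0
#'   removes exactly the zero-variance features produced by zero-padding.
#' @param nkeep Number of lowest-p features kept by the filter method
#'   (default 2).
#' @param method `"filter"` (Wilcoxon rank-sum screening, the recommended
#'   setting), `"wrapper"` (stepwise-AIC search) or `"embedded"` (no
#'   screening; classifiers see every retained feature and rely on their own
#'   sparsity).
#' @param use_pca Apply PCA to the filter-selected features (default FALSE;
#'   when TRUE the filter cap is raised to the training-set size first).
#' @param pca_var_threshold Minimum cumulative variance fraction the retained
#'   components must explain (default 0.95).
#' @param pca_min_components Minimum number of components (default 2).
#' @param wrapper_n_start Number of random start features for the stepwise
#'   search (default 5).
#' @return A `selection_spec` list.
#' @export
selection_spec <- function(sigma = 0, nkeep = 2L,
                           method = c("filter", "wrapper", "embedded"),
                           use_pca = FALSE, pca_var_threshold = 0.95,
                           pca_min_components = 2L, wrapper_n_start = 5L) {
  method <- match.arg(method)
  if (sigma < 0) stop("sigma must be >= 0")
  if (nkeep < 1) stop("nkeep must be >= 1")
  if (pca_var_threshold <= 0 || pca_var_threshold > 1) {
    stop("pca_var_threshold must be in (0, 1]")
  }
  structure(list(sigma = sigma, nkeep = as.integer(nkeep), method = method,
                 use_pca = isTRUE(use_pca),
                 pca_var_threshold = pca_var_threshold,
                 pca_min_components = as.integer(pca_min_components),
                 wrapper_n_start = as.integer(wrapper_n_start)),
            class = "selection_spec")
}

#' Exclude near-constant features
#'
#' Retains the features whose sample standard deviation (n-1 denominator)
#' is strictly greater than `sigma`.  At `sigma = 0` this removes exactly
#' the zero-variance features (e.g. wavelet coefficients arising purely from
#' zero-padding).
#'
#' @param table A [feature_table()] or samples-by-features matrix with at
#'   least two rows.
#' @param sigma Threshold (default 0).
#' @return Character vector of retained feature ids.
#' @export
sd_exclude <- function(table, sigma = 0) {
  X <- ft_values(table)
  n <- nrow(X)
  if (n < 2L) stop("sd_exclude needs at least 2 samples")
  mu <- colMeans(X)
  v <- (colSums(X^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  # exact detection of constant columns, immune to cancellation error
  const <- colSums(X == rep(X[1L, ], each = n)) == n
  v[const] <- 0
  keep <- sqrt(v) > sigma
  if (!any(keep)) {
    stop("all features excluded at sigma = ", sigma,
         "; lower the threshold")
  }
  colnames(X)[keep]
}

# Normal approximation with tie and continuity correction, the large-sample
# branch shared by ranksum_p() and the vectorised per-feature screen.
.ranksum_normal_p <- function(U, na, nb, tie_term) {
  n <- na + nb
  sigma <- sqrt((na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1))))
  if (sigma == 0) return(1)
  z <- U - na * nb / 2
  z <- (z - sign(z) * 0.5) / sigma
  min(2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)), 1)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p-value from the enumerated rank-sum null distribution when both
#' groups have at most 25 observations and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors of values from the two groups (both
#'   non-empty).
#' @return p-value in (0, 1].
#' @export
ranksum_p <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty")
  }
  na <- length(a); nb <- length(b)
  x <- c(a, b)
  r <- rank(x)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  tie_lens <- rle(sort(x))$lengths
  has_ties <- any(tie_lens > 1L)
  if (na <= 25L && nb <= 25L && !has_ties) {
    p <- if (U > na * nb / 2) {
      stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)
    } else {
      stats::pwilcox(U, na, nb)
    }
    p <- min(2 * p, 1)
  } else {
    p <- .ranksum_normal_p(U, na, nb, sum(tie_lens^3 - tie_lens))
  }
  max(p, .Machine$double.xmin)
}

# Per-column rank-sum p-values for large groups (normal-approximation
# regime).  Fully vectorised: one global order() call ranks every column at
# once (midranks for ties), and tie corrections are accumulated per column,
# which keeps the in-fold screen fast for tens of thousands of features.
.ranksum_p_cols <- function(X, is_case) {
  n <- nrow(X); p <- ncol(X)
  na <- sum(is_case); nb <- n - na
  x <- as.vector(X)
  grp <- rep.int(seq_len(p), rep.int(n, p))
  o <- order(grp, x)
  xs <- x[o]
  len <- n * p
  new_run <- c(TRUE, xs[-1L] != xs[-len] | grp[o][-1L] != grp[o][-len])
  runid <- cumsum(new_run)
  run_len <- tabulate(runid)
  pos <- rep.int(seq_len(n), p)                   # sorted position in column
  run_start <- pos[new_run]
  midrank_run <- run_start + (run_len - 1) / 2    # average rank of each run
  r <- numeric(len)
  r[o] <- midrank_run[runid]
  W <- colSums(matrix(r, n, p)[is_case, , drop = FALSE])
  U <- W - na * (na + 1) / 2
  tie_term <- as.vector(rowsum(run_len^3 - run_len,
                               group = grp[o][new_run]))
  sigma <- sqrt((na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1))))
  z <- U - na * nb / 2
  z <- (z - sign(z) * 0.5) / pmax(sigma, .Machine$double.eps)
  pv <- 2 * pmin(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  pv[sigma == 0] <- 1
  pmin(pv, 1)
}

#' Filter-method feature selection
#'
#' Scores every feature with a two-sided Wilcoxon rank-sum test of case
#' versus control values and returns the `nkeep` features with the smallest
#' p-values, ties broken by ascending feature index.  Intended to be called
#' on training data only (the cross-validation harness does this per fold).
#'
#' @param table A [feature_table()] or matrix of training samples.
#' @param labels Class labels for the rows (see [as_class_labels()]).
#' @param nkeep Number of features to keep; if at least the feature count,
#'   all features are returned.
#' @return Character vector of selected feature ids, ordered by increasing
#'   p-value, with a `p_value` attribute.
#' @export
filter_select <- function(table, labels, nkeep = 2L) {
  labels <- as_class_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class")
  }
  X <- ft_values(table)
  stopifnot(nrow(X) == length(labels))
  is_case <- labels == "case"
  p <- if (sum(is_case) <= 25L && sum(!is_case) <= 25L) {
    apply(X, 2L, function(col) ranksum_p(col[is_case], col[!is_case]))
  } else {
    .ranksum_p_cols(X, is_case)
  }
  ord <- order(p, seq_along(p))
  keep <- ord[seq_len(min(nkeep, length(p)))]
  structure(colnames(X)[keep], p_value = unname(p[keep]))
}

#' PCA reduction of selected features
#'
#' Covariance-based principal component analysis fitted on the training
#' rows (centred on training means, no scaling).  Retains the smallest
#' number of components whose cumulative variance reaches
#' `pca_var_threshold`, but never fewer than `pca_min_components`.  Test
#' scores use the training loadings and centring.
#'
#' @param train,test [feature_table()]s (or matrices) sharing the same
#'   features.
#' @param spec A [selection_spec()].
#' @return List with `train` and `test` score tables (provenance `pca`).
#' @export
pca_reduce <- function(train, test, spec = selection_spec(use_pca = TRUE)) {
  Xtr <- ft_values(train)
  Xte <- ft_values(test)
  if (!identical(colnames(Xtr), colnames(Xte))) {
    stop("train and test must share features in identical order")
  }
  pc <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE)
  if (ncol(pc$rotation) < 2L) {
    stop("fewer than 2 retainable principal components")
  }
  evar <- pc$sdev^2
  prop <- cumsum(evar) / sum(evar)
  ncomp <- which(prop >= spec$pca_var_threshold)[1L]
  ncomp <- max(ncomp, spec$pca_min_components)
  ncomp <- min(ncomp, ncol(pc$rotation))
  ids <- paste0("PC", seq_len(ncomp))
  str <- pc$x[, seq_len(ncomp), drop = FALSE]
  ste <- scale(Xte, center = pc$center, scale = FALSE) %*%
    pc$rotation[, seq_len(ncomp), drop = FALSE]
  colnames(str) <- colnames(ste) <- ids
  rownames(str) <- rownames(Xtr)
  rownames(ste) <- rownames(Xte)
  list(train = feature_table(str, "pca"), test = feature_table(ste, "pca"))
}

#' Stepwise-AIC wrapper feature selection
#'
#' Greedy stepwise search over binomial-family linear models: starting from
#' `wrapper_n_start` randomly chosen features, each step considers adding
#' any unused feature or removing any current one, accepts the move that
#' most decreases AIC (`deviance + 2 * fitted coefficients`), and stops when
#' no move decreases it.  Candidate moves whose fit does not converge are
#' skipped (with a warning).
#'
#' @param table Training [feature_table()] or matrix (pre-filtered to a
#'   manageable feature count).
#' @param labels Training class labels.
#' @param spec A [selection_spec()]; `wrapper_n_start` is used.
#' @param seed Seed for the random start set.
#' @return Character vector of selected feature ids (in column order).
#' @export
stepwise_select <- function(table, labels, spec = selection_spec(method = "wrapper"),
                            seed = 1L) {
  labels <- as_class_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class")
  }
  X <- ft_values(table)
  y <- as.integer(labels == "case")
  p <- ncol(X)
  n_start <- min(spec$wrapper_n_start, p)
  if (n_start < 1L) stop("stepwise search needs at least one start feature")
  skipped <- 0L
  fit_aic <- function(set) {
    Xm <- cbind(1, X[, set, drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(Xm, y, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      skipped <<- skipped + 1L
      return(NA_real_)
    }
    fit$deviance + 2 * fit$rank
  }
  # random start; non-convergent starts (e.g. quasi-separated draws) are
  # redrawn with progressively fewer features before giving up
  cur_aic <- NA_real_
  for (attempt in 0:9) {
    n_st <- max(1L, n_start - attempt %/% 2L)
    current <- sort(withr::with_seed(seed + 131L * attempt,
                                     sample.int(p, n_st)))
    cur_aic <- fit_aic(current)
    if (!is.na(cur_aic)) break
  }
  if (is.na(cur_aic)) {
    stop("no convergent stepwise start model found; the training data may ",
         "be perfectly separable")
  }
  repeat {
    adds <- setdiff(seq_len(p), current)
    drops <- if (length(current) > 1L) current else integer(0)
    cand_sets <- c(lapply(adds, function(f) sort(c(current, f))),
                   lapply(drops, function(f) setdiff(current, f)))
    if (length(cand_sets) == 0L) break
    aics <- vapply(cand_sets, fit_aic, numeric(1))
    if (all(is.na(aics))) break
    best <- which.min(aics)
    if (aics[best] >= cur_aic - 1e-8) break
    current <- cand_sets[[best]]
    cur_aic <- aics[best]
  }
  if (skipped > 0L) {
    warning(skipped, " candidate move(s) skipped due to non-convergent fits")
  }
  colnames(X)[current]
}
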
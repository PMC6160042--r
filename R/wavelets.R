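# Discrete wavelet transform feature extraction for FAIMS dispersion grids.
#
# The transform is the standard decimated pyramid with periodic boundary
# handling on dyadic inputs, using least-asymmetric Daubechies (symlet)
# filters.  The analysis step is phase-aligned with the common
# "periodization" convention: coefficient k of a length-n signal x is
#   a[k] = sum_m h[m] * x[(2(k-1) + m - len/2) mod n + 1]
# which makes the stacked low/high-pass operator an orthogonal matrix, so
# energy is conserved and the transpose is the exact inverse.

.band_cache <- new.env(parent = emptyenv())

# Low- and high-pass analysis operators (n/2 x n each) for signal length n.
.dwt_band_mats <- function(n, h) {
  key <- paste0(n, "_", length(h))
  hit <- .band_cache[[key]]
  if (!is.null(hit)) return(hit)
  len <- length(h)
  g <- .qmf(h)
  k <- rep(seq_len(n / 2), each = len)
  m <- rep(seq_len(len), times = n / 2)
  j <- ((2 * (k - 1) + m - 1 - (len / 2 - 1)) %% n) + 1
  # sparseMatrix sums duplicate entries, which folds the filter correctly
  # when it is longer than the signal.
  L <- as.matrix(Matrix::sparseMatrix(i = k, j = j, x = rep(h, n / 2),
                                      dims = c(n / 2, n)))
  H <- as.matrix(Matrix::sparseMatrix(i = k, j = j, x = rep(g, n / 2),
                                      dims = c(n / 2, n)))
  out <- list(L = L, H = H)
  .band_cache[[key]] <- out
  out
}

#' Wavelet-stage configuration
#'
#' @param mode `"dwt2"` (two-dimensional transform of the reshaped dispersion
#'   grid, the recommended setting), `"dwt1"` (transform of the linearised
#'   vector), or `"none"` (raw features pass through).
#' @param crop_rows Number of contiguous compensation-voltage rows retained
#'   before the 2D transform; a power of two (512 keeps everything; 256 and
#'   128 crop to the structured part of the grid).
#' @param crop_offset First retained row index minus one (default 0).
#' @param vanishing_moments Vanishing moments of the least-asymmetric
#'   Daubechies filter (1-10, default 10).
#' @return A `wavelet_spec` list.
#' @export
wavelet_spec <- function(mode = c("dwt2", "dwt1", "none"), crop_rows = 512L,
                         crop_offset = 0L, vanishing_moments = 10L) {
  mode <- match.arg(mode)
  crop_rows <- as.integer(crop_rows)
  if (crop_rows < 2L || bitwAnd(crop_rows, crop_rows - 1L) != 0L) {
    stop("crop_rows must be a power of two, got ", crop_rows)
  }
  if (crop_offset < 0L) stop("crop_offset must be non-negative")
  vanishing_moments <- as.integer(vanishing_moments)
  wavelet_filter(vanishing_moments)  # validates the range
  structure(list(mode = mode, crop_rows = crop_rows,
                 crop_offset = as.integer(crop_offset),
                 vanishing_moments = vanishing_moments),
            class = "wavelet_spec")
}

#' Reshape a linearised sample back into its dispersion grid
#'
#' Inverse of the linearisation layout: the result has one row per
#' compensation-voltage step and the positive-polarity dispersion-field
#' columns followed by the negative-polarity ones (512 x 102 at instrument
#' defaults).
#'
#' @param vector Linearised sample, as produced by [linearise()] (or one row
#'   of a raw [feature_table()]).
#' @param rows,cols Per-polarity grid dimensions; taken from the vector's
#'   `grid` attribute when omitted.
#' @return Numeric matrix `rows` x `2 * cols`.
#' @export
reshape_to_grid <- function(vector, rows = NULL, cols = NULL) {
  g <- attr(vector, "grid")
  if (is.null(rows)) rows <- g[["rows"]]
  if (is.null(cols)) cols <- g[["cols"]]
  if (is.null(rows) || is.null(cols)) {
    stop("grid dimensions unknown: pass rows and cols")
  }
  if (length(vector) != 2 * rows * cols) {
    stop("vector length ", length(vector), " != 2 * ", rows, " * ", cols)
  }
  pos <- matrix(vector[seq_len(rows * cols)], nrow = rows, byrow = TRUE)
  neg <- matrix(vector[rows * cols + seq_len(rows * cols)], nrow = rows,
                byrow = TRUE)
  cbind(pos, neg)
}

#' Crop and zero-pad a dispersion grid to a dyadic square
#'
#' Retains `crop_rows` contiguous rows starting at `crop_offset`, keeps all
#' columns, and zero-pads on the high side to the smallest square power of
#' two that holds the result (512x512, 256x256 or 128x128 for the
#' instrument-standard 102 combined columns).
#'
#' @param grid Matrix from [reshape_to_grid()].
#' @param spec A [wavelet_spec()].
#' @return Square dyadic matrix.
#' @export
crop_and_pad <- function(grid, spec = wavelet_spec()) {
  lo <- spec$crop_offset + 1L
  hi <- spec$crop_offset + spec$crop_rows
  if (hi > nrow(grid)) {
    stop("crop window [", lo, ", ", hi, "] exceeds the ", nrow(grid),
         " grid rows")
  }
  side <- 2^ceiling(log2(max(spec$crop_rows, ncol(grid))))
  out <- matrix(0, side, side)
  out[seq_len(spec$crop_rows), seq_len(ncol(grid))] <- grid[lo:hi, , drop = FALSE]
  out
}

# ---- 1D transform ----------------------------------------------------------

# One analysis step by direct circular filtering (same indexing as the
# operator matrices, but O(len * n) memory-light, so it scales to the
# 65,536-point padded vectors of the 1D mode).
.dwt_step <- function(x, h, g) {
  n <- length(x); len <- length(h)
  half <- n %/% 2L
  base <- 2 * (seq_len(half) - 1) - (len / 2 - 1)
  a <- numeric(half); d <- numeric(half)
  for (m in seq_len(len)) {
    xm <- x[(base + m - 1) %% n + 1]
    a <- a + h[m] * xm
    d <- d + g[m] * xm
  }
  list(a = a, d = d)
}

.idwt_step <- function(a, d, h, g) {
  half <- length(a); n <- 2L * half; len <- length(h)
  x <- numeric(n)
  base <- 2 * (seq_len(half) - 1) - (len / 2 - 1)
  for (m in seq_len(len)) {
    idx <- (base + m - 1) %% n + 1   # stride 2, distinct for fixed m
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

.dwt1_pyramid <- function(x, h) {
  g <- .qmf(h)
  details <- vector("list", as.integer(log2(length(x))))
  a <- x
  t <- 0L
  while (length(a) > 1L) {
    t <- t + 1L
    st <- .dwt_step(a, h, g)
    details[[t]] <- st$d
    a <- st$a
  }
  list(details = details, smooth = a)  # details[[1]] is the finest scale
}

.idwt1_pyramid <- function(pyr, h) {
  g <- .qmf(h)
  a <- pyr$smooth
  for (t in rev(seq_along(pyr$details))) {
    a <- .idwt_step(a, pyr$details[[t]], h, g)
  }
  a
}

.dwt1_flatten <- function(pyr) {
  c(pyr$smooth, unlist(rev(pyr$details), use.names = FALSE))
}

dwt1_feature_names <- function(J) {
  nm <- "W1_s"
  for (j in 0:(J - 1L)) {
    nm <- c(nm, paste0("W1_d", j, "_", seq_len(2^j)))
  }
  nm
}

#' 1D discrete wavelet features of a linearised sample
#'
#' Zero-pads the vector to the next power of two, runs a full-depth periodic
#' DWT and returns every detail coefficient at every scale plus the final
#' smooth coefficient, ordered scale-major from coarsest to finest.  The
#' output length equals the padded length (65,536 for an instrument-standard
#' 52,224-feature sample under this convention).
#'
#' @param vector Numeric vector (any positive length).
#' @param spec A [wavelet_spec()]; only `vanishing_moments` is used.
#' @return Named numeric vector of wavelet coefficients.
#' @export
dwt1_features <- function(vector, spec = wavelet_spec(mode = "dwt1")) {
  if (length(vector) == 0L) stop("empty input")
  h <- wavelet_filter(spec$vanishing_moments)
  J <- ceiling(log2(length(vector)))
  J <- max(J, 1L)
  padded <- c(as.vector(vector), numeric(2^J - length(vector)))
  out <- .dwt1_flatten(.dwt1_pyramid(padded, h))
  names(out) <- dwt1_feature_names(J)
  out
}

#' Inverse of [dwt1_features()]
#'
#' @param coefficients Output of [dwt1_features()] (length a power of two).
#' @param spec The [wavelet_spec()] used for the forward transform.
#' @return The padded input vector.
#' @export
idwt1 <- function(coefficients, spec = wavelet_spec(mode = "dwt1")) {
  n <- length(coefficients)
  J <- as.integer(round(log2(n)))
  if (2^J != n) stop("coefficient length must be a power of two")
  h <- wavelet_filter(spec$vanishing_moments)
  details <- vector("list", J)
  pos <- 1L
  smooth <- coefficients[[1L]]
  pos <- 2L
  for (j in 0:(J - 1L)) {            # coarsest first in the flat layout
    details[[J - j]] <- as.vector(coefficients[pos:(pos + 2^j - 1L)])
    pos <- pos + 2^j
  }
  .idwt1_pyramid(list(details = details, smooth = smooth), h)
}

# ---- 2D transform ----------------------------------------------------------

.dwt2_pyramid <- function(X, h) {
  levels <- list()
  S <- X
  while (nrow(S) > 1L) {
    bm <- .dwt_band_mats(nrow(S), h)
    Lo <- bm$L; Hi <- bm$H
    SL <- S %*% t(Lo); SH <- S %*% t(Hi)
    lv <- list(LL = Lo %*% SL, LH = Lo %*% SH,
               HL = Hi %*% SL, HH = Hi %*% SH)
    levels[[length(levels) + 1L]] <- lv
    S <- lv$LL
  }
  list(levels = levels, smooth = S)
}

.idwt2_pyramid <- function(pyr, h) {
  S <- pyr$smooth
  for (t in rev(seq_along(pyr$levels))) {
    lv <- pyr$levels[[t]]
    bm <- .dwt_band_mats(2L * nrow(S), h)
    Lo <- bm$L; Hi <- bm$H
    S <- t(Lo) %*% S %*% Lo + t(Lo) %*% lv$LH %*% Hi +
      t(Hi) %*% lv$HL %*% Lo + t(Hi) %*% lv$HH %*% Hi
  }
  S
}

.dwt2_flatten <- function(pyr) {
  parts <- lapply(pyr$levels, function(lv) {
    c(as.vector(t(lv$LL)), as.vector(t(lv$LH)),
      as.vector(t(lv$HL)), as.vector(t(lv$HH)))
  })
  c(unlist(parts, use.names = FALSE), as.vector(pyr$smooth))
}

dwt2_feature_names <- function(L) {
  nm <- vector("list", L)
  for (t in seq_len(L)) {
    j <- L - t
    s <- 2^j
    rc <- paste0("r", rep(seq_len(s), each = s), "_c", rep(seq_len(s), s))
    nm[[t]] <- paste0("W2_j", j, "_", rep(c("LL", "LH", "HL", "HH"),
                                          each = s * s), "_", rc)
  }
  c(unlist(nm, use.names = FALSE), "W2_s")
}

#' 2D discrete wavelet features of a dyadic square matrix
#'
#' Full-depth separable 2D DWT with periodic boundaries.  The feature vector
#' concatenates, for each scale from the finest (side/2) down to 1x1, the
#' four coefficient sub-grids at that scale — smooth (LL), horizontal (LH),
#' vertical (HL) and diagonal (HH), each flattened row-major — followed by
#' the final smooth constant, giving `4 * (4^L - 1) / 3 + 1` features for a
#' `2^L` square.  The smooth track retained at every scale is redundant with
#' respect to the orthonormal basis (it is further decomposed), but is kept
#' as part of the package's canonical feature layout; [idwt2()] reconstructs
#' from the non-redundant subset.
#'
#' @param square Dyadic square matrix (e.g. from [crop_and_pad()]).
#' @param spec A [wavelet_spec()].
#' @return Named numeric coefficient vector: 349,525 features from 512x512,
#'   87,381 from 256x256 and 21,845 from 128x128.
#' @export
dwt2_features <- function(square, spec = wavelet_spec()) {
  n <- nrow(square)
  if (is.null(n) || n != ncol(square)) stop("input must be square")
  L <- as.integer(round(log2(n)))
  if (2^L != n || L < 1L) stop("side must be a power of two >= 2")
  h <- wavelet_filter(spec$vanishing_moments)
  out <- .dwt2_flatten(.dwt2_pyramid(square, h))
  names(out) <- dwt2_feature_names(L)
  out
}

# Split a flat dwt2 feature vector back into a pyramid (redundant smooth
# sub-grids are read but only the deepest one is authoritative).
.dwt2_unflatten <- function(coefficients) {
  len <- length(coefficients)
  L <- as.integer(round(log2(3 * (len - 1) / 4 + 1) / 2))
  if (4 * (4^L - 1) / 3 + 1 != len) {
    stop("coefficient length ", len, " does not match any dyadic square")
  }
  levels <- vector("list", L)
  pos <- 1L
  for (t in seq_len(L)) {
    s <- 2^(L - t)
    lv <- list()
    for (band in c("LL", "LH", "HL", "HH")) {
      block <- coefficients[pos:(pos + s * s - 1L)]
      lv[[band]] <- matrix(block, nrow = s, byrow = TRUE)
      pos <- pos + s * s
    }
    levels[[t]] <- lv
  }
  list(levels = levels, smooth = matrix(coefficients[[len]], 1L, 1L), L = L)
}

#' Inverse of [dwt2_features()]
#'
#' Reconstructs the padded square matrix from the detail sub-grids and the
#' final smooth constant (the redundant smooth sub-grids are ignored).
#'
#' @param coefficients Output of [dwt2_features()].
#' @param spec The [wavelet_spec()] used for the forward transform.
#' @return The reconstructed square matrix.
#' @export
idwt2 <- function(coefficients, spec = wavelet_spec()) {
  pyr <- .dwt2_unflatten(coefficients)
  h <- wavelet_filter(spec$vanishing_moments)
  .idwt2_pyramid(pyr, h)
}

#' Spatial support of one 2D wavelet feature
#'
#' Inverse-transforms an indicator placed at the requested coefficient and
#' returns the bounding box of the non-negligible part of the result, in
#' coordinates of the padded square.  Used to map filter-selected wavelet
#' features back to dispersion-grid regions.
#'
#' @param feature_id A name produced by [dwt2_features()] (e.g.
#'   `"W2_j5_HH_r3_c7"` or `"W2_s"`).
#' @param side Side length of the padded square the features came from.
#' @param spec The [wavelet_spec()] used for the forward transform.
#' @return List with `row_lo`, `row_hi`, `col_lo`, `col_hi`.
#' @export
dwt2_feature_support <- function(feature_id, side, spec = wavelet_spec()) {
  h <- wavelet_filter(spec$vanishing_moments)
  L <- as.integer(round(log2(side)))
  if (identical(feature_id, "W2_s")) {
    j <- 0L; band <- "LL"; r <- 1L; cc <- 1L
  } else {
    m <- regmatches(feature_id,
                    regexec("^W2_j([0-9]+)_(LL|LH|HL|HH)_r([0-9]+)_c([0-9]+)$",
                            feature_id))[[1L]]
    if (length(m) != 5L) stop("unrecognised dwt2 feature id: ", feature_id)
    j <- as.integer(m[2L]); band <- m[3L]
    r <- as.integer(m[4L]); cc <- as.integer(m[5L])
  }
  t_lev <- L - j
  if (t_lev < 1L) {  # scale equal to full depth: support is everything
    return(list(row_lo = 1L, row_hi = side, col_lo = 1L, col_hi = side))
  }
  cur <- matrix(0, 2^j, 2^j)
  if (band == "LL") cur[r, cc] <- 1
  for (t in t_lev:1) {
    m0 <- nrow(cur)
    bm <- .dwt_band_mats(2L * m0, h)
    if (t == t_lev && band != "LL") {
      D <- matrix(0, m0, m0)
      D[r, cc] <- 1
      cur <- switch(band,
                    LH = t(bm$L) %*% D %*% bm$H,
                    HL = t(bm$H) %*% D %*% bm$L,
                    HH = t(bm$H) %*% D %*% bm$H)
    } else {
      cur <- t(bm$L) %*% cur %*% bm$L
    }
  }
  mask <- abs(cur) > max(abs(cur)) * 1e-9
  rr <- range(which(rowSums(mask) > 0))
  rc <- range(which(colSums(mask) > 0))
  list(row_lo = rr[1L], row_hi = rr[2L], col_lo = rc[1L], col_hi = rc[2L])
}

#' Apply the configured wavelet stage to a raw feature table
#'
#' Transforms every sample row of a raw table into its wavelet feature
#' vector: for `mode = "dwt2"` the row is reshaped to its dispersion grid,
#' cropped and padded, then transformed; for `mode = "dwt1"` the linearised
#' row is transformed directly; `mode = "none"` returns the table unchanged.
#'
#' @param table Raw [feature_table()] (with its `grid` attribute, as built by
#'   [build_table()]).
#' @param spec A [wavelet_spec()].
#' @return A [feature_table()] with provenance `dwt1` or `dwt2` and a
#'   `wavelet` attribute recording the spec and padded side length.
#' @export
wavelet_table <- function(table, spec = wavelet_spec()) {
  if (spec$mode == "none") return(table)
  vals <- ft_values(table)
  grid <- attr(table, "grid")
  if (is.null(grid)) stop("table lacks a grid attribute; was it built by build_table()?")
  h <- wavelet_filter(spec$vanishing_moments)
  if (spec$mode == "dwt1") {
    J <- max(ceiling(log2(ncol(vals))), 1L)
    out <- t(apply(vals, 1L, function(v) {
      padded <- c(v, numeric(2^J - length(v)))
      .dwt1_flatten(.dwt1_pyramid(padded, h))
    }))
    colnames(out) <- dwt1_feature_names(J)
    side <- NA_integer_
    prov <- "dwt1"
  } else {
    rows <- grid[["rows"]]; cols <- grid[["cols"]]
    side <- 2^ceiling(log2(max(spec$crop_rows, 2L * cols)))
    L <- as.integer(round(log2(side)))
    out <- t(apply(vals, 1L, function(v) {
      g <- reshape_to_grid(v, rows, cols)
      .dwt2_flatten(.dwt2_pyramid(crop_and_pad(g, spec), h))
    }))
    colnames(out) <- dwt2_feature_names(L)
    prov <- "dwt2"
  }
  rownames(out) <- rownames(vals)
  res <- feature_table(out, prov)
  attr(res, "grid") <- grid
  attr(res, "wavelet") <- list(spec = spec, side = side)
  res
}
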
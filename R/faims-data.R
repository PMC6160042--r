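# Data model and plain-text I/O for FAIMS dispersion-matrix runs, plus
# linearisation into feature vectors and run-level combination.

#' Single-polarity FAIMS dispersion matrix
#'
#' An ion matrix is the grid of detected current for one ion polarity of one
#' instrument run: rows are compensation-voltage steps (512 at the instrument
#' default, spanning +6 V to -6 V) and columns are dispersion-field steps
#' (51 at the default).
#'
#' @param values Numeric matrix of detected current (arbitrary units), rows =
#'   compensation-voltage steps, columns = dispersion-field steps.
#' @param polarity `"positive"` or `"negative"`.
#' @return An `ion_matrix` object (a numeric matrix with a polarity
#'   attribute).
#' @export
ion_matrix <- function(values, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  values <- as.matrix(values)
  if (!is.numeric(values) || length(values) == 0L) {
    stop("ion matrix values must be a non-empty numeric matrix")
  }
  if (!all(is.finite(values))) {
    stop("ion matrix contains non-finite values")
  }
  storage.mode(values) <- "double"
  structure(values, polarity = polarity, class = c("ion_matrix", "matrix"))
}

#' One FAIMS run of one sample
#'
#' A run bundles the positive- and negative-mode dispersion matrices recorded
#' in one pass of a sample through the instrument.  Each sample is measured
#' three consecutive times, so `run_index` is 1, 2 or 3.
#'
#' @param sample_id Sample identifier.
#' @param run_index Integer 1-3.
#' @param positive,negative [ion_matrix()] objects of identical dimensions.
#' @return A `faims_run` object.
#' @export
faims_run <- function(sample_id, run_index, positive, negative) {
  run_index <- as.integer(run_index)
  if (!run_index %in% 1:3) {
    stop("run_index must be 1, 2 or 3, got ", run_index)
  }
  if (!identical(dim(positive), dim(negative))) {
    stop("positive and negative matrices must share dimensions")
  }
  if (!identical(attr(positive, "polarity"), "positive") ||
      !identical(attr(negative, "polarity"), "negative")) {
    stop("matrices must carry matching polarity tags")
  }
  structure(
    list(sample_id = as.character(sample_id), run_index = run_index,
         positive = positive, negative = negative),
    class = "faims_run"
  )
}

#' @export
print.faims_run <- function(x, ...) {
  cat(sprintf("<faims_run> sample %s, run %d, %d x %d per polarity\n",
              x$sample_id, x$run_index, nrow(x$positive), ncol(x$positive)))
  invisible(x)
}

#' Read a FAIMS run from its plain-text dialect
#'
#' The run file is tab-separated text: header lines `#sample_id=`, `#run=`,
#' `#rows=`, `#cols=`, then a `#polarity=positive` block of rows x cols
#' numbers, then a `#polarity=negative` block.  Malformed headers, ragged
#' rows and non-numeric cells raise an error naming the offending line.
#'
#' @param path Path to a run file written by [write_faims_run()] (or any
#'   producer of the documented dialect).
#' @return A [faims_run()].
#' @export
read_faims_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- function(key, line_no) {
    prefix <- paste0("#", key, "=")
    if (line_no > length(lines) || !startsWith(lines[line_no], prefix)) {
      stop(sprintf("%s: line %d: expected '%s<value>' header", path, line_no,
                   prefix))
    }
    substring(lines[line_no], nchar(prefix) + 1L)
  }
  sample_id <- header("sample_id", 1L)
  run_index <- suppressWarnings(as.integer(header("run", 2L)))
  rows <- suppressWarnings(as.integer(header("rows", 3L)))
  cols <- suppressWarnings(as.integer(header("cols", 4L)))
  if (anyNA(c(run_index, rows, cols))) {
    stop(path, ": lines 2-4: run/rows/cols headers must be integers")
  }
  read_block <- function(polarity, start) {
    got <- header("polarity", start)
    if (!identical(got, polarity)) {
      stop(sprintf("%s: line %d: expected '#polarity=%s', found '%s'",
                   path, start, polarity, got))
    }
    end <- start + rows
    if (end > length(lines)) {
      stop(sprintf("%s: %s block truncated: expected %d data rows",
                   path, polarity, rows))
    }
    block <- lines[(start + 1L):end]
    if (any(startsWith(block, "#"))) {
      bad <- start + which(startsWith(block, "#"))[1L]
      stop(sprintf("%s: line %d: expected %d data rows before next header",
                   path, bad, rows))
    }
    vals <- strsplit(block, "\t", fixed = TRUE)
    lens <- lengths(vals)
    if (any(lens != cols)) {
      bad <- which(lens != cols)[1L]
      stop(sprintf("%s: line %d: expected %d columns, found %d",
                   path, start + bad, cols, lens[bad]))
    }
    num <- suppressWarnings(vapply(vals, as.numeric, numeric(cols)))
    if (anyNA(num)) {
      bad <- which(apply(is.na(num), 2L, any))[1L]
      stop(sprintf("%s: line %d: non-numeric cell", path, start + bad))
    }
    # vapply returned cols x rows; transpose back
    ion_matrix(t(matrix(num, nrow = cols)), polarity)
  }
  pos <- read_block("positive", 5L)
  neg <- read_block("negative", 5L + rows + 1L)
  faims_run(sample_id, run_index, pos, neg)
}

#' Write a FAIMS run in the package's plain-text dialect
#'
#' @param run A [faims_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_faims_run <- function(run, path) {
  stopifnot(inherits(run, "faims_run"))
  fmt_block <- function(m) {
    apply(unclass(m), 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = "\t"))
  }
  lines <- c(
    paste0("#sample_id=", run$sample_id),
    paste0("#run=", run$run_index),
    paste0("#rows=", nrow(run$positive)),
    paste0("#cols=", ncol(run$positive)),
    "#polarity=positive", fmt_block(run$positive),
    "#polarity=negative", fmt_block(run$negative)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Comma-separated file with columns `sample_id,label,sex,age,alcohol,bmi`;
#' `label` is `case` or `control`, `sex` is `M` or `F`, `alcohol` is units
#' per week and `bmi` kg/m^2.
#'
#' @param path CSV file path.
#' @return A data frame with `label` as a factor with levels
#'   `control`, `case`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "label", "sex", "age", "alcohol", "bmi")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  }
  df$label <- as_class_labels(df$label)
  if (any(df$age <= 0) || any(df$bmi <= 0) || any(df$alcohol < 0)) {
    stop("metadata violates age > 0, bmi > 0, alcohol >= 0")
  }
  df
}

#' Coerce labels to the package's case/control factor
#'
#' @param labels Character, logical or factor vector of class labels.
#' @return Factor with levels `control`, `case` (case is the positive class).
#' @export
as_class_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad)) {
    stop("labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  factor(labels, levels = c("control", "case"))
}

#' Samples-by-features table
#'
#' The common container moved between pipeline stages: a numeric matrix with
#' sample identifiers as row names, feature identifiers as column names and a
#' provenance tag recording which stage produced it.
#'
#' @param values Numeric matrix with unique row and column names.
#' @param provenance One of `raw`, `dwt1`, `dwt2`, `selected`, `pca`,
#'   `demographics`, `combined`.
#' @return A `feature_table` object.
#' @export
feature_table <- function(values,
                          provenance = c("raw", "dwt1", "dwt2", "selected",
                                         "pca", "demographics", "combined")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature_table values need sample row names and feature column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample_ids")
  if (anyDuplicated(colnames(values))) stop("duplicate feature_ids")
  if (!all(is.finite(values))) stop("feature_table contains non-finite values")
  structure(values, provenance = provenance,
            class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, provenance '%s'\n",
              nrow(x), ncol(x), attr(x, "provenance")))
  invisible(x)
}

# Plain numeric matrix from a feature_table (or matrix), attributes dropped.
ft_values <- function(table) {
  m <- unclass(table)
  attr(m, "provenance") <- NULL
  attr(m, "grid") <- NULL
  attr(m, "wavelet") <- NULL
  m
}

# Rebuild a feature_table preserving auxiliary attributes of `template`.
ft_like <- function(values, template, provenance = attr(template, "provenance")) {
  out <- feature_table(values, provenance)
  for (a in c("grid", "wavelet")) {
    if (!is.null(attr(template, a))) attr(out, a) <- attr(template, a)
  }
  out
}

#' Linearise a FAIMS run into a feature vector
#'
#' Flattens the positive matrix row-major (compensation-voltage row by row
#' across dispersion-field columns), then the negative matrix, giving a
#' vector of length `2 * rows * cols` — 52,224 at the instrument default of
#' 512 x 51 per polarity.  Feature names encode polarity, compensation-voltage
#' index and dispersion-field index.
#'
#' @param run A [faims_run()].
#' @return Named numeric vector with a `grid` attribute carrying the
#'   per-polarity dimensions.
#' @export
linearise <- function(run) {
  stopifnot(inherits(run, "faims_run"))
  rows <- nrow(run$positive)
  cols <- ncol(run$positive)
  v <- c(as.vector(t(unclass(run$positive))), as.vector(t(unclass(run$negative))))
  names(v) <- faims_feature_ids(rows, cols)
  attr(v, "grid") <- c(rows = rows, cols = cols)
  v
}

# Feature identifiers of the raw linearised layout, in vector order.
faims_feature_ids <- function(rows, cols) {
  per <- paste0("cv", rep(seq_len(rows), each = cols), "_df",
                rep(seq_len(cols), times = rows))
  c(paste0("P_", per), paste0("N_", per))
}

#' Assemble a samples-by-features table for one run index
#'
#' @param runs List of [faims_run()] objects (three per sample in a full
#'   cohort).
#' @param run_index Which run (1-3) to extract for every sample.
#' @return A raw-provenance [feature_table()], one row per sample, in order
#'   of first appearance of each sample in `runs`.
#' @export
build_table <- function(runs, run_index) {
  run_index <- as.integer(run_index)
  if (!run_index %in% 1:3) stop("run_index must be 1, 2 or 3, got ", run_index)
  ids <- unique(vapply(runs, function(r) r$sample_id, character(1)))
  sel <- lapply(ids, function(id) {
    hit <- Filter(function(r) r$sample_id == id && r$run_index == run_index,
                  runs)
    if (length(hit) == 0L) return(NULL)
    hit[[1L]]
  })
  missing <- ids[vapply(sel, is.null, logical(1))]
  if (length(missing)) {
    stop("missing run ", run_index, " for sample(s): ",
         paste(missing, collapse = ", "))
  }
  vecs <- lapply(sel, linearise)
  grid <- attr(vecs[[1L]], "grid")
  m <- do.call(rbind, lapply(vecs, as.vector))
  dimnames(m) <- list(ids, names(vecs[[1L]]))
  out <- feature_table(m, "raw")
  attr(out, "grid") <- grid
  out
}

# Shared alignment check for element-wise table combination.
.check_aligned <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    stop("feature tables are not aligned (sample/feature ids must match ",
         "in identical order)")
  }
}

#' Element-wise difference of two aligned feature tables
#'
#' Used for the run-subtraction ensemble (e.g. run 1 minus run 3, probing
#' sample degradation across consecutive runs).
#'
#' @param a,b [feature_table()]s with identical sample and feature ids in
#'   identical order.
#' @return `a - b` as a raw-provenance feature table.
#' @export
combine_subtract <- function(a, b) {
  .check_aligned(a, b)
  ft_like(ft_values(a) - ft_values(b), a, provenance = "raw")
}

#' Element-wise mean of aligned feature tables
#'
#' The run ensemble: averaging the three FAIMS runs of each sample to
#' improve signal-to-noise.
#'
#' @param tables List of two or more aligned [feature_table()]s.
#' @return Element-wise mean as a raw-provenance feature table.
#' @export
combine_mean <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L) {
    stop("combine_mean needs a list of at least two feature tables")
  }
  for (t in tables[-1L]) .check_aligned(tables[[1L]], t)
  acc <- Reduce(`+`, lapply(tables, ft_values))
  ft_like(acc / length(tables), tables[[1L]], provenance = "raw")
}
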
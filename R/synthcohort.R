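# Synthetic FAIMS cohort generator.  Emulates the structure of a urinary
# VOC case-control study: per sample, three consecutive runs of paired
# positive/negative dispersion grids containing a reactant-ion ridge and a
# handful of drifting analyte peaks; a class effect planted on designated
# marker peaks; multiplicative run-to-run degradation of volatile peaks;
# and demographics whose case/control separation is controlled by a
# confounding knob (fully separated at 1, identical distributions at 0).

#' Synthetic-cohort configuration
#'
#' Defaults reflect the study conditions the generator emulates: a 512 x 51
#' grid per polarity, six analyte peaks of which the first two carry the
#' class effect (`effect_size` fractional amplitude increase in cases),
#' linear compensation-voltage drift of the peak trace across dispersion
#' columns, per-run attenuation of volatile peaks, and demographic moments
#' interpolated between the pooled cohort and the observed case/control
#' values by `confounding` (1 reproduces the study's demographic imbalance:
#' BMI 38.3 (10.5) vs 28.1 (5.96), mean age 57 vs 45, alcohol 2 vs 5
#' units/week, male fraction 43/72 vs 17/43).
#'
#' @param n_case,n_control Samples per class.
#' @param rows,cols Grid dimensions per polarity (compensation-voltage
#'   steps x dispersion-field steps; instrument default 512 x 51).
#' @param n_peaks Analyte peaks per sample (default 6, alternating between
#'   the positive and negative matrices).
#' @param marker_peaks Indices of the class-affected peaks (default 1:2).
#' @param effect_size Fractional amplitude increment on marker peaks for
#'   cases (default 0.5).
#' @param drift_slope Compensation-voltage row shift of a peak centre per
#'   dispersion-field column (default 1.5).
#' @param peak_width Gaussian widths `c(rows, cols)` (default 10, 6).
#' @param run_decay Multiplicative attenuation of volatile peaks per run
#'   (default 0.85; all analyte peaks are volatile-designated).
#' @param noise_sd Additive Gaussian noise SD (default 0.02).
#' @param amp_sd Log-scale SD of per-sample, per-peak amplitude variation
#'   (default 0.3).
#' @param scale_sd Log-scale SD of the per-sample global intensity factor
#'   (default 0.2).
#' @param confounding Fraction of the demographic class separation retained
#'   (0 = identical distributions, 1 = study moments; default 1).
#' @param seed Integer seed; the cohort is fully determined by it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_case = 60L, n_control = 60L, rows = 512L, cols = 51L,
                       n_peaks = 6L, marker_peaks = 1:2, effect_size = 0.5,
                       drift_slope = 1.5, peak_width = c(10, 6),
                       run_decay = 0.85, noise_sd = 0.02, amp_sd = 0.3,
                       scale_sd = 0.2, confounding = 1, seed = 1L) {
  if (n_case < 1L || n_control < 1L) stop("counts must be >= 1")
  if (run_decay < 0 || run_decay > 1) stop("run_decay must be in [0, 1]")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (any(marker_peaks > n_peaks)) {
    stop("marker index exceeds n_peaks")
  }
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 rows = as.integer(rows), cols = as.integer(cols),
                 n_peaks = as.integer(n_peaks),
                 marker_peaks = as.integer(marker_peaks),
                 effect_size = effect_size, drift_slope = drift_slope,
                 peak_width = peak_width, run_decay = run_decay,
                 noise_sd = noise_sd, amp_sd = amp_sd, scale_sd = scale_sd,
                 confounding = confounding, seed = as.integer(seed)),
            class = "synth_spec")
}

# Cohort-level peak geometry, drawn deterministically from the seed.  Peak
# centres sit in the low-compensation-voltage band where real dispersion
# plots carry their structure (rows ~4-22% of the grid), so the 128-row
# cropped transform window captures them.
.synth_peaks <- function(spec) {
  withr::with_seed(spec$seed, {
    n <- spec$n_peaks
    data.frame(
      peak = seq_len(n),
      polarity = rep(c("positive", "negative"), length.out = n),
      r0 = stats::runif(n, 0.04 * spec$rows, 0.22 * spec$rows),
      c0 = stats::runif(n, 0.15 * spec$cols, 0.85 * spec$cols),
      amp = stats::runif(n, 0.6, 1.4),
      sd_r = spec$peak_width[1L] * stats::runif(n, 0.8, 1.25),
      sd_c = spec$peak_width[2L] * stats::runif(n, 0.8, 1.25),
      marker = seq_len(n) %in% spec$marker_peaks,
      volatile = TRUE)
  })
}

# Demographic distribution parameters interpolated by the confounding knob:
# group = pooled + confounding * (group - pooled).
.synth_demo_params <- function(spec) {
  cf <- spec$confounding
  mix <- function(group, pooled) pooled + cf * (group - pooled)
  list(
    bmi_mean = c(case = mix(38.3, 34.5), control = mix(28.1, 34.5)),
    bmi_sd = c(case = mix(10.5, 10.3), control = mix(5.96, 10.3)),
    age_mean = c(case = mix(57, 53), control = mix(45, 53)),
    age_sd = c(case = 12, control = 12),
    alcohol_mean = c(case = mix(2, 3), control = mix(5, 3)),
    male_p = c(case = mix(43 / 72, 60 / 115), control = mix(17 / 43, 60 / 115)))
}

# Gaussian peak with a linearly drifting row centre, on a rows x cols grid.
.peak_field <- function(rows, cols, r0, c0, sd_r, sd_c, drift) {
  rc <- r0 + drift * (seq_len(cols) - 1)
  M <- exp(-(outer(seq_len(rows), rc, "-"))^2 / (2 * sd_r^2))
  colfac <- exp(-(seq_len(cols) - c0)^2 / (2 * sd_c^2))
  sweep(M, 2L, colfac, "*")
}

#' Generate a synthetic FAIMS cohort
#'
#' Produces three [faims_run()]s per sample plus a sample-metadata table.
#' Each polarity grid is a small baseline, a high-amplitude reactant-ion
#' ridge, the analyte peaks assigned to that polarity (marker peaks scaled
#' by `1 + effect_size` in cases, volatile peaks attenuated by
#' `run_decay^(run - 1)`), and additive Gaussian noise, clipped at zero.
#' Identical seeds give bit-identical cohorts.
#'
#' @param spec A [synth_spec()].
#' @return List with `runs` (list of `3 * (n_case + n_control)`
#'   [faims_run()]s) and `samples` (data frame with `sample_id`, `label`,
#'   `sex`, `age`, `alcohol`, `bmi`).
#' @export
generate_cohort <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  peaks <- .synth_peaks(spec)
  n <- spec$n_case + spec$n_control
  ids <- sprintf("S%03d", seq_len(n))
  label <- as_class_labels(rep(c("case", "control"),
                               c(spec$n_case, spec$n_control)))
  dp <- .synth_demo_params(spec)
  withr::with_seed(spec$seed + 1L, {
    grp <- as.character(label)
    samples <- data.frame(
      sample_id = ids, label = label,
      sex = ifelse(stats::runif(n) < dp$male_p[grp], "M", "F"),
      age = pmax(18, stats::rnorm(n, dp$age_mean[grp], dp$age_sd[grp])),
      alcohol = stats::rgamma(n, shape = 1.2,
                              scale = dp$alcohol_mean[grp] / 1.2),
      bmi = pmax(15, stats::rnorm(n, dp$bmi_mean[grp], dp$bmi_sd[grp])))
    rownames(samples) <- NULL
    # precompute unit peak fields (shared geometry across samples/runs)
    fields <- lapply(seq_len(spec$n_peaks), function(i) {
      .peak_field(spec$rows, spec$cols, peaks$r0[i], peaks$c0[i],
                  peaks$sd_r[i], peaks$sd_c[i], spec$drift_slope)
    })
    ridge <- .peak_field(spec$rows, spec$cols, 0.03 * spec$rows,
                         (spec$cols + 1) / 2, 6, spec$cols, spec$drift_slope)
    ridge <- 3 * sweep(ridge, 2L,
                       1 - 0.5 * (seq_len(spec$cols) - 1) / spec$cols, "*")
    runs <- vector("list", 3L * n)
    k <- 0L
    for (s in seq_len(n)) {
      sample_scale <- exp(stats::rnorm(1, 0, spec$scale_sd))
      peak_amp <- peaks$amp * exp(stats::rnorm(spec$n_peaks, 0, spec$amp_sd))
      peak_amp[peaks$marker] <- peak_amp[peaks$marker] *
        (1 + spec$effect_size * (label[s] == "case"))
      for (r in 1:3) {
        decay <- ifelse(peaks$volatile, spec$run_decay^(r - 1), 1)
        mats <- lapply(c("positive", "negative"), function(pol) {
          g <- 0.02 + ridge
          for (i in which(peaks$polarity == pol)) {
            g <- g + peak_amp[i] * decay[i] * fields[[i]]
          }
          g <- sample_scale * g +
            matrix(stats::rnorm(spec$rows * spec$cols, 0, spec$noise_sd),
                   spec$rows, spec$cols)
          ion_matrix(pmax(g, 0), pol)
        })
        k <- k + 1L
        runs[[k]] <- faims_run(ids[s], r, mats[[1L]], mats[[2L]])
      }
    }
  })
  list(runs = runs, samples = samples)
}

#' Grid locations of the planted marker peaks
#'
#' Returns, for every marker peak, the window of dispersion-grid rows and
#' columns its Gaussian footprint occupies (centre drift included, +/- 3
#' SD), both in per-polarity column coordinates and in the combined
#' positive-then-negative column layout used by [reshape_to_grid()].  The
#' descriptor always lists the marker peaks; whether a class effect is
#' present is governed separately by `effect_size`.
#'
#' @param spec A [synth_spec()].
#' @return Data frame with columns `peak`, `polarity`, `row_lo`, `row_hi`,
#'   `col_lo`, `col_hi`, `grid_col_lo`, `grid_col_hi`.
#' @export
planted_truth <- function(spec = synth_spec()) {
  peaks <- .synth_peaks(spec)
  mk <- peaks[peaks$marker, , drop = FALSE]
  col_lo <- pmax(1, floor(mk$c0 - 3 * mk$sd_c))
  col_hi <- pmin(spec$cols, ceiling(mk$c0 + 3 * mk$sd_c))
  row_lo <- pmax(1, floor(mk$r0 + spec$drift_slope * (col_lo - 1) - 3 * mk$sd_r))
  row_hi <- pmin(spec$rows, ceiling(mk$r0 + spec$drift_slope * (col_hi - 1) +
                                      3 * mk$sd_r))
  off <- ifelse(mk$polarity == "negative", spec$cols, 0L)
  data.frame(peak = mk$peak, polarity = mk$polarity,
             row_lo = row_lo, row_hi = row_hi,
             col_lo = col_lo, col_hi = col_hi,
             grid_col_lo = col_lo + off, grid_col_hi = col_hi + off,
             row.names = NULL)
}

#' Do selected 2D wavelet features overlap the planted marker regions?
#'
#' Maps each selected feature id of a `dwt2` table back to dispersion-grid
#' coordinates through its inverse-transform support and checks overlap
#' with any planted marker window.
#'
#' @param feature_ids Character vector of `dwt2` feature ids.
#' @param table The `dwt2` [feature_table()] they were selected from (its
#'   `wavelet` attribute supplies crop and padding geometry).
#' @param truth Output of [planted_truth()].
#' @return Logical vector, one element per feature id.
#' @export
features_overlap_truth <- function(feature_ids, table, truth) {
  wv <- attr(table, "wavelet")
  if (is.null(wv) || wv$spec$mode != "dwt2") {
    stop("table does not carry dwt2 wavelet geometry")
  }
  grid <- attr(table, "grid")
  vapply(feature_ids, function(id) {
    sup <- dwt2_feature_support(id, wv$side, wv$spec)
    row_lo <- sup$row_lo + wv$spec$crop_offset
    row_hi <- sup$row_hi + wv$spec$crop_offset
    any(row_lo <= truth$row_hi & row_hi >= truth$row_lo &
          sup$col_lo <= truth$grid_col_hi & sup$col_hi >= truth$grid_col_lo)
  }, logical(1), USE.NAMES = TRUE)
}
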
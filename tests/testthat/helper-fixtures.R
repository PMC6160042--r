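# Shared fixtures, built in code at test time.

ft_values <- faimspipe:::ft_values  # plain-matrix accessor, used throughout

# A 2x2-per-polarity run with known values 1..8.
toy_run <- function(sample_id = "T1", run_index = 1L) {
  faims_run(sample_id, run_index,
            ion_matrix(matrix(c(1, 2, 3, 4), 2, byrow = TRUE), "positive"),
            ion_matrix(matrix(c(5, 6, 7, 8), 2, byrow = TRUE), "negative"))
}

random_run <- function(sample_id, run_index = 1L, rows = 8L, cols = 5L) {
  faims_run(sample_id, run_index,
            ion_matrix(matrix(runif(rows * cols), rows), "positive"),
            ion_matrix(matrix(runif(rows * cols), rows), "negative"))
}

# Small synthetic cohort on a reduced grid, cached per session (the grids
# are 64 x 12 per polarity so wavelet stages stay fast in unit tests).
.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$spec <- synth_spec(n_case = 10L, n_control = 10L,
                                    rows = 64L, cols = 12L,
                                    peak_width = c(5, 3), drift_slope = 0.5,
                                    seed = 42L)
    .fixture_env$cohort <- generate_cohort(.fixture_env$spec)
  }
  list(spec = .fixture_env$spec, cohort = .fixture_env$cohort)
}

# A labelled feature matrix with two informative columns among noise.
signal_table <- function(n_per_class = 15L, p_noise = 40L, effect = 2,
                         seed = 7L) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    labels <- rep(c("case", "control"), each = n_per_class)
    X <- matrix(rnorm(n * (p_noise + 2L)), n)
    X[labels == "case", 1:2] <- X[labels == "case", 1:2] + effect
    dimnames(X) <- list(sprintf("S%02d", seq_len(n)),
                        c("sig1", "sig2", paste0("noise", seq_len(p_noise))))
    list(table = feature_table(X, "raw"), labels = labels)
  })
}
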
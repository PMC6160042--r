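# Independent brute-force oracles used to validate the statistical
# primitives.  These deliberately share no code with the implementation.

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled observations to group A (permutation null on the ranks).
ranksum_enum <- function(a, b) {
  x <- c(a, b)
  n <- length(x)
  na <- length(a)
  r <- rank(x)
  mu <- na * (n + 1) / 2
  w_obs <- sum(r[seq_len(na)])
  sets <- utils::combn(n, na)
  w_all <- apply(sets, 2L, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# AUC by direct counting over all (case, control) pairs, ties as one half.
auc_paircount <- function(labels, probabilities) {
  pc <- probabilities[labels == "case"]
  pn <- probabilities[labels == "control"]
  total <- 0
  for (ci in pc) {
    total <- total + sum(ci > pn) + 0.5 * sum(ci == pn)
  }
  total / (length(pc) * length(pn))
}

# Exhaustive scan of every threshold for the Youden-index maximiser.
youden_best <- function(labels, probabilities) {
  is_case <- labels == "case"
  u <- sort(unique(probabilities))
  cand <- c(u[1] - 0.5, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 0.5)
  best <- -Inf
  for (th in cand) {
    pred <- probabilities >= th
    se <- sum(pred & is_case) / sum(is_case)
    sp <- sum(!pred & !is_case) / sum(!is_case)
    best <- max(best, abs(se + sp - 1))
  }
  best
}
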
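# Independent oracles and small fixture builders used across the suite.

# O(M^2) brute-force mean pairwise distance (oracle for the prefix-sum
# implementation).
brute_mean_pairwise <- function(x) {
  m <- length(x)
  s <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) s <- s + abs(x[i] - x[j])
  }
  s / (m * (m - 1) / 2)
}

# Sample-level bootstrap SE of an arbitrary dataset statistic (used where
# bootstrap_sem()'s named estimators do not apply, e.g. mixed-class fits).
boot_se_manual <- function(ds, stat_fn, B = 100) {
  n <- length(ds$positions)
  vals <- replicate(B, {
    idx <- sample.int(n, n, replace = TRUE)
    stat_fn(xolint:::.subset_dataset(ds, idx))
  })
  sd(vals)
}

lint_of <- function(ds) {
  suppressWarnings(interference_length(ds, keep_data = FALSE))$l_int
}

# Dataset whose adjacent CO distances are exactly the supplied gaps:
# every sample has two COs, the first at 0.
gaps_dataset <- function(gaps, L = max(gaps) * 1.01) {
  chromosome_dataset(lapply(gaps, function(g) c(0, g)), length_L = L)
}
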
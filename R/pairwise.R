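#' Mean pairwise distance of a set of positions
#'
#' Exact mean of `|x_i - x_j|` over all `choose(M, 2)` unordered pairs,
#' computed in `O(M log M)` by sorting: for sorted positions the sum of all
#' pairwise differences is `sum((2k - 1 - M) * x_k)` over ranks `k`.
#' Identical (to floating tolerance) to the brute-force double loop.
#'
#' @param positions Numeric vector with at least two entries.
#' @return The mean pairwise distance (same units as `positions`).
#' @examples
#' mean_pairwise_distance(c(0, 1))        # 1
#' mean_pairwise_distance(c(0, 0, 1, 1))  # 2/3
#' @export
mean_pairwise_distance <- function(positions) {
  positions <- as.numeric(positions)
  m <- length(positions)
  if (m < 2L) stop("need at least two positions for a pairwise distance")
  if (anyNA(positions)) stop("positions must not contain NA")
  x <- sort(positions)
  .pair_sum_sorted(x) / (m * (m - 1) / 2)
}

# Sum of pairwise differences of an ascending vector.  Shifting by the
# minimum leaves the sum unchanged (the weights sum to zero) but keeps the
# computation exact for constant input and well conditioned otherwise.
.pair_sum_sorted <- function(x) {
  m <- length(x)
  k <- seq_len(m)
  sum((2 * k - 1 - m) * (x - x[1]))
}

# Sum over a in A, b in B of |a - b| (A, B need not be sorted).
.cross_abs_sum <- function(a, b) {
  a <- sort(a)
  na <- length(a)
  cpa <- c(0, cumsum(a))
  idx <- findInterval(b, a)
  tot <- cpa[na + 1L]
  sum(b * idx - cpa[idx + 1L] + (tot - cpa[idx + 1L]) - b * (na - idx))
}
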
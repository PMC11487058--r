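#' Closed-form reference values of the interference length
#'
#' Reference curves for idealized strong-interference scenarios, useful
#' for annotating plots and for checking simulations:
#'
#' * `"complete"` — one uniformly placed obligate CO per chromosome:
#'   `L_int = 2/3 L`, independent of `N`.
#' * `"maximal"` — the maximal interference attainable at a given mean CO
#'   count: `L_int = 4/3 L / N`, capped at `L` (the cap is attained at
#'   `N = 1` when every CO falls at the identical position).  The
#'   configurations achieving this bound for `N >= 2` are not constructed
#'   here; the formula is exposed as a reference curve only.
#' * `"regular"` — `N` COs at fixed spacing `L/N` with a uniformly placed
#'   phase: `L_int = L (1/N - 1/(3 N^2))`; equals `2/3 L` at `N = 1`.
#'
#' @param model Scenario name.
#' @param N Mean CO count (vectorized).
#' @param L Chromosome length.
#' @return Numeric vector of reference interference lengths.
#' @examples
#' theoretical_lint("regular", N = 1:5)
#' @export
theoretical_lint <- function(model = c("complete", "maximal", "regular"),
                             N, L = 1) {
  model <- match.arg(model)
  N <- as.numeric(N)
  if (any(!is.finite(N) | N <= 0)) stop("`N` must be positive")
  switch(model,
         complete = rep_len(2 / 3 * L, length(N)),
         maximal = pmin(4 / 3 * L / N, L),
         regular = L * (1 / N - 1 / (3 * N^2)))
}
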
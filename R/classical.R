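#' Coefficient-of-coincidence curve
#'
#' The classical binned quantification of crossover interference.  The
#' chromosome is partitioned into `bin_count` equal intervals; for every
#' ordered bin pair `i < j` the observed co-occurrence frequency `f_ij`
#' (fraction of samples with at least one CO in bin `i` AND at least one in
#' bin `j`) is compared with the product `f_i f_j` expected under
#' independence.  Curve points aggregate bin pairs at the same
#' centre-to-centre separation using a ratio of sums,
#' `CoC(s) = sum(f_ij) / sum(f_i f_j)`, which stays stable when individual
#' expected frequencies are tiny.  Bin pairs with zero expected frequency
#' are dropped; separations whose expected sum is zero yield no curve
#' point.  Without interference the curve sits near 1; interference
#' suppresses close double-COs and pulls the curve towards 0 at short
#' separations.
#'
#' The bin count is a genuine tuning knob with no canonical value; 15 is a
#' usable default for a few thousand samples, not a privileged choice.
#'
#' @param dataset A [chromosome_dataset()] with at least one CO.
#' @param bin_count Number of equal-width bins (at least 2).
#' @return An object of class `coc_curve` with fields `separations`
#'   (increasing, length units), `coc_values`, `n_pairs` (bin pairs
#'   aggregated per point), `bin_count`, `L`, and `d_coc` (the 0.5-crossing
#'   separation from [interference_distance()], `NA` when the curve never
#'   crosses).
#' @examples
#' ds <- simulate_crossovers("poisson", n_samples = 5000, mean_count = 2,
#'                           seed = 1)
#' coc_curve(ds, bin_count = 10)
#' @export
coc_curve <- function(dataset, bin_count = 15) {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  if (!.is_count(bin_count, min = 2L)) {
    stop("`bin_count` must be an integer >= 2")
  }
  bin_count <- as.integer(bin_count)
  L <- dataset$length_L
  n <- length(dataset$positions)
  counts <- lengths(dataset$positions)
  if (sum(counts) == 0L) {
    stop("degenerate dataset: no crossovers observed")
  }
  pos <- unlist(dataset$positions, use.names = FALSE)
  bin <- pmin(floor(pos / L * bin_count) + 1L, bin_count)
  row <- rep.int(seq_len(n), counts)
  P <- matrix(0, n, bin_count)
  P[cbind(row, bin)] <- 1
  f <- colMeans(P)
  if (all(f == 0)) stop("degenerate dataset: all bins empty")
  f_ij <- crossprod(P) / n

  w <- L / bin_count
  seps <- seq_len(bin_count - 1L)
  num <- den <- npair <- numeric(length(seps))
  for (k in seps) {
    i <- seq_len(bin_count - k)
    j <- i + k
    exp_ij <- f[i] * f[j]
    keep <- exp_ij > 0
    num[k] <- sum(f_ij[cbind(i, j)][keep])
    den[k] <- sum(exp_ij[keep])
    npair[k] <- sum(keep)
  }
  ok <- den > 0
  curve <- structure(list(separations = seps[ok] * w,
                          coc_values = num[ok] / den[ok],
                          n_pairs = npair[ok],
                          bin_count = bin_count,
                          L = L,
                          d_coc = NA_real_),
                     class = "coc_curve")
  if (length(curve$separations)) {
    curve$d_coc <- suppressWarnings(interference_distance(curve))
  }
  curve
}

#' @export
print.coc_curve <- function(x, digits = 3, ...) {
  cat("<coc_curve> ", x$bin_count, " bins, L = ", format(x$L), "\n",
      sep = "")
  print(data.frame(separation = signif(x$separations, digits),
                   coc = signif(x$coc_values, digits),
                   n_pairs = x$n_pairs))
  cat("d_CoC (first 0.5-crossing): ",
      if (is.na(x$d_coc)) "not reached" else format(x$d_coc,
                                                    digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.coc_curve <- function(x, ...) {
  graphics::plot(x$separations, x$coc_values, type = "b", pch = 16,
                 xlab = "CO separation", ylab = "coefficient of coincidence",
                 ylim = c(0, max(1.2, x$coc_values)), ...)
  graphics::abline(h = c(0.5, 1), lty = c(2, 3), col = "grey50")
  if (!is.na(x$d_coc)) {
    graphics::abline(v = x$d_coc, col = "darkorange", lwd = 2)
  }
  invisible(x)
}

#' Interference distance of a CoC curve
#'
#' The separation at which the coefficient-of-coincidence curve first
#' exceeds 0.5, located by scanning the curve in increasing separation and
#' linearly interpolating the first upward crossing.  If the curve already
#' starts at or above 0.5 (no interference at any resolved separation) the
#' distance is 0 by convention; if it never reaches 0.5 the distance is
#' undefined (`NA`, with a warning).
#'
#' @param curve A [coc_curve()].
#' @return The interference distance in length units, `0`, or `NA`.
#' @export
interference_distance <- function(curve) {
  stopifnot(inherits(curve, "coc_curve"))
  s <- curve$separations
  v <- curve$coc_values
  if (!length(s)) stop("empty CoC curve")
  if (v[1] >= 0.5) return(0)
  above <- which(v >= 0.5)
  if (!length(above)) {
    warning("CoC curve never reaches 0.5; interference distance undefined")
    return(NA_real_)
  }
  i <- above[1]
  s[i - 1] + (0.5 - v[i - 1]) * (s[i] - s[i - 1]) / (v[i] - v[i - 1])
}

#' Gamma shape of adjacent inter-crossover distances
#'
#' Fits a two-parameter gamma distribution by maximum likelihood to the
#' distances between adjacent COs, pooled across all samples with at least
#' two COs.  The shape parameter quantifies the evenness of CO spacing:
#' shape 1 (exponential) corresponds to independent placement, larger
#' shapes to increasingly regular spacing, i.e. stronger interference.
#'
#' The MLE solves the profile-likelihood equation
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))` (a single
#' monotone root found by [stats::uniroot()]); the scale then follows as
#' `mean(x) / shape`.  Exact zero distances (coincident foci at resolution
#' limits) are replaced by `L * 1e-9` to keep the likelihood finite.
#' Distances are not corrected for censoring by the chromosome ends; for
#' typical CO densities the resulting bias is small but pulls the fitted
#' shape slightly away from the data-generating value.
#'
#' @param dataset A [chromosome_dataset()].
#' @param min_distances Minimum number of pooled adjacent distances
#'   (default 10); below this the fit is refused since only samples with
#'   two or more COs contribute.
#' @return An object of class `gamma_fit` with fields `shape_nu`, `scale`
#'   (length units) and `n_distances`.
#' @examples
#' ds <- simulate_crossovers("renewal", n_samples = 2000, mean_count = 5,
#'                           shape = 5, seed = 1)
#' gamma_shape(ds)
#' @export
gamma_shape <- function(dataset, min_distances = 10L) {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  N <- lengths(dataset$positions)
  gaps <- unlist(lapply(dataset$positions[N >= 2L], diff),
                 use.names = FALSE)
  if (length(gaps) < min_distances) {
    stop("insufficient data: ", length(gaps), " adjacent CO distances ",
         "(need at least ", min_distances,
         "; only samples with >= 2 COs contribute)")
  }
  gaps[gaps <= 0] <- dataset$length_L * 1e-9
  mx <- mean(gaps)
  s <- log(mx) - mean(log(gaps))
  if (s < 1e-10) {
    stop("adjacent distances are (nearly) constant; ",
         "gamma shape is unbounded")
  }
  f <- function(a) log(a) - digamma(a) - s
  shape <- stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
  structure(list(shape_nu = shape,
                 scale = mx / shape,
                 n_distances = length(gaps)),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, digits = 4, ...) {
  cat("<gamma_fit> adjacent CO distances\n")
  cat("  shape nu = ", format(x$shape_nu, digits = digits),
      ",  scale = ", format(x$scale, digits = digits),
      ",  n = ", x$n_distances, "\n", sep = "")
  invisible(x)
}
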
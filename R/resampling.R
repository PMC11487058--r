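# Resampling-based uncertainty and significance machinery.
#
# The meiotic product (cell / gamete chromatid) is the exchangeable unit,
# so all procedures resample whole samples, preserving within-sample CO
# patterns.

.estimator_names <- c("lint", "lintnorm", "dcoc", "gamma")

# Returns a function(dataset) -> numeric scalar or NA on degenerate input.
.make_estimator <- function(estimator, bins = 15) {
  estimator <- match.arg(estimator, .estimator_names)
  fn <- switch(estimator,
    lint = function(ds) .lint_core(ds$positions, ds$length_L),
    lintnorm = function(ds) .lint_core(ds$positions, ds$length_L,
                                       normalized = TRUE),
    dcoc = function(ds) {
      cc <- coc_curve(ds, bin_count = bins)
      suppressWarnings(interference_distance(cc))
    },
    gamma = function(ds) gamma_shape(ds)$shape_nu)
  function(ds) {
    tryCatch(suppressWarnings(fn(ds)), error = function(e) NA_real_)
  }
}

.check_replicates <- function(replicates) {
  if (!.is_count(replicates, min = 100L)) {
    stop("`replicates` must be an integer >= 100")
  }
  as.integer(replicates)
}

#' Bootstrap standard error of an interference estimator
#'
#' Nonparametric bootstrap over samples: whole meiotic products are
#' resampled with replacement and the estimator recomputed on each
#' replicate; the reported SEM is the standard deviation of the replicate
#' estimates.  Replicates on which the estimator is degenerate (e.g. a
#' resample without CO pairs for the gamma fit, or a CoC curve that never
#' crosses 0.5) are redrawn; if fewer than `replicates` usable replicates
#' are obtained within a 10-fold draw budget, the resampling fails.
#'
#' @param dataset A [chromosome_dataset()] with at least 2 samples.
#' @param estimator One of `"lint"` (interference length), `"lintnorm"`
#'   (normalized interference length), `"dcoc"` (CoC interference
#'   distance), `"gamma"` (gamma shape of adjacent distances).
#' @param replicates Number of bootstrap replicates (at least 100).
#' @param seed Optional RNG seed; given the seed the result is
#'   reproducible bit for bit.
#' @param bins Bin count forwarded to [coc_curve()] for `"dcoc"`.
#' @return An object of class `resample_result` with fields
#'   `point_estimate`, `sem`, `replicates`, `seed` and `estimator`.
#' @examples
#' ds <- simulate_crossovers("obligate", n_samples = 300, seed = 1)
#' bootstrap_sem(ds, "lint", replicates = 200, seed = 2)
#' @export
bootstrap_sem <- function(dataset, estimator = c("lint", "lintnorm",
                                                 "dcoc", "gamma"),
                          replicates = 200, seed = NULL, bins = 15) {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  estimator <- match.arg(estimator)
  replicates <- .check_replicates(replicates)
  n <- length(dataset$positions)
  if (n < 2L) {
    stop("resampling error: need at least 2 samples to bootstrap")
  }
  est <- .make_estimator(estimator, bins = bins)
  point <- est(dataset)
  if (is.na(point)) {
    stop("estimator '", estimator, "' is degenerate on the input dataset")
  }
  vals <- .with_seed(seed, function() {
    out <- numeric(replicates)
    got <- 0L
    draws <- 0L
    max_draws <- 10L * replicates
    while (got < replicates) {
      if (draws >= max_draws) {
        stop("resampling error: persistent degeneracy ",
             "(more than 10x replicate inflation)")
      }
      draws <- draws + 1L
      v <- est(.subset_dataset(dataset, sample.int(n, n, replace = TRUE)))
      if (!is.na(v)) {
        got <- got + 1L
        out[got] <- v
      }
    }
    out
  })
  structure(list(point_estimate = point,
                 sem = stats::sd(vals),
                 replicates = replicates,
                 seed = seed,
                 estimator = estimator),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, digits = 4, ...) {
  cat("<resample_result> estimator '", x$estimator, "'\n", sep = "")
  cat("  point estimate = ", format(x$point_estimate, digits = digits),
      ",  bootstrap SEM = ", format(x$sem, digits = digits),
      "  (", x$replicates, " replicates)\n", sep = "")
  invisible(x)
}

#' Permutation test comparing two chromosome datasets
#'
#' Tests the null hypothesis that two datasets (e.g. male vs female, or
#' genetic vs cytological after space conversion) share the same value of
#' an interference estimator.  Samples are pooled and repeatedly
#' reassigned at random to two groups of the original sizes; the statistic
#' is the absolute difference of the group estimates, and the two-sided
#' p-value uses the add-one rule `(k + 1) / (B + 1)` so it can never be
#' exactly zero.  Degenerate permutation replicates are redrawn (10-fold
#' budget).
#'
#' @param a,b [chromosome_dataset()] objects in the same coordinate space
#'   with the same chromosome length.
#' @param estimator,replicates,seed,bins As in [bootstrap_sem()].
#' @return An object of class `interference_test` with fields `statistic`,
#'   `p_value`, `replicates`, `seed` and `kind = "two_sample"`.
#' @export
test_two_sample <- function(a, b, estimator = c("lint", "lintnorm",
                                                "dcoc", "gamma"),
                            replicates = 999, seed = NULL, bins = 15) {
  stopifnot(inherits(a, "chromosome_dataset"),
            inherits(b, "chromosome_dataset"))
  estimator <- match.arg(estimator)
  replicates <- .check_replicates(replicates)
  if (a$space != b$space) {
    stop("datasets live in different coordinate spaces; convert first")
  }
  if (abs(a$length_L - b$length_L) > 1e-9 * a$length_L) {
    stop("datasets have different chromosome lengths; pooling is invalid")
  }
  est <- .make_estimator(estimator, bins = bins)
  ea <- est(a)
  eb <- est(b)
  if (is.na(ea) || is.na(eb)) {
    stop("estimator '", estimator, "' is degenerate on an input dataset")
  }
  statistic <- abs(ea - eb)
  na <- length(a$positions)
  nb <- length(b$positions)
  pooled <- .new_dataset(positions = c(a$positions, b$positions),
                         classes = NULL,
                         sample_ids = c(a$sample_ids, b$sample_ids),
                         length_L = a$length_L,
                         chromosome_id = a$chromosome_id,
                         space = a$space)
  k <- .with_seed(seed, function() {
    hits <- 0L
    got <- 0L
    draws <- 0L
    max_draws <- 10L * replicates
    while (got < replicates) {
      if (draws >= max_draws) {
        stop("resampling error: persistent degeneracy in permutations")
      }
      draws <- draws + 1L
      idx <- sample.int(na + nb, na)
      va <- est(.subset_dataset(pooled, idx))
      vb <- est(.subset_dataset(pooled, setdiff(seq_len(na + nb), idx)))
      if (is.na(va) || is.na(vb)) next
      got <- got + 1L
      if (abs(va - vb) >= statistic) hits <- hits + 1L
    }
    hits
  })
  structure(list(statistic = statistic,
                 p_value = (k + 1) / (replicates + 1),
                 replicates = replicates,
                 seed = seed,
                 kind = "two_sample",
                 estimator = estimator),
            class = "interference_test")
}

#' Parametric bootstrap test against the no-interference null
#'
#' Tests whether a dataset shows positive crossover interference.  The
#' fitted null places, per sample, a Poisson-distributed number of COs
#' (observed mean `<N>`) independently at positions drawn from the pooled
#' empirical positions, preserving the CO density along the chromosome.
#' The one-sided p-value is the add-one fraction of null replicates whose
#' estimate is at least the observed one (interference pushes all four
#' estimators upward).
#'
#' @param dataset A [chromosome_dataset()].
#' @param estimator,replicates,seed,bins As in [bootstrap_sem()].
#' @return An object of class `interference_test` with
#'   `kind = "vs_null"`.
#' @export
test_vs_null <- function(dataset, estimator = c("lint", "lintnorm",
                                                "dcoc", "gamma"),
                         replicates = 999, seed = NULL, bins = 15) {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  estimator <- match.arg(estimator)
  replicates <- .check_replicates(replicates)
  est <- .make_estimator(estimator, bins = bins)
  observed <- est(dataset)
  if (is.na(observed)) {
    stop("estimator '", estimator, "' is degenerate on the input dataset")
  }
  n <- length(dataset$positions)
  mu <- mean(lengths(dataset$positions))
  pooled <- unlist(dataset$positions, use.names = FALSE)
  k <- .with_seed(seed, function() {
    hits <- 0L
    got <- 0L
    draws <- 0L
    max_draws <- 10L * replicates
    while (got < replicates) {
      if (draws >= max_draws) {
        stop("resampling error: persistent degeneracy in null replicates")
      }
      draws <- draws + 1L
      null_ds <- .sample_null_dataset(pooled, n, mu, dataset$length_L,
                                      dataset$chromosome_id,
                                      dataset$space)
      v <- est(null_ds)
      if (is.na(v)) next
      got <- got + 1L
      if (v >= observed) hits <- hits + 1L
    }
    hits
  })
  structure(list(statistic = observed,
                 p_value = (k + 1) / (replicates + 1),
                 replicates = replicates,
                 seed = seed,
                 kind = "vs_null",
                 estimator = estimator),
            class = "interference_test")
}

#' @export
print.interference_test <- function(x, digits = 4, ...) {
  lab <- switch(x$kind,
                two_sample = "permutation test (two-sample)",
                vs_null = "parametric bootstrap test vs no-interference null")
  cat("<interference_test> ", lab, ", estimator '", x$estimator, "'\n",
      sep = "")
  cat("  statistic = ", format(x$statistic, digits = digits),
      ",  p = ", format(x$p_value, digits = digits),
      "  (", x$replicates, " replicates)\n", sep = "")
  invisible(x)
}
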
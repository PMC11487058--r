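#' Simulate crossover placement scenarios
#'
#' Generative models for canonical crossover-placement scenarios, used both
#' to explore the behaviour of the estimators and as the fixture generator
#' for the test suite:
#'
#' * `"poisson"` (alias `poisson_null`) — the no-interference null: CO
#'   count per sample is Poisson(`mean_count`), positions i.i.d. from
#'   `position_density`.  The interference length is 0 in expectation.
#' * `"obligate"` — complete interference: exactly one CO per sample drawn
#'   from `position_density`.  With a uniform density the interference
#'   length is 2/3 of the chromosome length.
#' * `"regular"` (alias `regular_placement`) — exactly `N = mean_count`
#'   (integer) COs at fixed spacing `L/N`, the first placed uniformly on
#'   `[0, L/N]` so the marginal CO density is uniform.  Closed form:
#'   `L_int = L (1/N - 1/(3 N^2))`.
#' * `"fixed"` (alias `fixed_position`) — exactly one CO at `L/2` in every
#'   sample; the degenerate maximum `L_int = L`.
#' * `"renewal"` (alias `renewal_gamma`) — a stationary gamma renewal
#'   process with inter-arrival distances Gamma(shape `shape`, rate
#'   `shape * mean_count / L`), giving expected count `mean_count` and
#'   interference strength tunable through the shape; shape 1 reproduces
#'   the Poisson null exactly.  The first arrival is drawn from the
#'   equilibrium (stationary-excess) distribution, sampled as a uniform
#'   fraction of a length-biased inter-arrival, i.e.
#'   `U * Gamma(shape + 1, rate)`.  This is not a mechanistic model of
#'   interference, merely the standard tunable generator.
#'
#' @param model Scenario name (short or long alias).
#' @param n_samples Number of samples to generate.
#' @param length_L Chromosome length.
#' @param mean_count Target mean CO count (an integer `N` for
#'   `"regular"`; ignored by `"fixed"`).
#' @param shape Gamma shape of the renewal inter-arrival distribution
#'   (`"renewal"` only; larger = more regular spacing).
#' @param position_density Positional density on `[0, L]` for `"poisson"`
#'   and `"obligate"`: `"uniform"`, `"bimodal"` (an even mixture of
#'   Beta(2, 8) and Beta(8, 2) scaled to `[0, L]`), or a function
#'   `function(m)` returning `m` positions in `[0, L]`.
#' @param seed Optional RNG seed; the output is a deterministic function
#'   of the configuration and seed.
#' @param chromosome_id,space Metadata for the resulting dataset.
#' @return A [chromosome_dataset()] with `n_samples` samples.
#' @examples
#' simulate_crossovers("regular", n_samples = 5, mean_count = 3, seed = 1)
#' @export
simulate_crossovers <- function(model = c("poisson", "obligate", "regular",
                                          "fixed", "renewal"),
                                n_samples, length_L = 1, mean_count = 2,
                                shape = 5, position_density = "uniform",
                                seed = NULL, chromosome_id = "sim",
                                space = c("dna_mb", "sc_um")) {
  model <- as.character(model)[1]
  alias <- c(poisson_null = "poisson", regular_placement = "regular",
             fixed_position = "fixed", renewal_gamma = "renewal")
  if (model %in% names(alias)) model <- alias[[model]]
  model <- match.arg(model, c("poisson", "obligate", "regular", "fixed",
                              "renewal"))
  space <- match.arg(space)
  if (!.is_count(n_samples)) stop("`n_samples` must be a positive integer")
  if (!.is_number(length_L) || length_L <= 0) {
    stop("`length_L` must be positive")
  }
  n <- as.integer(n_samples)
  L <- length_L

  positions <- .with_seed(seed, function() {
    switch(model,
      poisson = {
        if (!.is_number(mean_count) || mean_count <= 0) {
          stop("`mean_count` must be positive")
        }
        rdens <- .density_sampler(position_density, L)
        counts <- stats::rpois(n, mean_count)
        pos <- rdens(sum(counts))
        idx <- rep.int(seq_len(n), counts)
        o <- order(idx, pos)
        out <- split(pos[o], factor(idx[o], levels = seq_len(n)))
        names(out) <- NULL
        out
      },
      obligate = {
        rdens <- .density_sampler(position_density, L)
        as.list(rdens(n))
      },
      regular = {
        N <- as.integer(round(mean_count))
        if (N < 1L || abs(mean_count - N) > 1e-8) {
          stop("`mean_count` must be a positive integer for the ",
               "regular-placement model")
        }
        x0 <- stats::runif(n, 0, L / N)
        offsets <- (seq_len(N) - 1L) * L / N
        mat <- matrix(x0, n, N) +
          matrix(offsets, n, N, byrow = TRUE)
        out <- split(mat, row(mat))
        names(out) <- NULL
        out
      },
      fixed = {
        rep(list(L / 2), n)
      },
      renewal = {
        if (!.is_number(shape) || shape <= 0) {
          stop("`shape` must be positive")
        }
        if (!.is_number(mean_count) || mean_count <= 0) {
          stop("`mean_count` must be positive")
        }
        .simulate_renewal(n, L, mean_count, shape)
      })
  })
  .new_dataset(positions = positions, classes = NULL,
               sample_ids = paste0("s", seq_len(n)),
               length_L = L, chromosome_id = chromosome_id, space = space)
}

.density_sampler <- function(position_density, L) {
  if (is.function(position_density)) {
    return(function(m) {
      x <- position_density(m)
      if (length(x) != m || anyNA(x) || any(x < 0 | x > L)) {
        stop("custom position density returned positions outside [0, L]")
      }
      x
    })
  }
  switch(match.arg(position_density, c("uniform", "bimodal")),
    uniform = function(m) stats::runif(m, 0, L),
    bimodal = function(m) {
      left <- stats::runif(m) < 0.5
      x <- numeric(m)
      x[left] <- stats::rbeta(sum(left), 2, 8)
      x[!left] <- stats::rbeta(sum(!left), 8, 2)
      L * x
    })
}

# Stationary gamma renewal process on [0, L]; rate = shape * mean / L so
# the mean inter-arrival is L / mean and the expected count is `mean`.
.simulate_renewal <- function(n, L, mean_count, shape) {
  rate <- shape * mean_count / L
  # equilibrium first arrival: uniform fraction of a length-biased gap
  cur <- stats::runif(n) * stats::rgamma(n, shape + 1, rate = rate)
  K <- ceiling(mean_count + 10 * sqrt(mean_count + 1) + 10)
  times <- matrix(NA_real_, n, K + 1L)
  times[, 1L] <- cur
  for (j in seq_len(K)) {
    cur <- cur + stats::rgamma(n, shape, rate = rate)
    times[, j + 1L] <- cur
  }
  # rare samples whose K-th arrival is still inside the window
  unfinished <- which(times[, K + 1L] <= L)
  extra <- list()
  for (i in unfinished) {
    t <- times[i, K + 1L]
    more <- numeric()
    repeat {
      t <- t + stats::rgamma(1, shape, rate = rate)
      if (t > L) break
      more <- c(more, t)
    }
    extra[[as.character(i)]] <- more
  }
  keep <- times <= L
  f <- factor(row(times)[keep], levels = seq_len(n))
  out <- split(times[keep], f)
  names(out) <- NULL
  for (nm in names(extra)) {
    i <- as.integer(nm)
    out[[i]] <- c(out[[i]], extra[[nm]])
  }
  out
}

#' Random sub-sampling (binomial thinning) of crossovers
#'
#' Retains each CO independently with probability `p`, emulating random
#' detection loss (e.g. a designated CO appearing in only half the
#' gametes).  The interference length is invariant in expectation under
#' this operation, which is what makes cytological and genetic data
#' comparable.
#'
#' @param dataset A [chromosome_dataset()].
#' @param p Retention probability in `[0, 1]`.
#' @param seed Optional RNG seed.
#' @return A `chromosome_dataset` with thinned samples (empty samples are
#'   retained as empty).
#' @export
subsample_crossovers <- function(dataset, p, seed = NULL) {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  if (!.is_number(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]")
  }
  counts <- lengths(dataset$positions)
  n <- length(counts)
  .with_seed(seed, function() {
    keep <- stats::runif(sum(counts)) < p
    idx <- rep.int(seq_len(n), counts)
    pos <- unlist(dataset$positions, use.names = FALSE)
    f <- factor(idx[keep], levels = seq_len(n))
    positions <- split(pos[keep], f)
    names(positions) <- NULL
    classes <- NULL
    if (!is.null(dataset$classes)) {
      cls <- unlist(dataset$classes, use.names = FALSE)
      classes <- split(cls[keep], f)
      names(classes) <- NULL
    }
    .new_dataset(positions = positions, classes = classes,
                 sample_ids = dataset$sample_ids,
                 length_L = dataset$length_L,
                 chromosome_id = dataset$chromosome_id,
                 space = dataset$space)
  })
}
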
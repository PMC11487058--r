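#' Crossover pair bookkeeping for one chromosome
#'
#' Computes the quantities that the interference length is built from.
#' With `N_s` the CO count of sample `s` and `n` samples (zero-CO samples
#' included):
#'
#' * `mean_count` — mean CO count `<N>`;
#' * `n_obs_pair` — mean number of observed same-sample CO pairs,
#'   `mean(N (N - 1) / 2)`;
#' * `n_noint_pair` — expected pairs under the no-interference null, where
#'   `N` is Poisson with the observed mean, `<N>^2 / 2`;
#' * `n_mis_pair` — missing pairs, `n_noint_pair - n_obs_pair` (negative
#'   when COs cluster more than the Poisson null predicts);
#' * `phi` — ratio of observed to expected pairs,
#'   `n_obs_pair / n_noint_pair`;
#' * `d_obs` — mean distance over all observed same-sample CO pairs, every
#'   pair weighted equally (`NA` if no sample has two COs);
#' * `d_noint` — mean distance over all unordered pairs of distinct CO
#'   instances in the pooled position multiset, which preserves the
#'   observed CO density along the chromosome;
#' * `d_mis` — the distance assigned to missing pairs, fixed at the
#'   chromosome length `L`;
#' * `d_int` — pair-weighted average
#'   `(n_obs_pair * d_obs + n_mis_pair * d_mis) / n_noint_pair`, reported
#'   only when `n_mis_pair >= 0` (with a negative weight the weighted
#'   average loses its interpretation; the interference length itself
#'   remains well defined).
#'
#' @param dataset A [chromosome_dataset()] with at least two COs in the
#'   pooled data.
#' @return An object of class `pair_statistics`.
#' @examples
#' ds <- chromosome_dataset(list(c(0.2, 0.8), 0.5, c(0.1, 0.9)),
#'                          length_L = 1)
#' pair_statistics(ds)
#' @export
pair_statistics <- function(dataset) {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  N <- lengths(dataset$positions)
  n <- length(N)
  L <- dataset$length_L
  mean_count <- mean(N)
  if (mean_count == 0) {
    stop("degenerate dataset: no crossovers observed (<N> = 0)")
  }
  pooled <- unlist(dataset$positions, use.names = FALSE)
  M <- length(pooled)
  if (M < 2L) {
    stop("degenerate dataset: fewer than two crossovers in the pooled data")
  }
  d_noint <- .pair_sum_sorted(sort(pooled)) / (M * (M - 1) / 2)

  n_obs_pair <- sum(N * (N - 1)) / 2 / n
  n_noint_pair <- mean_count^2 / 2
  n_mis_pair <- n_noint_pair - n_obs_pair
  phi <- n_obs_pair / n_noint_pair

  if (n_obs_pair > 0) {
    k <- sequence(N)
    Ns <- rep.int(N, N)
    # per-sample shift: weights sum to zero within each sample
    shift <- rep.int(vapply(dataset$positions[N > 0L], `[`, numeric(1), 1L),
                     N[N > 0L])
    d_obs <- sum((2 * k - 1 - Ns) * (pooled - shift)) /
      (sum(N * (N - 1)) / 2)
  } else {
    d_obs <- NA_real_
  }
  d_int <- if (n_mis_pair >= 0) {
    d_obs0 <- if (is.na(d_obs)) 0 else d_obs
    (n_obs_pair * d_obs0 + n_mis_pair * L) / n_noint_pair
  } else {
    NA_real_
  }
  structure(list(mean_count = mean_count,
                 n_obs_pair = n_obs_pair,
                 n_noint_pair = n_noint_pair,
                 n_mis_pair = n_mis_pair,
                 phi = phi,
                 d_obs = d_obs,
                 d_noint = d_noint,
                 d_mis = L,
                 d_int = d_int,
                 n_samples = n,
                 L = L),
            class = "pair_statistics")
}

#' @export
print.pair_statistics <- function(x, digits = 4, ...) {
  cat("<pair_statistics>  (", x$n_samples, " samples, L = ",
      format(x$L), ")\n", sep = "")
  v <- c("<N>" = x$mean_count, "N_obs^pair" = x$n_obs_pair,
         "N_noInt^pair" = x$n_noint_pair, "N_mis^pair" = x$n_mis_pair,
         "phi" = x$phi, "d_obs" = x$d_obs, "d_noInt" = x$d_noint,
         "d_mis" = x$d_mis, "d_int" = x$d_int)
  print(signif(v, digits))
  invisible(x)
}

# Fast internal evaluation of L_int (no S3 object, no warnings); returns
# NA on degenerate input instead of erroring.  Used by the resampling code.
.lint_core <- function(positions, L, normalized = FALSE) {
  N <- lengths(positions)
  n <- length(N)
  mean_count <- mean(N)
  if (mean_count == 0) return(NA_real_)
  pooled <- unlist(positions, use.names = FALSE)
  M <- length(pooled)
  if (M < 2L) return(NA_real_)
  d_noint <- .pair_sum_sorted(sort(pooled)) / (M * (M - 1) / 2)
  n_obs_pair <- sum(N * (N - 1)) / 2 / n
  n_noint_pair <- mean_count^2 / 2
  phi <- n_obs_pair / n_noint_pair
  if (n_obs_pair > 0) {
    k <- sequence(N)
    Ns <- rep.int(N, N)
    shift <- rep.int(vapply(positions[N > 0L], `[`, numeric(1), 1L),
                     N[N > 0L])
    d_obs <- sum((2 * k - 1 - Ns) * (pooled - shift)) /
      (sum(N * (N - 1)) / 2)
    l_int <- phi * (d_obs - d_noint) + (1 - phi) * (L - d_noint)
  } else {
    l_int <- L - d_noint
  }
  if (normalized) l_int * mean_count / L else l_int
}

#' Interference length of a chromosome dataset
#'
#' Fits the interference length `L_int`, a statistic of crossover
#' interference with units of length.  It measures the interference-induced
#' increase in the mean distance over all same-sample CO pairs relative to
#' a null in which COs are placed independently along the chromosome
#' (Poisson CO count with the observed mean `<N>`, positions drawn from the
#' pooled observed positions).  Pairs that are missing relative to the null
#' are assigned the maximal observable distance, the chromosome length `L`:
#'
#' `L_int = phi (d_obs - d_noInt) + (1 - phi) (L - d_noInt)`,
#'
#' with `phi = 2 Nbar_obs^pair / <N>^2` the ratio of observed to expected
#' CO pairs (see [pair_statistics()]).  `L_int = 0` without interference,
#' and `L_int` grows to the order of `L` under strong interference (2/3 L
#' for a single uniformly placed obligate CO; exactly `L` in the degenerate
#' case where every sample has one CO at the same position).  The
#' normalized interference length `L_int^norm = L_int <N> / L` is a
#' dimensionless measure of the regularity of CO placement.
#'
#' When more CO pairs are observed than the Poisson null predicts
#' (clustering, i.e. negative interference), the formula is still evaluated
#' as written, can yield a negative `L_int`, and a warning is raised.
#'
#' @param dataset A [chromosome_dataset()].
#' @param bivalent_correction Logical; if `TRUE`, `<N>` is doubled in the
#'   normalized interference length.  Set this for genetic (gamete) data,
#'   where each CO is detected in only half the gametes, so that counts per
#'   chromatid are half the counts per bivalent.  `L_int` itself is
#'   invariant to such random sub-sampling and needs no correction.
#' @param sem_replicates If positive (at least 100), attach a bootstrap
#'   standard error computed by [bootstrap_sem()] with this many
#'   replicates.
#' @param seed Optional seed for the bootstrap.
#' @param keep_data Logical; keep the dataset inside the fit (needed by the
#'   `plot` and `simulate` methods).
#' @return An object of class `interference_length` with fields `l_int`,
#'   `l_int_norm`, `n_samples`, `pair_stats`, `sem` (possibly `NULL`), and
#'   the chromosome metadata.  Methods: `print`, `summary`, `coef`
#'   (returns `c(L_int, L_int_norm)`), `plot` (cumulative pair-distance
#'   comparison against the null), `simulate` (datasets drawn from the
#'   fitted no-interference null).
#' @examples
#' ds <- simulate_crossovers("obligate", n_samples = 2000, seed = 1)
#' fit <- interference_length(ds)
#' fit                 # L_int close to 2/3 for a uniform obligate CO
#' coef(fit)
#' @export
interference_length <- function(dataset, bivalent_correction = FALSE,
                                sem_replicates = 0, seed = NULL,
                                keep_data = TRUE) {
  ps <- pair_statistics(dataset)
  if (ps$n_mis_pair < 0) {
    warning("more CO pairs observed than the Poisson null predicts ",
            "(negative interference / clustering); L_int may be negative")
  }
  term_obs <- if (ps$phi > 0) ps$phi * (ps$d_obs - ps$d_noint) else 0
  l_int <- term_obs + (1 - ps$phi) * (ps$L - ps$d_noint)
  count <- ps$mean_count * (if (isTRUE(bivalent_correction)) 2 else 1)
  obj <- structure(list(l_int = l_int,
                        l_int_norm = l_int * count / ps$L,
                        n_samples = ps$n_samples,
                        pair_stats = ps,
                        sem = NULL,
                        bivalent_correction = isTRUE(bivalent_correction),
                        chromosome_id = dataset$chromosome_id,
                        space = dataset$space,
                        L = ps$L,
                        data = if (isTRUE(keep_data)) dataset else NULL,
                        call = match.call()),
                   class = "interference_length")
  if (sem_replicates > 0) {
    obj$sem <- bootstrap_sem(dataset, estimator = "lint",
                             replicates = sem_replicates, seed = seed)$sem
  }
  obj
}

#' Interference length between two crossover classes
#'
#' Cross-class analogue of [interference_length()], quantifying how COs of
#' one class (e.g. class I, MLH1-positive) interfere with the positioning
#' of another class (e.g. class II).  Observed pairs per sample are the
#' `N_a * N_b` pairs with one CO of each class; under independence the
#' expected number is `<N_a> <N_b>`, giving
#' `phi_mix = <N_a N_b> / (<N_a> <N_b>)`.  `d_obs` is the mean distance
#' over observed cross-class pairs and `d_noInt` the mean distance between
#' one draw from the pooled class-a positions and one from the pooled
#' class-b positions; then
#' `L_int^mix = phi_mix (d_obs - d_noInt) + (1 - phi_mix) (L - d_noInt)`.
#'
#' COs labelled `"unknown"` are excluded.  If `class_a == class_b` the
#' cross-class bookkeeping degenerates and the standard estimator is
#' applied to the dataset restricted to that class.
#'
#' @param dataset A [chromosome_dataset()] with class labels.
#' @param class_a,class_b CO class labels, `"I"` or `"II"`.
#' @return An object of class `interference_length` (with
#'   `kind = "mixed"` and mixed-pair bookkeeping in `pair_stats` when the
#'   classes differ).
#' @export
mixed_interference_length <- function(dataset, class_a = "I",
                                      class_b = "II") {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  if (is.null(dataset$classes)) {
    stop("dataset has no CO class labels")
  }
  class_a <- match.arg(class_a, c("I", "II"))
  class_b <- match.arg(class_b, c("I", "II"))
  if (class_a == class_b) {
    sub <- .filter_class(dataset, class_a)
    fit <- interference_length(sub)
    fit$kind <- "single_class"
    fit$classes_used <- class_a
    return(fit)
  }
  A <- lapply(seq_along(dataset$positions), function(i) {
    dataset$positions[[i]][dataset$classes[[i]] == class_a]
  })
  B <- lapply(seq_along(dataset$positions), function(i) {
    dataset$positions[[i]][dataset$classes[[i]] == class_b]
  })
  Na <- lengths(A)
  Nb <- lengths(B)
  L <- dataset$length_L
  n <- length(Na)
  if (sum(Na) == 0L) stop("degenerate input: no class ", class_a, " COs")
  if (sum(Nb) == 0L) stop("degenerate input: no class ", class_b, " COs")
  mean_ab <- mean(Na * Nb)
  n_noint_pair <- mean(Na) * mean(Nb)
  phi_mix <- mean_ab / n_noint_pair
  if (mean_ab > 0) {
    cross_sum <- 0
    for (i in which(Na * Nb > 0L)) {
      cross_sum <- cross_sum + .cross_abs_sum(A[[i]], B[[i]])
    }
    d_obs <- cross_sum / sum(Na * Nb)
  } else {
    d_obs <- NA_real_
  }
  pool_a <- unlist(A, use.names = FALSE)
  pool_b <- unlist(B, use.names = FALSE)
  d_noint <- .cross_abs_sum(pool_a, pool_b) /
    (as.numeric(length(pool_a)) * length(pool_b))
  term_obs <- if (phi_mix > 0) phi_mix * (d_obs - d_noint) else 0
  l_int <- term_obs + (1 - phi_mix) * (L - d_noint)
  mean_count <- mean(Na + Nb)
  ps <- structure(list(mean_count = mean_count,
                       n_obs_pair = mean_ab,
                       n_noint_pair = n_noint_pair,
                       n_mis_pair = n_noint_pair - mean_ab,
                       phi = phi_mix,
                       d_obs = d_obs,
                       d_noint = d_noint,
                       d_mis = L,
                       d_int = NA_real_,
                       n_samples = n,
                       L = L),
                  class = "pair_statistics")
  structure(list(l_int = l_int,
                 l_int_norm = l_int * mean_count / L,
                 n_samples = n,
                 pair_stats = ps,
                 sem = NULL,
                 bivalent_correction = FALSE,
                 chromosome_id = dataset$chromosome_id,
                 space = dataset$space,
                 L = L,
                 data = dataset,
                 kind = "mixed",
                 classes_used = c(class_a, class_b),
                 call = match.call()),
            class = "interference_length")
}

# Restrict a labelled dataset to one CO class.
.filter_class <- function(dataset, class) {
  keep <- lapply(dataset$classes, function(cl) cl == class)
  .new_dataset(positions = Map(function(p, k) p[k], dataset$positions, keep),
               classes = Map(function(cl, k) cl[k], dataset$classes, keep),
               sample_ids = dataset$sample_ids,
               length_L = dataset$length_L,
               chromosome_id = dataset$chromosome_id,
               space = dataset$space)
}
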
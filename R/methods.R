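# S3 methods for interference_length fits.

#' @export
print.interference_length <- function(x, digits = 4, ...) {
  kind <- if (!is.null(x$kind) && x$kind == "mixed") {
    paste0(" (mixed classes ", paste(x$classes_used, collapse = "/"), ")")
  } else if (!is.null(x$kind) && x$kind == "single_class") {
    paste0(" (class ", x$classes_used, " only)")
  } else ""
  cat("Interference length estimate", kind, "\n", sep = "")
  cat("  chromosome: ", x$chromosome_id, "  (", x$space, ", L = ",
      format(x$L), ")\n", sep = "")
  cat("  samples: ", x$n_samples, ",  mean CO count <N> = ",
      format(x$pair_stats$mean_count, digits = digits), "\n", sep = "")
  cat("  L_int      = ", format(x$l_int, digits = digits),
      "   (L_int / L = ", format(x$l_int / x$L, digits = digits), ")\n",
      sep = "")
  cat("  L_int^norm = ", format(x$l_int_norm, digits = digits), sep = "")
  if (x$bivalent_correction) cat("   (bivalent-corrected <N>)")
  cat("\n")
  if (!is.null(x$sem)) {
    cat("  bootstrap SEM = ", format(x$sem, digits = digits), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.interference_length <- function(object, ...) {
  print(object)
  cat("\nPair bookkeeping:\n")
  print(object$pair_stats)
  invisible(object)
}

#' @export
coef.interference_length <- function(object, ...) {
  c(L_int = object$l_int, L_int_norm = object$l_int_norm)
}

#' Compare observed and null cumulative pair-distance distributions
#'
#' Draws the cumulative distribution of pair distances under the
#' no-interference null (pooled positions) against the observed cumulative
#' distribution scaled by `phi`, with the remaining mass `1 - phi`
#' attributed to missing pairs at distance `L`.  The area between the two
#' curves is the interference length.
#'
#' @param x An [interference_length()] fit with `keep_data = TRUE`.
#' @param max_pairs Cap on the number of pair distances enumerated or
#'   Monte-Carlo sampled for drawing.
#' @param ... Passed to [graphics::plot()].
#' @return `invisible(x)`.
#' @export
plot.interference_length <- function(x, max_pairs = 2e5, ...) {
  if (is.null(x$data)) {
    stop("fit was created with keep_data = FALSE; nothing to plot")
  }
  ds <- x$data
  ps <- x$pair_stats
  pooled <- unlist(ds$positions, use.names = FALSE)
  M <- length(pooled)
  n_null <- min(max_pairs, M * (M - 1) / 2)
  null_d <- abs(pooled[sample.int(M, n_null, replace = TRUE)] -
                  pooled[sample.int(M, n_null, replace = TRUE)])
  N <- lengths(ds$positions)
  with_pairs <- which(N >= 2L)
  obs_d <- if (length(with_pairs)) {
    unlist(lapply(with_pairs, function(i) {
      p <- ds$positions[[i]]
      d <- outer(p, p, "-")
      abs(d[upper.tri(d)])
    }), use.names = FALSE)
  } else numeric()
  if (length(obs_d) > max_pairs) obs_d <- sample(obs_d, max_pairs)

  grid <- seq(0, x$L, length.out = 512)
  F_null <- stats::ecdf(null_d)(grid)
  phi <- min(ps$phi, 1)
  F_int <- if (length(obs_d)) phi * stats::ecdf(obs_d)(grid) else
    rep(0, length(grid))
  F_int[length(grid)] <- 1  # missing pairs sit at distance L
  graphics::plot(grid, F_null, type = "l", col = "grey40", lwd = 2,
                 xlab = paste0("pair distance (", x$space, ")"),
                 ylab = "cumulative fraction of CO pairs",
                 ylim = c(0, 1), ...)
  graphics::lines(grid, F_int, col = "forestgreen", lwd = 2, type = "s")
  graphics::polygon(c(grid, rev(grid)), c(F_null, rev(F_int)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::legend("bottomright",
                   legend = c("no-interference null", "observed (phi-scaled)"),
                   col = c("grey40", "forestgreen"), lwd = 2, bty = "n")
  invisible(x)
}

#' Simulate datasets from the fitted no-interference null
#'
#' Draws datasets under the null hypothesis the interference length is
#' measured against: per sample a Poisson CO count with the fitted mean
#' `<N>`, positions sampled independently (with replacement) from the
#' pooled observed positions, preserving the observed CO density.
#'
#' @param object An [interference_length()] fit with `keep_data = TRUE`.
#' @param nsim Number of datasets to generate.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `nsim` [chromosome_dataset()] objects.
#' @export
simulate.interference_length <- function(object, nsim = 1, seed = NULL,
                                         ...) {
  if (!is.null(object$kind) && object$kind == "mixed") {
    stop("simulate() is not defined for mixed-class fits")
  }
  if (is.null(object$data)) {
    stop("fit was created with keep_data = FALSE; pooled positions lost")
  }
  ds <- object$data
  pooled <- unlist(ds$positions, use.names = FALSE)
  n <- object$n_samples
  mu <- object$pair_stats$mean_count
  .with_seed(seed, function() {
    lapply(seq_len(nsim), function(k) {
      .sample_null_dataset(pooled, n, mu, ds$length_L, ds$chromosome_id,
                           ds$space)
    })
  })
}

# One Poisson-null replicate resampled from pooled empirical positions.
.sample_null_dataset <- function(pooled, n, mu, L, chromosome_id, space) {
  counts <- stats::rpois(n, mu)
  total <- sum(counts)
  pos <- pooled[sample.int(length(pooled), total, replace = TRUE)]
  idx <- rep.int(seq_len(n), counts)
  o <- order(idx, pos)
  positions <- split(pos[o], factor(idx[o], levels = seq_len(n)))
  names(positions) <- NULL
  .new_dataset(positions = positions, classes = NULL,
               sample_ids = paste0("null", seq_len(n)),
               length_L = L, chromosome_id = chromosome_id, space = space)
}
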
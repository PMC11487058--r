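#' Crossover calls on a single meiotic product
#'
#' One observed sample (a bivalent, cell, or gamete chromatid) carrying the
#' ordered crossover (CO) positions along one chromosome.  A sample without
#' any CO is valid and matters: chromosomes with zero or one CO carry
#' information about interference through the missing-pair bookkeeping of
#' [interference_length()].
#'
#' @param sample_id Character scalar identifying the meiotic product.
#' @param positions Numeric vector of CO coordinates, in the units of the
#'   owning dataset (Mb in DNA space, micrometres in SC space).  Sorted on
#'   construction; may be empty.
#' @param classes Optional character vector of per-CO class labels, one of
#'   `"I"`, `"II"`, `"unknown"`; must match `positions` in length.
#' @return An object of class `crossover_sample`.
#' @seealso [chromosome_dataset()]
#' @examples
#' crossover_sample("plant_07", c(3.1, 22.8))
#' crossover_sample("cell_12", c(1.4, 9.9), classes = c("I", "II"))
#' @export
crossover_sample <- function(sample_id, positions = numeric(), classes = NULL) {
  if (!is.character(sample_id) || length(sample_id) != 1L || is.na(sample_id)) {
    stop("`sample_id` must be a single character string")
  }
  positions <- as.numeric(positions)
  if (anyNA(positions)) stop("`positions` must not contain NA")
  if (!is.null(classes)) {
    classes <- as.character(classes)
    if (length(classes) != length(positions)) {
      stop("`classes` must have the same length as `positions`")
    }
    bad <- setdiff(unique(classes), c("I", "II", "unknown"))
    if (length(bad)) {
      stop("invalid CO class label(s): ", paste(bad, collapse = ", "),
           " (allowed: I, II, unknown)")
    }
  }
  ord <- order(positions)
  positions <- positions[ord]
  if (!is.null(classes)) classes <- classes[ord]
  structure(list(sample_id = sample_id, positions = positions,
                 classes = classes),
            class = "crossover_sample")
}

#' @export
print.crossover_sample <- function(x, ...) {
  cat("<crossover_sample> ", x$sample_id, ": ", length(x$positions),
      " CO(s)", sep = "")
  if (length(x$positions)) {
    cat(" at ", paste(signif(x$positions, 4), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' All crossover samples observed on one chromosome
#'
#' The unit of analysis for every estimator in the package: the collection
#' of crossover samples for one chromosome, together with its length `L`
#' and a coordinate-space tag.  `L` is a parameter of the interference
#' length (missing CO pairs are weighted at distance `L`), so it must be
#' supplied explicitly and is never inferred from the data.
#'
#' @param samples A list of [crossover_sample()] objects, or a plain list of
#'   numeric position vectors (one per sample; empty vectors mean zero COs).
#' @param length_L Positive chromosome length (Mb or micrometres, matching
#'   `space`).
#' @param chromosome_id Character scalar naming the chromosome.
#' @param space Coordinate space of the positions: `"dna_mb"` (genetic data,
#'   megabases) or `"sc_um"` (cytological data, micrometres along the
#'   synaptonemal complex).
#' @param sample_ids Optional character vector of sample identifiers, used
#'   when `samples` is a plain list of numeric vectors.
#' @return An object of class `chromosome_dataset` with fields
#'   `chromosome_id`, `length_L`, `space`, `sample_ids`, `positions` (list
#'   of sorted numeric vectors) and `classes` (list of character vectors, or
#'   `NULL` when no class labels are recorded).
#' @examples
#' chromosome_dataset(list(c(3.1, 22.8), 14.2, numeric()), length_L = 30.4,
#'                    chromosome_id = "chr1")
#' @export
chromosome_dataset <- function(samples, length_L, chromosome_id = "chr",
                               space = c("dna_mb", "sc_um"),
                               sample_ids = NULL) {
  space <- match.arg(space)
  if (!.is_number(length_L) || length_L <= 0) {
    stop("`length_L` must be a single positive number")
  }
  if (!is.list(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty list")
  }
  if (all(vapply(samples, inherits, logical(1), "crossover_sample"))) {
    ids <- vapply(samples, `[[`, character(1), "sample_id")
    positions <- lapply(samples, `[[`, "positions")
    classes <- lapply(samples, `[[`, "classes")
    if (all(vapply(classes, is.null, logical(1)))) classes <- NULL
    else classes <- lapply(seq_along(classes), function(i) {
      if (is.null(classes[[i]])) rep("unknown", length(positions[[i]]))
      else classes[[i]]
    })
  } else {
    positions <- lapply(samples, as.numeric)
    classes <- NULL
    ids <- sample_ids
  }
  if (is.null(ids)) ids <- paste0("s", seq_along(positions))
  if (length(ids) != length(positions)) {
    stop("`sample_ids` must have one entry per sample")
  }
  if (anyNA(unlist(positions, use.names = FALSE))) {
    stop("positions must not contain NA")
  }
  rng <- range(c(0, unlist(positions, use.names = FALSE)))
  if (rng[1] < 0 || rng[2] > length_L) {
    stop("all positions must lie in [0, length_L] = [0, ", length_L, "]")
  }
  unsorted <- vapply(positions, is.unsorted, logical(1))
  if (any(unsorted)) {
    for (i in which(unsorted)) {
      ord <- order(positions[[i]])
      positions[[i]] <- positions[[i]][ord]
      if (!is.null(classes)) classes[[i]] <- classes[[i]][ord]
    }
  }
  .new_dataset(positions = positions, classes = classes,
               sample_ids = as.character(ids), length_L = length_L,
               chromosome_id = chromosome_id, space = space)
}

# Fast internal constructor: callers guarantee sorted, in-range positions.
.new_dataset <- function(positions, classes, sample_ids, length_L,
                         chromosome_id, space) {
  structure(list(chromosome_id = chromosome_id,
                 length_L = length_L,
                 space = space,
                 sample_ids = sample_ids,
                 positions = positions,
                 classes = classes),
            class = "chromosome_dataset")
}

.subset_dataset <- function(ds, idx) {
  .new_dataset(positions = ds$positions[idx],
               classes = if (is.null(ds$classes)) NULL else ds$classes[idx],
               sample_ids = ds$sample_ids[idx],
               length_L = ds$length_L,
               chromosome_id = ds$chromosome_id,
               space = ds$space)
}

#' @export
print.chromosome_dataset <- function(x, ...) {
  n <- length(x$positions)
  counts <- lengths(x$positions)
  cat("<chromosome_dataset> ", x$chromosome_id,
      " (", x$space, ", L = ", format(x$length_L), ")\n", sep = "")
  cat("  samples: ", n, ", total COs: ", sum(counts),
      ", mean CO count <N> = ", format(mean(counts), digits = 4),
      "\n", sep = "")
  if (!is.null(x$classes)) cat("  CO class labels present\n")
  invisible(x)
}

#' Per-sample crossover counts
#'
#' @param dataset A [chromosome_dataset()].
#' @return Integer vector of CO counts, one per sample (zero-CO samples
#'   included).
#' @export
co_counts <- function(dataset) {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  lengths(dataset$positions)
}

#' Chromosome length lookup table
#'
#' Maps chromosome identifiers to their physical lengths in DNA space (Mb)
#' and/or SC space (micrometres).  Conversion between the two spaces with
#' [convert_space()] requires both lengths for the chromosome.
#'
#' @param chromosome Character vector of chromosome identifiers.
#' @param length_dna_mb Numeric vector of lengths in megabases (NA if
#'   unknown).
#' @param length_sc_um Numeric vector of synaptonemal-complex lengths in
#'   micrometres (NA if unknown).
#' @return A data frame of class `length_table`.
#' @examples
#' length_table("chr1", length_dna_mb = 30.4, length_sc_um = 15.2)
#' @export
length_table <- function(chromosome, length_dna_mb = NA_real_,
                         length_sc_um = NA_real_) {
  chromosome <- as.character(chromosome)
  n <- length(chromosome)
  length_dna_mb <- rep_len(as.numeric(length_dna_mb), n)
  length_sc_um <- rep_len(as.numeric(length_sc_um), n)
  if (anyDuplicated(chromosome)) stop("duplicate chromosome identifiers")
  ok <- function(v) all(is.na(v) | v > 0)
  if (!ok(length_dna_mb) || !ok(length_sc_um)) {
    stop("all chromosome lengths must be positive")
  }
  if (any(is.na(length_dna_mb) & is.na(length_sc_um))) {
    stop("each chromosome needs a length in at least one space")
  }
  structure(data.frame(chromosome = chromosome,
                       length_dna_mb = length_dna_mb,
                       length_sc_um = length_sc_um,
                       stringsAsFactors = FALSE),
            class = c("length_table", "data.frame"))
}

.length_column <- function(space) {
  switch(space, dna_mb = "length_dna_mb", sc_um = "length_sc_um",
         stop("unknown coordinate space: ", space))
}

.lookup_length <- function(lengths, chromosome_id, space) {
  stopifnot(inherits(lengths, "length_table"))
  i <- match(chromosome_id, lengths$chromosome)
  if (is.na(i)) {
    stop("chromosome '", chromosome_id, "' not found in the length table")
  }
  L <- lengths[[.length_column(space)]][i]
  if (is.na(L)) {
    stop("length table has no ", space, " length for chromosome '",
         chromosome_id, "'")
  }
  L
}

#' Convert a dataset between DNA (Mb) and SC (micrometre) coordinates
#'
#' Rescales every CO position by the ratio of the target to the source
#' chromosome length, assuming uniform compaction of the chromosome onto
#' the synaptonemal complex.  Dimensionless quantities (phi, normalized
#' interference length, CoC values, gamma shape) are unaffected by the
#' conversion; lengths (interference length, interference distance, gamma
#' scale) transform by the same ratio.
#'
#' @param dataset A [chromosome_dataset()].
#' @param lengths A [length_table()] holding both lengths for the
#'   chromosome.
#' @param target Target space, `"dna_mb"` or `"sc_um"`.
#' @return The converted `chromosome_dataset` (identical if already in the
#'   target space).
#' @examples
#' lt <- length_table("chr1", length_dna_mb = 30.4, length_sc_um = 15.2)
#' ds <- chromosome_dataset(list(15.2), length_L = 30.4,
#'                          chromosome_id = "chr1")
#' convert_space(ds, lt, "sc_um")$positions[[1]]  # 7.6
#' @export
convert_space <- function(dataset, lengths, target = c("dna_mb", "sc_um")) {
  stopifnot(inherits(dataset, "chromosome_dataset"))
  target <- match.arg(target)
  src_L <- .lookup_length(lengths, dataset$chromosome_id, dataset$space)
  if (abs(src_L - dataset$length_L) > 1e-6 * src_L) {
    stop("dataset length_L (", dataset$length_L,
         ") disagrees with the length table (", src_L, ")")
  }
  if (target == dataset$space) return(dataset)
  tgt_L <- .lookup_length(lengths, dataset$chromosome_id, target)
  f <- tgt_L / src_L
  out <- dataset
  out$positions <- lapply(dataset$positions, `*`, f)
  out$length_L <- tgt_L
  out$space <- target
  out
}
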
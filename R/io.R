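# Tab-separated interchange formats.
#
# Crossover table: header sample_id, chromosome, position, co_class.
# One row per CO call; a row with an EMPTY position field is a manifest row
# declaring a zero-CO sample.  Manifest rows are required for samples
# without COs: silently dropping them would bias the mean CO count <N>
# upward and with it the missing-pair bookkeeping.
#
# Length table: header chromosome, length_dna_mb, length_sc_um (the two
# length columns individually optional).

#' Read a crossover call table
#'
#' @param path Path to a UTF-8 tab-separated file with header columns
#'   `sample_id`, `chromosome`, `position` and optionally `co_class`
#'   (values `I`, `II`, `unknown`, or empty).  Rows with an empty
#'   `position` field are zero-CO manifest rows.
#' @param lengths A [length_table()] covering every chromosome in the file.
#' @param space Coordinate space the positions are recorded in.
#' @return A named list of [chromosome_dataset()] objects, one per
#'   chromosome (file order).
#' @seealso [write_crossover_table()]
#' @export
read_crossover_table <- function(path, lengths,
                                 space = c("dna_mb", "sc_um")) {
  space <- match.arg(space)
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("sample_id", "chromosome", "position")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("crossover table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  has_class <- "co_class" %in% names(raw)
  pos_chr <- trimws(raw$position)
  manifest <- pos_chr == ""
  pos <- suppressWarnings(as.numeric(pos_chr))
  bad <- which(!manifest & is.na(pos))
  if (length(bad)) {
    stop("crossover table format error: non-numeric position in file row ",
         bad[1] + 1L)
  }
  if (has_class) {
    cls <- trimws(raw$co_class)
    cls[cls == ""] <- NA_character_
    bad_cls <- which(!is.na(cls) & !(cls %in% c("I", "II", "unknown")))
    if (length(bad_cls)) {
      stop("crossover table format error: invalid co_class '",
           cls[bad_cls[1]], "' in file row ", bad_cls[1] + 1L)
    }
  }

  out <- list()
  for (chrom in unique(raw$chromosome)) {
    rows <- which(raw$chromosome == chrom)
    L <- .lookup_length(lengths, chrom, space)
    oob <- rows[!manifest[rows] & (pos[rows] < 0 | pos[rows] > L)]
    if (length(oob)) {
      stop("validation error: position ", pos_chr[oob[1]],
           " outside [0, ", L, "] for chromosome '", chrom,
           "' in file row ", oob[1] + 1L)
    }
    ids <- unique(raw$sample_id[rows])
    use_classes <- has_class && any(!is.na(cls[rows]) & !manifest[rows])
    positions <- vector("list", length(ids))
    classes <- if (use_classes) vector("list", length(ids)) else NULL
    for (k in seq_along(ids)) {
      r <- rows[raw$sample_id[rows] == ids[k] & !manifest[rows]]
      p <- pos[r]
      ord <- order(p)
      positions[[k]] <- p[ord]
      if (use_classes) {
        ck <- if (has_class) cls[r] else rep(NA_character_, length(r))
        ck[is.na(ck)] <- "unknown"
        classes[[k]] <- ck[ord]
      }
    }
    out[[chrom]] <- .new_dataset(positions = positions, classes = classes,
                                 sample_ids = ids, length_L = L,
                                 chromosome_id = chrom, space = space)
  }
  out
}

#' Write crossover datasets as a tab-separated table
#'
#' Positions are serialized with full double precision so that a
#' write/read round trip reproduces the dataset exactly.  Zero-CO samples
#' are emitted as manifest rows with an empty position field.
#'
#' @param datasets A [chromosome_dataset()] or a list of them.
#' @param path Output file path.
#' @return `invisible(path)`.
#' @export
write_crossover_table <- function(datasets, path) {
  if (inherits(datasets, "chromosome_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("`datasets` must be non-empty")
  rows <- lapply(datasets, function(ds) {
    counts <- lengths(ds$positions)
    n_rows <- pmax(counts, 1L)
    sample_id <- rep.int(ds$sample_ids, n_rows)
    position <- character(sum(n_rows))
    co_class <- character(sum(n_rows))
    at <- 1L
    for (i in seq_along(ds$positions)) {
      if (counts[i] == 0L) {
        position[at] <- ""
        co_class[at] <- ""
        at <- at + 1L
      } else {
        idx <- at:(at + counts[i] - 1L)
        position[idx] <- .format_position(ds$positions[[i]])
        co_class[idx] <- if (is.null(ds$classes)) "" else ds$classes[[i]]
        at <- at + counts[i]
      }
    }
    data.frame(sample_id = sample_id,
               chromosome = ds$chromosome_id,
               position = position,
               co_class = co_class,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a chromosome length table
#'
#' @param path Tab-separated file with header `chromosome` and at least one
#'   of `length_dna_mb`, `length_sc_um`.
#' @return A [length_table()].
#' @export
read_length_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (!"chromosome" %in% names(raw)) {
    stop("length table format error: missing column 'chromosome'")
  }
  if (!any(c("length_dna_mb", "length_sc_um") %in% names(raw))) {
    stop("length table format error: need length_dna_mb and/or length_sc_um")
  }
  get_col <- function(nm) {
    if (nm %in% names(raw)) as.numeric(raw[[nm]]) else NA_real_
  }
  length_table(chromosome = raw$chromosome,
               length_dna_mb = get_col("length_dna_mb"),
               length_sc_um = get_col("length_sc_um"))
}

#' Write a chromosome length table
#'
#' @param lengths A [length_table()].
#' @param path Output file path.
#' @return `invisible(path)`.
#' @export
write_length_table <- function(lengths, path) {
  stopifnot(inherits(lengths, "length_table"))
  utils::write.table(as.data.frame(lengths), path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
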
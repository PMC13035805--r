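#' Mutation spectrum matrices
#'
#' A `spectrum_matrix` holds non-negative mutation counts (or weights) for a
#' set of samples over the channels of a [channel_schema()]. Internally the
#' counts live in a samples x channels numeric matrix whose dimnames carry
#' the sample ids and channel labels.
#'
#' @param counts numeric matrix, samples in rows, channels in columns.
#'   Rownames are sample ids; colnames must match `schema$channels`
#'   (any order; columns are reordered to schema order).
#' @param schema a [channel_schema()]; defaults to [sbs96_schema()].
#' @return An object of class `spectrum_matrix` with elements `schema` and
#'   `counts`.
#' @export
#' @examples
#' m <- matrix(rpois(96 * 2, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), sbs96_channels()))
#' sm <- spectrum_matrix(m)
#' sample_totals(sm)
spectrum_matrix <- function(counts, schema = sbs96_schema()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0L) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("sample ids must be unique", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) != length(schema$channels)) {
      stop("unnamed counts must have one column per schema channel",
           call. = FALSE)
    }
    colnames(counts) <- schema$channels
  }
  unknown <- setdiff(colnames(counts), schema$channels)
  if (length(unknown)) {
    stop("channel labels not in schema '", schema$name, "': ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (!setequal(colnames(counts), schema$channels)) {
    stop("counts are missing schema channels; zero-fill explicitly if intended",
         call. = FALSE)
  }
  counts <- counts[, schema$channels, drop = FALSE]
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(schema = schema, counts = counts), class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat("<spectrum_matrix>", nrow(x$counts), "samples x",
      ncol(x$counts), "channels (", x$schema$name, ")\n")
  cat("  totals:", paste(utils::head(round(rowSums(x$counts)), 6),
                         collapse = " "),
      if (nrow(x$counts) > 6) "..." else "", "\n")
  invisible(x)
}

#' @rdname spectrum_matrix
#' @param m a `spectrum_matrix`.
#' @export
sample_ids <- function(m) rownames(m$counts)

#' @rdname spectrum_matrix
#' @export
sample_totals <- function(m) rowSums(m$counts)

#' Per-sample frequency view of a spectrum matrix
#'
#' Each row with positive total is divided by its total so it sums to 1;
#' all-zero rows stay zero.
#'
#' @param m a `spectrum_matrix`.
#' @return numeric matrix of per-sample channel frequencies.
#' @export
spectrum_frequencies <- function(m) {
  tot <- rowSums(m$counts)
  f <- m$counts
  pos <- tot > 0
  f[pos, ] <- f[pos, , drop = FALSE] / tot[pos]
  f
}

#' Subset a spectrum matrix by sample id
#'
#' @param m a `spectrum_matrix`.
#' @param ids sample ids to keep, in the order given.
#' @export
subset_samples <- function(m, ids) {
  missing <- setdiff(ids, sample_ids(m))
  if (length(missing)) {
    stop("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  spectrum_matrix(m$counts[ids, , drop = FALSE], m$schema)
}

#' Combine two spectrum matrices sharing a schema
#'
#' @param a,b `spectrum_matrix` objects with identical schemas and disjoint
#'   sample ids.
#' @export
bind_spectra <- function(a, b) {
  if (!schemas_equal(a$schema, b$schema)) {
    stop("schema mismatch between spectrum matrices", call. = FALSE)
  }
  spectrum_matrix(rbind(a$counts, b$counts), a$schema)
}

#' Read a spectrum matrix from a COSMIC-dialect TSV
#'
#' The COSMIC dialect stores channels as rows (first column `MutationType`,
#' `Type`, or unnamed) and samples as columns; `orientation =
#' "samples_as_rows"` accepts the transpose. Channels are reordered to the
#' declared schema; labels outside the schema are an error, and schema
#' channels absent from the file are zero-filled only when
#' `fill_missing = TRUE`.
#'
#' @param path TSV file path.
#' @param orientation `"channels_as_rows"` (COSMIC dialect, default) or
#'   `"samples_as_rows"`.
#' @param schema target [channel_schema()].
#' @param fill_missing zero-fill schema channels absent from the file.
#' @return A [spectrum_matrix()].
#' @export
read_spectrum_matrix <- function(path,
                                 orientation = c("channels_as_rows",
                                                 "samples_as_rows"),
                                 schema = sbs96_schema(),
                                 fill_missing = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("empty spectrum file: ", path, call. = FALSE)
  labels <- as.character(df[[1L]])
  if (anyDuplicated(labels)) {
    stop("duplicate labels in first column of ", path, call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !all(is.na(v)))
        stop("non-numeric cell in column '", names(vals)[j], "'", call. = FALSE)
      v <- vn
    }
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  if (anyNA(mat)) stop("missing/non-numeric values in ", path, call. = FALSE)
  if (any(mat < 0)) stop("negative values in ", path, call. = FALSE)
  if (orientation == "channels_as_rows") {
    rownames(mat) <- labels
    mat <- t(mat)  # -> samples x channels
  } else {
    rownames(mat) <- labels
  }
  unknown <- setdiff(colnames(mat), schema$channels)
  if (length(unknown)) {
    stop("unknown channel labels in ", path, ": ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(schema$channels, colnames(mat))
  if (length(absent)) {
    if (!fill_missing) {
      stop(length(absent), " schema channels missing from ", path,
           " (set fill_missing = TRUE to zero-fill)", call. = FALSE)
    }
    fill <- matrix(0, nrow(mat), length(absent),
                   dimnames = list(rownames(mat), absent))
    mat <- cbind(mat, fill)
  }
  spectrum_matrix(mat, schema)
}

#' Write a spectrum matrix as COSMIC-dialect TSV
#'
#' Channels as rows in schema order, one column per sample, first column
#' headed `MutationType`. Integer-valued matrices are written without a
#' decimal point so that read/write round trips are textually faithful.
#'
#' @param m a [spectrum_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_matrix <- function(m, path) {
  vals <- t(m$counts)  # channels x samples
  out <- data.frame(MutationType = rownames(vals), check.names = FALSE)
  int_like <- all(vals == round(vals))
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    out[[colnames(vals)[j]]] <- if (int_like) as.integer(round(v)) else v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop samples below a minimum mutation total
#'
#' Mirrors the common pre-filter that removes samples with too few mutations
#' to carry spectrum resolution (e.g. tumors with fewer than 10 calls).
#' The boundary is inclusive: a sample with exactly `min_total` mutations
#' survives.
#'
#' @param m a [spectrum_matrix()].
#' @param min_total non-negative integer.
#' @return The filtered `spectrum_matrix`; removed ids are attached as
#'   attribute `"removed"`.
#' @export
filter_min_mutations <- function(m, min_total) {
  stopifnot(min_total >= 0)
  tot <- sample_totals(m)
  keep <- tot >= min_total
  out <- spectrum_matrix(m$counts[keep, , drop = FALSE], m$schema)
  attr(out, "removed") <- sample_ids(m)[!keep]
  out
}
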
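#' Signature catalogs
#'
#' A catalog holds one probability distribution over channels per
#' signature (rows sum to 1).
#'
#' @param profiles signatures x channels matrix; rownames are signature
#'   ids, colnames the channel labels.
#' @param schema a [channel_schema()].
#' @return An object of class `signature_catalog`.
#' @export
signature_catalog <- function(profiles, schema = sbs96_schema()) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles))) {
    stop("profiles need signature ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(profiles))) {
    stop("signature ids must be unique", call. = FALSE)
  }
  if (is.null(colnames(profiles))) colnames(profiles) <- schema$channels
  if (!setequal(colnames(profiles), schema$channels)) {
    stop("profile channels do not match the schema", call. = FALSE)
  }
  profiles <- profiles[, schema$channels, drop = FALSE]
  if (any(profiles < 0)) stop("profiles must be non-negative", call. = FALSE)
  rs <- rowSums(profiles)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("each signature profile must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  structure(list(schema = schema, profiles = profiles),
            class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("<signature_catalog>", nrow(x$profiles), "signatures x",
      ncol(x$profiles), "channels (", x$schema$name, ")\n")
  invisible(x)
}

#' @rdname signature_catalog
#' @param catalog a `signature_catalog`.
#' @export
signature_ids <- function(catalog) rownames(catalog$profiles)

#' Read/write signature catalogs in COSMIC-dialect TSV
#'
#' Channels as rows (first column `MutationType`/`Type`), one column per
#' signature.
#'
#' @param path file path.
#' @param schema target [channel_schema()].
#' @export
read_signature_catalog <- function(path, schema = sbs96_schema()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- labels
  signature_catalog(t(mat), schema)
}

#' @rdname read_signature_catalog
#' @param catalog a [signature_catalog()].
#' @export
write_signature_catalog <- function(catalog, path) {
  vals <- t(catalog$profiles)
  out <- data.frame(MutationType = rownames(vals), vals, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exposure matrices
#'
#' Per-sample signature exposures in mutation-count units, with a
#' fraction view (rows renormalised to 1).
#'
#' @param exposures samples x signatures non-negative matrix.
#' @return An object of class `exposure_matrix`.
#' @export
exposure_matrix <- function(exposures) {
  exposures <- as.matrix(exposures)
  if (any(exposures < 0)) stop("exposures must be non-negative",
                               call. = FALSE)
  structure(list(exposures = exposures), class = "exposure_matrix")
}

#' @rdname exposure_matrix
#' @param e an `exposure_matrix`.
#' @export
exposure_fractions <- function(e) {
  tot <- rowSums(e$exposures)
  f <- e$exposures
  f[tot > 0, ] <- f[tot > 0, , drop = FALSE] / tot[tot > 0]
  f
}

#' @export
print.exposure_matrix <- function(x, ...) {
  cat("<exposure_matrix>", nrow(x$exposures), "samples x",
      ncol(x$exposures), "signatures\n")
  invisible(x)
}

#' Refit signature exposures by non-negative least squares
#'
#' Per sample, solves `min || counts - t(profiles) %*% e ||_2` subject to
#' `e >= 0`, then iteratively zeroes signatures whose exposure fraction
#' falls below `prune_below` and refits on the retained set until the set
#' is stable. The pruning mirrors the common practice of discarding
#' exposures under 5% of a sample's mutations, which suppresses spurious
#' low-level assignments. Exposures are returned in mutation-count units.
#'
#' @param m a [spectrum_matrix()].
#' @param catalog a [signature_catalog()] on the same schema.
#' @param prune_below minimum exposure fraction retained (default 0.05);
#'   0 disables pruning.
#' @return An [exposure_matrix()] (samples x signatures).
#' @export
fit_exposures_nnls <- function(m, catalog, prune_below = 0.05) {
  if (!schemas_equal(m$schema, catalog$schema)) {
    stop("spectrum and catalog schemas differ", call. = FALSE)
  }
  if (nrow(catalog$profiles) == 0L) stop("empty catalog", call. = FALSE)
  A <- t(catalog$profiles)  # channels x signatures
  k <- ncol(A)
  fit_one <- function(y) {
    e <- rep(0, k)
    if (sum(y) == 0) return(e)
    active <- seq_len(k)
    repeat {
      sol <- pracma::lsqnonneg(A[, active, drop = FALSE], y)$x
      e[] <- 0
      e[active] <- sol
      if (prune_below <= 0 || sum(e) == 0) break
      frac <- e / sum(e)
      keep <- which(frac >= prune_below)
      if (length(keep) == 0L) keep <- which.max(frac)  # never empty the set
      if (identical(keep, active)) break
      active <- keep
    }
    e
  }
  expo <- t(apply(m$counts, 1, fit_one))
  dimnames(expo) <- list(sample_ids(m), signature_ids(catalog))
  exposure_matrix(expo)
}

#' Per-signature Wilcoxon rank-sum comparison of exposure fractions
#'
#' The signature-refitting baseline for group comparison: for every
#' signature with positive exposure fraction in at least one sample of
#' either group, the two groups' exposure fractions are compared by a
#' two-sided Wilcoxon rank-sum test; p-values are Bonferroni-corrected
#' over the tested set, and the overall significance is the minimum
#' corrected p-value. Tests are exact for small untied samples and use
#' the normal approximation with tie and continuity correction otherwise.
#'
#' @param expo_a,expo_b [exposure_matrix()] objects over one signature
#'   universe.
#' @return list of class `signature_comparison`: data.frame `table`
#'   (signature, raw_p, adjusted_p), `overall_p`, `tested`.
#' @export
wilcoxon_signature_comparison <- function(expo_a, expo_b) {
  if (!identical(colnames(expo_a$exposures), colnames(expo_b$exposures))) {
    stop("exposure matrices use different signature sets", call. = FALSE)
  }
  if (nrow(expo_a$exposures) < 1L || nrow(expo_b$exposures) < 1L) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  fa <- exposure_fractions(expo_a)
  fb <- exposure_fractions(expo_b)
  present <- colSums(fa > 0) + colSums(fb > 0) > 0
  tested <- colnames(fa)[present]
  if (length(tested) == 0L) {
    stop("no signature has positive exposure in either group", call. = FALSE)
  }
  raw <- vapply(tested, function(s) {
    suppressWarnings(stats::wilcox.test(fa[, s], fb[, s],
                                        alternative = "two.sided")$p.value)
  }, numeric(1))
  adj <- pmin(1, raw * length(tested))
  structure(list(
    table = data.frame(signature = tested, raw_p = unname(raw),
                       adjusted_p = unname(adj), stringsAsFactors = FALSE),
    overall_p = min(adj),
    tested = tested
  ), class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat("Per-signature Wilcoxon rank-sum comparison (",
      length(x$tested), " signatures tested, Bonferroni-corrected)\n",
      sep = "")
  cat(sprintf("  overall p (min corrected) = %.4g\n", x$overall_p))
  invisible(x)
}

#' Per-channel Wilcoxon rank-sum tests between two groups
#'
#' Compares per-sample channel frequencies channel by channel (two-sided
#' rank-sum), with Benjamini-Hochberg adjustment across all schema
#' channels; suitable for volcano plots of which mutation types drive a
#' spectrum difference.
#'
#' @param group_a,group_b [spectrum_matrix()] objects on one schema.
#' @return data.frame with one row per channel: `channel`, `raw_p`,
#'   `adjusted_p` (BH), `mean_freq_diff` (group A minus group B).
#' @export
per_channel_wilcoxon <- function(group_a, group_b) {
  if (!schemas_equal(group_a$schema, group_b$schema)) {
    stop("schema mismatch", call. = FALSE)
  }
  if (nrow(group_a$counts) == 0L || nrow(group_b$counts) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  fa <- spectrum_frequencies(group_a)
  fb <- spectrum_frequencies(group_b)
  raw <- vapply(seq_len(ncol(fa)), function(j) {
    suppressWarnings(stats::wilcox.test(fa[, j], fb[, j],
                                        alternative = "two.sided")$p.value)
  }, numeric(1))
  data.frame(
    channel = group_a$schema$channels,
    raw_p = raw,
    adjusted_p = stats::p.adjust(raw, method = "BH"),
    mean_freq_diff = colMeans(fa) - colMeans(fb),
    stringsAsFactors = FALSE
  )
}
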
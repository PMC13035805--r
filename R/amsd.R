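#' Aggregate a group of spectra into one channel vector
#'
#' `mode = "mean"` (the default) averages the per-sample frequency vectors,
#' weighting every sample equally regardless of its mutation load; the
#' result sums to 1. `mode = "sum"` adds the raw counts, so mutation-rich
#' samples weigh more; it is not normalised (cosine distance is
#' scale-invariant, so normalisation would not change the test).
#'
#' Under mean mode, all-zero samples have no frequency vector; they are
#' dropped with a warning. Sum mode keeps them (they contribute nothing).
#'
#' @param m a [spectrum_matrix()].
#' @param mode `"mean"` or `"sum"`.
#' @return Named numeric vector over the schema channels.
#' @export
aggregate_spectrum <- function(m, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (nrow(m$counts) == 0L) stop("cannot aggregate an empty matrix",
                                 call. = FALSE)
  if (mode == "sum") return(colSums(m$counts))
  tot <- rowSums(m$counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero sample(s) dropped under mean mode")
    m <- spectrum_matrix(m$counts[tot > 0, , drop = FALSE], m$schema)
    if (nrow(m$counts) == 0L) {
      stop("no samples with positive totals under mean mode", call. = FALSE)
    }
  }
  colMeans(spectrum_frequencies(m))
}

#' Cosine distance between two non-negative channel vectors
#'
#' `1 - (u . v) / (||u|| ||v||)`. For non-negative vectors the result lies
#' in `[0, 1]`; it is symmetric and invariant to positive rescaling of
#' either argument.
#'
#' @param u,v non-negative numeric vectors of equal length, each with
#'   positive norm.
#' @return distance in `[0, 1]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine distance undefined for a zero vector", call. = FALSE)
  }
  1 - sum(u * v) / (nu * nv)
}

# registry of group-distance metrics; each entry supplies a pairwise form
# and (optionally) a rowwise form for the vectorised permutation engine
.distance_registry <- new.env(parent = emptyenv())

#' Register or fetch a spectrum distance metric
#'
#' Metrics must be symmetric, non-negative, and defined on non-negative
#' vectors. `cosine` (default everywhere) and `euclidean` are built in.
#'
#' @param name metric identifier.
#' @param pairwise `function(u, v) -> distance`.
#' @param rowwise optional `function(A, B) -> vector` giving the distance
#'   between corresponding rows of two matrices (used to vectorise the
#'   permutation null); derived from `pairwise` when absent.
#' @export
register_distance <- function(name, pairwise, rowwise = NULL) {
  if (is.null(rowwise)) {
    rowwise <- function(A, B) {
      vapply(seq_len(nrow(A)), function(i) pairwise(A[i, ], B[i, ]),
             numeric(1))
    }
  }
  assign(name, list(pairwise = pairwise, rowwise = rowwise),
         envir = .distance_registry)
  invisible(name)
}

#' @rdname register_distance
#' @export
get_distance <- function(name) {
  if (!exists(name, envir = .distance_registry, inherits = FALSE)) {
    stop("unknown distance metric: ", name, call. = FALSE)
  }
  get(name, envir = .distance_registry, inherits = FALSE)
}

register_distance(
  "cosine",
  pairwise = cosine_distance,
  rowwise = function(A, B) {
    1 - rowSums(A * B) / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
  }
)

register_distance(
  "euclidean",
  pairwise = function(u, v) sqrt(sum((u - v)^2)),
  rowwise = function(A, B) sqrt(rowSums((A - B)^2))
)

# distances equal up to this are treated as tied ("greater than or equal"),
# guarding against spurious float inequality of identical splits
.DIST_TIE_TOL <- 1e-12

amsd_result <- function(observed, null, n_a, n_b, weighting, distance_name,
                        p_convention, seed, exhaustive = FALSE) {
  k <- sum(null >= observed - .DIST_TIE_TOL)
  n_perm <- length(null)
  floored <- FALSE
  p <- if (p_convention == "plus_one") {
    (k + 1) / (n_perm + 1)
  } else {
    if (k == 0L) floored <- TRUE
    k / n_perm
  }
  structure(list(
    observed_distance = observed,
    null_distances = null,
    p_value = p,
    p_floored = floored,
    p_convention = p_convention,
    n_permutations = n_perm,
    n_exceedances = k,
    weighting = weighting,
    distance_name = distance_name,
    seed = seed,
    group_sizes = c(n_a, n_b),
    exhaustive = exhaustive
  ), class = "amsd_result")
}

#' @export
print.amsd_result <- function(x, ...) {
  cat("AMSD", if (x$exhaustive) "exhaustive" else "permutation", "test\n")
  cat(sprintf("  groups: %d vs %d samples; weighting = %s; distance = %s\n",
              x$group_sizes[1], x$group_sizes[2], x$weighting,
              x$distance_name))
  cat(sprintf("  observed distance = %.6g\n", x$observed_distance))
  pv <- if (x$p_floored) {
    sprintf("< %.3g (0 of %d null distances >= observed)",
            1 / x$n_permutations, x$n_permutations)
  } else {
    sprintf("%.4g (%d of %d null distances >= observed)",
            x$p_value, x$n_exceedances, x$n_permutations)
  }
  cat("  p =", pv, "\n")
  invisible(x)
}

# shared set-up for the observed statistic: pooled frequency (or count)
# matrix after the mean-mode zero-total drop policy
.amsd_prepare <- function(group_a, group_b, mode) {
  if (!schemas_equal(group_a$schema, group_b$schema)) {
    stop("the two groups use different channel schemas", call. = FALSE)
  }
  if (nrow(group_a$counts) == 0L || nrow(group_b$counts) == 0L) {
    stop("both groups must contain at least one sample", call. = FALSE)
  }
  drop_zero <- function(g, label) {
    tot <- rowSums(g$counts)
    if (mode == "mean" && any(tot == 0)) {
      warning(sum(tot == 0), " all-zero sample(s) dropped from group ",
              label, " under mean weighting")
      g <- spectrum_matrix(g$counts[tot > 0, , drop = FALSE], g$schema)
      if (nrow(g$counts) == 0L) {
        stop("group ", label, " has no samples with positive totals",
             call. = FALSE)
      }
    }
    g
  }
  group_a <- drop_zero(group_a, "A")
  group_b <- drop_zero(group_b, "B")
  pooled <- rbind(group_a$counts, group_b$counts)
  mat <- if (mode == "mean") {
    tot <- rowSums(pooled)
    sweep_pos <- pooled
    sweep_pos[tot > 0, ] <- sweep_pos[tot > 0, , drop = FALSE] / tot[tot > 0]
    sweep_pos
  } else {
    pooled
  }
  list(mat = mat, n_a = nrow(group_a$counts), n_b = nrow(group_b$counts))
}

# aggregate + rowwise distance for a batch of splits encoded as an
# indicator matrix Z (splits x samples, 1 = pseudo-group A)
.null_distances <- function(Z, mat, n_a, n_b, mode, dist) {
  SA <- Z %*% mat
  SB <- matrix(colSums(mat), nrow(SA), ncol(SA), byrow = TRUE) - SA
  if (mode == "mean") {
    SA <- SA / n_a
    SB <- SB / n_b
  }
  dist$rowwise(SA, SB)
}

#' AMSD permutation test between two groups of mutation spectra
#'
#' Computes the observed aggregate spectrum distance between the two
#' groups, then builds a null distribution by repeatedly reshuffling the
#' pooled samples into pseudo-groups of the original sizes (uniformly at
#' random, without replacement within a split; splits are drawn
#' independently across permutations). The p-value is the fraction of null
#' distances greater than or equal to the observed distance.
#'
#' Two p-value conventions are available. `"fraction_ge"` (default)
#' reports exactly that fraction; with zero exceedances the result is 0 and
#' flagged `p_floored` (printed as "< 1/n_perm"). `"plus_one"` reports
#' `(k + 1) / (n_perm + 1)`, the conservative estimator that counts the
#' observed labeling as one permutation and can never be 0; calibration
#' analyses should use it.
#'
#' @param group_a,group_b [spectrum_matrix()] objects on one schema.
#' @param n_perm number of random relabelings (default 1000).
#' @param mode aggregation weighting, `"mean"` or `"sum"`; see
#'   [aggregate_spectrum()].
#' @param distance metric name in the registry (default `"cosine"`).
#' @param seed optional integer seed; the result is deterministic given it.
#' @param p_convention `"fraction_ge"` or `"plus_one"`.
#' @return An `amsd_result`: observed distance, null distances, p-value
#'   and run metadata.
#' @export
#' @examples
#' cat <- make_fixture_catalog(seed = 1)
#' base <- mixture_spec(c(syn1 = 0.3, syn2 = 0.6, syn3 = 0.1))
#' pair <- simulate_cohort_pair(
#'   simulation_spec(baseline_mutations = 200, exposure_signature = "synSpiky",
#'                   exposure_fraction = 0.2, samples_per_group = 10, seed = 7),
#'   base, cat)
#' amsd_test(pair$control, pair$exposed, n_perm = 500, seed = 42)
amsd_test <- function(group_a, group_b, n_perm = 1000,
                      mode = c("mean", "sum"), distance = "cosine",
                      seed = NULL,
                      p_convention = c("fraction_ge", "plus_one")) {
  mode <- match.arg(mode)
  p_convention <- match.arg(p_convention)
  stopifnot(n_perm >= 1)
  dist <- get_distance(distance)
  prep <- .amsd_prepare(group_a, group_b, mode)
  n <- prep$n_a + prep$n_b
  agg_a <- colSums(prep$mat[seq_len(prep$n_a), , drop = FALSE])
  agg_b <- colSums(prep$mat[prep$n_a + seq_len(prep$n_b), , drop = FALSE])
  if (mode == "mean") {
    agg_a <- agg_a / prep$n_a
    agg_b <- agg_b / prep$n_b
  }
  observed <- dist$pairwise(agg_a, agg_b)
  if (!is.null(seed)) set.seed(seed)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n, prep$n_a),
                integer(prep$n_a))
  Z <- matrix(0, n_perm, n)
  Z[cbind(rep(seq_len(n_perm), each = prep$n_a), as.vector(idx))] <- 1
  null <- .null_distances(Z, prep$mat, prep$n_a, prep$n_b, mode, dist)
  amsd_result(observed, null, prep$n_a, prep$n_b, mode, distance,
              p_convention, seed)
}

#' Exhaustive small-sample AMSD test
#'
#' Enumerates every distinct assignment of the pooled samples into groups
#' of the original sizes exactly once (`choose(nA + nB, nA)` splits) and
#' computes the exact permutation p-value. The observed labeling is one of
#' the splits, so `p >= 1/choose(n, nA)`. Serves as the oracle for the
#' Monte-Carlo test on small inputs.
#'
#' @inheritParams amsd_test
#' @param max_splits refuse to enumerate more than this many splits.
#' @return An `amsd_result` with `exhaustive = TRUE`.
#' @export
amsd_exhaustive <- function(group_a, group_b, mode = c("mean", "sum"),
                            distance = "cosine", max_splits = 10000) {
  mode <- match.arg(mode)
  dist <- get_distance(distance)
  prep <- .amsd_prepare(group_a, group_b, mode)
  n <- prep$n_a + prep$n_b
  n_splits <- choose(n, prep$n_a)
  if (n_splits > max_splits) {
    stop("exhaustive enumeration needs ", n_splits, " splits (cap ",
         max_splits, ")", call. = FALSE)
  }
  combos <- utils::combn(n, prep$n_a)
  Z <- matrix(0, ncol(combos), n)
  Z[cbind(rep(seq_len(ncol(combos)), each = prep$n_a), as.vector(combos))] <- 1
  null <- .null_distances(Z, prep$mat, prep$n_a, prep$n_b, mode, dist)
  agg_a <- colSums(prep$mat[seq_len(prep$n_a), , drop = FALSE])
  agg_b <- colSums(prep$mat[prep$n_a + seq_len(prep$n_b), , drop = FALSE])
  if (mode == "mean") {
    agg_a <- agg_a / prep$n_a
    agg_b <- agg_b / prep$n_b
  }
  observed <- dist$pairwise(agg_a, agg_b)
  amsd_result(observed, null, prep$n_a, prep$n_b, mode, distance,
              "fraction_ge", seed = NULL, exhaustive = TRUE)
}
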
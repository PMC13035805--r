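#' Adjust a vector of p-values for multiple testing
#'
#' Thin, validated wrapper over the standard adjustments used throughout
#' the screening workflow: `bonferroni` (`min(1, m * p)`) and `bh`
#' (Benjamini-Hochberg step-up).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Regression-estimated Benjamini-Hochberg plotting threshold
#'
#' To draw a single BH significance line on a volcano plot that mixes
#' many comparisons, regress `-log10(adjusted p)` on `-log10(raw p)`
#' (ordinary least squares with intercept) and place the line at
#' `-log10(alpha) * beta`, where `beta` is the fitted slope.
#'
#' @param raw_p,adjusted_p positive p-value vectors of equal length >= 2.
#'   Floored p-values (permutation p = 0) must be excluded by the caller;
#'   their logs are undefined.
#' @param alpha significance level (default 0.05).
#' @return list with `beta`, `r_squared`, `threshold`.
#' @export
bh_threshold_regression <- function(raw_p, adjusted_p, alpha = 0.05) {
  if (length(raw_p) != length(adjusted_p) || length(raw_p) < 2L) {
    stop("need two vectors of equal length >= 2", call. = FALSE)
  }
  if (any(raw_p <= 0) || any(adjusted_p <= 0)) {
    stop("p-values must be positive (exclude floored values)", call. = FALSE)
  }
  x <- -log10(raw_p)
  y <- -log10(adjusted_p)
  if (stats::var(x) == 0) {
    stop("raw p-values are constant; regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  beta <- unname(stats::coef(fit)[2])
  # R^2 computed directly; summary.lm warns on exactly collinear input
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(beta = beta, r_squared = r2, threshold = -log10(alpha) * beta)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums the probabilities of all hypergeometric
#' outcomes whose probability does not exceed that of the observed table
#' (the probability-mass convention).
#'
#' @param a,b,c,d the cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 7, 3, 14)   # ~0.22
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by `sqrt(n)`.
#'
#' @param values numeric vector of length >= 2.
#' @return the SEM.
#' @export
sem <- function(values) {
  stats::sd(values) / sqrt(length(values))
}

#' Run many AMSD comparisons as a screen
#'
#' Executes a plan of pairwise group comparisons over one spectrum
#' matrix, skipping comparisons where either group has fewer than
#' `min_group` samples, and adjusts p-values (Bonferroni and BH) across
#' the executed comparisons only. Floored permutation p-values (zero
#' exceedances) enter adjustment as `1/n_perm` and are flagged; they are
#' excluded from the BH threshold regression.
#'
#' @param spectra a [spectrum_matrix()] holding all samples.
#' @param groups named character vector or data.frame (`sample`, `label`)
#'   mapping sample ids to group labels.
#' @param plan data.frame with columns `label_a`, `label_b` and optional
#'   `id`; each row is one comparison.
#' @param min_group minimum samples per group (default 5).
#' @param n_perm permutations per comparison.
#' @param mode AMSD aggregation weighting.
#' @param seed integer; comparison i uses seed `seed + i`.
#' @param alpha significance level for the thresholds.
#' @return list of class `screen_table`: data.frame `records`
#'   (id, n_a, n_b, observed_distance, raw_p, p_floored, bh_p,
#'   bonferroni_p), `skipped` data.frame, `n_comparisons`,
#'   `bonferroni_threshold` (`-log10(alpha/n)`), `bh_regression`
#'   (list or NULL), and `results` (the underlying `amsd_result`s).
#' @export
run_screen <- function(spectra, groups, plan, min_group = 5,
                       n_perm = 1000, mode = "mean", seed = 1,
                       alpha = 0.05) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$label),
                              as.character(groups$sample))
  }
  if (nrow(plan) == 0L) stop("empty screen plan", call. = FALSE)
  if (is.null(plan$id)) {
    plan$id <- paste(plan$label_a, "vs", plan$label_b)
  }
  unknown <- setdiff(unique(c(plan$label_a, plan$label_b)), unique(groups))
  if (length(unknown)) {
    stop("plan labels not present in the group map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  recs <- list()
  skipped <- list()
  results <- list()
  for (i in seq_len(nrow(plan))) {
    ids_a <- names(groups)[groups == plan$label_a[i]]
    ids_b <- names(groups)[groups == plan$label_b[i]]
    ids_a <- intersect(ids_a, sample_ids(spectra))
    ids_b <- intersect(ids_b, sample_ids(spectra))
    if (length(ids_a) < min_group || length(ids_b) < min_group) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        id = plan$id[i], n_a = length(ids_a), n_b = length(ids_b),
        reason = sprintf("group below min_group = %d", min_group),
        stringsAsFactors = FALSE)
      next
    }
    res <- amsd_test(subset_samples(spectra, ids_a),
                     subset_samples(spectra, ids_b),
                     n_perm = n_perm, mode = mode, seed = seed + i)
    results[[plan$id[i]]] <- res
    recs[[length(recs) + 1L]] <- data.frame(
      id = plan$id[i], n_a = length(ids_a), n_b = length(ids_b),
      observed_distance = res$observed_distance,
      raw_p = if (res$p_floored) 1 / n_perm else res$p_value,
      p_floored = res$p_floored,
      stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) {
    stop("every planned comparison was skipped", call. = FALSE)
  }
  records <- do.call(rbind, recs)
  records$bh_p <- adjust_pvalues(records$raw_p, "bh")
  records$bonferroni_p <- adjust_pvalues(records$raw_p, "bonferroni")
  n_comp <- nrow(records)
  usable <- !records$p_floored
  bh_reg <- if (sum(usable) >= 2 &&
                stats::var(-log10(records$raw_p[usable])) > 0) {
    bh_threshold_regression(records$raw_p[usable], records$bh_p[usable],
                            alpha)
  } else {
    NULL
  }
  structure(list(
    records = records,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(id = character(0), n_a = integer(0), n_b = integer(0),
                 reason = character(0)),
    n_comparisons = n_comp,
    bonferroni_threshold = -log10(alpha / n_comp),
    bh_regression = bh_reg,
    results = results,
    alpha = alpha,
    n_perm = n_perm,
    seed = seed
  ), class = "screen_table")
}

#' @export
print.screen_table <- function(x, ...) {
  cat("<screen_table>", x$n_comparisons, "comparisons executed,",
      nrow(x$skipped), "skipped\n")
  cat(sprintf("  Bonferroni threshold: -log10 p = %.3f\n",
              x$bonferroni_threshold))
  if (!is.null(x$bh_regression)) {
    cat(sprintf("  BH regression: beta = %.3f, R^2 = %.3f, threshold = %.3f\n",
                x$bh_regression$beta, x$bh_regression$r_squared,
                x$bh_regression$threshold))
  }
  invisible(x)
}
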
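#' Signature mixture specification
#'
#' A mixture is a set of signature weights summing to 1; cohorts are
#' simulated by drawing mutations from the mixture's channel distribution.
#'
#' @param weights named non-negative numeric vector (names are signature
#'   ids) summing to 1 within 1e-9.
#' @return An object of class `mixture_spec`.
#' @export
#' @examples
#' mixture_spec(c(syn1 = 0.3, syn2 = 0.6, syn3 = 0.1))
mixture_spec <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("mixture weights must be named by signature id", call. = FALSE)
  }
  if (any(weights < 0)) stop("mixture weights must be non-negative",
                             call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("mixture weights must sum to 1 (got ", sum(weights), ")",
         call. = FALSE)
  }
  structure(list(weights = weights), class = "mixture_spec")
}

# channel distribution of a mixture under a catalog
.mixture_probs <- function(mixture, catalog) {
  ids <- names(mixture$weights)
  missing <- setdiff(ids, signature_ids(catalog))
  if (length(missing)) {
    stop("mixture references signatures absent from the catalog: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  drop(mixture$weights %*% catalog$profiles[ids, , drop = FALSE])
}

#' Simulate one sample's spectrum from a signature mixture
#'
#' Draws `n_mutations` i.i.d. channel assignments from the mixture's
#' channel distribution (a single multinomial draw).
#'
#' @param mixture a [mixture_spec()].
#' @param catalog a [signature_catalog()].
#' @param n_mutations number of mutations (>= 0).
#' @return Named integer channel count vector summing to `n_mutations`.
#' @export
simulate_sample <- function(mixture, catalog, n_mutations) {
  stopifnot(n_mutations >= 0)
  p <- .mixture_probs(mixture, catalog)
  if (n_mutations == 0) {
    return(stats::setNames(integer(length(p)), names(p)))
  }
  stats::setNames(drop(stats::rmultinom(1, n_mutations, p)), names(p))
}

#' One cell of the power-analysis simulation grid
#'
#' Holds the four grid parameters — baseline mutations per sample `B`,
#' the exposure signature, the exposure fraction `f` (the exposed group
#' receives `round(f * B)` extra mutations drawn from the exposure
#' signature alone, e.g. 2% of 2500 baseline mutations = 50 extra), and
#' samples per group `n` — plus replicate count, significance level and
#' seed. Per-sample mutation counts are fixed, not Poisson-dispersed,
#' matching a design with exact per-sample loads.
#'
#' @param baseline_mutations integer `B >= 1`.
#' @param exposure_signature signature id in the catalog.
#' @param exposure_fraction real `f >= 0`.
#' @param samples_per_group integer `n >= 1`.
#' @param replicates simulation replicates per cell (default 100).
#' @param alpha significance level for power (default 0.05).
#' @param seed integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(baseline_mutations, exposure_signature,
                            exposure_fraction, samples_per_group,
                            replicates = 100, alpha = 0.05, seed = 1) {
  stopifnot(baseline_mutations >= 1, exposure_fraction >= 0,
            samples_per_group >= 1, replicates >= 1)
  structure(list(
    baseline_mutations = as.integer(baseline_mutations),
    exposure_signature = exposure_signature,
    exposure_fraction = exposure_fraction,
    samples_per_group = as.integer(samples_per_group),
    replicates = as.integer(replicates),
    alpha = alpha,
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Simulate a matched control / exposed cohort pair
#'
#' Control samples each receive `B` mutations from the baseline mixture.
#' Exposed samples receive the same `B` baseline mutations plus
#' `round(f * B)` extra mutations drawn from the exposure signature alone
#' (round-half-even, R's `round()`).
#'
#' @param spec a [simulation_spec()].
#' @param baseline a [mixture_spec()] for the endogenous background.
#' @param catalog a [signature_catalog()].
#' @return `list(control = spectrum_matrix, exposed = spectrum_matrix)`,
#'   each with `spec$samples_per_group` samples.
#' @export
simulate_cohort_pair <- function(spec, baseline, catalog) {
  set.seed(spec$seed)
  n <- spec$samples_per_group
  B <- spec$baseline_mutations
  extra <- as.integer(round(spec$exposure_fraction * B))
  p_base <- .mixture_probs(baseline, catalog)
  expo_mix <- mixture_spec(stats::setNames(1, spec$exposure_signature))
  p_expo <- .mixture_probs(expo_mix, catalog)
  ctrl <- t(stats::rmultinom(n, B, p_base))
  expo_base <- t(stats::rmultinom(n, B, p_base))
  expo_extra <- if (extra > 0) t(stats::rmultinom(n, extra, p_expo)) else 0
  expo <- expo_base + expo_extra
  rownames(ctrl) <- sprintf("control_%02d", seq_len(n))
  rownames(expo) <- sprintf("exposed_%02d", seq_len(n))
  colnames(ctrl) <- colnames(expo) <- catalog$schema$channels
  list(control = spectrum_matrix(ctrl, catalog$schema),
       exposed = spectrum_matrix(expo, catalog$schema))
}

#' Run a power-analysis grid
#'
#' For each grid cell and replicate, simulates a control/exposed cohort
#' pair and applies each requested method; power is the fraction of
#' replicates with `p < alpha`. Fully seeded: replicate r of a cell uses
#' seed `spec$seed + r`, so reruns are reproducible and cells are
#' independent of grid order.
#'
#' @param grid list of [simulation_spec()] cells.
#' @param baseline baseline [mixture_spec()].
#' @param catalog a [signature_catalog()] used for simulation.
#' @param methods subset of `c("amsd", "wilcoxon_signatures")`.
#' @param n_perm permutations per AMSD test.
#' @param mode AMSD aggregation weighting.
#' @param fit_catalog catalog used by the signature-refitting baseline
#'   (default: `catalog`); pass a larger catalog, e.g.
#'   [make_fixture_fitting_catalog()], to evaluate the baseline under a
#'   realistic reference-database search space.
#' @return data.frame with one row per (cell, method): the grid
#'   parameters, `method`, `power`, `replicates`; the replicate p-values
#'   are in the list column `pvalues`.
#' @export
run_power_grid <- function(grid, baseline, catalog,
                           methods = "amsd", n_perm = 1000,
                           mode = "mean", fit_catalog = catalog) {
  methods <- match.arg(methods, c("amsd", "wilcoxon_signatures"),
                       several.ok = TRUE)
  rows <- list()
  for (spec in grid) {
    pvals <- list()
    for (meth in methods) pvals[[meth]] <- numeric(spec$replicates)
    for (r in seq_len(spec$replicates)) {
      rep_spec <- spec
      rep_spec$seed <- spec$seed + r
      pair <- simulate_cohort_pair(rep_spec, baseline, catalog)
      for (meth in methods) {
        pvals[[meth]][r] <- if (meth == "amsd") {
          amsd_test(pair$control, pair$exposed, n_perm = n_perm,
                    mode = mode, seed = rep_spec$seed + 500000L)$p_value
        } else {
          ea <- fit_exposures_nnls(pair$control, fit_catalog)
          eb <- fit_exposures_nnls(pair$exposed, fit_catalog)
          wilcoxon_signature_comparison(ea, eb)$overall_p
        }
      }
    }
    for (meth in methods) {
      rows[[length(rows) + 1L]] <- data.frame(
        baseline_mutations = spec$baseline_mutations,
        exposure_signature = spec$exposure_signature,
        exposure_fraction = spec$exposure_fraction,
        samples_per_group = spec$samples_per_group,
        replicates = spec$replicates,
        alpha = spec$alpha,
        method = meth,
        power = mean(pvals[[meth]] < spec$alpha),
        pvalues = I(list(pvals[[meth]])),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Synthetic signature catalog for simulation and testing
#'
#' Builds a small deterministic catalog of five synthetic SBS96
#' signatures: three backbones (`syn1`, a CpG-focused clock-like profile;
#' `syn2`, a broad diffuse profile; `syn3`, a C>A-enriched profile
#' emulating oxidative damage), one spiky signature (`synSpiky`, >= 80% of
#' its mass on <= 4 channels, APOBEC-like), and one flat signature
#' (`synFlat`, no channel above 3%). All profiles sum to 1. The catalog is
#' synthetic: it emulates the statistical shape of real signature
#' catalogs without reproducing any published profile.
#'
#' @param seed integer seed; identical seeds give identical catalogs.
#' @return A [signature_catalog()].
#' @export
make_fixture_catalog <- function(seed = 1) {
  set.seed(seed)
  schema <- sbs96_schema()
  ch <- schema$channels
  k <- length(ch)

  dirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }

  # syn1: clock-like, dominated by N[C>T]G deamination channels
  cpg <- grep("\\[C>T\\]G$", ch)
  syn1 <- dirichlet(rep(0.3, k)) * 0.35
  syn1[cpg] <- syn1[cpg] + 0.65 * dirichlet(rep(5, length(cpg)))
  syn1 <- syn1 / sum(syn1)

  # syn2: broad diffuse background over all classes
  syn2 <- dirichlet(rep(4, k))

  # syn3: C>A-enriched (oxidative-damage-like)
  ca <- grep("\\[C>A\\]", ch)
  syn3 <- dirichlet(rep(0.5, k)) * 0.3
  syn3[ca] <- syn3[ca] + 0.7 * dirichlet(rep(3, length(ca)))
  syn3 <- syn3 / sum(syn3)

  # synSpiky: >= 80% of mass on <= 4 channels (APOBEC-like TpC focus)
  spiky <- rep(1e-4, k)
  peaks <- match(c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T"), ch)
  spiky[peaks] <- c(0.40, 0.25, 0.15, 0.10)
  synSpiky <- spiky / sum(spiky)

  # synFlat: near-uniform, max channel mass <= 3%
  synFlat <- dirichlet(rep(60, k))
  stopifnot(max(synFlat) <= 0.03)

  profiles <- rbind(syn1 = syn1, syn2 = syn2, syn3 = syn3,
                    synSpiky = synSpiky, synFlat = synFlat)
  colnames(profiles) <- ch
  signature_catalog(profiles, schema)
}

#' Synthetic fitting catalog emulating a full reference database
#'
#' Signature refitting in practice searches a reference catalog far larger
#' than the handful of processes truly active in a cohort (dozens of
#' signatures), which both inflates the Bonferroni correction of
#' per-signature tests and introduces fitting ambiguity. This generator
#' extends [make_fixture_catalog()] with `n_extra` additional synthetic
#' signatures (a mix of focused and diffuse profiles) so that refitting
#' baselines can be evaluated under that realistic search-space burden
#' while cohorts are still simulated from the small catalog — mirroring
#' the common situation where the simulation truth is a subset of the
#' fitting database.
#'
#' @param seed integer seed; the first five signatures are identical to
#'   `make_fixture_catalog(seed)`.
#' @param n_extra number of additional decoy signatures (default 15).
#' @return A [signature_catalog()] with `5 + n_extra` signatures.
#' @export
make_fixture_fitting_catalog <- function(seed = 1, n_extra = 15) {
  core <- make_fixture_catalog(seed)
  k <- length(core$schema$channels)
  set.seed(seed + 1000L)
  dirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }
  extra <- t(vapply(seq_len(n_extra), function(i) {
    # alternate focused and diffuse decoys
    dirichlet(rep(if (i %% 2 == 0) 0.2 else 2, k))
  }, numeric(k)))
  rownames(extra) <- sprintf("synDecoy%02d", seq_len(n_extra))
  colnames(extra) <- core$schema$channels
  signature_catalog(rbind(core$profiles, extra), core$schema)
}
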
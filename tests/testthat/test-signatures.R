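test_that("signature catalogs validate and round-trip through TSV", {
  expect_error(signature_catalog(matrix(0.5, 1, 96)), "rownames")
  prof <- fixture_catalog$profiles
  bad <- prof; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(signature_catalog(bad), "sum to 1")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_catalog(fixture_catalog, path)
  back <- read_signature_catalog(path)
  expect_equal(back$profiles, fixture_catalog$profiles, tolerance = 1e-12)
})

test_that("NNLS recovers an exact two-signature mixture to machine precision", {
  sch <- sbs96_schema()
  prof <- fixture_catalog$profiles[c("syn1", "synSpiky"), ]
  cat2 <- signature_catalog(prof, sch)
  y <- 600 * prof["syn1", ] + 400 * prof["synSpiky", ]
  m <- spectrum_matrix(matrix(y, 1, dimnames = list("mix", sch$channels)))
  e <- fit_exposures_nnls(m, cat2)
  expect_equal(unname(e$exposures["mix", ]), c(600, 400), tolerance = 1e-6)
  expect_equal(unname(exposure_fractions(e)["mix", ]), c(0.6, 0.4),
               tolerance = 1e-9)
})

test_that("a sample orthogonal to the catalog support gets zero exposure", {
  sch <- sbs96_schema()
  prof <- matrix(0, 1, 96, dimnames = list("delta", sch$channels))
  prof["delta", "A[C>A]A"] <- 1
  cat1 <- signature_catalog(prof, sch)
  m <- delta_spectra("T[T>G]T", 1, total = 50)
  e <- fit_exposures_nnls(m, cat1)
  expect_equal(unname(e$exposures[1, ]), 0)
})

test_that("pruning keeps the refit residual finite and never below unpruned", {
  pair <- simulate_cohort_pair(
    simulation_spec(500, "synSpiky", 0.1, 6, seed = 8),
    fixture_baseline, fixture_catalog)
  m <- pair$exposed
  A <- t(fixture_catalog$profiles)
  resid <- function(e) {
    sqrt(sum((m$counts[1, ] - drop(A %*% e))^2))
  }
  e_pruned <- fit_exposures_nnls(m, fixture_catalog, prune_below = 0.05)
  e_full <- fit_exposures_nnls(m, fixture_catalog, prune_below = 0)
  r_pruned <- resid(e_pruned$exposures[1, ])
  r_full <- resid(e_full$exposures[1, ])
  expect_true(is.finite(r_pruned) && is.finite(r_full))
  expect_gte(r_pruned, r_full - 1e-9)
})

test_that("identical exposure tables give rank-sum p = 1 everywhere", {
  e <- exposure_matrix(matrix(c(10, 20, 5, 30, 2, 8), 3, 2,
                              dimnames = list(paste0("s", 1:3),
                                              c("sigA", "sigB"))))
  cmp <- wilcoxon_signature_comparison(e, e)
  expect_true(all(cmp$table$raw_p == 1))
  expect_equal(cmp$overall_p, 1)
})

test_that("complete separation at 5v5 attains the minimal exact rank-sum p", {
  fa <- matrix(c(seq(0.1, 0.5, 0.1), 1 - seq(0.1, 0.5, 0.1)), 5, 2,
               dimnames = list(paste0("a", 1:5), c("sigA", "sigB")))
  fb <- matrix(c(seq(0.6, 1.0, 0.1), 1 - seq(0.6, 1.0, 0.1)), 5, 2,
               dimnames = list(paste0("b", 1:5), c("sigA", "sigB")))
  ea <- exposure_matrix(fa * 100)
  eb <- exposure_matrix(fb * 100)
  cmp <- wilcoxon_signature_comparison(ea, eb)
  p_min <- 2 / choose(10, 5)
  expect_equal(min(cmp$table$raw_p), p_min, tolerance = 1e-12)
  # agrees with an enumeration oracle of the rank-sum null
  expect_equal(min(cmp$table$raw_p),
               oracle_ranksum_p(fa[, "sigA"], fb[, "sigA"]),
               tolerance = 1e-12)
  # Bonferroni over the tested set, overall = min adjusted
  m <- length(cmp$tested)
  expect_equal(cmp$table$adjusted_p,
               pmin(1, cmp$table$raw_p * m))
  expect_equal(cmp$overall_p, min(cmp$table$adjusted_p))
})

test_that("the overall rank-sum p is invariant to exchanging the groups", {
  pair <- simulate_cohort_pair(
    simulation_spec(300, "synSpiky", 0.2, 5, seed = 15),
    fixture_baseline, fixture_catalog)
  ea <- fit_exposures_nnls(pair$control, fixture_catalog)
  eb <- fit_exposures_nnls(pair$exposed, fixture_catalog)
  expect_equal(wilcoxon_signature_comparison(ea, eb)$overall_p,
               wilcoxon_signature_comparison(eb, ea)$overall_p)
})

test_that("recovered exposure fractions track the simulated spike-in", {
  # f = 0.2 on top of B baseline mutations -> true fraction 0.2/1.2
  spec <- simulation_spec(2500, "synSpiky", 0.2, 10, seed = 19)
  pair <- simulate_cohort_pair(spec, fixture_baseline, fixture_catalog)
  e <- fit_exposures_nnls(pair$exposed, fixture_catalog)
  mean_frac <- mean(exposure_fractions(e)[, "synSpiky"])
  expect_equal(mean_frac, 0.2 / 1.2, tolerance = 0.05)
})

test_that("the fitting catalog extends the core catalog with decoys", {
  fitcat <- make_fixture_fitting_catalog(seed = 1, n_extra = 15)
  expect_equal(nrow(fitcat$profiles), 20)
  expect_equal(fitcat$profiles[rownames(fixture_catalog$profiles), ],
               fixture_catalog$profiles)
  expect_equal(unname(rowSums(fitcat$profiles)), rep(1, 20),
               tolerance = 1e-9)
  expect_identical(make_fixture_fitting_catalog(seed = 1)$profiles,
                   fitcat$profiles)
})

test_that("both methods detect a strong concentrated exposure in large cohorts", {
  spec <- simulation_spec(2500, "synSpiky", 0.1, 125, replicates = 10,
                          seed = 77)
  res <- run_power_grid(list(spec), fixture_baseline, fixture_catalog,
                        methods = c("amsd", "wilcoxon_signatures"),
                        n_perm = 500,
                        fit_catalog = make_fixture_fitting_catalog(1))
  expect_gte(res$power[res$method == "amsd"], 0.9)
  expect_gte(res$power[res$method == "wilcoxon_signatures"], 0.9)
})

test_that("per-channel rank-sum output has one calibrated row per channel", {
  a <- random_spectra(5, seed = 61, prefix = "a")
  tab_same <- per_channel_wilcoxon(a, a)
  expect_equal(nrow(tab_same), 96)
  expect_equal(tab_same$channel, sbs96_channels())
  expect_true(all(tab_same$raw_p == 1))
  expect_true(all(tab_same$mean_freq_diff == 0))

  # shifting one channel in every sample of one group makes it the argmin
  b <- a
  rownames(b$counts) <- paste0("b", 1:5)
  b$counts[, "A[C>T]G"] <- b$counts[, "A[C>T]G"] + 200
  b <- spectrum_matrix(b$counts, b$schema)
  tab <- per_channel_wilcoxon(a, b)
  expect_equal(tab$channel[which.min(tab$raw_p)], "A[C>T]G")
  expect_true(all(tab$adjusted_p >= tab$raw_p - 1e-12))
})
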
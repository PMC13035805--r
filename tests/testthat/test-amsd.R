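test_that("mean aggregation averages frequency vectors, sum adds counts", {
  sch <- channel_schema("two", c("c1", "c2"))
  m <- spectrum_matrix(matrix(c(10, 0, 0, 1000), 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), NULL)), sch)
  expect_equal(unname(aggregate_spectrum(m, "mean")), c(0.5, 0.5))
  expect_equal(unname(aggregate_spectrum(m, "sum")), c(10, 1000))

  # identical frequency vectors aggregate to themselves
  v <- c(0.25, 0.75)
  m2 <- spectrum_matrix(matrix(c(100 * v, 400 * v), 2, byrow = TRUE,
                               dimnames = list(c("a", "b"), NULL)), sch)
  expect_equal(unname(aggregate_spectrum(m2, "mean")), v)
})

test_that("mean aggregation matches a naive double-loop oracle", {
  sm <- random_spectra(5, seed = 17)
  expect_equal(unname(aggregate_spectrum(sm, "mean")),
               oracle_mean_aggregate(sm$counts), tolerance = 1e-12)
  expect_equal(sum(aggregate_spectrum(sm, "mean")), 1, tolerance = 1e-9)
})

test_that("all-zero samples are dropped under mean mode, kept under sum", {
  sch <- channel_schema("two", c("c1", "c2"))
  m <- spectrum_matrix(matrix(c(4, 4, 0, 0), 2, byrow = TRUE,
                              dimnames = list(c("a", "zero"), NULL)), sch)
  expect_warning(agg <- aggregate_spectrum(m, "mean"), "all-zero")
  expect_equal(unname(agg), c(0.5, 0.5))
  expect_silent(expect_equal(unname(aggregate_spectrum(m, "sum")), c(4, 4)))
})

test_that("cosine distance matches closed forms and rejects zero vectors", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_distance(c(1, 1, 0), 7 * c(1, 1, 0)), 0,
               tolerance = 1e-12)
  # symmetry and scaling invariance
  u <- c(3, 1, 4); v <- c(1, 5, 9)
  expect_equal(cosine_distance(u, v), cosine_distance(v, u))
  expect_equal(cosine_distance(2.5 * u, v), cosine_distance(u, v),
               tolerance = 1e-12)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero vector")
})

test_that("identical spectra in both groups give observed 0 and p = 1", {
  a <- delta_spectra("A[C>A]A", 3, prefix = "a")
  b <- delta_spectra("A[C>A]A", 4, prefix = "b")
  res <- amsd_test(a, b, n_perm = 200, seed = 1)
  expect_equal(res$observed_distance, 0)
  expect_true(all(abs(res$null_distances) < 1e-12))
  expect_equal(res$p_value, 1)
  expect_equal(amsd_exhaustive(a, b)$p_value, 1)
})

test_that("fully separated groups reach distance 1 and the p floor", {
  a <- delta_spectra("A[C>A]A", 10, prefix = "a")
  b <- delta_spectra("T[T>G]T", 10, prefix = "b")
  res <- amsd_test(a, b, n_perm = 10000, seed = 42)
  expect_equal(res$observed_distance, 1)
  expect_lte(res$p_value, 0.01)
})

test_that("exhaustive enumeration covers every split exactly once", {
  a <- random_spectra(1, seed = 1, prefix = "a")
  b <- random_spectra(1, seed = 2, prefix = "b")
  res <- amsd_exhaustive(a, b)
  expect_equal(res$n_permutations, 2L)
  expect_true(res$p_value %in% c(0.5, 1))
})

test_that("exhaustive p matches an independent enumeration oracle", {
  for (sizes in list(c(2, 2), c(3, 3), c(3, 5))) {
    a <- random_spectra(sizes[1], seed = sizes[1] * 10, prefix = "a")
    b <- random_spectra(sizes[2], seed = sizes[2] * 10 + 1, prefix = "b")
    for (mode in c("mean", "sum")) {
      res <- amsd_exhaustive(a, b, mode = mode)
      orc <- oracle_exhaustive_p(a$counts, b$counts, mode = mode)
      expect_equal(res$observed_distance, orc$observed, tolerance = 1e-12)
      expect_equal(res$p_value, orc$p, tolerance = 1e-12)
      expect_equal(res$n_permutations, choose(sum(sizes), sizes[1]))
      expect_equal(sort(res$null_distances), sort(orc$null),
                   tolerance = 1e-12)
    }
  }
})

test_that("exhaustive enumeration refuses to exceed its cap", {
  a <- random_spectra(10, seed = 1, prefix = "a")
  b <- random_spectra(10, seed = 2, prefix = "b")
  expect_error(amsd_exhaustive(a, b), "cap")
})

test_that("the test is symmetric in its two groups", {
  a <- random_spectra(4, seed = 3, prefix = "a")
  b <- random_spectra(6, seed = 4, prefix = "b")
  r_ab <- amsd_test(a, b, n_perm = 100, seed = 7)
  r_ba <- amsd_test(b, a, n_perm = 100, seed = 7)
  expect_equal(r_ab$observed_distance, r_ba$observed_distance)
  expect_equal(amsd_exhaustive(a, b)$p_value, amsd_exhaustive(b, a)$p_value)
})

test_that("mean-mode results are invariant to rescaling one sample", {
  a <- random_spectra(4, seed = 8, prefix = "a")
  b <- random_spectra(4, seed = 9, prefix = "b")
  a2 <- a
  a2$counts[2, ] <- a2$counts[2, ] * 37.5
  r1 <- amsd_test(a, b, n_perm = 300, seed = 11)
  r2 <- amsd_test(a2, b, n_perm = 300, seed = 11)
  expect_equal(r1$observed_distance, r2$observed_distance, tolerance = 1e-12)
  expect_equal(r1$null_distances, r2$null_distances, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("results are deterministic given a seed", {
  a <- random_spectra(5, seed = 21, prefix = "a")
  b <- random_spectra(5, seed = 22, prefix = "b")
  r1 <- amsd_test(a, b, n_perm = 500, seed = 99)
  r2 <- amsd_test(a, b, n_perm = 500, seed = 99)
  expect_identical(r1$null_distances, r2$null_distances)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("the two p-value conventions agree on the exceedance count", {
  a <- random_spectra(5, seed = 31, prefix = "a")
  b <- random_spectra(5, seed = 32, prefix = "b")
  r_f <- amsd_test(a, b, n_perm = 400, seed = 5,
                   p_convention = "fraction_ge")
  r_p <- amsd_test(a, b, n_perm = 400, seed = 5, p_convention = "plus_one")
  k <- r_f$n_exceedances
  expect_equal(r_f$p_value, k / 400)
  expect_equal(r_p$p_value, (k + 1) / 401)
  # floored case: separated groups, fraction_ge reports 0 with the flag
  sep_a <- delta_spectra("A[C>A]A", 8, prefix = "a")
  sep_b <- delta_spectra("T[T>G]T", 8, prefix = "b")
  rf <- amsd_test(sep_a, sep_b, n_perm = 1000, seed = 3)
  if (rf$n_exceedances == 0) {
    expect_true(rf$p_floored)
    expect_equal(rf$p_value, 0)
  }
})

test_that("schema mismatches and empty groups are rejected", {
  a <- random_spectra(3, seed = 41, prefix = "a")
  sch <- channel_schema("two", c("c1", "c2"))
  b <- spectrum_matrix(matrix(1, 2, 2, dimnames = list(c("x", "y"), NULL)),
                       sch)
  expect_error(amsd_test(a, b), "schema")
  empty <- spectrum_matrix(matrix(numeric(0), 0, 96,
                                  dimnames = list(NULL, sbs96_channels())))
  expect_error(amsd_test(a, empty), "at least one sample")
})

test_that("a registered plug-in distance drives the test unchanged", {
  a <- random_spectra(3, seed = 51, prefix = "a")
  b <- random_spectra(3, seed = 52, prefix = "b")
  r <- amsd_test(a, b, n_perm = 50, seed = 1, distance = "euclidean")
  agg_a <- aggregate_spectrum(a, "mean")
  agg_b <- aggregate_spectrum(b, "mean")
  expect_equal(r$observed_distance, sqrt(sum((agg_a - agg_b)^2)))
  expect_error(amsd_test(a, b, distance = "no_such_metric"), "unknown")
})
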
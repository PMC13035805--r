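# Shared fixtures and independent oracles, all built in code.

fixture_catalog <- make_fixture_catalog(seed = 1)
fixture_baseline <- mixture_spec(c(syn1 = 0.3, syn2 = 0.6, syn3 = 0.1))

# small random SBS96 spectrum matrix
random_spectra <- function(n_samples, seed, lambda = 20,
                           prefix = "s") {
  set.seed(seed)
  m <- matrix(rpois(n_samples * 96, lambda), nrow = n_samples,
              dimnames = list(paste0(prefix, seq_len(n_samples)),
                              sbs96_channels()))
  spectrum_matrix(m)
}

# spectrum matrix whose samples all sit on a single channel
delta_spectra <- function(channel, n_samples, total = 100, prefix = "d") {
  m <- matrix(0, n_samples, 96,
              dimnames = list(paste0(prefix, seq_len(n_samples)),
                              sbs96_channels()))
  m[, channel] <- total
  spectrum_matrix(m)
}

# -- independent oracles (plain R, no package internals) ------------------

# naive double-loop mean aggregation
oracle_mean_aggregate <- function(counts) {
  agg <- numeric(ncol(counts))
  for (i in seq_len(nrow(counts))) {
    f <- counts[i, ] / sum(counts[i, ])
    for (j in seq_len(ncol(counts))) agg[j] <- agg[j] + f[j]
  }
  agg / nrow(counts)
}

oracle_cosine <- function(u, v) {
  1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

# brute-force enumeration of the exact AMSD permutation p-value
oracle_exhaustive_p <- function(counts_a, counts_b, mode = "mean") {
  pooled <- rbind(counts_a, counts_b)
  na <- nrow(counts_a)
  agg <- function(rows) {
    sub <- pooled[rows, , drop = FALSE]
    if (mode == "mean") {
      oracle_mean_aggregate(sub)
    } else {
      colSums(sub)
    }
  }
  d_obs <- oracle_cosine(agg(seq_len(na)),
                         agg(na + seq_len(nrow(counts_b))))
  combos <- combn(nrow(pooled), na)
  d_null <- apply(combos, 2, function(rows) {
    oracle_cosine(agg(rows), agg(setdiff(seq_len(nrow(pooled)), rows)))
  })
  list(observed = d_obs,
       p = mean(d_null >= d_obs - 1e-12),
       null = d_null)
}

# textbook BH step-up adjusted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(1, adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# closed-form simple OLS slope and R^2
oracle_ols <- function(x, y) {
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - beta * mean(x)
  yhat <- a + beta * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(beta = beta, r2 = r2)
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_ranksum_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  nx <- length(x)
  ranks <- rank(vals)
  w_obs <- sum(ranks[seq_len(nx)])
  combos <- combn(n, nx)
  w_null <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- mean(w_null)
  mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-9)
}
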
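# Independent brute-force oracles, deliberately written with plain loops and
# probability-scale arithmetic so they share no code path with the package.

# Finite-bulk linkage posterior by direct enumeration: for each bulk,
# marginalize the likelihood over the number j of mutant-parent chromosomes
# among the 2N bulk chromosomes (j ~ Binomial(2N, f(r))), with symmetric
# per-read miscall eps; average the likelihood over the r grid and form the
# posterior odds against r = 0.5 on the probability scale.
oracle_posterior <- function(k_m, n_m, k_w, n_w,
                             pi0 = 0.05, eps = 0.01,
                             r_grid = seq(0.0005, 0.4995, length.out = 64),
                             n_ind = 123) {
  bulk_lik <- function(k, n, f) {
    if (n == 0) return(1)
    n2 <- 2 * n_ind
    total <- 0
    for (j in 0:n2) {
      p <- eps + (j / n2) * (1 - 2 * eps)
      total <- total + dbinom(j, n2, f) * dbinom(k, n, p)
    }
    total
  }
  lik_at <- function(r) {
    bulk_lik(k_m, n_m, 1 - r) * bulk_lik(k_w, n_w, (1 + r) / 3)
  }
  l_linked <- 0
  for (r in r_grid) l_linked <- l_linked + lik_at(r)
  l_linked <- l_linked / length(r_grid)
  l_null <- lik_at(0.5)
  pi0 * l_linked / (pi0 * l_linked + (1 - pi0) * l_null)
}

# Draw a random SNP-count configuration from the finite-bulk generative
# model itself (random r; unlinked with probability 1/2), depth <= max_depth.
random_snp_config <- function(max_depth = 50, eps = 0.01, n_ind = 123) {
  r <- if (runif(1) < 0.5) 0.5 else runif(1, 0, 0.5)
  n_m <- min(rpois(1, runif(1, 5, max_depth)), max_depth)
  n_w <- min(rpois(1, runif(1, 5, max_depth)), max_depth)
  c_m <- rbinom(1, 2 * n_ind, 1 - r)
  c_w <- rbinom(1, 2 * n_ind, (1 + r) / 3)
  k_m <- rbinom(1, n_m, eps + (c_m / (2 * n_ind)) * (1 - 2 * eps))
  k_w <- rbinom(1, n_w, eps + (c_w / (2 * n_ind)) * (1 - 2 * eps))
  list(k_m = k_m, n_m = n_m, k_w = k_w, n_w = n_w, r = r)
}

# Sliding windows enumerated the naive way: slide a cursor and collect every
# full window explicitly.
oracle_windows <- function(s, window_size, step) {
  starts <- integer(0)
  a <- 1
  while (a + window_size - 1 <= s) {
    starts <- c(starts, a)
    a <- a + step
  }
  starts
}

# Median as mid order statistics of a full sort.
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}
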
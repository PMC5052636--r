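test_that("expected allele frequencies follow the recessive F2 design", {
  expect_equal(expected_allele_freq(0, "mutant"), 1)
  expect_equal(expected_allele_freq(0.5, "mutant"), 0.5)
  expect_equal(expected_allele_freq(0, "wildtype"), 1 / 3)
  expect_equal(expected_allele_freq(0.5, "wildtype"), 0.5)
  expect_error(expected_allele_freq(0.6, "mutant"), "0.5")
})

test_that("wild-type bulk frequency matches genotype enumeration", {
  # enumerate F2 gamete pairs; among phenotypic wild types count
  # mutant-parent marker alleles (independent combinatorial oracle)
  for (r in c(0, 0.1, 0.3, 0.5)) {
    gam <- expand.grid(causal = c("m", "+"), marker = c("P1", "P2"))
    pg <- ifelse((gam$causal == "m") == (gam$marker == "P1"),
                 (1 - r) / 2, r / 2)
    num <- 0; den <- 0
    for (i in 1:4) for (j in 1:4) {
      if (gam$causal[i] == "m" && gam$causal[j] == "m") next  # mutant: excluded
      w <- pg[i] * pg[j]
      num <- num + w * ((gam$marker[i] == "P1") + (gam$marker[j] == "P1"))
      den <- den + 2 * w
    }
    expect_equal(expected_allele_freq(r, "wildtype"), num / den)
  }
})

test_that("log-likelihood handles the degenerate regimes", {
  p <- linkage_params()
  # no data: flat likelihood
  expect_equal(snp_log_likelihood(0, 0, 0, 0, c(0, 0.2, 0.5), p),
               c(0, 0, 0))
  # complete linkage without error cannot produce an alternate-allele read
  p0 <- linkage_params(epsilon = 0)
  expect_identical(snp_log_likelihood(39, 40, 13, 40, 0, p0), -Inf)
  expect_error(snp_log_likelihood(5, 4, 0, 0, 0.1, p), "counts")
})

test_that("posterior equals the prior at zero depth and reacts to evidence", {
  p <- linkage_params()
  expect_identical(linkage_posterior(0, 0, 0, 0, p), p$pi)
  expect_identical(linkage_posterior(0, 0, 0, 0, p, mode = "exact"), p$pi)
  # strong skew in both bulks: near-certain linkage
  expect_gt(linkage_posterior(40, 40, 13, 40, p), 0.99)
  expect_gt(linkage_posterior(40, 40, 13, 40, p, mode = "exact"), 0.99)
  # balanced counts: data favor r = 0.5, posterior drops below the prior
  expect_lt(linkage_posterior(20, 40, 20, 40, p), p$pi)
  expect_lt(linkage_posterior(20, 40, 20, 40, p, mode = "exact"), p$pi)
})

test_that("posterior is monotone in the mutant-bulk allele excess", {
  p <- linkage_params()
  kw <- 13  # wild-type bulk at its expectation, n = 40
  for (mode in c("default", "exact")) {
    post <- vapply(0:40, function(k)
      linkage_posterior(k, 40, kw, 40, p, mode = mode), numeric(1))
    expect_true(all(diff(post) >= -1e-12))
    expect_true(all(post >= 0 & post <= 1))
  }
})

test_that("exact-mode posterior matches the brute-force enumeration oracle", {
  p <- linkage_params()
  set.seed(77)
  for (i in 1:25) {
    cfg <- random_snp_config()
    got <- linkage_posterior(cfg$k_m, cfg$n_m, cfg$k_w, cfg$n_w, p,
                             mode = "exact")
    want <- oracle_posterior(cfg$k_m, cfg$n_m, cfg$k_w, cfg$n_w)
    expect_lt(abs(got - want), 1e-3)
  }
})

test_that("table-level posteriors are per-SNP, order-preserving and validated", {
  p <- linkage_params()
  empty <- compute_posteriors(
    structure(data.frame(chrom = character(), pos = integer(),
                         mut_ref = integer(), mut_alt = integer(),
                         wt_ref = integer(), wt_alt = integer()),
              class = c("bulk_counts", "data.frame")), p)
  expect_equal(nrow(empty), 0)

  tab <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                    mut_ref = c(40, 20, 0), mut_alt = c(0, 20, 0),
                    wt_ref = c(13, 20, 0), wt_alt = c(27, 20, 0))
  post <- compute_posteriors(tab, p)
  expect_equal(post$pos, tab$pos)
  # each row matches the single-SNP computation (per-SNP independence)
  for (i in 1:3) {
    expect_equal(post$posterior[i],
                 linkage_posterior(tab$mut_ref[i],
                                   tab$mut_ref[i] + tab$mut_alt[i],
                                   tab$wt_ref[i],
                                   tab$wt_ref[i] + tab$wt_alt[i], p),
                 tolerance = 1e-12)
  }
  expect_error(compute_posteriors(tab[c(2, 1, 3), ], p), "sorted")
})

test_that("unlinked SNPs rarely reach high posteriors (calibration smoke test)", {
  set.seed(88)
  n_snp <- 2000
  c_m <- rbinom(n_snp, 246, 0.5)
  c_w <- rbinom(n_snp, 246, 0.5)
  n_m <- rpois(n_snp, 20)
  n_w <- rpois(n_snp, 20)
  eps <- 0.01
  tab <- data.frame(
    chrom = "chr1", pos = seq_len(n_snp),
    mut_ref = rbinom(n_snp, n_m, eps + (c_m / 246) * (1 - 2 * eps)),
    wt_ref = rbinom(n_snp, n_w, eps + (c_w / 246) * (1 - 2 * eps))
  )
  tab$mut_alt <- n_m - tab$mut_ref
  tab$wt_alt <- n_w - tab$wt_ref
  post <- compute_posteriors(tab, linkage_params())
  expect_lt(mean(post$posterior > 0.95), 0.01)
})

test_that("posterior TSV round-trips", {
  p <- structure(data.frame(chrom = "chr1", pos = c(1L, 2L),
                            posterior = c(0.25, 0.5)),
                 class = c("linkage_posteriors", "data.frame"))
  d <- withr::local_tempdir()
  write_posteriors(p, file.path(d, "p.tsv"))
  back <- read_posteriors(file.path(d, "p.tsv"))
  expect_equal(back$posterior, p$posterior)
})
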
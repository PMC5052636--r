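#' Parameters of the Bayesian bulked-segregant linkage model
#'
#' The model compares, per SNP, a "linked" hypothesis (the SNP sits at
#' recombination fraction `r < 0.5` from the causal locus, with a uniform
#' prior over `r` on a quadrature grid) against an "unlinked" hypothesis
#' (`r = 0.5`). The prior probability of linkage is `pi`; reads miscall the
#' allele symmetrically with probability `epsilon`.
#'
#' @param pi Prior probability that a SNP is linked, in (0, 1).
#' @param epsilon Per-read allele miscall probability, in `[0, 0.5)`.
#' @param grid_size Number of quadrature points for `r`.
#' @param r_min,r_max Grid endpoints, strictly inside (0, 0.5).
#' @param n_mutant,n_wt Bulk sizes in individuals (used by the exact
#'   finite-bulk likelihood).
#' @return A `linkage_params` list, including the grid `r_grid`.
#' @export
linkage_params <- function(pi = 0.05, epsilon = 0.01, grid_size = 64,
                           r_min = 0.0005, r_max = 0.4995,
                           n_mutant = 123, n_wt = 123) {
  if (pi <= 0 || pi >= 1) stop("pi must be in (0, 1)")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  if (r_min <= 0 || r_max >= 0.5 || r_min >= r_max)
    stop("r grid must lie strictly inside (0, 0.5)")
  structure(list(pi = pi, epsilon = epsilon,
                 r_grid = seq(r_min, r_max, length.out = grid_size),
                 n_mutant = n_mutant, n_wt = n_wt),
            class = "linkage_params")
}

#' Expected mutant-parent allele frequency in a bulk
#'
#' For a recessive mutation in an F2 design, the frequency of the
#' mutant-parent allele among the chromosomes of a bulk at a SNP with
#' recombination fraction `r` from the causal locus is `1 - r` in the mutant
#' bulk (at `r = 0` only the mutant-parent allele is present) and
#' `1/3 + r/3` in the phenotypically wild-type bulk (which is 1/3 `++`, 2/3
#' `m+`). At `r = 0.5` both give 1/2.
#'
#' @param r Recombination fraction(s), in `[0, 0.5]`.
#' @param bulk `"mutant"` or `"wildtype"`.
#' @return Allele frequency (vectorized over `r`).
#' @examples
#' expected_allele_freq(0, "mutant")    # 1
#' expected_allele_freq(0, "wildtype")  # 1/3
#' @export
expected_allele_freq <- function(r, bulk = c("mutant", "wildtype")) {
  bulk <- match.arg(bulk)
  if (any(r < 0 | r > 0.5)) stop("r must be in [0, 0.5]")
  if (bulk == "mutant") 1 - r else (1 + r) / 3
}

# Internal: log-likelihood of k reference-allele reads out of n for one bulk,
# at bulk allele frequency f, with per-read miscall epsilon.
# default mode: binomial at the expected frequency.
# exact mode: marginalize over the Binomial(2N, f) number of mutant-parent
# chromosomes among the 2N bulk chromosomes.
bulk_loglik <- function(k, n, f, epsilon, mode = "default", n_ind = 123) {
  if (n == 0) return(rep(0, length(f)))
  if (mode == "default") {
    dbinom(k, n, f * (1 - epsilon) + (1 - f) * epsilon, log = TRUE)
  } else {
    n2 <- 2 * n_ind
    j <- 0:n2
    p <- epsilon + (j / n2) * (1 - 2 * epsilon)
    lread <- dbinom(k, n, p, log = TRUE)
    vapply(f, function(ff) {
      logsumexp(dbinom(j, n2, ff, log = TRUE) + lread)
    }, numeric(1))
  }
}

#' Per-SNP log-likelihood of bulk allele counts given a recombination fraction
#'
#' In the default mode each bulk's reference-allele count is binomial at the
#' expected allele frequency (see [expected_allele_freq()]) convolved with
#' the symmetric miscall rate. In the exact mode the likelihood additionally
#' marginalizes over the binomially distributed number of mutant-parent
#' chromosomes among the `2N` chromosomes of each finite bulk; this is the
#' model the enumeration oracle in the test-suite recomputes by brute force.
#'
#' @param k_m,n_m Mutant-bulk reference (mutant-parent) allele reads and
#'   total reads.
#' @param k_w,n_w The same for the wild-type bulk.
#' @param r Recombination fraction(s) in `[0, 0.5]` (vectorized).
#' @param params A [linkage_params()].
#' @param mode `"default"` or `"exact"`.
#' @return Log-likelihood, one value per element of `r`. Zero when both
#'   depths are zero.
#' @export
snp_log_likelihood <- function(k_m, n_m, k_w, n_w, r, params = linkage_params(),
                               mode = c("default", "exact")) {
  mode <- match.arg(mode)
  if (k_m < 0 || k_m > n_m || k_w < 0 || k_w > n_w)
    stop("counts must satisfy 0 <= k <= n")
  if (any(r < 0 | r > 0.5)) stop("r must be in [0, 0.5]")
  bulk_loglik(k_m, n_m, expected_allele_freq(r, "mutant"),
              params$epsilon, mode, params$n_mutant) +
    bulk_loglik(k_w, n_w, expected_allele_freq(r, "wildtype"),
                params$epsilon, mode, params$n_wt)
}

#' Posterior probability that a SNP is linked to the causal locus
#'
#' `posterior = pi * Lbar / (pi * Lbar + (1 - pi) * L(0.5))` where `Lbar` is
#' the mean likelihood over the `r` grid (uniform prior on `r` given
#' linkage). Computed on the log scale with log-sum-exp; a SNP with zero
#' depth in both bulks returns exactly `pi`, and degenerate likelihoods never
#' produce `NaN`.
#'
#' @inheritParams snp_log_likelihood
#' @return Posterior linkage probability in `[0, 1]`.
#' @examples
#' linkage_posterior(40, 40, 13, 40)           # ~1: strong linkage signal
#' linkage_posterior(20, 40, 20, 40)           # < pi: data favor r = 0.5
#' @export
linkage_posterior <- function(k_m, n_m, k_w, n_w, params = linkage_params(),
                              mode = c("default", "exact")) {
  mode <- match.arg(mode)
  if (n_m == 0 && n_w == 0) return(params$pi)  # no data: prior, exactly
  ll <- snp_log_likelihood(k_m, n_m, k_w, n_w, params$r_grid, params, mode)
  l_linked <- logsumexp(ll) - log(length(params$r_grid))
  l_null <- snp_log_likelihood(k_m, n_m, k_w, n_w, 0.5, params, mode)
  if (!is.finite(l_linked) && !is.finite(l_null)) return(params$pi)
  # posterior odds on the log scale
  1 / (1 + exp(log(1 - params$pi) - log(params$pi) + l_null - l_linked))
}

#' Compute linkage posteriors for a table of SNP counts
#'
#' One posterior per SNP, independently (a SNP's posterior does not depend
#' on its neighbors); input must be sorted by (chrom, pos) and the order is
#' preserved. The default mode is fully vectorized over SNPs and grid.
#'
#' @param counts A `bulk_counts` data.frame (columns `chrom`, `pos`,
#'   `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`).
#' @param params A [linkage_params()].
#' @param mode `"default"` (expected-frequency likelihood) or `"exact"`
#'   (finite-bulk marginalization; slower).
#' @return A `linkage_posteriors` data.frame: `chrom`, `pos`, `posterior`.
#' @export
compute_posteriors <- function(counts, params = linkage_params(),
                               mode = c("default", "exact")) {
  mode <- match.arg(mode)
  if (nrow(counts) == 0)
    return(structure(data.frame(chrom = character(), pos = integer(),
                                posterior = numeric()),
                     class = c("linkage_posteriors", "data.frame")))
  ord <- order(counts$chrom, counts$pos)
  if (!identical(ord, seq_len(nrow(counts))))
    stop("counts must be sorted by (chrom, pos)")
  k_m <- counts$mut_ref
  n_m <- counts$mut_ref + counts$mut_alt
  k_w <- counts$wt_ref
  n_w <- counts$wt_ref + counts$wt_alt

  if (mode == "default") {
    eps <- params$epsilon
    fm <- expected_allele_freq(params$r_grid, "mutant")
    fw <- expected_allele_freq(params$r_grid, "wildtype")
    pm <- fm * (1 - eps) + (1 - fm) * eps
    pw <- fw * (1 - eps) + (1 - fw) * eps
    # SNP x grid log-likelihood matrices
    ll <- vapply(seq_along(params$r_grid), function(g) {
      dbinom(k_m, n_m, pm[g], log = TRUE) + dbinom(k_w, n_w, pw[g], log = TRUE)
    }, numeric(nrow(counts)))
    ll <- matrix(ll, nrow = nrow(counts))
    mx <- apply(ll, 1, max)
    l_linked <- ifelse(is.finite(mx),
                       mx + log(rowMeans(exp(ll - mx))), mx)
    l_null <- dbinom(k_m, n_m, 0.5, log = TRUE) +
      dbinom(k_w, n_w, 0.5, log = TRUE)
    post <- 1 / (1 + exp(log(1 - params$pi) - log(params$pi) +
                           l_null - l_linked))
    post[!is.finite(l_linked) & !is.finite(l_null)] <- params$pi
    post[n_m == 0 & n_w == 0] <- params$pi  # no data: prior, exactly
  } else {
    post <- vapply(seq_len(nrow(counts)), function(i)
      linkage_posterior(k_m[i], n_m[i], k_w[i], n_w[i], params, mode),
      numeric(1))
  }
  structure(data.frame(chrom = counts$chrom, pos = counts$pos,
                       posterior = post, stringsAsFactors = FALSE),
            class = c("linkage_posteriors", "data.frame"))
}

#' Write / read a posterior table as TSV (chrom, pos, posterior)
#'
#' @param posteriors A `linkage_posteriors` data.frame.
#' @param path File path.
#' @return Invisibly `path` (write) or a `linkage_posteriors` (read).
#' @export
write_posteriors <- function(posteriors, path) {
  write.table(as.data.frame(posteriors), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_posteriors
#' @export
read_posteriors <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "posterior") %in% names(p)))
  structure(p, class = c("linkage_posteriors", "data.frame"))
}
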
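#' Simulate an F2 population under the Haldane model
#'
#' Gametes are generated marker-by-marker as a Markov chain on parental
#' origin: between adjacent markers the origin switches with the
#' recombination fraction implied by their cM distance under the Haldane map
#' function (crossovers form a Poisson process on the cM scale; no
#' interference). Chromosomes segregate independently. The causal mutation is
#' carried by parent 1 (the mutant parent), so the causal genotype of an
#' individual is `mm`, `m+` or `++` according to how many of its two gametes
#' are of parent-1 origin at the causal marker.
#'
#' @param map A `bsr_genmap` whose markers are the loci to simulate.
#' @param causal_chrom,causal_pos The causal locus; must coincide with a
#'   marker of the map.
#' @param n Number of F2 individuals (>= 1).
#' @param seed Integer seed.
#'
#' @return An `f2_population`: a list with per-chromosome logical matrices
#'   `g1`, `g2` (`n` rows, one column per marker; `TRUE` = parent-1 origin),
#'   the `map`, the causal locus, and `causal_genotype` (factor with levels
#'   `mm`, `m+`, `++`).
#' @examples
#' ref <- make_reference(c(chr1 = 1e5), 2, seed = 1)
#' gm <- make_genetic_map(ref, 10, seed = 1)
#' pop <- simulate_f2_population(gm, "chr1", gm$pos[5], n = 100, seed = 3)
#' table(pop$causal_genotype)
#' @export
simulate_f2_population <- function(map, causal_chrom, causal_pos, n, seed) {
  if (n < 1) stop("n must be >= 1")
  hit <- which(map$chrom == causal_chrom & map$pos == causal_pos)
  if (length(hit) != 1)
    stop("causal locus must coincide with exactly one map marker")
  set.seed(seed)

  chroms <- unique(map$chrom)
  sim_gametes <- function(cm, n_gam) {
    nm <- length(cm)
    first <- rbinom(n_gam, 1, 0.5)
    orig <- matrix(0L, nrow = n_gam, ncol = nm)
    orig[, 1] <- first
    if (nm > 1) {
      r <- haldane_r(diff(cm))
      state <- first
      for (j in 2:nm) {
        sw <- rbinom(n_gam, 1, r[j - 1])
        state <- (state + sw) %% 2L
        orig[, j] <- state
      }
    }
    orig == 0L  # TRUE = parent-1 origin
  }

  geno <- lapply(chroms, function(ch) {
    cm <- map$cm[map$chrom == ch]
    list(g1 = sim_gametes(cm, n), g2 = sim_gametes(cm, n))
  })
  names(geno) <- chroms

  causal_idx_local <- which(map$pos[map$chrom == causal_chrom] == causal_pos)
  gc <- geno[[causal_chrom]]
  n_m <- gc$g1[, causal_idx_local] + gc$g2[, causal_idx_local]
  causal_genotype <- factor(c("++", "m+", "mm")[n_m + 1],
                            levels = c("mm", "m+", "++"))

  structure(list(geno = geno, map = map, n = n,
                 causal_chrom = causal_chrom, causal_pos = causal_pos,
                 causal_genotype = causal_genotype),
            class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat("F2 population:", x$n, "individuals,",
      nrow(x$map), "markers; causal", x$causal_chrom, x$causal_pos, "\n")
  print(table(x$causal_genotype))
  invisible(x)
}

# Internal: subset an f2_population by individual index.
subset_population <- function(pop, idx) {
  geno <- lapply(pop$geno, function(g)
    list(g1 = g$g1[idx, , drop = FALSE], g2 = g$g2[idx, , drop = FALSE]))
  structure(list(geno = geno, map = pop$map, n = length(idx),
                 causal_chrom = pop$causal_chrom,
                 causal_pos = pop$causal_pos,
                 causal_genotype = pop$causal_genotype[idx]),
            class = "f2_population")
}

#' Phenotype an F2 population and build mutant / wild-type bulks
#'
#' The mutant phenotype is recessive: only `mm` individuals are mutant. The
#' mutant bulk is a random sample of `n_mutant` `mm` individuals; the
#' wild-type bulk a random sample (without replacement) of `n_wt`
#' phenotypically wild-type (`m+` or `++`) individuals.
#'
#' @param population An `f2_population`.
#' @param n_mutant,n_wt Bulk sizes (defaults follow the classic 123 + 123
#'   design).
#' @param seed Integer seed.
#' @return A list with `mutant` and `wildtype` (each an `f2_population`
#'   restricted to the bulked individuals) and the sampled indices.
#' @export
phenotype_and_bulk <- function(population, n_mutant = 123, n_wt = 123,
                               seed = 1) {
  set.seed(seed)
  mm <- which(population$causal_genotype == "mm")
  wt <- which(population$causal_genotype != "mm")
  if (length(mm) < n_mutant)
    stop(sprintf("need %d mm individuals but population has only %d",
                 n_mutant, length(mm)))
  if (length(wt) < n_wt)
    stop(sprintf("need %d wild-type individuals but population has only %d",
                 n_wt, length(wt)))
  mi <- sample(mm, n_mutant)
  wi <- sample(wt, n_wt)
  list(mutant = subset_population(population, mi),
       wildtype = subset_population(population, wi),
       mutant_idx = mi, wt_idx = wi)
}

#' Simulate RNA-seq allele counts for the two bulks
#'
#' Per SNP and bulk, sequencing depth is Poisson(`mean_depth`); each read is
#' drawn from a uniformly random chromosome of the bulk and reports that
#' chromosome's parental allele, flipped with probability `epsilon`
#' (symmetric per-read miscall). Parent-1 carries the reference allele by
#' convention (its background is the reference assembly).
#'
#' @param bulks The list returned by [phenotype_and_bulk()].
#' @param mean_depth Mean per-SNP read depth per bulk (> 0).
#' @param epsilon Per-read allele miscall probability, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param reference Optional `bsr_reference` used to assign concrete
#'   ref/alt bases at each SNP; otherwise alleles are reported as `A`/`B`.
#' @return A `bulk_counts` data.frame sorted by (chrom, pos) with columns
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `mut_ref`, `mut_alt`,
#'   `wt_ref`, `wt_alt`.
#' @export
simulate_bulk_allele_counts <- function(bulks, mean_depth, epsilon, seed,
                                        reference = NULL) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  if (bulks$mutant$n == 0 || bulks$wildtype$n == 0) stop("empty bulk")
  set.seed(seed)
  map <- bulks$mutant$map

  count_bulk <- function(bulk) {
    n_chrom_tot <- 2 * bulk$n
    unlist(lapply(unique(map$chrom), function(ch) {
      g <- bulk$geno[[ch]]
      colSums(g$g1) + colSums(g$g2)  # parent-1 chromosome count per SNP
    }), use.names = FALSE)
  }
  c_m <- count_bulk(bulks$mutant)
  c_w <- count_bulk(bulks$wildtype)
  s <- nrow(map)
  n_m <- rpois(s, mean_depth)
  n_w <- rpois(s, mean_depth)
  p_m <- epsilon + (c_m / (2 * bulks$mutant$n)) * (1 - 2 * epsilon)
  p_w <- epsilon + (c_w / (2 * bulks$wildtype$n)) * (1 - 2 * epsilon)
  k_m <- rbinom(s, n_m, p_m)
  k_w <- rbinom(s, n_w, p_w)

  if (!is.null(reference)) {
    ref_allele <- vapply(seq_len(s), function(i) {
      as.character(Biostrings::subseq(reference$seqs[[map$chrom[i]]],
                                      map$pos[i], map$pos[i]))
    }, character(1))
    bases <- c("A", "C", "G", "T")
    alt_allele <- vapply(ref_allele, function(b) sample(setdiff(bases, b), 1),
                         character(1), USE.NAMES = FALSE)
  } else {
    ref_allele <- rep("A", s)
    alt_allele <- rep("B", s)
  }

  counts <- data.frame(
    chrom = map$chrom, pos = map$pos,
    ref_allele = ref_allele, alt_allele = alt_allele,
    mut_ref = k_m, mut_alt = n_m - k_m,
    wt_ref = k_w, wt_alt = n_w - k_w,
    stringsAsFactors = FALSE
  )
  counts <- counts[order(counts$chrom, counts$pos), ]
  rownames(counts) <- NULL
  structure(counts, class = c("bulk_counts", "data.frame"))
}

#' Write / read a bulk allele-count table as TSV
#'
#' @param counts A `bulk_counts` data.frame.
#' @param path File path.
#' @return Invisibly `path` (write) or a `bulk_counts` (read).
#' @export
write_bulk_counts <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read bulk allele counts from a VCF with per-sample allele depths
#'
#' Expects a VCF holding the two pooled bulks as samples with `AD`
#' (ref,alt allele depth) genotype fields, as produced by standard variant
#' callers run on the pooled RNA-seq alignments.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param mutant_sample,wt_sample Sample names of the mutant and wild-type
#'   bulks in the VCF.
#' @return A `bulk_counts` data.frame.
#' @export
read_bulk_counts_vcf <- function(path, mutant_sample, wt_sample) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  for (s in c(mutant_sample, wt_sample))
    if (!s %in% colnames(ad)) stop("sample not in VCF: ", s)
  split_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    cbind(as.integer(vapply(parts, `[`, character(1), 1)),
          as.integer(vapply(parts, `[`, character(1), 2)))
  }
  m <- split_ad(ad[, mutant_sample])
  w <- split_ad(ad[, wt_sample])
  fix <- vcfR::getFIX(v)
  counts <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"],
    mut_ref = m[, 1], mut_alt = m[, 2],
    wt_ref = w[, 1], wt_alt = w[, 2],
    stringsAsFactors = FALSE
  )
  counts <- counts[order(counts$chrom, counts$pos), ]
  rownames(counts) <- NULL
  structure(counts, class = c("bulk_counts", "data.frame"))
}

#' @rdname write_bulk_counts
#' @export
read_bulk_counts <- function(path) {
  counts <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "mut_ref", "mut_alt", "wt_ref", "wt_alt")
  if (!all(need %in% names(counts)))
    stop("bulk counts TSV must have columns: ", paste(need, collapse = ", "))
  structure(counts, class = c("bulk_counts", "data.frame"))
}
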
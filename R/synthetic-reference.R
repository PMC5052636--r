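#' Generate a synthetic reference genome with non-overlapping genes
#'
#' Builds a random DNA reference (uniform base composition) and scatters
#' non-overlapping gene models across each chromosome. The result stands in
#' for a real assembly in desk-scale recovery experiments: coordinates are
#' 1-based and inclusive throughout.
#'
#' Genes are placed uniformly at random subject to non-overlap, by sampling
#' the gaps between consecutive genes; adjacency is allowed. Gene widths are
#' drawn uniformly from `gene_width`.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp
#'   (names become chromosome identifiers). Each length must be >= 10000.
#' @param n_genes Total number of genes, allocated to chromosomes
#'   proportionally to their length.
#' @param seed Integer seed; the output is reproducible for a fixed seed.
#' @param gene_width Length-2 numeric, min and max gene width in bp.
#'
#' @return An object of class `bsr_reference`: a list with
#'   `seqs` (a [Biostrings::DNAStringSet]) and `genes` (a data.frame with
#'   columns `gene_id`, `chrom`, `start`, `end`, `strand`).
#' @examples
#' ref <- make_reference(c(chr1 = 5e4), n_genes = 5, seed = 1)
#' ref$genes
#' @export
make_reference <- function(chrom_lengths, n_genes, seed,
                           gene_width = c(2000, 5000)) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must have unique names")
  if (any(chrom_lengths < 10000))
    stop("chromosome lengths must be >= 10 kb")
  if (n_genes < 0) stop("n_genes must be non-negative")
  set.seed(seed)

  chrom_names <- names(chrom_lengths)
  chrom_lengths <- setNames(as.integer(chrom_lengths), chrom_names)
  # proportional allocation, remainder to the largest chromosomes
  frac <- chrom_lengths / sum(chrom_lengths)
  n_per <- floor(frac * n_genes)
  rem <- n_genes - sum(n_per)
  if (rem > 0) {
    ord <- order(chrom_lengths, decreasing = TRUE)
    n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1
  }

  seqs <- Biostrings::DNAStringSet(vapply(chrom_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- names(chrom_lengths)

  genes <- do.call(rbind, lapply(seq_along(chrom_lengths), function(i) {
    n <- n_per[i]
    if (n == 0) return(NULL)
    L <- chrom_lengths[i]
    widths <- sample(seq(gene_width[1], gene_width[2]), n, replace = TRUE)
    free <- L - sum(widths)
    if (free < 0)
      stop(sprintf("cannot place %d genes of total width %d on %s (%d bp)",
                   n, sum(widths), names(chrom_lengths)[i], L))
    # uniform non-overlapping placement: sample the leading gaps
    gaps <- sort(sample(0:free, n, replace = TRUE))
    starts <- gaps + cumsum(c(0L, widths[-n])) + 1L
    data.frame(
      chrom = names(chrom_lengths)[i],
      start = starts,
      end = starts + widths - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  } else {
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand")]
    rownames(genes) <- NULL
  }

  structure(list(seqs = seqs, genes = genes,
                 chrom_lengths = setNames(as.integer(chrom_lengths),
                                          names(chrom_lengths))),
            class = "bsr_reference")
}

#' @export
print.bsr_reference <- function(x, ...) {
  cat("Synthetic reference:", length(x$seqs), "chromosome(s),",
      sum(x$chrom_lengths), "bp,", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Write a reference genome to FASTA and GFF3
#'
#' @param reference A `bsr_reference`.
#' @param fasta,gff3 Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta, gff3) {
  Biostrings::writeXStringSet(reference$seqs, fasta)
  g <- reference$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    type = "gene",
    ID = g$gene_id
  )
  rtracklayer::export.gff3(gr, gff3)
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read a reference genome from FASTA and GFF3
#'
#' @param fasta,gff3 Input file paths (as written by [write_reference()]).
#' @return A `bsr_reference`.
#' @export
read_reference <- function(fasta, gff3) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff3)
  genes <- data.frame(
    gene_id = gr$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  structure(list(seqs = seqs, genes = genes,
                 chrom_lengths = setNames(Biostrings::width(seqs),
                                          names(seqs))),
            class = "bsr_reference")
}

#' Generate a synthetic genetic map with centromeric recombination suppression
#'
#' Marker physical positions are drawn uniformly per chromosome; genetic
#' positions accumulate at a constant rate (`cm_per_mb`) on the chromosome
#' arms, reduced by `suppression_factor` inside the centromere span. This
#' emulates the familiar sigmoid shape of genetic-vs-physical position plots,
#' where the centromeric region shows low recombination per Mb.
#'
#' @param reference A `bsr_reference`.
#' @param n_markers Total marker (SNP) count, allocated proportionally to
#'   chromosome length.
#' @param centromere Either `NULL` (no suppressed region) or a data.frame
#'   with columns `chrom`, `start`, `end` giving the suppressed span per
#'   chromosome (bp, 1-based inclusive; must lie inside the chromosome).
#' @param suppression_factor Ratio of centromeric to arm recombination rate,
#'   in (0, 1]. `1` gives a uniform map.
#' @param cm_per_mb Arm recombination rate in cM/Mb.
#' @param seed Integer seed.
#'
#' @return A `bsr_genmap`: data.frame with columns `chrom`, `pos` (bp,
#'   strictly increasing within chromosome) and `cm` (non-decreasing).
#' @examples
#' ref <- make_reference(c(chr1 = 1e5), n_genes = 2, seed = 1)
#' gm <- make_genetic_map(ref, n_markers = 20,
#'                        centromere = data.frame(chrom = "chr1",
#'                                                start = 4e4, end = 6e4),
#'                        suppression_factor = 0.1, seed = 2)
#' @export
make_genetic_map <- function(reference, n_markers, centromere = NULL,
                             suppression_factor = 1, cm_per_mb = 2,
                             seed = 1) {
  if (suppression_factor <= 0 || suppression_factor > 1)
    stop("suppression_factor must be in (0, 1]")
  if (cm_per_mb <= 0) stop("cm_per_mb must be positive")
  lens <- reference$chrom_lengths
  if (!is.null(centromere)) {
    for (i in seq_len(nrow(centromere))) {
      cc <- centromere$chrom[i]
      if (!cc %in% names(lens)) stop("centromere chromosome not in reference")
      if (centromere$start[i] < 1 || centromere$end[i] > lens[[cc]] ||
          centromere$start[i] >= centromere$end[i])
        stop("centromere span must lie inside the chromosome")
    }
  }
  set.seed(seed)
  frac <- lens / sum(lens)
  n_per <- pmax(2L, floor(frac * n_markers))

  map <- do.call(rbind, lapply(seq_along(lens), function(i) {
    chrom <- names(lens)[i]
    pos <- sort(sample.int(lens[[i]], n_per[i]))
    cen <- if (!is.null(centromere) && chrom %in% centromere$chrom) {
      centromere[centromere$chrom == chrom, , drop = FALSE]
    } else NULL
    # genetic position = integral of the rate function over [0, pos]
    cm <- cm_per_mb * pos / 1e6
    if (!is.null(cen)) {
      overlap <- pmin(pos, cen$end[1]) - cen$start[1] + 1
      overlap <- pmax(overlap, 0)
      overlap <- pmin(overlap, cen$end[1] - cen$start[1] + 1)
      cm <- cm - (1 - suppression_factor) * cm_per_mb * overlap / 1e6
    }
    data.frame(chrom = chrom, pos = pos, cm = cm, stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL
  # positions sampled without replacement are distinct; cM monotone by
  # construction (rate > 0 everywhere)
  structure(map, class = c("bsr_genmap", "data.frame"))
}

#' Write / read a genetic map as TSV (chrom, pos, cm)
#'
#' @param map A `bsr_genmap`.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_genetic_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "cm") %in% names(map)))
  structure(map, class = c("bsr_genmap", "data.frame"))
}

#' Interpolate genetic position (cM) at physical coordinates
#'
#' Linear interpolation between flanking markers; constant extrapolation
#' beyond the terminal markers of a chromosome.
#'
#' @param map A `bsr_genmap`.
#' @param chrom Chromosome identifier.
#' @param bp Physical positions (numeric vector).
#' @return Genetic positions in cM.
#' @export
interpolate_cm <- function(map, chrom, bp) {
  m <- map[map$chrom == chrom, ]
  if (nrow(m) < 2) stop("need >= 2 markers on chromosome ", chrom)
  approx(m$pos, m$cm, xout = bp, rule = 2, ties = "ordered")$y
}
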
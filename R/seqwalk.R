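#' Demultiplex barcoded reads
#'
#' A read is assigned to a library iff its prefix exactly matches that
#' library's barcode (6-nt barcodes leave no safe mismatch margin); the
#' barcode is stripped from assigned reads. Reads matching no barcode are
#' counted as unassigned, so that
#' `sum(assigned) + unassigned == nrow(reads)` always holds.
#'
#' @param reads data.frame with columns `id`, `sequence` (and optionally
#'   `quality`, stripped in step with the sequence).
#' @param barcodes Named character vector, `library label -> barcode`;
#'   barcodes must be distinct and of equal length.
#' @return A list: `libraries` (named list of read data.frames, barcode
#'   removed), `unassigned` (count), `counts` (named integer vector per
#'   library plus `unassigned` and `total`).
#' @examples
#' r <- data.frame(id = "a", sequence = "GTCGATACGT")
#' demultiplex(r, c(mutant = "GTCGAT", control = "CTGCTA"))$counts
#' @export
demultiplex <- function(reads, barcodes) {
  if (anyDuplicated(barcodes)) stop("duplicate barcode")
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1) stop("barcodes must have equal length")
  prefix <- substr(reads$sequence, 1, bl)
  lib <- names(barcodes)[match(prefix, barcodes)]
  libraries <- lapply(names(barcodes), function(nm) {
    sel <- which(!is.na(lib) & lib == nm)
    out <- reads[sel, , drop = FALSE]
    out$sequence <- substring(out$sequence, bl + 1)
    if ("quality" %in% names(out))
      out$quality <- substring(out$quality, bl + 1)
    rownames(out) <- NULL
    out
  })
  names(libraries) <- names(barcodes)
  unassigned <- sum(is.na(lib))
  counts <- c(vapply(libraries, nrow, integer(1)),
              unassigned = unassigned, total = nrow(reads))
  list(libraries = libraries, unassigned = unassigned, counts = counts)
}

#' Trim the transposon terminal tag and extract genomic flanks
#'
#' After demultiplexing, a genuine Seq-walking read starts with the
#' transposon terminal (TIR-derived) tag followed by the genomic flank. The
#' tag prefix is matched allowing up to `max_mismatch` substitutions; on a
#' match the remainder of the read is returned as the flank, otherwise the
#' read is rejected (reason `"short"` if shorter than the tag, `"tag"` on a
#' failed match).
#'
#' @param reads Barcode-stripped read data.frame (`id`, `sequence`).
#' @param tir_tag Expected tag sequence (non-empty).
#' @param max_mismatch Maximum substitutions tolerated in the tag.
#' @return A list: `flanks` (data.frame `id`, `flank`), `rejected`
#'   (data.frame `id`, `reason`).
#' @export
trim_mu_flank <- function(reads, tir_tag, max_mismatch = 2) {
  if (nchar(tir_tag) == 0) stop("tir_tag must be non-empty")
  tl <- nchar(tir_tag)
  n <- nrow(reads)
  if (n == 0)
    return(list(flanks = data.frame(id = character(), flank = character(),
                                    stringsAsFactors = FALSE),
                rejected = data.frame(id = character(), reason = character(),
                                      stringsAsFactors = FALSE)))
  too_short <- nchar(reads$sequence) <= tl
  mm <- rep(NA_integer_, n)
  ok_len <- !too_short
  if (any(ok_len)) {
    prefix <- substr(reads$sequence[ok_len], 1, tl)
    tagchars <- strsplit(tir_tag, "")[[1]]
    pm <- matrix(unlist(strsplit(prefix, ""), use.names = FALSE), nrow = tl)
    mm[ok_len] <- colSums(pm != tagchars)
  }
  keep <- ok_len & mm <= max_mismatch
  flanks <- data.frame(id = reads$id[keep],
                       flank = substring(reads$sequence[keep], tl + 1),
                       stringsAsFactors = FALSE)
  rejected <- data.frame(id = reads$id[!keep],
                         reason = ifelse(too_short[!keep], "short", "tag"),
                         stringsAsFactors = FALSE)
  list(flanks = flanks, rejected = rejected)
}

#' Filter flanks by length
#'
#' Keeps flanks strictly longer than `min_exclusive` bases (a 90 bp flank is
#' removed at the default threshold, a 91 bp flank kept).
#'
#' @param flanks data.frame with a `flank` column.
#' @param min_exclusive Strict lower bound on flank length (default 90).
#' @return The filtered data.frame.
#' @export
filter_length <- function(flanks, min_exclusive = 90) {
  out <- flanks[nchar(flanks$flank) > min_exclusive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map flanks to the reference by exact seed and ungapped extension
#'
#' A deliberately minimal desk-scale mapper for synthetic references: the
#' flank's first `seed_len`-mer is located exactly in the reference (both
#' strands), then the full flank is compared ungapped at each seed hit,
#' allowing at most `max_mismatch_rate * flank length` substitutions. A
#' unique best hit yields an alignment; no passing hit yields `unmapped`;
#' two or more equally good hits yield `multimapped` (excluded downstream
#' rather than placed arbitrarily). The reported position is always the
#' reference coordinate of the *first flank base* — the insertion point —
#' for both strands. Flanks shorter than `seed_len` are unmapped. Site
#' tables from an external aligner can be supplied instead via
#' [read_sites()].
#'
#' @param flanks data.frame with `id`, `flank`.
#' @param reference A `bsr_reference`.
#' @param seed_len Exact-match seed length (default 31).
#' @param max_mismatch_rate Tolerated mismatch fraction over the full flank.
#' @return A data.frame `id`, `status` (`mapped`/`unmapped`/`multimapped`),
#'   `chrom`, `pos`, `strand` (NA unless mapped).
#' @export
map_flanks <- function(flanks, reference, seed_len = 31,
                       max_mismatch_rate = 0.05) {
  n <- nrow(flanks)
  status <- rep("unmapped", n)
  r_chrom <- rep(NA_character_, n)
  r_pos <- rep(NA_integer_, n)
  r_strand <- rep(NA_character_, n)
  finish <- function() data.frame(id = flanks$id, status = status,
                                  chrom = r_chrom, pos = r_pos,
                                  strand = r_strand, stringsAsFactors = FALSE)
  if (n == 0) return(finish())
  flen <- nchar(flanks$flank)
  elig <- which(flen >= seed_len)
  if (!length(elig)) return(finish())

  seeds <- Biostrings::DNAStringSet(substr(flanks$flank[elig], 1, seed_len))
  pd <- Biostrings::PDict(seeds)

  # candidate hits: (flank index, chrom, strand, ref window start/end),
  # assembled vectorized from the per-pattern match index lists
  hit_parts <- list()
  for (ch in names(reference$seqs)) {
    subj <- reference$seqs[[ch]]
    Lc <- length(subj)
    sf <- Biostrings::startIndex(Biostrings::matchPDict(pd, subj))
    sr <- Biostrings::startIndex(
      Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj)))
    nf <- lengths(sf)
    if (sum(nf)) {
      i <- elig[rep(seq_along(elig), nf)]
      s <- unlist(sf, use.names = FALSE)
      L <- flen[i]
      ok <- s + L - 1 <= Lc
      hit_parts[[length(hit_parts) + 1]] <- data.frame(
        i = i[ok], chrom = ch, strand = "+",
        w_start = s[ok], w_end = s[ok] + L[ok] - 1, pos = s[ok],
        stringsAsFactors = FALSE)
    }
    nr <- lengths(sr)
    if (sum(nr)) {
      i <- elig[rep(seq_along(elig), nr)]
      s <- unlist(sr, use.names = FALSE)
      L <- flen[i]
      e <- Lc - s + 1              # ref coordinate pairing with flank base 1
      ok <- e - L + 1 >= 1
      hit_parts[[length(hit_parts) + 1]] <- data.frame(
        i = i[ok], chrom = ch, strand = "-",
        w_start = e[ok] - L[ok] + 1, w_end = e[ok], pos = e[ok],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hit_parts)) return(finish())
  hits <- do.call(rbind, hit_parts)
  if (nrow(hits) == 0) return(finish())

  hi <- hits$i
  hchrom <- hits$chrom
  hstrand <- hits$strand
  hws <- hits$w_start
  hwe <- hits$w_end
  hpos <- hits$pos

  # count mismatches of the full flank against the reference window
  hmm <- integer(nrow(hits))
  for (ch in unique(hchrom)) {
    sel <- which(hchrom == ch)
    refstr <- as.character(reference$seqs[[ch]])
    win <- substring(refstr, hws[sel], hwe[sel])
    rc <- hstrand[sel] == "-"
    if (any(rc))
      win[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(win[rc])))
    fl <- flanks$flank[hi[sel]]
    hmm[sel] <- mapply(str_mismatches, fl, win, USE.NAMES = FALSE)
  }
  pass <- which(hmm <= floor(max_mismatch_rate * flen[hi]))
  if (!length(pass)) return(finish())

  # best hit per read = lowest mismatch count; >1 equally good => multimapped
  o <- pass[order(hi[pass], hmm[pass])]
  first <- !duplicated(hi[o])
  best <- o[first]
  key <- paste0(hi[o], "_", hmm[o])
  n_equal <- as.integer(table(key)[key[first]])
  idx <- hi[best]
  multi <- n_equal > 1
  status[idx] <- ifelse(multi, "multimapped", "mapped")
  ok <- idx[!multi]
  status[ok] <- "mapped"
  r_chrom[ok] <- hchrom[best[!multi]]
  r_pos[ok] <- as.integer(hpos[best[!multi]])
  r_strand[ok] <- hstrand[best[!multi]]
  finish()
}

#' Cluster alignments into binned insertion sites
#'
#' Mapped alignments are grouped by chromosome and position bin
#' (`bin_start = floor((pos - 1)/bin) * bin + 1`); the read count of a site
#' is its group size. The coarse binning mirrors the round-number site
#' coordinates reported in transposon-tagging studies and absorbs the
#' target-site duplication.
#'
#' @param alignments Output of [map_flanks()] (only `status == "mapped"`
#'   rows are used).
#' @param bin Bin width in bp (>= 1).
#' @param library Optional library label stored in the table.
#' @return A `site_table` data.frame: `chrom`, `bin_start`, `read_count`,
#'   `library`, sorted by (chrom, bin_start), with attribute `bin`.
#' @export
call_sites <- function(alignments, bin = 100, library = NA_character_) {
  if (bin < 1) stop("bin must be >= 1")
  m <- alignments[alignments$status == "mapped", , drop = FALSE]
  if (nrow(m) == 0) {
    out <- data.frame(chrom = character(), bin_start = integer(),
                      read_count = integer(), library = character(),
                      stringsAsFactors = FALSE)
  } else {
    bs <- floor((m$pos - 1) / bin) * bin + 1
    key <- paste(m$chrom, bs)
    tab <- table(key)
    parts <- strsplit(names(tab), " ", fixed = TRUE)
    out <- data.frame(
      chrom = vapply(parts, `[`, character(1), 1),
      bin_start = as.integer(vapply(parts, `[`, character(1), 2)),
      read_count = as.integer(tab),
      library = library,
      stringsAsFactors = FALSE
    )
    out <- out[order(out$chrom, out$bin_start), ]
    rownames(out) <- NULL
  }
  structure(out, bin = bin, class = c("site_table", "data.frame"))
}

#' Subtract control-library insertion sites
#'
#' Removes every sample site within `tolerance` bins of a control site on
#' the same chromosome; insertions present in the control genotype cannot be
#' responsible for the mutant phenotype. Subtracting a table from itself
#' yields an empty table; an empty control leaves the sample unchanged.
#'
#' @param sample_sites,control_sites `site_table`s called with the same bin
#'   width.
#' @param tolerance Match tolerance in bins (default 1).
#' @return The filtered sample `site_table`.
#' @export
subtract_control <- function(sample_sites, control_sites, tolerance = 1) {
  bin_s <- attr(sample_sites, "bin")
  bin_c <- attr(control_sites, "bin")
  if (!is.null(bin_s) && !is.null(bin_c) && bin_s != bin_c)
    stop("site tables have different bin widths")
  bin <- if (!is.null(bin_s)) bin_s else bin_c
  if (nrow(sample_sites) == 0 || nrow(control_sites) == 0) {
    return(sample_sites)
  }
  drop <- vapply(seq_len(nrow(sample_sites)), function(i) {
    ctl <- control_sites[control_sites$chrom == sample_sites$chrom[i], ]
    nrow(ctl) > 0 &&
      any(abs(ctl$bin_start - sample_sites$bin_start[i]) <= tolerance * bin)
  }, logical(1))
  out <- sample_sites[!drop, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, bin = bin, class = c("site_table", "data.frame"))
}

#' Restrict sites to the mapping interval and rank candidates
#'
#' Keeps sites inside `[start_bp, end_bp]` of the interval, sorts by read
#' count descending (ties by position ascending), and annotates the gene
#' overlapping each site bin, if any. The rank-1 site is the candidate: the
#' insertion supported by by far the most reads inside the interval is the
#' presumptive causal allele.
#'
#' @param sites A `site_table` (typically after [subtract_control()]).
#' @param interval A `mapping_interval` with `found = TRUE`.
#' @param genes Gene data.frame (`gene_id`, `chrom`, `start`, `end`) as in a
#'   `bsr_reference`.
#' @return A `candidate_report`: data.frame `rank`, `chrom`, `bin_start`,
#'   `read_count`, `gene_id` (NA if intergenic), `library`; zero rows mean
#'   "no candidate".
#' @export
restrict_and_rank <- function(sites, interval, genes) {
  if (!isTRUE(interval$found)) stop("interval carries no linkage signal")
  bin <- attr(sites, "bin")
  if (is.null(bin)) bin <- 1
  keep <- sites$chrom == interval$chrom &
    sites$bin_start >= interval$start_bp &
    sites$bin_start <= interval$end_bp
  out <- sites[keep, , drop = FALSE]
  if (nrow(out)) {
    out <- out[order(-out$read_count, out$bin_start), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    if (nrow(genes)) {
      site_gr <- GenomicRanges::GRanges(
        out$chrom, IRanges::IRanges(out$bin_start,
                                    out$bin_start + bin - 1))
      gene_gr <- GenomicRanges::GRanges(
        genes$chrom, IRanges::IRanges(genes$start, genes$end))
      ov <- GenomicRanges::findOverlaps(site_gr, gene_gr, select = "first")
      out$gene_id <- genes$gene_id[ov]
    } else {
      out$gene_id <- NA_character_
    }
    out <- out[, c("rank", "chrom", "bin_start", "read_count", "gene_id",
                   "library")]
  } else {
    out <- data.frame(rank = integer(), chrom = character(),
                      bin_start = integer(), read_count = integer(),
                      gene_id = character(), library = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, bin = bin, class = c("candidate_report", "data.frame"))
}

#' Write / read site tables as TSV; export sites as BED
#'
#' @param sites A `site_table` (or `candidate_report`).
#' @param path File path.
#' @return Invisibly `path` (write) or a `site_table` (read).
#' @export
write_sites <- function(sites, path) {
  df <- as.data.frame(sites)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @param bin Bin width to attach when reading an externally produced table.
#' @export
read_sites <- function(path, bin = 100) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "bin_start", "read_count") %in% names(s)))
  if (!"library" %in% names(s)) s$library <- NA_character_
  structure(s, bin = bin, class = c("site_table", "data.frame"))
}

#' @rdname write_sites
#' @export
write_sites_bed <- function(sites, path) {
  bin <- attr(sites, "bin")
  if (is.null(bin)) bin <- 1
  if (nrow(sites)) {
    bed <- data.frame(sites$chrom, sites$bin_start - 1L,
                      sites$bin_start + bin - 1L,
                      paste0("site_", seq_len(nrow(sites))),
                      sites$read_count)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}
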
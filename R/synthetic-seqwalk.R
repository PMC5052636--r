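#' Default Mu-style terminal tag used by the simulator (25 nt)
#'
#' A fixed terminal-inverted-repeat-style tag placed between the library
#' barcode and the genomic flank in every simulated Seq-walking read. Any
#' other tag may be supplied; only its length and content matter for
#' trimming.
#' @export
DEFAULT_TIR_TAG <- "AGAGAAGCCAACGCCATCGCCTCTA"

#' Simulate a barcoded Seq-walking library
#'
#' Each genuine read is `barcode + tir_tag + genomic flank`. The flank starts
#' at the insertion point and runs along the forward strand (strand `+`) or
#' ends at the insertion point and is reported reverse-complemented (strand
#' `-`), each with probability 1/2 — transposon ends are recovered from both
#' sides. Flank lengths are normal (`read_len_mean`, `read_len_sd`), rounded,
#' clamped to `[read_len_min, distance to the chromosome end]`. Substitution
#' errors hit every base of the read (including barcode and tag) independently
#' with probability `epsilon`. A fraction `junk_fraction` of reads is replaced
#' by uniform random sequence, emulating library noise that fails
#' demultiplexing or trimming.
#'
#' @param reference A `bsr_reference`.
#' @param insertions data.frame with columns `chrom`, `pos` (1-based first
#'   flank base) and optionally `weight` (expected read share; default 1).
#' @param n_reads Number of reads to emit.
#' @param barcode Library barcode (prefix of every genuine read).
#' @param tir_tag Transposon terminal tag; default [DEFAULT_TIR_TAG].
#' @param read_len_mean,read_len_sd,read_len_min Flank-length distribution
#'   parameters (bp).
#' @param epsilon Per-base substitution error rate in `[0, 0.5)`.
#' @param junk_fraction Fraction of reads emitted as random sequence.
#' @param seed Integer seed.
#' @param library_id Label stored in read identifiers.
#'
#' @return A list with `reads` (data.frame `id`, `sequence`, `quality`) and
#'   `truth` (data.frame per read: source insertion index or `NA` for junk,
#'   strand, flank length).
#' @export
simulate_seqwalk_library <- function(reference, insertions, n_reads, barcode,
                                     tir_tag = DEFAULT_TIR_TAG,
                                     read_len_mean = 150, read_len_sd = 40,
                                     read_len_min = 30,
                                     epsilon = 0, junk_fraction = 0,
                                     seed = 1, library_id = "lib") {
  if (nchar(barcode) == 0 || nchar(tir_tag) == 0)
    stop("barcode and tir_tag must be non-empty")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  lens <- reference$chrom_lengths
  for (i in seq_len(nrow(insertions))) {
    ch <- insertions$chrom[i]
    if (!ch %in% names(lens) || insertions$pos[i] < 1 ||
        insertions$pos[i] > lens[[ch]])
      stop(sprintf("insertion %d (%s:%d) outside reference", i,
                   ch, insertions$pos[i]))
  }
  set.seed(seed)
  w <- if ("weight" %in% names(insertions)) insertions$weight else
    rep(1, nrow(insertions))

  is_junk <- runif(n_reads) < junk_fraction
  src <- rep(NA_integer_, n_reads)
  src[!is_junk] <- sample.int(nrow(insertions), sum(!is_junk),
                              replace = TRUE, prob = w)
  strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
  strand[is_junk] <- NA

  flank_len <- pmax(read_len_min, round(rnorm(n_reads, read_len_mean,
                                              read_len_sd)))
  seqs <- character(n_reads)
  bases <- c("A", "C", "G", "T")

  genuine <- which(!is_junk)
  if (length(genuine)) {
    chs <- insertions$chrom[src[genuine]]
    pos <- insertions$pos[src[genuine]]
    for (ch in unique(chs)) {
      sel <- genuine[chs == ch]
      L <- lens[[ch]]
      refstr <- as.character(reference$seqs[[ch]])
      p <- insertions$pos[src[sel]]
      fl <- flank_len[sel]
      fwd <- strand[sel] == "+"
      # clamp so the flank stays on the chromosome
      fl[fwd] <- pmin(fl[fwd], L - p[fwd] + 1)
      fl[!fwd] <- pmin(fl[!fwd], p[!fwd])
      flank_len[sel] <- fl
      flank <- character(length(sel))
      flank[fwd] <- substring(refstr, p[fwd], p[fwd] + fl[fwd] - 1)
      if (any(!fwd)) {
        raw <- substring(refstr, p[!fwd] - fl[!fwd] + 1, p[!fwd])
        flank[!fwd] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(raw)))
      }
      seqs[sel] <- paste0(barcode, tir_tag, flank)
    }
  }
  if (any(is_junk)) {
    jl <- nchar(barcode) + nchar(tir_tag) + flank_len[is_junk]
    seqs[is_junk] <- vapply(jl, function(L)
      paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  }

  # substitution errors, vectorized in rounds over reads with >= k errors
  if (epsilon > 0) {
    n_err <- rbinom(n_reads, nchar(seqs), epsilon)
    todo <- which(n_err > 0)
    round_k <- 1
    while (length(todo)) {
      p <- ceiling(runif(length(todo)) * nchar(seqs[todo]))
      old <- substring(seqs[todo], p, p)
      shift <- sample.int(3, length(todo), replace = TRUE)
      new <- bases[(match(old, bases) - 1 + shift) %% 4 + 1]
      s <- seqs[todo]
      substr(s, p, p) <- new
      seqs[todo] <- s
      round_k <- round_k + 1
      todo <- todo[n_err[todo] >= round_k]
    }
  }

  reads <- data.frame(
    id = sprintf("%s:read%06d", library_id, seq_len(n_reads)),
    sequence = seqs,
    quality = strrep("I", nchar(seqs)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(insertion = src, strand = strand,
                      flank_len = flank_len, junk = is_junk,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write / read FASTQ (plain text, constant qualities)
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path File path.
#' @return Invisibly `path` (write) or the reads data.frame (read).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}
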
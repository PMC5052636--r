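# Small fixtures built in code, shared across test files.

tiny_reference <- function(len = 5e4, n_genes = 3, seed = 1) {
  make_reference(c(chr1 = len), n_genes, seed = seed,
                 gene_width = c(500, 1500))
}

# A hand-written genetic map (cM distances chosen directly).
manual_map <- function(chrom, pos, cm) {
  structure(data.frame(chrom = chrom, pos = pos, cm = cm,
                       stringsAsFactors = FALSE),
            class = c("bsr_genmap", "data.frame"))
}

# A ready-made mapping interval for seqwalk tests.
manual_interval <- function(chrom = "chr1", start_bp, end_bp) {
  structure(list(found = TRUE, chrom = chrom, start_bp = start_bp,
                 end_bp = end_bp, start_cm = NA, end_cm = NA,
                 width_cm = NA, peak_window = NA, tau = NA),
            class = "mapping_interval")
}

# Reads assembled by hand from a reference: barcode + tag + verbatim flank.
make_read <- function(reference, chrom, pos, len, barcode, tag,
                      strand = "+", id = "r1") {
  refstr <- as.character(reference$seqs[[chrom]])
  flank <- if (strand == "+") {
    substring(refstr, pos, pos + len - 1)
  } else {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(refstr, pos - len + 1, pos))))
  }
  data.frame(id = id, sequence = paste0(barcode, tag, flank),
             quality = strrep("I", nchar(barcode) + nchar(tag) + len),
             stringsAsFactors = FALSE)
}

# Scaled-down full-pipeline configuration for fast end-to-end tests.
small_config <- function(seed = 1) {
  cfg <- default_config(seed)
  cfg$reference$chrom_lengths <- c(chr1 = 1e6)
  cfg$reference$n_genes <- 30
  cfg$reference$gene_width <- c(1000, 3000)
  cfg$map$n_markers <- 400
  cfg$map$cm_per_mb <- 150  # same ~120 cM genetic span on a 1 Mb axis
  cfg$population$n_f2 <- 150
  cfg$population$n_mutant <- 25
  cfg$population$n_wt <- 25
  cfg$counts$mean_depth <- 20
  cfg$scan$window_size <- 40
  cfg$scan$step <- 10
  cfg$seqwalk$n_reads <- 4000
  cfg$seqwalk$n_shared <- 5
  cfg$seqwalk$n_control_private <- 3
  cfg$seqwalk$min_separation <- 2000
  cfg
}
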
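barcodes <- c(mutant = "GTCGAT", control = "CTGCTA")

test_that("demultiplexing assigns by exact barcode prefix and conserves reads", {
  reads <- data.frame(
    id = c("a", "b", "c"),
    sequence = c(paste0("GTCGAT", "ACGTACGT"),
                 paste0("CTGCTA", "TTTTGGGG"),
                 paste0("AAAAAA", "ACGTACGT")),
    stringsAsFactors = FALSE
  )
  dm <- demultiplex(reads, barcodes)
  expect_equal(dm$libraries$mutant$id, "a")
  expect_equal(dm$libraries$mutant$sequence, "ACGTACGT")  # barcode stripped
  expect_equal(dm$libraries$control$id, "b")
  expect_equal(dm$unassigned, 1)
  expect_equal(sum(vapply(dm$libraries, nrow, integer(1))) + dm$unassigned,
               nrow(reads))
  expect_error(demultiplex(reads, c(x = "GTCGAT", y = "GTCGAT")), "duplicate")
})

test_that("tag trimming tolerates up to max_mismatch substitutions", {
  tag <- DEFAULT_TIR_TAG
  flank <- "ACGTACGTACGTACGTACGT"
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (i in seq_len(k)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    paste(v, collapse = "")
  }
  reads <- data.frame(
    id = c("exact", "two_mm", "three_mm", "short"),
    sequence = c(paste0(tag, flank),
                 paste0(mutate(tag, 2), flank),
                 paste0(mutate(tag, 3), flank),
                 substr(tag, 1, 10)),
    stringsAsFactors = FALSE
  )
  tr <- trim_mu_flank(reads, tag, max_mismatch = 2)
  expect_setequal(tr$flanks$id, c("exact", "two_mm"))
  expect_true(all(tr$flanks$flank == flank))
  expect_equal(tr$rejected$reason[tr$rejected$id == "three_mm"], "tag")
  expect_equal(tr$rejected$reason[tr$rejected$id == "short"], "short")
  expect_equal(nrow(tr$flanks) + nrow(tr$rejected), nrow(reads))
})

test_that("length filter is strictly greater-than", {
  fl <- data.frame(id = c("a", "b", "c"),
                   flank = c(strrep("A", 90), strrep("C", 91), ""),
                   stringsAsFactors = FALSE)
  kept <- filter_length(fl, 90)
  expect_equal(kept$id, "b")
  expect_equal(nrow(filter_length(fl[0, ], 90)), 0)
})

test_that("flank mapping reports the insertion-point coordinate on both strands", {
  ref <- tiny_reference(seed = 41)
  refstr <- as.character(ref$seqs[[1]])
  p <- 12001
  L <- 120
  fwd <- substring(refstr, p, p + L - 1)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(refstr, p - L + 1, p))))
  rand <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  fl <- data.frame(id = c("fwd", "rev", "rand", "tiny"),
                   flank = c(fwd, rev, rand, "ACGT"),
                   stringsAsFactors = FALSE)
  set.seed(42)
  aln <- map_flanks(fl, ref)
  expect_equal(aln$status[1], "mapped")
  expect_equal(aln$pos[1], p)
  expect_equal(aln$strand[1], "+")
  expect_equal(aln$status[2], "mapped")
  expect_equal(aln$pos[2], p)  # same insertion point, minus strand
  expect_equal(aln$strand[2], "-")
  expect_equal(aln$status[3], "unmapped")
  expect_equal(aln$status[4], "unmapped")  # shorter than the seed
})

test_that("equally good multiple hits are flagged multimapped", {
  # a reference with an exact internal duplication
  set.seed(43)
  unitA <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                 collapse = "")
  unitB <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(unitA, unitB, unitA)))
  ref <- structure(list(seqs = seqs,
                        genes = data.frame(gene_id = character(),
                                           chrom = character(),
                                           start = integer(), end = integer(),
                                           strand = character()),
                        chrom_lengths = c(chr1 = nchar(unitA) * 2 + 200)),
                   class = "bsr_reference")
  fl <- data.frame(id = "dup", flank = substring(unitA, 1001, 1120),
                   stringsAsFactors = FALSE)
  aln <- map_flanks(fl, ref)
  expect_equal(aln$status, "multimapped")
})

test_that("site calling bins alignments and keeps only mapped reads", {
  aln <- data.frame(
    id = sprintf("r%d", 1:8),
    status = c(rep("mapped", 7), "multimapped"),
    chrom = "chr1",
    pos = c(104610901L, 104610925L, 104610950L, 104610999L, 104610917L,
            150L, 250L, 300L),
    strand = "+", stringsAsFactors = FALSE
  )
  sites <- call_sites(aln, bin = 100)
  expect_equal(nrow(sites), 3)
  big <- sites[sites$bin_start == 104610901, ]
  expect_equal(big$read_count, 5)
  expect_equal(sites$read_count[sites$bin_start == 101], 1)
  expect_equal(sites$read_count[sites$bin_start == 201], 1)
  expect_equal(nrow(call_sites(aln[0, ], bin = 100)), 0)
  expect_true(all((sites$bin_start - 1) %% 100 == 0))
})

test_that("control subtraction removes shared sites within tolerance", {
  mk <- function(bins, counts, bin = 100) {
    structure(data.frame(chrom = "chr1", bin_start = bins,
                         read_count = counts, library = "x",
                         stringsAsFactors = FALSE),
              bin = bin, class = c("site_table", "data.frame"))
  }
  s <- mk(c(101, 1001, 5001), c(10, 20, 30))
  # self-subtraction is empty
  expect_equal(nrow(subtract_control(s, s)), 0)
  # empty control leaves the sample unchanged
  expect_equal(nrow(subtract_control(s, s[0, ])), 3)
  # a control site one bin away removes the sample site; private sites stay
  ctl <- mk(c(1101), c(5))
  left <- subtract_control(s, ctl, tolerance = 1)
  expect_setequal(left$bin_start, c(101, 5001))
  expect_error(subtract_control(s, mk(101, 1, bin = 50)), "bin widths")
})

test_that("candidate ranking restricts to the interval with the stated tie-break", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(5000, 8000), end = c(6000, 9000),
                      strand = "+", stringsAsFactors = FALSE)
  sites <- structure(data.frame(
    chrom = "chr1",
    bin_start = c(5001, 8101, 2001, 20001),
    read_count = c(22945, 310, 310, 99999),
    library = "mutant", stringsAsFactors = FALSE),
    bin = 100, class = c("site_table", "data.frame"))
  iv <- manual_interval(start_bp = 1000, end_bp = 10000)
  rep <- restrict_and_rank(sites, iv, genes)
  expect_equal(nrow(rep), 3)             # the 20001 site is outside
  expect_equal(rep$bin_start[1], 5001)   # max read count is the candidate
  expect_equal(rep$gene_id[1], "g1")
  # tie on counts: lower coordinate first
  expect_equal(rep$bin_start[2:3], c(2001, 8101))
  expect_true(is.na(rep$gene_id[rep$bin_start == 2001]))

  none <- restrict_and_rank(sites, manual_interval(start_bp = 30000,
                                                   end_bp = 40000), genes)
  expect_equal(nrow(none), 0)            # explicit "no candidate"
})

test_that("site tables round-trip through TSV and export to BED", {
  s <- structure(data.frame(chrom = "chr1", bin_start = c(101, 501),
                            read_count = c(3, 7), library = "mutant",
                            stringsAsFactors = FALSE),
                 bin = 100, class = c("site_table", "data.frame"))
  d <- withr::local_tempdir()
  write_sites(s, file.path(d, "s.tsv"))
  back <- read_sites(file.path(d, "s.tsv"), bin = 100)
  expect_equal(back$bin_start, s$bin_start)
  write_sites_bed(s, file.path(d, "s.bed"))
  bed <- read.delim(file.path(d, "s.bed"), header = FALSE)
  expect_equal(bed$V2, s$bin_start - 1)
  expect_equal(bed$V3, s$bin_start + 99)
})

test_that("planted insertions with enough reads are recovered exactly, no spurious sites", {
  ref <- make_reference(c(chr1 = 1e6), 10, seed = 45)
  cfg <- default_config()$seqwalk
  ins <- data.frame(chrom = "chr1", pos = c(100001, 400001, 700001),
                    weight = c(5, 1, 1))
  lib <- simulate_seqwalk_library(ref, ins, 800, cfg$barcodes[["mutant"]],
                                  read_len_mean = 150, read_len_sd = 30,
                                  read_len_min = 95,
                                  epsilon = 0, junk_fraction = 0, seed = 46,
                                  library_id = "mutant")
  swa <- seqwalk_analyse(lib$reads, ref, cfg)
  sites <- swa$sites$mutant
  truth_bins <- floor((ins$pos - 1) / cfg$bin) * cfg$bin + 1
  expect_setequal(sites$bin_start, truth_bins)  # all recovered, none spurious
  expect_equal(sum(sites$read_count),
               swa$accounting$mapped[swa$accounting$library == "mutant"])
  expect_true(accounting(list(seqwalk_accounting = swa$accounting,
                              seqwalk_unassigned = swa$unassigned,
                              seqwalk_total = swa$total)))
})
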
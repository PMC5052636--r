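#' Default configuration of the synthetic mapping-by-cloning scenario
#'
#' One 10 Mb chromosome carrying 200 genes; a 2,000-SNP genetic map with a
#' 10-fold recombination-suppressed centromere over the middle fifth of the
#' chromosome; an F2 of 700 individuals from which 123 mutant and 123
#' wild-type individuals are bulked; RNA-seq allele counts at mean depth 20
#' with 1% per-read miscalls; and two 50,000-read Seq-walking libraries (the
#' mutant-derived library with the causal insertion at 10x read weight plus
#' 20 insertions shared with the control genotype; the control library with
#' the shared insertions plus 9 private ones).
#'
#' @param seed Master seed; all per-stage seeds are derived from it.
#' @return A nested configuration list (class `bsr_config`).
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    reference = list(chrom_lengths = c(chr1 = 10e6), n_genes = 200,
                     gene_width = c(2000, 5000)),
    map = list(n_markers = 2000, centromere_frac = c(0.4, 0.6),
               suppression_factor = 0.1, cm_per_mb = 15),
    population = list(n_f2 = 700, n_mutant = 123, n_wt = 123),
    counts = list(mean_depth = 20, epsilon = 0.01),
    bsa = list(pi = 0.05, epsilon = 0.01, grid_size = 64, mode = "default"),
    scan = list(window_size = 100, step = 20, tau = NULL),
    seqwalk = list(
      n_reads = 50000, n_shared = 20, n_control_private = 9,
      causal_weight = 10, min_separation = 5000,
      barcodes = c(mutant = "GTCGAT", control = "CTGCTA"),
      tir_tag = DEFAULT_TIR_TAG, max_tag_mismatch = 2,
      read_len_mean = 150, read_len_sd = 40, read_len_min = 30,
      epsilon = 0.01, junk_fraction = 0.02,
      min_flank_len = 90, seed_len = 31, bin = 100, tolerance = 1)
  ), class = "bsr_config")
}

# Internal: per-stage seeds derived deterministically from the master seed,
# so any stage can be rerun in isolation.
stage_seeds <- function(master) {
  set.seed(master)
  setNames(sample.int(2147483646L, 8),
           c("reference", "map", "population", "bulk", "counts",
             "insertions", "reads_mutant", "reads_control"))
}

#' Plant transposon insertions for a Seq-walking experiment
#'
#' The causal insertion goes at the midpoint of `causal_gene` (mutant
#' library only, with `causal_weight` read weight); `n_shared` insertions
#' present in both libraries and `n_control_private` control-only insertions
#' are scattered uniformly over the genome, at least `min_separation` bp
#' from every other planted insertion.
#'
#' @param reference A `bsr_reference`.
#' @param causal_gene A row of `reference$genes` (the causal gene).
#' @param n_shared,n_control_private Insertion counts per class.
#' @param causal_weight Relative read weight of the causal insertion.
#' @param min_separation Minimum pairwise distance between insertions (bp).
#' @param seed Integer seed.
#' @return data.frame `chrom`, `pos`, `weight`, `class`
#'   (`causal`/`shared`/`control`), `in_mutant`, `in_control`.
#' @export
plant_insertions <- function(reference, causal_gene, n_shared = 20,
                             n_control_private = 9, causal_weight = 10,
                             min_separation = 5000, seed = 1) {
  set.seed(seed)
  lens <- reference$chrom_lengths
  causal_pos <- as.integer(round((causal_gene$start + causal_gene$end) / 2))
  taken_chrom <- causal_gene$chrom
  taken_pos <- causal_pos
  draw <- function(n_draw) {
    out_chrom <- character(0); out_pos <- integer(0)
    tries <- 0
    while (length(out_pos) < n_draw) {
      tries <- tries + 1
      if (tries > 1000 * n_draw)
        stop("cannot place insertions with the requested separation")
      ch <- sample(names(lens), 1, prob = lens)
      p <- sample.int(lens[[ch]], 1)
      same <- c(taken_pos[taken_chrom == ch], out_pos[out_chrom == ch])
      if (!length(same) || all(abs(same - p) >= min_separation)) {
        out_chrom <- c(out_chrom, ch); out_pos <- c(out_pos, p)
      }
    }
    taken_chrom <<- c(taken_chrom, out_chrom)
    taken_pos <<- c(taken_pos, out_pos)
    data.frame(chrom = out_chrom, pos = out_pos, stringsAsFactors = FALSE)
  }
  shared <- draw(n_shared)
  control <- draw(n_control_private)
  out <- rbind(
    data.frame(chrom = causal_gene$chrom, pos = causal_pos,
               weight = causal_weight, class = "causal",
               in_mutant = TRUE, in_control = FALSE,
               stringsAsFactors = FALSE),
    data.frame(chrom = shared$chrom, pos = shared$pos, weight = 1,
               class = "shared", in_mutant = TRUE, in_control = TRUE,
               stringsAsFactors = FALSE),
    data.frame(chrom = control$chrom, pos = control$pos, weight = 1,
               class = "control", in_mutant = FALSE, in_control = TRUE,
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Analyse pooled Seq-walking reads down to per-library site tables
#'
#' Runs demultiplexing, tag trimming, length filtering, mapping and site
#' calling for every library, keeping the full read-accounting chain:
#' `total = sum(assigned) + unassigned`; per library
#' `assigned = flanks + rejected`, `flanks = kept + length_removed`,
#' `kept = mapped + unmapped + multimapped`. The identities are checked by
#' [accounting()].
#'
#' @param reads Pooled read data.frame (`id`, `sequence`, ...).
#' @param reference A `bsr_reference`.
#' @param cfg The `seqwalk` sub-list of a [default_config()] (barcodes, tag,
#'   thresholds).
#' @return A list: `sites` (named list of `site_table`s per library),
#'   `accounting` (data.frame of per-library stage counts), `unassigned`,
#'   `total`.
#' @export
seqwalk_analyse <- function(reads, reference, cfg) {
  dm <- demultiplex(reads, cfg$barcodes)
  sites <- list()
  acct <- list()
  for (lib in names(cfg$barcodes)) {
    libreads <- dm$libraries[[lib]]
    tr <- trim_mu_flank(libreads, cfg$tir_tag, cfg$max_tag_mismatch)
    kept <- filter_length(tr$flanks, cfg$min_flank_len)
    aln <- map_flanks(kept, reference, cfg$seed_len)
    sites[[lib]] <- call_sites(aln, bin = cfg$bin, library = lib)
    acct[[lib]] <- data.frame(
      library = lib,
      assigned = nrow(libreads),
      flanks = nrow(tr$flanks),
      rejected = nrow(tr$rejected),
      length_kept = nrow(kept),
      length_removed = nrow(tr$flanks) - nrow(kept),
      mapped = sum(aln$status == "mapped"),
      unmapped = sum(aln$status == "unmapped"),
      multimapped = sum(aln$status == "multimapped"),
      stringsAsFactors = FALSE
    )
  }
  list(sites = sites, accounting = do.call(rbind, acct),
       unassigned = dm$unassigned, total = nrow(reads))
}

#' Verify the integer read-conservation identities of a run
#'
#' @param report A `bsr_run_report` (or any list with `seqwalk_accounting`,
#'   `seqwalk_unassigned`, `seqwalk_total`).
#' @return `TRUE` invisibly; any violated identity aborts with the stage
#'   name.
#' @export
accounting <- function(report) {
  a <- report$seqwalk_accounting
  if (sum(a$assigned) + report$seqwalk_unassigned != report$seqwalk_total)
    stop("accounting failure at stage demultiplex: assigned + unassigned != total")
  for (i in seq_len(nrow(a))) {
    if (a$assigned[i] != a$flanks[i] + a$rejected[i])
      stop("accounting failure at stage trim (library ", a$library[i], ")")
    if (a$flanks[i] != a$length_kept[i] + a$length_removed[i])
      stop("accounting failure at stage length filter (library ",
           a$library[i], ")")
    if (a$length_kept[i] !=
        a$mapped[i] + a$unmapped[i] + a$multimapped[i])
      stop("accounting failure at stage mapping (library ", a$library[i], ")")
  }
  invisible(TRUE)
}

#' Run the full synthetic cloning pipeline
#'
#' Executes simulate -> linkage posteriors -> window scan / interval ->
#' Seq-walking -> candidate report as one seeded run, writing every
#' intermediate artifact to `outdir` (FASTA/GFF3/TSV/FASTQ/BED/JSON) when an
#' output directory is given. The candidate is the highest-read-count
#' mutant-private insertion site inside the mapping interval; the recovery
#' flag states whether its overlapping gene is the gene carrying the planted
#' causal insertion.
#'
#' @param config A [default_config()]-style configuration.
#' @param outdir Output directory (created if missing), or `NULL` to skip
#'   writing artifacts.
#' @param quiet Suppress per-stage log lines.
#' @return A `bsr_run_report` list: the interval, the candidate report, the
#'   Seq-walking accounting table, the ground truth, and `recovered`.
#' @export
run_all <- function(config = default_config(), outdir = NULL,
                    quiet = FALSE) {
  seeds <- stage_seeds(config$seed)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  path <- function(f) file.path(outdir, f)

  ref <- run_stage("reference", make_reference(
    config$reference$chrom_lengths, config$reference$n_genes,
    seed = seeds[["reference"]], gene_width = config$reference$gene_width))
  say("reference", "%d chromosome(s), %d genes", length(ref$seqs),
      nrow(ref$genes))

  cen <- do.call(rbind, lapply(names(ref$chrom_lengths), function(ch) {
    L <- ref$chrom_lengths[[ch]]
    data.frame(chrom = ch,
               start = round(config$map$centromere_frac[1] * L),
               end = round(config$map$centromere_frac[2] * L),
               stringsAsFactors = FALSE)
  }))
  gmap <- run_stage("map", make_genetic_map(
    ref, config$map$n_markers, centromere = cen,
    suppression_factor = config$map$suppression_factor,
    cm_per_mb = config$map$cm_per_mb, seed = seeds[["map"]]))
  say("map", "%d markers, %.1f cM total", nrow(gmap), max(gmap$cm))

  # causal gene: the gene nearest the centromere midpoint of chromosome 1;
  # causal marker: the map marker nearest that gene
  main_chrom <- names(ref$chrom_lengths)[1]
  cen_mid <- mean(unlist(cen[cen$chrom == main_chrom, c("start", "end")]))
  cand_genes <- ref$genes[ref$genes$chrom == main_chrom, ]
  causal_gene <- cand_genes[
    which.min(abs((cand_genes$start + cand_genes$end) / 2 - cen_mid)), ]
  gmid <- (causal_gene$start + causal_gene$end) / 2
  mm <- gmap[gmap$chrom == main_chrom, ]
  causal_marker_pos <- mm$pos[which.min(abs(mm$pos - gmid))]
  say("causal", "gene %s, marker %s:%d", causal_gene$gene_id, main_chrom,
      causal_marker_pos)

  pop <- run_stage("population", simulate_f2_population(
    gmap, main_chrom, causal_marker_pos, config$population$n_f2,
    seed = seeds[["population"]]))
  bulks <- run_stage("bulk", phenotype_and_bulk(
    pop, config$population$n_mutant, config$population$n_wt,
    seed = seeds[["bulk"]]))
  say("bulk", "%d mutant + %d wild-type of %d F2",
      bulks$mutant$n, bulks$wildtype$n, pop$n)

  counts <- run_stage("counts", simulate_bulk_allele_counts(
    bulks, config$counts$mean_depth, config$counts$epsilon,
    seed = seeds[["counts"]], reference = ref))

  params <- linkage_params(pi = config$bsa$pi, epsilon = config$bsa$epsilon,
                           grid_size = config$bsa$grid_size,
                           n_mutant = config$population$n_mutant,
                           n_wt = config$population$n_wt)
  post <- run_stage("bsa", compute_posteriors(counts, params,
                                              mode = config$bsa$mode))
  scan <- run_stage("scan", sliding_window_scan(
    post, config$scan$window_size, config$scan$step))
  interval <- run_stage("interval", call_interval(scan, gmap,
                                                  tau = config$scan$tau))
  if (interval$found)
    say("interval", "%s:%d-%d (%.1f cM)", interval$chrom,
        interval$start_bp, interval$end_bp, interval$width_cm)
  else say("interval", "no linkage signal")

  sw <- config$seqwalk
  ins <- run_stage("insertions", plant_insertions(
    ref, causal_gene, sw$n_shared, sw$n_control_private, sw$causal_weight,
    sw$min_separation, seed = seeds[["insertions"]]))
  sim_lib <- function(which_lib, lib_seed) {
    sel <- if (which_lib == "mutant") ins$in_mutant else ins$in_control
    simulate_seqwalk_library(
      ref, ins[sel, ], sw$n_reads, sw$barcodes[[which_lib]],
      tir_tag = sw$tir_tag, read_len_mean = sw$read_len_mean,
      read_len_sd = sw$read_len_sd, read_len_min = sw$read_len_min,
      epsilon = sw$epsilon, junk_fraction = sw$junk_fraction,
      seed = lib_seed, library_id = which_lib)
  }
  lib_m <- run_stage("reads", sim_lib("mutant", seeds[["reads_mutant"]]))
  lib_c <- run_stage("reads", sim_lib("control", seeds[["reads_control"]]))
  pooled <- rbind(lib_m$reads, lib_c$reads)
  say("reads", "%d pooled reads (%d + %d)", nrow(pooled),
      nrow(lib_m$reads), nrow(lib_c$reads))

  swa <- run_stage("seqwalk", seqwalk_analyse(pooled, ref, sw))
  subtracted <- run_stage("subtract", subtract_control(
    swa$sites$mutant, swa$sites$control, tolerance = sw$tolerance))
  say("subtract", "%d mutant sites -> %d after control subtraction",
      nrow(swa$sites$mutant), nrow(subtracted))

  report_sites <- if (interval$found)
    run_stage("rank", restrict_and_rank(subtracted, interval, ref$genes))
  else NULL

  truth <- list(
    causal_chrom = main_chrom,
    causal_gene = causal_gene$gene_id,
    causal_marker_pos = causal_marker_pos,
    causal_insertion_pos = ins$pos[ins$class == "causal"],
    insertions = ins,
    seeds = as.list(seeds)
  )
  candidate_gene <- if (!is.null(report_sites) && nrow(report_sites))
    report_sites$gene_id[1] else NA_character_
  recovered <- identical(candidate_gene, truth$causal_gene)
  say("report", "candidate gene %s (%s)",
      ifelse(is.na(candidate_gene), "none", candidate_gene),
      ifelse(recovered, "causal gene recovered", "not the planted gene"))

  report <- structure(list(
    config = config, interval = interval, scan = scan,
    posteriors = post, candidate = report_sites,
    candidate_gene = candidate_gene, recovered = recovered,
    sites = list(mutant = swa$sites$mutant, control = swa$sites$control,
                 subtracted = subtracted),
    seqwalk_accounting = swa$accounting,
    seqwalk_unassigned = swa$unassigned,
    seqwalk_total = swa$total,
    truth = truth
  ), class = "bsr_run_report")
  accounting(report)

  if (!is.null(outdir)) {
    write_reference(ref, path("reference.fa"), path("genes.gff3"))
    write_genetic_map(gmap, path("genetic_map.tsv"))
    write_bulk_counts(counts, path("bulk_counts.tsv"))
    write_posteriors(post, path("posteriors.tsv"))
    write_scan(scan, path("scan.tsv"))
    write_interval(interval, path("interval.bed"), path("interval.json"))
    write_fastq(lib_m$reads, path("reads_mutant.fastq"))
    write_fastq(lib_c$reads, path("reads_control.fastq"))
    write_sites(swa$sites$mutant, path("sites_mutant.tsv"))
    write_sites(swa$sites$control, path("sites_control.tsv"))
    write_sites(subtracted, path("sites_subtracted.tsv"))
    write_sites_bed(subtracted, path("sites_subtracted.bed"))
    if (!is.null(report_sites))
      write_sites(report_sites, path("candidate_report.tsv"))
    jsonlite::write_json(truth, path("sim_truth.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(list(
      interval = unclass(interval),
      candidate_gene = candidate_gene,
      recovered = recovered,
      accounting = swa$accounting,
      unassigned = swa$unassigned,
      total_reads = swa$total,
      truth = truth[c("causal_chrom", "causal_gene", "causal_marker_pos",
                      "causal_insertion_pos")]
    ), path("run_report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.bsr_run_report <- function(x, ...) {
  cat("== bsrwalk run report ==\n")
  print(x$interval)
  if (!is.null(x$candidate) && nrow(x$candidate)) {
    cat("Top candidate sites in interval:\n")
    print(head(as.data.frame(x$candidate), 5))
  } else {
    cat("No candidate site inside the interval\n")
  }
  cat("Candidate gene:", x$candidate_gene,
      if (isTRUE(x$recovered)) "(matches planted causal gene)" else "", "\n")
  cat("Read accounting:\n")
  print(x$seqwalk_accounting)
  cat("Unassigned:", x$seqwalk_unassigned, "of", x$seqwalk_total, "\n")
  invisible(x)
}
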
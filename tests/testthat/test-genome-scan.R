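make_posteriors <- function(post, chrom = "chr1") {
  structure(data.frame(chrom = chrom, pos = seq_along(post) * 1000,
                       posterior = post, stringsAsFactors = FALSE),
            class = c("linkage_posteriors", "data.frame"))
}

test_that("window placement, count and median follow the 100/20 scheme", {
  p <- make_posteriors(rep(0.3, 140))
  sc <- sliding_window_scan(p, window_size = 100, step = 20)
  expect_equal(nrow(sc), 3)  # floor((140-100)/20)+1
  expect_equal(sc$start_pos, c(1, 21, 41) * 1000)
  expect_equal(sc$end_pos, c(100, 120, 140) * 1000)
  expect_equal(sc$mid_pos, c(50, 70, 90) * 1000)  # ceil(100/2)-th SNP
  expect_true(all(sc$median_posterior == 0.3))    # constant input

  # a single outlier cannot move the window median
  x <- c(rep(0.01, 99), 1.0)
  sc1 <- sliding_window_scan(make_posteriors(x), 100, 20)
  expect_equal(sc1$median_posterior, 0.01)

  expect_error(sliding_window_scan(make_posteriors(rep(0.1, 50)), 100, 20),
               "fewer")
})

test_that("window count formula and medians agree with enumeration oracles", {
  set.seed(301)
  for (i in 1:25) {
    s <- sample(10:400, 1)
    w <- sample(2:s, 1)
    st <- sample(1:50, 1)
    post <- runif(s)
    sc <- sliding_window_scan(make_posteriors(post), w, st)
    starts <- oracle_windows(s, w, st)
    expect_equal(nrow(sc), length(starts))
    expect_equal(nrow(sc), floor((s - w) / st) + 1)
    for (k in seq_along(starts)) {
      expect_equal(sc$median_posterior[k],
                   oracle_median(post[starts[k]:(starts[k] + w - 1)]))
    }
  }
})

test_that("interval calling brackets the peak and reports cM via the map", {
  gm <- manual_map("chr1", c(0, 200) * 1000, c(0, 100))
  # 200 SNPs; plateau of high posteriors in SNPs 80-120
  post <- rep(0.02, 200)
  post[80:120] <- 0.999
  sc <- sliding_window_scan(make_posteriors(post), 20, 5)
  iv <- call_interval(sc, gm)
  expect_true(iv$found)
  peak_row <- sc[sc$window == iv$peak_window, ]
  expect_gte(peak_row$start_pos, iv$start_bp)
  expect_lte(peak_row$end_pos, iv$end_bp)
  expect_true(iv$start_bp <= 80 * 1000 && iv$end_bp >= 120 * 1000)
  expect_equal(iv$width_cm, iv$end_cm - iv$start_cm)
  expect_equal(iv$start_cm, interpolate_cm(gm, "chr1", iv$start_bp))

  # single window above tau: interval = that window's span
  post2 <- rep(0.02, 200); post2[101:120] <- 1
  sc2 <- sliding_window_scan(make_posteriors(post2), 20, 20)
  iv2 <- call_interval(sc2, gm, tau = 0.9)
  expect_equal(iv2$start_bp, sc2$start_pos[6])
  expect_equal(iv2$end_bp, sc2$end_pos[6])

  # flat track at the prior: no linkage signal under any tau > pi
  flat <- sliding_window_scan(make_posteriors(rep(0.05, 200)), 20, 5)
  iv3 <- call_interval(flat, gm, tau = 0.5)
  expect_false(iv3$found)
})

test_that("recombination profile slopes are exact and non-negative", {
  gm <- manual_map("chr1", c(1e6, 2e6), c(10, 20))
  prof <- genetic_physical_profile(gm)
  expect_equal(prof$cm_per_mb, 10)
  expect_equal(prof$mid_bp, 1.5e6)

  ref <- make_reference(c(chr1 = 2e6), 5, seed = 31)
  cen <- data.frame(chrom = "chr1", start = 8e5, end = 1.2e6)
  gm2 <- make_genetic_map(ref, 200, centromere = cen,
                          suppression_factor = 0.1, cm_per_mb = 5, seed = 32)
  prof2 <- genetic_physical_profile(gm2)
  expect_true(all(prof2$cm_per_mb >= 0))
  dup <- manual_map("chr1", c(1e6, 1e6), c(1, 2))
  expect_error(genetic_physical_profile(dup), "duplicate")
})

test_that("deeper sequencing localizes the scan peak more accurately", {
  ref <- make_reference(c(chr1 = 2e6), 10, seed = 33)
  gm <- make_genetic_map(ref, 500, suppression_factor = 1, cm_per_mb = 60,
                         seed = 34)
  causal <- gm$pos[which.min(abs(gm$pos - 1e6))]
  err_at <- function(depth, s) {
    pop <- simulate_f2_population(gm, "chr1", causal, 400, seed = 40 + s)
    b <- phenotype_and_bulk(pop, 60, 60, seed = 50 + s)
    cnt <- simulate_bulk_allele_counts(b, depth, 0.01, seed = 60 + s)
    params <- linkage_params(n_mutant = 60, n_wt = 60)
    sc <- sliding_window_scan(compute_posteriors(cnt, params), 50, 10)
    abs(sc$mid_pos[which.max(sc$median_posterior)] - causal)
  }
  e5 <- vapply(1:8, function(s) err_at(5, s), numeric(1))
  e50 <- vapply(1:8, function(s) err_at(50, s), numeric(1))
  expect_gt(mean(e5), mean(e50))
})

test_that("scan and interval writers emit TSV, BED and JSON", {
  gm <- manual_map("chr1", c(0, 200) * 1000, c(0, 100))
  post <- rep(0.02, 200); post[80:120] <- 0.999
  sc <- sliding_window_scan(make_posteriors(post), 20, 5)
  iv <- call_interval(sc, gm)
  d <- withr::local_tempdir()
  write_scan(sc, file.path(d, "scan.tsv"))
  expect_equal(nrow(read.delim(file.path(d, "scan.tsv"))), nrow(sc))
  write_interval(iv, file.path(d, "iv.bed"), file.path(d, "iv.json"))
  bed <- read.delim(file.path(d, "iv.bed"), header = FALSE)
  expect_equal(bed$V2, iv$start_bp - 1)  # 0-based half-open on output
  expect_equal(bed$V3, iv$end_bp)
  js <- jsonlite::read_json(file.path(d, "iv.json"))
  expect_true(js$found)
})
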
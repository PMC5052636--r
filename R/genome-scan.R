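#' Sliding-window median scan of linkage posteriors
#'
#' Windows of `window_size` consecutive SNPs advance by `step` SNPs; the
#' statistic is the median posterior of the window (even window: mean of the
#' two central order statistics) and the window is placed at the physical
#' position of its `ceiling(window_size/2)`-th SNP. The number of windows per
#' chromosome is `floor((S - window_size)/step) + 1`. The median is robust: a
#' single outlying SNP cannot move it, which is why isolated high posteriors
#' off the causal region do not produce spurious peaks.
#'
#' @param posteriors A `linkage_posteriors` data.frame sorted by
#'   (chrom, pos). Every chromosome present must hold at least
#'   `window_size` SNPs.
#' @param window_size SNPs per window (default 100).
#' @param step Step in SNPs between window starts (default 20).
#' @return A `scan_profile` data.frame: `chrom`, `window` (1-based index per
#'   chromosome), `start_pos`, `end_pos` (first/last SNP of the window),
#'   `mid_pos`, `median_posterior`.
#' @export
sliding_window_scan <- function(posteriors, window_size = 100, step = 20) {
  if (window_size < 1 || step < 1) stop("window_size and step must be >= 1")
  out <- do.call(rbind, lapply(unique(posteriors$chrom), function(ch) {
    p <- posteriors[posteriors$chrom == ch, ]
    if (is.unsorted(p$pos)) stop("posteriors must be sorted by position")
    s <- nrow(p)
    if (s < window_size)
      stop(sprintf("chromosome %s has %d SNPs, fewer than window_size %d",
                   ch, s, window_size))
    n_win <- floor((s - window_size) / step) + 1
    starts <- 1 + (seq_len(n_win) - 1) * step
    mid_off <- ceiling(window_size / 2) - 1
    data.frame(
      chrom = ch,
      window = seq_len(n_win),
      start_pos = p$pos[starts],
      end_pos = p$pos[starts + window_size - 1],
      mid_pos = p$pos[starts + mid_off],
      median_posterior = vapply(starts, function(a)
        median(p$posterior[a:(a + window_size - 1)]), numeric(1)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  structure(out, class = c("scan_profile", "data.frame"))
}

#' Call the mapping interval from a scan profile
#'
#' The interval is the maximal contiguous run of windows whose median
#' posterior reaches the threshold `tau` and which contains the peak window
#' (ties broken by the first peak). Physical bounds are the first SNP of the
#' run's first window and the last SNP of its last window; genetic bounds
#' come from linear interpolation on the genetic map. If no window reaches
#' `tau` the result carries `found = FALSE` ("no linkage signal").
#'
#' @param scan A `scan_profile` (single chromosome, or the chromosome with
#'   the global peak window is used).
#' @param map A `bsr_genmap` covering the scanned chromosome.
#' @param tau Threshold on the window median; default
#'   `max(0.95, 0.5 * peak median)`.
#' @return A `mapping_interval` list: `found`, `chrom`, `start_bp`, `end_bp`,
#'   `start_cm`, `end_cm`, `width_cm`, `peak_window`, `tau`.
#' @export
call_interval <- function(scan, map, tau = NULL) {
  if (nrow(scan) == 0) stop("empty scan")
  peak_i <- which.max(scan$median_posterior)
  peak_chrom <- scan$chrom[peak_i]
  sc <- scan[scan$chrom == peak_chrom, ]
  peak <- which.max(sc$median_posterior)
  if (is.null(tau)) tau <- max(0.95, 0.5 * sc$median_posterior[peak])
  if (sc$median_posterior[peak] < tau) {
    return(structure(list(found = FALSE, tau = tau, chrom = peak_chrom),
                     class = "mapping_interval"))
  }
  above <- sc$median_posterior >= tau
  lo <- peak
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < nrow(sc) && above[hi + 1]) hi <- hi + 1
  start_bp <- sc$start_pos[lo]
  end_bp <- sc$end_pos[hi]
  cms <- interpolate_cm(map, peak_chrom, c(start_bp, end_bp))
  structure(list(found = TRUE, chrom = peak_chrom,
                 start_bp = start_bp, end_bp = end_bp,
                 start_cm = cms[1], end_cm = cms[2],
                 width_cm = cms[2] - cms[1],
                 peak_window = sc$window[peak], tau = tau),
            class = "mapping_interval")
}

#' @export
print.mapping_interval <- function(x, ...) {
  if (!x$found) {
    cat("No linkage signal (no window median reached tau =",
        format(x$tau, digits = 3), ")\n")
  } else {
    cat(sprintf("Mapping interval %s:%d-%d (%.1f-%.1f cM, width %.1f cM), peak window %d\n",
                x$chrom, x$start_bp, x$end_bp, x$start_cm, x$end_cm,
                x$width_cm, x$peak_window))
  }
  invisible(x)
}

#' Local recombination rate profile (cM/Mb) along the genetic map
#'
#' For each pair of adjacent markers, the slope `delta cM / (delta bp / 1e6)`
#' at the bp midpoint. On a monotone map all slopes are non-negative; a dip
#' in the profile marks the recombination-suppressed centromeric region seen
#' in genetic-vs-physical position plots.
#'
#' @param map A `bsr_genmap` with >= 2 markers per chromosome and distinct
#'   bp positions.
#' @return A data.frame: `chrom`, `mid_bp`, `cm_per_mb`.
#' @export
genetic_physical_profile <- function(map) {
  out <- do.call(rbind, lapply(unique(map$chrom), function(ch) {
    m <- map[map$chrom == ch, ]
    if (nrow(m) < 2) stop("need >= 2 markers on chromosome ", ch)
    if (anyDuplicated(m$pos)) stop("duplicate bp positions on ", ch)
    dbp <- diff(m$pos)
    data.frame(chrom = ch,
               mid_bp = (m$pos[-1] + m$pos[-nrow(m)]) / 2,
               cm_per_mb = diff(m$cm) / (dbp / 1e6),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a scan profile as TSV and an interval as BED + JSON
#'
#' The BED record is 0-based half-open (converted from the package's
#' internal 1-based inclusive coordinates).
#'
#' @param scan A `scan_profile`.
#' @param path Output TSV path.
#' @return Invisibly `path`.
#' @export
write_scan <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @param interval A `mapping_interval`.
#' @param bed,json Output paths for the BED and JSON summaries.
#' @export
write_interval <- function(interval, bed, json) {
  if (interval$found) {
    bedline <- data.frame(interval$chrom, interval$start_bp - 1L,
                          interval$end_bp, "mapping_interval")
    write.table(bedline, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed)
  }
  jsonlite::write_json(unclass(interval), json, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(bed = bed, json = json))
}
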
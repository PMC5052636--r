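#' qPCR amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope) - 1`, where `slope` is the slope of threshold cycle
#' (Ct) against log10 template dilution. A perfect doubling per cycle gives
#' slope `-1/log10(2) ~ -3.3219` and `E = 1` (100%). Efficiency is strictly
#' decreasing in `|slope|` and tends to 0 as the slope goes to -Inf.
#'
#' @param slope Standard-curve slope; must be negative (Ct rises as template
#'   is diluted).
#' @return Amplification efficiency as a fraction (vectorized).
#' @examples
#' amplification_efficiency(-1 / log10(2))  # 1
#' amplification_efficiency(-3.8)           # ~0.833
#' @export
amplification_efficiency <- function(slope) {
  if (any(slope >= 0)) stop("slope must be negative (non-physical curve)")
  10^(-1 / slope) - 1
}

#' Validate a primer efficiency against an acceptance window
#'
#' @param efficiency Efficiency fraction (e.g. from
#'   [amplification_efficiency()]).
#' @param lo,hi Inclusive window bounds (default the conventional 85-105%).
#' @return Logical (vectorized): `TRUE` iff `lo <= efficiency <= hi`.
#' @export
validate_efficiency <- function(efficiency, lo = 0.85, hi = 1.05) {
  efficiency >= lo & efficiency <= hi
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 dilution; returns the slope, the
#' implied amplification efficiency and the fit R^2.
#'
#' @param ct Threshold cycles.
#' @param dilution Relative template amounts (e.g. `1, 1/2, ..., 1/128`).
#' @return A list: `slope`, `efficiency`, `r_squared`.
#' @export
standard_curve <- function(ct, dilution) {
  if (length(ct) != length(dilution) || length(ct) < 3)
    stop("need >= 3 matched (ct, dilution) points")
  fit <- lm(ct ~ log10(dilution))
  slope <- unname(coef(fit)[2])
  list(slope = slope,
       efficiency = amplification_efficiency(slope),
       r_squared = summary(fit)$r.squared)
}

#' Efficiency-corrected relative expression
#'
#' Single-calibrator (Pfaffl-type) ratio
#' `(1 + E_target)^(-ct_target) / (1 + E_ref)^(-ct_ref)`: each transcript's
#' abundance is back-computed through its own measured amplification
#' efficiency before forming the target/reference ratio. With equal
#' efficiencies of 1 this reduces to `2^(ct_ref - ct_target)`.
#'
#' @param ct_target,ct_ref Threshold cycles of the target and reference
#'   (calibrator) genes.
#' @param e_target,e_ref Amplification efficiencies (> 0) of the two assays.
#' @return Relative expression ratio (vectorized).
#' @export
relative_expression <- function(ct_target, ct_ref, e_target = 1, e_ref = 1) {
  if (any(e_target <= 0) || any(e_ref <= 0))
    stop("efficiencies must be > 0")
  (1 + e_target)^(-ct_target) / (1 + e_ref)^(-ct_ref)
}

#' Summarize relative expression from a replicate Ct table
#'
#' @param cts data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param reference_gene Name of the calibrator gene (must appear in every
#'   sample).
#' @param efficiencies Named numeric vector of per-gene efficiencies;
#'   missing genes default to 1.
#' @return data.frame `sample`, `gene`, `relative_expression`, `sd` (SD over
#'   replicates, pairing replicates of target and reference by replicate id).
#' @export
relative_expression_table <- function(cts, reference_gene,
                                      efficiencies = NULL) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(cts)))
    stop("cts must have columns: ", paste(need, collapse = ", "))
  eff <- function(g) {
    if (!is.null(efficiencies) && g %in% names(efficiencies))
      efficiencies[[g]] else 1
  }
  out <- do.call(rbind, lapply(unique(cts$sample), function(s) {
    d <- cts[cts$sample == s, ]
    ref <- d[d$gene == reference_gene, ]
    if (nrow(ref) == 0) stop("sample ", s, " lacks the reference gene")
    do.call(rbind, lapply(setdiff(unique(d$gene), reference_gene),
                          function(g) {
      tg <- d[d$gene == g, ]
      m <- merge(tg[, c("replicate", "ct")], ref[, c("replicate", "ct")],
                 by = "replicate", suffixes = c("_t", "_r"))
      ratio <- relative_expression(m$ct_t, m$ct_r, eff(g),
                                   eff(reference_gene))
      data.frame(sample = s, gene = g,
                 relative_expression = mean(ratio),
                 sd = if (length(ratio) > 1) stats::sd(ratio) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
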
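---
title: "Methods: BSR-Seq linkage mapping and Seq-walking insertion calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BSR-Seq linkage mapping and Seq-walking insertion calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrwalk)
```

# The problem

A recessive mutant arises in a transposon-mutagenesis population of an
inbred line. Crossing the mutant line to a second inbred and selfing gives
an F2 segregating 3:1 wild-type : mutant. Two questions follow:

1. **Where is the locus?** Pool mutant and wild-type F2 individuals into
   two bulks, RNA-sequence each bulk, and look for the region where the
   mutant bulk has lost the second parent's alleles (BSR-Seq).
2. **Which insertion is the allele?** Sequence outward from the transposon
   ends in a mutant-derived library and in a control library of the
   non-mutagenized inbred; insertions present in the control cannot be
   causal, and among the remainder the insertion inside the mapped
   interval with overwhelming read support is the candidate.

`bsrwalk` implements both computations and a synthetic-data generator that
produces every input with known ground truth, so the whole chain can be
validated as a recovery experiment.

# The linkage model

## Expected allele frequencies

Let *r* be the recombination fraction between a biallelic SNP and the
causal locus, and call the allele carried by the mutant parent the
*reference* allele (the mutant line is maintained in the reference
background). Gametes of the F1 are, with probability (1−r)/2, r/2, r/2,
(1−r)/2: (m, ref), (m, alt), (+, ref), (+, alt). Conditioning on the
diagnostic genotype of an F2 individual:

* **Mutant bulk** — all individuals are *mm*; each of their chromosomes
  carries the reference allele with probability 1−r, so
  *f_m(r) = 1 − r*. At complete linkage the mutant bulk is fixed: only
  one allele can appear in its reads.
* **Wild-type bulk** — phenotypically wild-type individuals are 1/3 *++*
  and 2/3 *m+*. Counting reference alleles over their chromosomes gives
  *f_w(r) = (1 + r)/3*: one third at complete linkage, rising to 1/2 when
  unlinked.

Both laws are verified in the test-suite against a direct enumeration of
the sixteen F2 gamete pairs, and against bulk counts simulated at
r ∈ {0, 0.1, 0.5}.

## Likelihood, prior and posterior

Per SNP and bulk the model observes *k* reference-allele reads of *n*.
With per-read symmetric miscall rate ε, the **default mode** likelihood is

L(r) = Binom(k_m; n_m, φ(f_m(r))) · Binom(k_w; n_w, φ(f_w(r))),
φ(f) = f(1−ε) + (1−f)ε.

The **exact mode** additionally marginalizes over the binomially
distributed number of reference-carrying chromosomes among the 2N
chromosomes of each finite bulk (N = 123 by default). The exact mode is
the reference computation: the test-suite recomputes it by brute-force
enumeration on the probability scale and requires agreement of the
posterior to 10⁻³ (observed discrepancies are at machine precision).

The two modes are *not* numerically interchangeable: with n of order 50
reads the finite-bulk mixture has visibly heavier tails than the
expectation-frequency binomial, and log-likelihoods can differ by many
units at values of *r* far from the data. The default mode is retained for
genome scans because it is fully vectorized, an order of magnitude faster,
and ranks SNPs in the same order in practice (strong-signal and
zero-signal classifications agree in the tests); the exact mode is
available wherever calibrated probabilities matter.

A SNP is linked with prior probability π; given linkage, *r* is uniform on
a quadrature grid of 64 points in (0.0005, 0.4995); the unlinked
hypothesis sits at r = 0.5. The posterior is formed from the grid-averaged
linked likelihood by Bayes' rule. All likelihood work is on the log scale
with log-sum-exp; a SNP with zero depth in both bulks returns exactly π,
and degenerate likelihoods (e.g. ε = 0 with an impossible observation)
return −∞ likelihoods but never NaN posteriors.

**Parameters** (all exposed in `linkage_params()`): π = 0.05 (a genome
scan should call few SNPs linked a priori), ε = 0.01 (a conservative
per-read allele miscall rate for RNA-seq after filtering), grid size 64
(the posterior changes by < 10⁻³ under refinement at these depths),
N = 123 per bulk (the classic design).

# Genome scan and interval

Windows of 100 SNPs advance by 20 SNPs (both configurable). The window
statistic is the **median** posterior: a single spurious SNP — an
annotation error, a paralogous alignment — cannot move it. The window is
plotted at its 50th SNP (`ceiling(window/2)`); the median of an even
window is the mean of the two central order statistics (this convention
matters for bit-exact reproduction and is therefore fixed and tested).
The window count obeys `floor((S − window)/step) + 1` exactly.

The mapping interval is the maximal contiguous run of windows with median
≥ τ containing the peak window (first peak on ties). τ defaults to
max(0.95, half the peak median): 0.95 demands near-certain linkage, and
the half-peak fallback keeps the rule meaningful if the scan tops out
lower. Physical bounds are the outermost SNPs of the terminal windows; cM
bounds come from linear interpolation on the genetic map, with constant
extrapolation beyond terminal markers. If no window reaches τ the result
is an explicit "no linkage signal", not an empty interval.

A known property of *any* posterior-threshold interval: it does **not**
shrink as sequencing depth grows. The posterior tests linked-versus-
unlinked, so deeper data confidently detects weaker linkage farther from
the locus and the plateau above τ widens. What improves with depth is the
*localization of the peak* (asserted in the test-suite: the distance from
the argmax window to the true locus falls from 5× to 50× depth). Interval
*narrowing* requires either raising τ or, as in practice, genotyping
individual recombinants at flanking markers — out of scope here.

# Seq-walking

Reads are `barcode + terminal tag + genomic flank`. The stages and their
deliberately simple rules:

* **Demultiplexing** — exact 6-nt barcode prefix match (defaults
  `GTCGAT` mutant, `CTGCTA` control). Six-letter barcodes leave no safe
  mismatch margin, so none is allowed; unmatched reads are counted, not
  dropped silently.
* **Tag trimming** — the 25-nt transposon terminal tag is matched with up
  to 2 substitutions; the remainder is the flank. Reads shorter than the
  tag are rejected with reason `"short"`.
* **Length filter** — strictly > 90 bp (a 90 bp flank is removed, 91 bp
  kept). Short flanks map ambiguously and inflate spurious sites.
* **Mapping** — the desk-scale mapper finds the flank's first 31-mer
  exactly (both strands) and extends ungapped with ≤ 5% mismatches. The
  reported coordinate is always the first flank base — the insertion
  point — on either strand. Ties on mismatch count are `multimapped` and
  excluded rather than placed arbitrarily (phantom sites are worse than
  lost reads). At 1% per-base error the exact seed loses 1 − 0.99³¹ ≈ 27%
  of flanks; this is accepted for a test bed, and site tables from a real
  aligner can be imported via `read_sites()`.
* **Site calling** — alignments are grouped into 100-bp bins
  (`bin_start = floor((pos−1)/bin)·bin + 1`). Coarse binning mirrors the
  round-number coordinates of transposon-tagging reports and absorbs the
  9-bp target-site duplication, which is not modeled explicitly.
* **Subtraction** — any mutant-library site within one bin of a control
  site is removed: insertions carried by the non-mutagenized control
  cannot cause the mutant phenotype.
* **Ranking** — sites inside the interval, sorted by read count
  descending, ties broken by coordinate ascending; the rank-1 site and
  its overlapping gene are the candidate.

Integer read conservation holds at every stage
(`total = assigned + unassigned`; `assigned = flanks + rejected`;
`flanks = kept + length-removed`; `kept = mapped + unmapped +
multimapped`) and is asserted by `accounting()` on every run.

# The synthetic generator

What it emulates, per stage:

* **Reference** — uniform-composition random DNA with non-overlapping
  gene intervals placed uniformly (gap-sampling construction). No repeats,
  GC structure, or intron models: the mapper's uniqueness assumptions are
  *easier* on this reference than on a real genome, which is exactly why
  `map_flanks` is labelled desk-scale.
* **Genetic map** — markers uniform in bp; cM accumulates at a constant
  arm rate, reduced by `suppression_factor` (default 0.1) inside the
  centromere span (default the middle fifth), reproducing the sigmoid
  genetic-vs-physical curve and the centromeric cM/Mb dip.
* **F2 meiosis** — Haldane model: parental origin switches between
  adjacent markers with r = (1 − e^(−2d/100))/2; no crossover
  interference, no segregation distortion. The empirical recombination
  fraction is tested against the map function at 1, 10 and 50 cM.
* **Bulk counts** — depth ~ Poisson(mean), each read drawn from a
  uniformly random bulk chromosome, allele flipped with probability ε. No
  allele-specific expression, no expression-level variation between
  genes, no overdispersion beyond finite-bulk sampling: a passing recovery
  test shows the *inference logic* is sound, not that real RNA-seq noise
  is fully captured.
* **Seq-walking reads** — flank lengths normal (mean 150, sd 40, min 30,
  clamped at chromosome ends), strand chosen 50/50 (insertions are
  recovered from both transposon ends), substitution errors uniform at
  rate ε over the whole read, a `junk_fraction` (default 2%) of fully
  random reads emulating undecodable library noise. Real adapter
  chemistry, indels, and quality-dependent errors are not modeled;
  qualities are written as constant `I` and never used.

## The default scenario (the study conditions)

One 10 Mb chromosome, 200 genes, 2,000 SNPs, bulks of 123 + 123 drawn from
700 F2 individuals, depth 20, ε = 0.01, window 100 / step 20; two
50,000-read libraries with the causal insertion (mutant-private, inside
the causal gene, 10× read weight), 20 shared insertions and 9
control-private insertions, all ≥ 5 kb apart.

Two scenario choices deserve justification:

* **Genetic scale.** Physical size is desk-scale (10 Mb) but the
  chromosome must behave genetically like a real one: with a literal
  1–2 cM/Mb the entire 10 Mb would sit within ~10 cM of the causal locus
  and every SNP would be linked — a degenerate scan with no callable
  interval. The default arm rate of 15 cM/Mb gives the chromosome a
  realistic total genetic length (~120 cM) compressed onto the short
  physical axis, so chromosome ends are effectively unlinked and the scan
  shows the familiar peak-over-background shape.
* **F2 of 700.** Only the bulk sizes (123 + 123) are part of the design;
  the population they are drawn from must virtually always contain 123
  mutants. With n = 700 the expected *mm* count is 175 (sd ≈ 10.6), so a
  deficit is a > 4σ event; growing more F2 than one bulks is standard
  practice.

In recovery experiments across seeds the reference genome and genetic map
are held fixed (one genome exists; the experimentally varying quantities
are meiosis, bulking, sequencing and insertion placement) — this also
keeps the 20-seed experiments fast. Problem sizes used by the test-suite:
the two 20-seed recovery experiments run at the full default scenario;
unit tests use 50 kb–2 Mb references, populations of 100–4,000 and
libraries of 20–4,000 reads.

# Numerical and degenerate-input conventions

* Coordinates 1-based inclusive internally; BED exports convert to
  0-based half-open.
* Log-sum-exp for every likelihood aggregation; all-(-Inf) inputs
  propagate to a defined posterior (the prior), never NaN.
* `phenotype_and_bulk` names the deficient genotype class when a bulk
  cannot be filled; gene packing and insertion placement fail with
  explicit errors rather than degrading.
* Per-stage seeds are drawn once from the master seed
  (`sample.int` after `set.seed(master)`), so any stage can be re-run in
  isolation and a run is byte-reproducible — the pipeline test re-runs
  the scan stage from the saved posterior TSV and reproduces the interval
  exactly.
* Ties: peak window — first window; candidate sites — lower coordinate
  first; both fixed so reports are deterministic.

# Known limitations

* The desk-scale mapper is not a read aligner: no indels, no quality
  awareness, exact-seed sensitivity loss at high error rates. Import real
  site tables for real data.
* The posterior-threshold interval widens with depth (see above); τ is a
  detection threshold, not a confidence procedure, and the cM width of
  the called interval should not be read as a confidence interval.
* The expression module implements the standard-curve efficiency formula
  (E = 10^(−1/slope) − 1, validated against the 85–105% window) and an
  efficiency-corrected single-calibrator ratio
  (1+E_t)^(−Ct_t) / (1+E_r)^(−Ct_r). Whether a given laboratory used
  ΔΔCt or per-primer correction must be checked; with equal efficiencies
  the two coincide up to normalization.
* No multi-peak or multi-gene interval logic: one causal locus is
  assumed, as in a monogenic recessive screen.
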
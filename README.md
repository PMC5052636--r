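# bsrwalk

Map-based cloning of recessive mutants by **bulked-segregant RNA-seq
(BSR-Seq) linkage mapping** and **transposon Seq-walking**, as an R package
with a fully seeded synthetic test bed.

The package is written for geneticists who clone genes from biparental
crosses of inbred lines (the motivating system is maize root-hair
mutagenesis with the *Mutator* transposon): an F2 population segregating
3:1 for a recessive mutant is phenotyped, mutant and wild-type individuals
are pooled into two bulks, the bulks are RNA-sequenced, and the causal
locus reveals itself as a region where the mutant bulk carries only the
mutant-parent allele. A transposon flanking-sequence ("Seq-walking")
library from mutant-derived plants, minus a control library from the
non-mutagenized inbred, then pinpoints the insertion allele inside the
mapped interval.

## The model

For a SNP at recombination fraction *r* from the causal locus in a
recessive F2 design, the expected frequency of the mutant-parent allele
among bulk chromosomes is

* mutant bulk (all *mm*): **f_m(r) = 1 − r**
* wild-type bulk (1/3 *++*, 2/3 *m+*): **f_w(r) = 1/3 + r/3**

Observed reference-allele read counts *k* of *n* per bulk are binomial at
these frequencies convolved with a symmetric per-read miscall rate ε
(optionally marginalizing over the finite 2N bulk chromosomes). The
per-SNP posterior probability of linkage compares a linked hypothesis
(uniform prior over *r* on a quadrature grid in (0, 0.5)) with the
unlinked hypothesis *r* = 0.5 under a prior linkage probability π:

```
posterior = π · mean_r L(r) / ( π · mean_r L(r) + (1 − π) · L(0.5) )
```

Chromosomes are scanned with a sliding window of 100 SNPs advancing by 20
SNPs; the window statistic is the **median** posterior (robust to isolated
SNPs), and the mapping interval is the contiguous run of windows above a
threshold that contains the peak, reported in bp and (via the genetic map)
in cM. Seq-walking reads are demultiplexed by exact 6-nt barcode, trimmed
of the transposon terminal tag (≤ 2 mismatches), length-filtered
(strictly > 90 bp), mapped by unique exact 31-mer seed plus ungapped
extension, clustered into 100-bp site bins, subtracted against the control
library, and ranked by supporting read count inside the interval.

Every input can be simulated with known ground truth: reference genome and
gene models, a genetic map with centromeric recombination suppression, F2
gametes under the Haldane model (no interference), bulk allele counts, and
barcoded Seq-walking FASTQ with planted insertions.

## Worked example

```r
library(bsrwalk)
report <- run_all(default_config(seed = 11), outdir = "run1")
```

```
[reference] 1 chromosome(s), 200 genes
[map] 2000 markers, 122.8 cM total
[causal] gene gene0099, marker chr1:5039495
[bulk] 123 mutant + 123 wild-type of 700 F2
[interval] chr1:3182818-6968043 (29.8 cM)
[reads] 100000 pooled reads (50000 + 50000)
[subtract] 21 mutant sites -> 1 after control subtraction
[report] candidate gene gene0099 (causal gene recovered)
```

```r
print(report)
```

```
== bsrwalk run report ==
Mapping interval chr1:3182818-6968043 (47.7-77.5 cM, width 29.8 cM), peak window 54
Top candidate sites in interval:
  rank chrom bin_start read_count  gene_id library
1    1  chr1   5045701      10459 gene0099 mutant
Candidate gene: gene0099 (matches planted causal gene)
Read accounting:
        library assigned flanks rejected length_kept length_removed mapped unmapped multimapped
mutant   mutant    46199  46124       75       42932           3192  31524    11408           0
control control    46004  45925       79       42746           3179  31325    11421           0
Unassigned: 7797 of 100000
```

Reading the output: the window scan confined the causal locus to a
29.8 cM interval around the recombination-suppressed centromere; of the 21
insertion sites seen in the mutant Seq-walking library, control
subtraction left a single site, supported by 10,459 reads, inside the
interval and inside gene `gene0099` — exactly the gene in which the
simulator planted the causal insertion. The accounting table tracks every
read through demultiplexing (exact barcode; ~8% of reads are simulated
library noise), tag trimming, the > 90 bp length filter, and mapping (the
~27% unmapped flanks are the expected loss of an exact 31-mer seed at 1%
per-base error, 1 − 0.99³¹).

All stages are also callable individually (`make_reference`,
`make_genetic_map`, `simulate_f2_population`, `phenotype_and_bulk`,
`simulate_bulk_allele_counts`, `compute_posteriors`,
`sliding_window_scan`, `call_interval`, `demultiplex`, `trim_mu_flank`,
`filter_length`, `map_flanks`, `call_sites`, `subtract_control`,
`restrict_and_rank`, qPCR helpers `amplification_efficiency`,
`standard_curve`, `relative_expression`), and a thin command-line wrapper
with `simulate` / `bsa` / `scan` / `qpcr` / `run-all` subcommands lives in
`inst/cli/bsrwalk.R`. See `vignettes/bsrwalk-methods.Rmd` for the model,
its assumptions and the numerical choices.

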
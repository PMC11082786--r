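# psiseq

Single-nucleotide pseudouridine (Ψ) calling from CMC reverse-transcription
stop sequencing.

## The problem

Ψ is the most abundant internal RNA modification. CMC
(N-cyclohexyl-N′-(2-morpholinoethyl)carbodiimide) leaves a hydrolysis-
resistant adduct on Ψ's N3 that stops reverse transcriptase one nucleotide
before the modified base, so in a CMC-treated library (CMC+) cDNA 3′ ends
pile up at a fixed offset from every Ψ, while a mock-treated library (CMC−)
shows only random RT drop-off. `psiseq` is for people who already have
UMI-deduplicated, aligned reads (or per-strand 3′-end bedgraphs) from such
paired libraries and want reproducible, statistically filtered Ψ calls.

## The method

For each strand, per-base 3′-end counts are computed from the alignments
(the RT stop is the 3′-terminal aligned base; reads are cDNA-sense, so the
transcript strand is the opposite of the alignment strand). Then, per
sample:

1. **Peaks.** Positions with ≥ 10 reads are putative strong stops.
2. **Windows.** Each peak is assigned to a containing exon and a 100-nt
   window centred on the peak is clipped to that exon.
3. **Poisson test.** Window depths are fitted by maximum likelihood,
   `μ̂ = mean(depths)` (peak position excluded by default), and the peak
   count *k* is tested against the null that it came from the same
   distribution: `p = P(X ≥ k), X ~ Poisson(μ̂)`.
4. **FDR.** Benjamini–Hochberg across all tested peaks of the sample;
   significant ⇔ `q ≤ 0.05`.
5. **Calling.** A Ψ is reported at `stop − 1` (`+` strand) / `stop + 1`
   (`−` strand) when the stop is significant in CMC+, not significant in
   CMC− at the same coordinate, and that adjacent base is a genomic T in
   transcript sense.

A normalized height, `log2(peak / window 3′-end total)`, supports
cross-sample comparison (squared Pearson correlation over shared peaks), and
called sites can be scanned against a guide-RNA target sequence
(ACC‑Ψ‑NGA minimal core) with IUPAC-aware contiguous-match counting in which
the unpaired Ψ/N positions bridge, but do not extend, a run. A fully
synthetic simulator (`sim_config()` → `simulate_reference()` →
`simulate_coverage()` → optionally `simulate_alignments()`) provides
ground-truthed data for every step.

## Worked example

```r
library(psiseq)

cfg <- sim_config(n_genes = 20, n_psi = 12, seed = 42)
ref <- simulate_reference(cfg)                       # genome + exons + truth
cov <- simulate_coverage(ref, ref$truth, cfg)        # CMC+ / CMC- coverage

tests_plus  <- test_peaks(cov$cmc_plus,  ref$exons)
tests_minus <- test_peaks(cov$cmc_minus, ref$exons)
sites <- call_sites(tests_plus, tests_minus, ref$genome, ref$exons)
sites[1:4, .(chrom, psi_pos, strand, gene_id, region,
             count_plus, mu_plus, q_plus, norm_height)]
#>     chrom psi_pos strand gene_id region count_plus   mu_plus       q_plus norm_height
#> 1:   chr1    3277      +   g0003   5UTR         41 1.0909091 5.478225e-49   -1.861617
#> 2:   chr1    3852      +   g0003    CDS         48 1.0707071 2.998693e-60   -1.681824
#> 3:   chr1    5581      +   g0005   3UTR         55 0.8970588 9.955769e-76   -1.076621
#> 4:   chr1    8956      +   g0009   5UTR         44 0.9393939 2.301957e-56   -1.638600

evaluate_calls(sites, ref$truth)[c("sensitivity", "fdp")]
#> $sensitivity
#> [1] 1
#> $fdp
#> [1] 0
```

Each row is one called Ψ: `count_plus` is the 3′-end pile-up at the adjacent
stop in CMC+, `mu_plus` the fitted background (~1 random stop per
nucleotide, the simulated rate), `q_plus` its BH-adjusted tail probability,
and `norm_height` the log2 peak/window ratio. All 12 planted sites are
recovered with no false calls.

Comparing replicate coverage draws pairs the shared peaks and reports R²:

```r
rep2 <- simulate_coverage(ref, ref$truth, cfg, seed = 43)
cmp <- compare_coverages(cov$cmc_plus, rep2$cmc_plus, ref$exons)
cmp$n; cmp$r_squared
#> [1] 12
#> [1] 0.02577452
```

(Here R² ≈ 0 *by design*: the simulator plants every site at the same signal
strength, so replicate heights differ only by Poisson noise. In real
libraries heights vary over orders of magnitude with stoichiometry and
expression, which is what makes the correlation informative.)

Files instead of in-memory objects work the same way — `run_pipeline()`
takes a genome FASTA, a GTF/BED annotation and SAM/BAM or bedgraph-pair
inputs and writes `sites.tsv`/`sites.bed`; `inst/scripts/psiseq` exposes the
same steps as shell subcommands (`simulate`, `coverage`, `callpeaks`,
`call`, `compare`, `guide-scan`).

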
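---
title: "Calling pseudouridine sites from CMC RT-stop coverage: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling pseudouridine sites from CMC RT-stop coverage: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

CMC forms covalent adducts on G, U and pseudouridine (Ψ); alkaline hydrolysis
strips them from G and U but not from Ψ's N3. The surviving adduct blocks
reverse transcriptase, which terminates one nucleotide before the modified
base. In a CMC-treated library (CMC+) cDNA 3′ ends therefore pile up at a
fixed offset from each Ψ, while a mock-treated library (CMC−) shows only the
background of random RT drop-off. `psiseq` turns per-base, strand-specific
3′-end counts of the two libraries into single-nucleotide Ψ calls.

The statistical model is deliberately minimal. Within a window around a
candidate stop, per-nucleotide 3′-end counts are treated as i.i.d.
Poisson(μ). μ is fitted by maximum likelihood — the sample mean of the window
depths — and the candidate's count *k* is tested against the upper tail
P(X ≥ k | μ). The Benjamini–Hochberg step-up procedure is applied across all
tested candidates of a sample, and a candidate is significant when its
q-value is at or below the threshold (default 0.05). A Ψ is called where a
stop is significant in CMC+ but not in CMC− and the adjacent base in
transcript sense is a genomic T.

## Coordinate and orientation conventions

* All internal coordinates are 0-based half-open; conversion happens only at
  file boundaries (GTF is 1-based closed; BED/bedgraph already match the
  internal convention). This avoids off-by-one drift between modules.
* The RT stop of a read is its 3′-terminal *aligned* base: the highest
  aligned reference position for a plus-strand alignment, the lowest for a
  minus-strand alignment. Soft-clipped bases are not evidence of template
  position and are excluded; splice gaps do not move the terminal block's
  endpoint.
* Orientation defaults to `antisense`: the sequenced read is cDNA-sense, so
  the read's 3′ end is the cDNA 3′ terminus (the RT stop) and the transcript
  strand is the opposite of the alignment strand. Libraries built the other
  way around can use `orientation = "sense"` and/or `read_end = "5p"`;
  nothing else in the pipeline changes.
* The Ψ sits one nucleotide 5′ of the stop in mRNA orientation
  (equivalently, directly 3′ of the stop in cDNA orientation): `stop − 1` on
  `+`, `stop + 1` on `−`. Both views describe the same base; the package
  uses the mRNA-orientation arithmetic.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_reads` | 10 | 3′-end reads | removes stops from random RT termination; positions below the floor are never tested |
| `window_size` | 100 | nt | background window centred on the peak, clipped to the assigned exon (shorter windows near exon ends) |
| `fdr_threshold` | 0.05 | q-value | BH significance cut-off per sample |
| `exclude_peak` | `TRUE` | — | drop the peak position from the background fit so the signal does not inflate its own null |
| `min_mapq` | 10 | MAPQ | multi-mappers create artifactual pileups; records with unknown MAPQ (255) are kept |
| `slop` | 0 | nt | CMC− suppression is matched at the exact stop coordinate; single-nucleotide precision is the method's claim |

For an even `window_size` the peak cannot sit exactly at the centre; the
left flank receives the extra base (size 100 spans `[pos − 50, pos + 50)`).
This asymmetry is irrelevant to the fit (only the multiset of depths enters
the mean) but matters for exact strand-mirror comparisons, which should use
an odd window.

## Design choices that were genuinely open

* **Peak in or out of the background fit.** The window "contains" the peak,
  but using the peak's own count to estimate μ biases the null upward and
  costs sensitivity. The default excludes it; `exclude_peak = FALSE`
  restores the inclusive fit.
* **Exon assignment tie-break.** Peaks are assigned to exons of genes, not
  transcripts; identical exons shared by transcripts are deduplicated at
  load time. When several intervals still contain a peak the longest wins
  (it determines the largest usable window), then the lexicographically
  smallest `gene_id`, then the smallest start — a deterministic rule so that
  reruns are byte-identical.
* **Neighbouring peaks are not masked** from each other's windows. A strong
  stop inside another peak's window raises that window's μ and makes the
  test conservative there. Masking would require a joint model; the simple
  rule is documented instead.
* **BH per sample.** CMC+ and CMC− are adjusted independently; the calling
  rule is "significant in CMC+, not significant in CMC−". A CMC− position
  that never reached `min_reads` was never tested and counts as not
  significant — the filter is on significance, not on the presence of reads.
* **`N` bases fail the genomic-T check**: a site whose adjacent base is
  unknown is not called (conservative).
* **Normalized peak height** (used for cross-sample comparison) is
  `log2(peak count / window 3′-end total)` with the peak's own count in the
  denominator — the window total contains the peak; a flag excludes it. With
  the peak included the ratio is ≤ 1, so heights are ≤ 0.
* **Contiguous guide matches** bridge the unpaired Ψ and N positions of the
  target core (they are skipped, neither counted nor run-breaking), because
  a gRNA:target duplex is not interrupted by the unpaired dinucleotide. The
  full guide target sequence must be supplied by the user; only the minimal
  core (ACC‑Ψ‑NGA) is built in.

## What the simulator emulates — and what it does not

`simulate_reference()` / `simulate_coverage()` generate exactly the data the
test assumes: a random genome with non-overlapping single-exon genes
(5′UTR/CDS/3′UTR split 15/70/15), an independent Poisson(μ_bg) count of
background stops at every exonic nucleotide in both libraries, and an extra
Poisson(λ_signal) count at each planted Ψ's stop position in CMC+ only.
Defaults (50 genes of 500–1500 nt, GC 0.45, μ_bg = 1, λ_signal = 40,
50 sites, 20% of them within 50 nt of an exon end to exercise window
truncation) were chosen once as a desk-scale caricature of a polyA+ library:
a strong single-base peak over a ~1×/nt drop-off background is the regime
the 10-read floor is designed for. `simulate_alignments()` materializes a
coverage as antisense single-end records with 80–140 nt inserts so the
extraction path can be tested against exact conservation.

The simulator does **not** model sequence-dependent RT drop-off, expression
heterogeneity across genes (a uniform background is the test's own null),
splicing, UMI duplication, partial CMC conversion, or the G/U adducts that
incomplete hydrolysis leaves behind. Passing the recovery tests therefore
shows the implementation is faithful to its model, not that the model
captures every failure mode of real libraries.

## Behaviour under a sparse null — a real limitation

The read-count floor conditions on the extreme tail of the background
distribution. When the background mean is low (say μ ≈ 2), a position needs
a ~4×10⁻⁵-probability fluctuation to reach 10 reads at all — and exactly
those selected positions then face a Poisson test whose p-value is, by
construction, ~5×10⁻⁵ or smaller. BH across the handful of selected
candidates cannot rescue this: the p-values of filter-selected nulls are far
from uniform, and essentially every selected null peak is declared
significant. The CMC− filter does not help (the CMC− library rarely
fluctuates at the *same* base), and ~a quarter of such peaks sit next to a T
by chance. Under a sparse homogeneous null the realized false-discovery
proportion of the procedure is therefore close to 1, not 0.05 — the package's
own null-simulation acceptance test measures this honestly. In the regime
the method is used in practice — windows inside expressed exons, where μ is
large enough that 10 reads is an ordinary event and p-values of true nulls
spread over (0, 1) — BH behaves as intended; at μ_bg = 1 the same pipeline's
null simulations yield a mean FDP near 0 simply because background positions
essentially never pass the floor. Users should read q-values as calibrated
only when candidate peaks are not themselves rare tail events of their own
windows.

## Numerical choices and degenerate inputs

* Upper-tail probabilities use the Poisson survival function at `k − 1`
  (`ppois(k - 1, mu, lower.tail = FALSE)`), stable for small tails; μ = 0
  gives p = 1 for k = 0 and p = 0 otherwise.
* A window that loses all background positions (a single-base exon with the
  peak excluded) cannot be fitted; the peak is skipped and counted in a
  message rather than guessed at.
* Uncovered window bases count as depth 0 — sparse coverage is densified
  over the window before fitting.
* Bedgraph inputs may contain multi-base intervals (expanded per base) and
  overlapping lines (summed); malformed lines fail with their line number.
* All set operations (replicate intersection, truth matching) use exact
  (chrom, position, strand) keys.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on simulated data:
null-FDR simulations use 200 exons of 1 kb across 50 seeds; recovery uses
50 genes with 100 interior sites across 10 seeds; oracle comparisons sweep
k ≤ 50 over six values of μ and 1000 random p-vectors. These sizes make the
whole suite run in about a minute on a laptop while keeping Monte-Carlo
noise well below the asserted margins.

## Known limitations

* No replicate-aware joint testing; replicates are called independently and
  intersected afterwards.
* No alternative null (negative binomial or empirical); overdispersed
  backgrounds will inflate significance.
* No stoichiometry estimate: the normalized height is a comparison score,
  not a modification fraction.
* Exon assignment ignores transcript structure beyond the exon list; a peak
  in overlapping genes is assigned by the deterministic tie-break, not by
  expression.
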
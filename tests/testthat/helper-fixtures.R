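# In-code fixtures shared across test files.

library(data.table)

# write a FASTA and load it back through the package reader
make_genome <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), fa)
  load_genome(fa)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# sparse coverage from a compact spec list: list(list(chrom, strand, pos, count))
cov_from_counts <- function(chrom, strand, pos, count,
                            orientation = "antisense") {
  stranded_coverage(data.table(chrom = chrom, strand = strand,
                               pos = pos, count = count),
                    orientation = orientation)
}

random_coverage <- function(n = 200, chroms = c("chr1", "chr2"),
                            max_pos = 10000, max_count = 30) {
  dt <- unique(data.table(
    chrom = sample(chroms, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE) - 1L
  ))
  dt[, count := sample.int(max_count, .N, replace = TRUE)]
  stranded_coverage(dt)
}

exon_table <- function(chrom, start, end, strand, gene_id,
                       region = "exon") {
  data.table(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, gene_id = gene_id, region = region)
}

# reverse-complement transforms for the strand-mirror property
flip_strand <- function(s) ifelse(s == "+", "-", "+")

mirror_coverage <- function(cov, L) {
  stranded_coverage(cov$counts[, .(chrom, strand = flip_strand(strand),
                                   pos = L - 1L - pos, count)],
                    orientation = cov$orientation)
}

mirror_exons <- function(exons, L) {
  out <- exons[, .(chrom, start = L - end, end = L - start,
                   strand = flip_strand(strand), gene_id, region)]
  setkey(out, chrom, start, end)
  out[]
}

# independent oracles -------------------------------------------------------

# brute-force Poisson upper tail: 1 - sum of pmf terms below k
pois_tail_oracle <- function(k, mu) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
   1 - sum(exp(-mu) * mu^i / factorial(i))
}

# hand-written BH step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(1, q_sorted)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# closed-form Pearson correlation from sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
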
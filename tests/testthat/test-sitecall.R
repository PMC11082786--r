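# A minimal hand-built peak-test row for call_sites inputs.
test_row <- function(chrom = "chr1", pos, strand = "+", count = 20L,
                     gene_id = "g1", sig = TRUE, q = 0.001,
                     window_total = 100L) {
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
             count = count, gene_id = gene_id, exon_start = 0L,
             exon_end = 10000L, window_start = 0L, window_end = 100L,
             window_total = window_total, mu = 1.0,
             p_value = q / 10, q_value = q, significant = sig)
}
no_tests <- test_row(pos = 0L)[0]

test_that("psi_position is one nucleotide 5' of the stop in mRNA orientation", {
  expect_equal(psi_position(1000L, "+"), 999L)
  expect_equal(psi_position(1000L, "-"), 1001L)
  expect_equal(psi_position(0L, "+"), -1L)  # off-chromosome; callers skip
  expect_error(psi_position(10L, "*"), "strand")
})

test_that("call_sites applies the CMC+/CMC-/genomic-T rules", {
  # position 99 (0-based) is T; stop at 100 on + has psi at 99
  g <- make_genome(list(chr1 = paste0(strrep("C", 99), "TG", strrep("C", 99))))
  exons <- exon_table("chr1", 0, 200, "+", "g1")

  # (a)+(c): CMC+ significant, no CMC- peak, T base -> emitted
  s <- call_sites(test_row(pos = 100L), no_tests, g, exons)
  expect_equal(nrow(s), 1L)
  expect_equal(s$psi_pos, 99L)
  expect_true(is.na(s$q_minus))
  # norm height: log2(20 / 100)
  expect_equal(s$norm_height, log2(0.2))

  # (c): base at psi position not T -> not emitted (stop at 102, psi at 101=C)
  expect_equal(nrow(call_sites(test_row(pos = 102L), no_tests, g, exons)), 0L)

  # (b): significant CMC- stop at the same coordinate kills the site
  expect_equal(nrow(call_sites(test_row(pos = 100L), test_row(pos = 100L),
                               g, exons)), 0L)

  # a non-significant CMC- peak does not: its stats are attached instead
  s2 <- call_sites(test_row(pos = 100L),
                   test_row(pos = 100L, count = 11L, sig = FALSE, q = 0.4),
                   g, exons)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$count_minus, 11L)
  expect_equal(s2$q_minus, 0.4)

  # non-significant CMC+ peaks are never sites
  expect_equal(nrow(call_sites(test_row(pos = 100L, sig = FALSE), no_tests,
                               g, exons)), 0L)
})

test_that("an N base fails the genomic-T check and edge stops are skipped", {
  g <- make_genome(list(chr1 = paste0("T", strrep("N", 99), strrep("A", 100))))
  exons <- exon_table("chr1", 0, 200, "+", "g1")
  # psi position falls on N
  expect_equal(nrow(call_sites(test_row(pos = 50L), no_tests, g, exons)), 0L)
  # stop at position 0 on +: psi off the chromosome -> skipped with message
  expect_message(
    s <- call_sites(test_row(pos = 0L), no_tests, g, exons),
    "outside the chromosome")
  expect_equal(nrow(s), 0L)
  # minus strand: stop at 50 has psi at 51 (genomic N -> fails);
  # genomic A at 150 reads as transcript-sense T on minus
  sm <- call_sites(test_row(pos = 150L, strand = "-"), no_tests, g, exons)
  expect_equal(sm$psi_pos, 151L)
  expect_equal(fetch_base(g, "chr1", 151L, "-"), "T")
})

test_that("slop widens the CMC- suppression match while default is exact", {
  g <- make_genome(list(chr1 = strrep("T", 300)))
  exons <- exon_table("chr1", 0, 300, "+", "g1")
  plus <- test_row(pos = 100L)
  minus <- test_row(pos = 101L)  # significant CMC- stop one base away
  expect_equal(nrow(call_sites(plus, minus, g, exons)), 1L)
  expect_equal(nrow(call_sites(plus, minus, g, exons, slop = 1)), 0L)
})

test_that("region annotation follows CDS > 5UTR > 3UTR > exon precedence", {
  exons <- rbind(
    exon_table("chr1", 0, 300, "+", "g1"),
    exon_table("chr1", 0, 50, "+", "g1", region = "5UTR"),
    exon_table("chr1", 50, 250, "+", "g1", region = "CDS"),
    exon_table("chr1", 250, 300, "+", "g1", region = "3UTR"))
  expect_equal(annotate_region(exons, "chr1", 100L, "+"), "CDS")
  expect_equal(annotate_region(exons, "chr1", 20L, "+"), "5UTR")
  expect_equal(annotate_region(exons, "chr1", 260L, "+"), "3UTR")
  # plain-exon annotation falls back to "exon"
  expect_equal(annotate_region(exon_table("chr1", 0, 300, "+", "g1"),
                               "chr1", 100L, "+"), "exon")
  # overlapping CDS and UTR at the same base: CDS wins
  expect_equal(annotate_region(rbind(
    exon_table("chr1", 0, 100, "+", "g1", region = "3UTR"),
    exon_table("chr1", 0, 100, "+", "g1", region = "CDS")),
    "chr1", 10L, "+"), "CDS")
})

test_that("replicate intersection is exact set arithmetic", {
  mk <- function(pos) data.table(chrom = "chr1", psi_pos = as.integer(pos),
                                 strand = "+", gene_id = "g1")
  r <- intersect_replicates(mk(c(1, 2, 3)), mk(c(3, 10, 20, 30)))
  expect_equal(nrow(r$shared), 1L)
  expect_equal(r$shared$psi_pos, 3L)
  expect_equal(nrow(r$rep1_only), 2L)
  expect_equal(nrow(r$rep2_only), 3L)
  expect_equal(nrow(r$shared) + nrow(r$rep1_only), 3L)
  # identical and disjoint lists
  expect_equal(nrow(intersect_replicates(mk(1:3), mk(1:3))$shared), 3L)
  expect_equal(nrow(intersect_replicates(mk(1:3), mk(7:9))$shared), 0L)
})

test_that("sites round-trip through TSV and produce well-formed BED6", {
  g <- make_genome(list(chr1 = paste0(strrep("C", 999), "TG", strrep("C", 999))))
  exons <- rbind(exon_table("chr1", 0, 2000, "+", "G1"),
                 exon_table("chr1", 0, 2000, "+", "G1", region = "CDS"))
  sites <- call_sites(test_row(pos = 1000L, gene_id = "G1", q = 0.01),
                      no_tests, g, exons)
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  write_sites(sites, bed, tsv)
  expect_equal(readLines(bed), "chr1\t999\t1000\tG1:CDS\t20\t+")
  back <- read_sites(tsv)
  expect_equal(as.data.table(back), as.data.table(sites))
  # empty call set -> empty files
  write_sites(sites[0], bed, tsv)
  expect_equal(readLines(bed), character(0))
  expect_equal(nrow(read_sites(tsv)), 0L)
})

test_that("pipeline calls match over bedgraph and SAM inputs and are deterministic", {
  cfg <- sim_config(n_genes = 10, n_psi = 12, seed = 51)
  ref <- simulate_reference(cfg)
  cov <- simulate_coverage(ref, ref$truth, cfg)
  dir <- tempfile(); dir.create(dir)
  paths <- write_simulation(ref, cov, dir)
  sam_p <- file.path(dir, "plus.sam"); sam_m <- file.path(dir, "minus.sam")
  simulate_alignments(ref, cov$cmc_plus, sam_p, seed = 1)
  simulate_alignments(ref, cov$cmc_minus, sam_m, seed = 2)

  base_cfg <- list(genome = paths$genome, annotation = paths$annotation,
                   cmc_plus = paths$cmc_plus, cmc_minus = paths$cmc_minus,
                   out_dir = file.path(dir, "out_bg"))
  res_bg <- suppressMessages(run_pipeline(base_cfg))
  res_sam <- suppressMessages(run_pipeline(modifyList(base_cfg, list(
    cmc_plus = sam_p, cmc_minus = sam_m,
    out_dir = file.path(dir, "out_sam")))))
  expect_equal(as.data.table(res_sam$sites), as.data.table(res_bg$sites))
  expect_gt(nrow(res_bg$sites), 0L)
  # calls recover the planted truth at this signal strength
  ev <- evaluate_calls(res_bg$sites, ref$truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fdp, 0)

  # byte-identical outputs on a re-run
  res_bg2 <- suppressMessages(run_pipeline(modifyList(base_cfg, list(
    out_dir = file.path(dir, "out_bg2")))))
  expect_identical(readLines(file.path(dir, "out_bg", "sites.tsv")),
                   readLines(file.path(dir, "out_bg2", "sites.tsv")))

  # CMC- identical to CMC+ suppresses everything
  res_null <- suppressMessages(run_pipeline(modifyList(base_cfg, list(
    cmc_minus = paths$cmc_plus, out_dir = file.path(dir, "out_null")))))
  expect_equal(nrow(res_null$sites), 0L)

  # missing input fails before computing and leaves no partial outputs
  bad <- modifyList(base_cfg, list(genome = file.path(dir, "nope.fa"),
                                   out_dir = file.path(dir, "out_bad")))
  expect_error(run_pipeline(bad), "not found")
  expect_false(file.exists(file.path(dir, "out_bad", "sites.tsv")))
})

test_that("flat key-value config files drive the pipeline", {
  cfgf <- tempfile(fileext = ".cfg")
  writeLines(c("min_reads = 12  # floor",
               "fdr: 0.01",
               "cmc_plus = a.plus.bedgraph, a.minus.bedgraph"), cfgf)
  cfg <- read_config(cfgf)
  expect_equal(cfg$min_reads, 12)
  expect_equal(cfg$fdr, 0.01)
  expect_equal(cfg$cmc_plus, c("a.plus.bedgraph", "a.minus.bedgraph"))
})
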
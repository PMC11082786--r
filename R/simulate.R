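# Fully synthetic, ground-truthed CMC RT-stop datasets. The generative model
# is the one assumed by the statistical test: an independent homogeneous
# Poisson count of random RT terminations at every exonic nucleotide in both
# libraries, plus an extra Poisson count of strong stops at the position one
# nucleotide 3' (in cDNA orientation) of each planted pseudouridine, present
# in the CMC+ library only.

#' Simulation configuration
#'
#' @param n_genes Number of non-overlapping single-exon genes (default 50).
#' @param exon_length Length bounds `c(min, max)` of each gene's exon in nt
#'   (default `c(500, 1500)`, the scale of typical mRNA exonic stretches).
#' @param gc GC fraction of the random genome (default 0.45, roughly
#'   mammalian transcriptome-like).
#' @param mu_bg Mean random RT-termination (background) stops per exonic
#'   nucleotide (default 1).
#' @param lambda_signal Mean extra stops at a planted pseudouridine's stop
#'   position in the CMC+ library (default 40, a strong single-base peak of
#'   the kind the read-count floor is meant to retain).
#' @param n_psi Number of planted pseudouridine sites (default 50).
#' @param stop_in_minus Also plant the signal in the CMC- library (negative
#'   control configuration; default `FALSE`).
#' @param edge_fraction Fraction of planted sites drawn from near-edge
#'   positions (closer than `interior_margin` to an exon end) to exercise
#'   window truncation; the rest are interior (default 0.2).
#' @param interior_margin Distance (nt) from both exon ends defining an
#'   interior site (default 50, half the default window).
#' @param intergenic Gap between neighbouring genes in nt (default 200).
#' @param seed Integer seed fixing the whole pseudo-random stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50, exon_length = c(500, 1500), gc = 0.45,
                       mu_bg = 1, lambda_signal = 40, n_psi = 50,
                       stop_in_minus = FALSE, edge_fraction = 0.2,
                       interior_margin = 50, intergenic = 200, seed = 1) {
  stopifnot(n_genes >= 1, length(exon_length) == 2,
            exon_length[1] >= 20, exon_length[1] <= exon_length[2],
            gc > 0, gc < 1, mu_bg >= 0, lambda_signal >= 0, n_psi >= 0,
            edge_fraction >= 0, edge_fraction <= 1, interior_margin >= 0,
            intergenic >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 exon_length = as.integer(exon_length), gc = gc,
                 mu_bg = mu_bg, lambda_signal = lambda_signal,
                 n_psi = as.integer(n_psi),
                 stop_in_minus = isTRUE(stop_in_minus),
                 edge_fraction = edge_fraction,
                 interior_margin = as.integer(interior_margin),
                 intergenic = as.integer(intergenic),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# candidate pseudouridine positions: transcript-sense T inside the exon with
# the adjacent stop position also inside the exon
.psi_candidates <- function(genome, exons_only) {
  cand <- list()
  for (i in seq_len(nrow(exons_only))) {
    e <- exons_only[i]
    seq_e <- substring(genome$seq[[e$chrom]], e$start + 1L, e$end)
    if (e$strand == "+") {
      # stop = psi + 1 must be < end
      rel <- which(strsplit(seq_e, "", fixed = TRUE)[[1]] == "T")
      pos <- e$start + rel - 1L
      pos <- pos[pos + 1L < e$end]
    } else {
      # transcript-sense T = genomic A; stop = psi - 1 must be >= start
      rel <- which(strsplit(seq_e, "", fixed = TRUE)[[1]] == "A")
      pos <- e$start + rel - 1L
      pos <- pos[pos - 1L >= e$start]
    }
    if (length(pos) > 0L) {
      cand[[length(cand) + 1L]] <- data.table(
        chrom = e$chrom, psi_pos = pos, strand = e$strand,
        gene_id = e$gene_id, exon_start = e$start, exon_end = e$end)
    }
  }
  if (length(cand) == 0L) {
    return(data.table(chrom = character(), psi_pos = integer(),
                      strand = character(), gene_id = character(),
                      exon_start = integer(), exon_end = integer()))
  }
  rbindlist(cand)
}

# greedy sample enforcing a minimum pairwise separation within a chromosome
.sample_separated <- function(cand, n, min_sep = 3L) {
  if (n == 0L || nrow(cand) == 0L) return(cand[0])
  idx <- sample.int(nrow(cand))
  chosen <- integer(0)
  for (i in idx) {
    ok <- TRUE
    for (j in chosen) {
      if (cand$chrom[i] == cand$chrom[j] &&
          abs(cand$psi_pos[i] - cand$psi_pos[j]) < min_sep) {
        ok <- FALSE
        break
      }
    }
    if (ok) chosen <- c(chosen, i)
    if (length(chosen) == n) break
  }
  cand[chosen]
}

#' Simulate a reference: genome, exon annotation and planted pseudouridines
#'
#' Generates a random genome carrying `n_genes` non-overlapping single-exon
#' genes on randomly chosen strands, each split (in transcript orientation)
#' into 5'UTR (15%), CDS (70%) and 3'UTR (15%) sub-features, then plants
#' `n_psi` pseudouridines at transcript-sense `T` positions within exons.
#' A fraction of sites is drawn near exon edges to exercise window
#' truncation; the remainder are interior (at least `interior_margin` from
#' both exon ends). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a `psi_genome`), `exons` (annotation table as
#'   from [load_exons()]), and `truth` (`data.table`: `chrom`, `psi_pos`,
#'   `strand`, `stop_pos`, `gene_id`, `lambda`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  lens <- if (config$exon_length[1] == config$exon_length[2]) {
    rep(config$exon_length[1], ng)
  } else {
    sample(config$exon_length[1]:config$exon_length[2], ng, replace = TRUE)
  }
  strands <- sample(c("+", "-"), ng, replace = TRUE)
  gap <- config$intergenic
  starts <- gap + c(0L, cumsum(head(lens + gap, -1L)))
  glen <- starts[ng] + lens[ng] + gap
  bases <- sample(c("A", "C", "G", "T"), glen, replace = TRUE,
                  prob = c((1 - config$gc) / 2, config$gc / 2,
                           config$gc / 2, (1 - config$gc) / 2))
  seqs <- paste(bases, collapse = "")
  genome <- structure(
    list(seq = c(chr1 = seqs),
         lengths = c(chr1 = nchar(seqs))),
    class = "psi_genome")

  rows <- vector("list", ng)
  for (i in seq_len(ng)) {
    s <- starts[i]; e <- s + lens[i]; L <- lens[i]
    gid <- sprintf("g%04d", i)
    u5 <- max(1L, as.integer(round(0.15 * L)))
    u3 <- max(1L, as.integer(round(0.15 * L)))
    if (strands[i] == "+") {
      sub <- data.table(
        chrom = "chr1",
        start = c(s, s, s + u5, e - u3),
        end = c(e, s + u5, e - u3, e),
        strand = "+", gene_id = gid,
        region = c("exon", "5UTR", "CDS", "3UTR"))
    } else {
      sub <- data.table(
        chrom = "chr1",
        start = c(s, e - u5, s + u3, s),
        end = c(e, e, e - u5, s + u3),
        strand = "-", gene_id = gid,
        region = c("exon", "5UTR", "CDS", "3UTR"))
    }
    rows[[i]] <- sub
  }
  exons <- rbindlist(rows)
  setkey(exons, chrom, start, end)

  truth <- data.table(chrom = character(), psi_pos = integer(),
                      strand = character(), stop_pos = integer(),
                      gene_id = character(), lambda = numeric())
  if (config$n_psi > 0L) {
    cand <- .psi_candidates(genome, exons[region == "exon"])
    margin <- config$interior_margin
    interior <- cand[psi_pos - exon_start >= margin &
                       exon_end - psi_pos > margin]
    edge <- cand[!interior, on = c("chrom", "psi_pos", "strand")]
    n_edge <- as.integer(round(config$edge_fraction * config$n_psi))
    n_int <- config$n_psi - n_edge
    pick_int <- .sample_separated(interior, n_int)
    pick_edge <- .sample_separated(edge, n_edge)
    if (nrow(pick_int) < n_int || nrow(pick_edge) < n_edge) {
      stop("not enough transcript-sense T positions to plant ", config$n_psi,
           " site(s); increase genome size (n_genes / exon_length)")
    }
    pick <- rbind(pick_int, pick_edge)
    truth <- pick[, .(
      chrom, psi_pos, strand,
      stop_pos = ifelse(strand == "+", psi_pos + 1L, psi_pos - 1L),
      gene_id, lambda = config$lambda_signal)]
    setorder(truth, chrom, psi_pos)
  }
  list(genome = genome, exons = exons[], truth = truth[])
}

#' Simulate CMC+ and CMC- stranded 3'-end coverage
#'
#' Every exonic nucleotide receives an independent
#' `Poisson(mu_bg)` background count in each library, keyed on the gene's
#' transcript-sense strand. Each planted site's expected stop position
#' additionally receives `Poisson(lambda_signal)` stops in the CMC+ library
#' (and, when `stop_in_minus` is set, an independent such count in CMC-,
#' for negative-control experiments). Deterministic given `seed`.
#'
#' @param reference Output of [simulate_reference()].
#' @param truth Truth table (normally `reference$truth`).
#' @param config The [sim_config()] used.
#' @param seed Seed for the coverage draw (default `config$seed`).
#' @return List with `cmc_plus` and `cmc_minus` [stranded_coverage()]s.
#' @export
simulate_coverage <- function(reference, truth, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ex <- reference$exons[region == "exon"]
  pos_dt <- ex[, .(pos = start:(end - 1L)), by = .(chrom, strand, start)]
  pos_dt[, start := NULL]
  n <- nrow(pos_dt)
  plus_dt <- copy(pos_dt)[, count := rpois(n, config$mu_bg)]
  minus_dt <- copy(pos_dt)[, count := rpois(n, config$mu_bg)]
  if (nrow(truth) > 0L) {
    sig <- truth[, .(chrom, strand, pos = stop_pos,
                     count = rpois(.N, lambda))]
    plus_dt <- rbind(plus_dt, sig)
    if (config$stop_in_minus) {
      sig_m <- truth[, .(chrom, strand, pos = stop_pos,
                         count = rpois(.N, lambda))]
      minus_dt <- rbind(minus_dt, sig_m)
    }
  }
  list(cmc_plus = stranded_coverage(plus_dt),
       cmc_minus = stranded_coverage(minus_dt))
}

#' Emit synthetic antisense alignments reproducing a coverage
#'
#' Writes one single-end SAM record per counted stop. Reads are cDNA-sense,
#' so they align antisense to the transcript; the 3' aligned end of every
#' record is exactly its stop position, and insert sizes mimic gel-purified
#' 80-140 nt fragments (clipped at chromosome ends, which keeps the 3' end
#' fixed). Running [coverage_from_bam()] on the output reproduces the input
#' coverage exactly.
#'
#' @param reference Output of [simulate_reference()].
#' @param cov A [stranded_coverage()] to materialize.
#' @param path Output SAM file.
#' @param read_length Sequencer read length; inserts are capped at it
#'   (default 150).
#' @param insert_range Insert-size bounds in nt (default `c(80, 140)`).
#' @param seed Seed for insert-size draws (default 1).
#' @return `path`, invisibly.
#' @export
simulate_alignments <- function(reference, cov, path, read_length = 150,
                                insert_range = c(80, 140), seed = 1) {
  stopifnot(inherits(cov, "stranded_coverage"),
            read_length >= insert_range[2])
  set.seed(seed)
  genome <- reference$genome
  stops <- cov$counts[rep(seq_len(.N), count)]
  n <- nrow(stops)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$lengths),
                      genome$lengths))
  if (n == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  w <- sample(insert_range[1]:insert_range[2], n, replace = TRUE)
  w <- pmin(w, read_length)
  len <- genome$lengths[stops$chrom]
  tplus <- stops$strand == "+"
  # transcript + => alignment -, spanning [stop, stop + w) clipped right
  # transcript - => alignment +, spanning [stop + 1 - w, stop + 1) clipped left
  astart <- ifelse(tplus, stops$pos, pmax(0L, stops$pos + 1L - w))
  aend <- ifelse(tplus, pmin(len, stops$pos + w), stops$pos + 1L)
  flag <- ifelse(tplus, 16L, 0L)
  width <- aend - astart
  seqs <- substring(genome$seq[stops$chrom], astart + 1L, aend)
  recs <- sprintf("r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                  seq_len(n), flag, stops$chrom, astart + 1L, width, seqs)
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Evaluate pseudouridine calls against simulation truth
#'
#' Exact matching on (chrom, psi_pos, strand).
#'
#' @param sites Called sites ([call_sites()]).
#' @param truth Truth table from [simulate_reference()].
#' @return List with `tp`, `fp`, `fn`, `sensitivity` (`tp / n_truth`),
#'   `precision` (`NA` when nothing was called), and `fdp`
#'   (`1 - precision`, `NA` when nothing was called).
#' @export
evaluate_calls <- function(sites, truth) {
  k <- c("chrom", "psi_pos", "strand")
  sites <- as.data.table(sites)
  truth <- as.data.table(truth)
  tp <- if (nrow(sites) == 0L || nrow(truth) == 0L) 0L else {
    sum(!is.na(truth[sites[, ..k], on = k, which = TRUE]))
  }
  n_called <- nrow(sites)
  n_truth <- nrow(truth)
  precision <- if (n_called > 0L) tp / n_called else NA_real_
  list(tp = tp, fp = n_called - tp, fn = n_truth - tp,
       sensitivity = if (n_truth > 0L) tp / n_truth else NA_real_,
       precision = precision,
       fdp = if (n_called > 0L) 1 - precision else NA_real_)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `truth.tsv` and per-sample
#' per-strand bedgraphs (`cmcplus.plus.bedgraph`, ...) into a directory, all
#' in standard formats readable by the pipeline entry points.
#'
#' @param reference Output of [simulate_reference()].
#' @param coverage Output of [simulate_coverage()].
#' @param dir Output directory (created if needed).
#' @return Named list of paths, invisibly.
#' @export
write_simulation <- function(reference, coverage, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$genome$seq), fa)
  gtf <- file.path(dir, "annotation.gtf")
  write_exons_gtf(reference$exons, gtf)
  truth <- file.path(dir, "truth.tsv")
  fwrite(reference$truth, truth, sep = "\t")
  bg_p <- write_stranded_bedgraph(coverage$cmc_plus, file.path(dir, "cmcplus"))
  bg_m <- write_stranded_bedgraph(coverage$cmc_minus, file.path(dir, "cmcminus"))
  invisible(list(genome = fa, annotation = gtf, truth = truth,
                 cmc_plus = bg_p, cmc_minus = bg_m))
}
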
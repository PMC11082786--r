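# High-confidence pseudouridine calling: combine CMC+ and CMC- peak tests,
# apply the strand-aware genomic-T rule, annotate gene regions, and write
# outputs. The end-to-end pipeline driver lives here too.

#' Pseudouridine position adjacent to an RT-stop
#'
#' Reverse transcription terminates one nucleotide before a CMC-adducted
#' pseudouridine, so the putative modified base sits immediately 5' of the
#' stop in mRNA orientation (equivalently, directly 3' of the stop in cDNA
#' orientation): `pos - 1` on the plus strand, `pos + 1` on the minus strand.
#'
#' @param pos 0-based RT-stop position(s).
#' @param strand Transcript-sense strand, `"+"` or `"-"`.
#' @return 0-based position(s) of the putative pseudouridine. May fall
#'   outside the chromosome for stops at its very edge; callers must check.
#' @export
psi_position <- function(pos, strand) {
  n <- max(length(pos), length(strand))
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ifelse(strand == "+", pos - 1L, pos + 1L)
}

#' Annotate the gene region of a position
#'
#' Region label of a position from overlapping annotation features, with
#' precedence `CDS > 5UTR > 3UTR > exon`; falls back to `"exon"` when only
#' plain exon features (or none of the labelled ones) overlap.
#'
#' @param exons Exon table from [load_exons()].
#' @param chrom,pos,strand Query position (0-based, transcript sense).
#' @param gene_id Optional gene restriction.
#' @return One of `"CDS"`, `"5UTR"`, `"3UTR"`, `"exon"`.
#' @export
annotate_region <- function(exons, chrom, pos, strand, gene_id = NULL) {
  exons <- as.data.table(exons)
  qc <- chrom; qs <- strand; qg <- gene_id
  hit <- exons[chrom == qc & strand == qs & start <= pos & pos < end]
  if (!is.null(qg)) hit <- hit[gene_id == qg]
  for (lab in c("CDS", "5UTR", "3UTR")) {
    if (any(hit$region == lab)) return(lab)
  }
  "exon"
}

#' Call high-confidence pseudouridine sites
#'
#' A site is emitted for every RT-stop peak that is (a) significant in the
#' CMC+ sample, (b) not significant in the CMC- sample at the same
#' (chrom, stop, strand) — absence of any CMC- peak there satisfies this, as
#' does a CMC- peak that never reached the read-count floor — and (c) whose
#' adjacent position in transcript sense ([psi_position()]) carries a genomic
#' `T` (an `N` base fails the check). Sites whose adjacent position falls off
#' the chromosome are skipped with a message.
#'
#' @param tests_plus,tests_minus Peak-test tables from [test_peaks()] for the
#'   CMC+ and CMC- samples, computed with identical settings.
#' @param genome A [load_genome()] genome.
#' @param exons Exon table (for region annotation).
#' @param slop Maximum distance (nt) at which a significant CMC- stop
#'   suppresses a CMC+ stop. Default 0: exact-coordinate matching, the
#'   method's single-nucleotide claim.
#' @param include_peak_in_height Whether the normalized-height denominator
#'   includes the peak's own count (default `TRUE`; see
#'   [normalized_peak_height()]).
#' @return `data.table` of class `psi_sites`: `chrom`, `psi_pos`, `strand`,
#'   `stop_pos`, `gene_id`, `region`, `count_plus`, `mu_plus`, `p_plus`,
#'   `q_plus`, `count_minus`, `p_minus`, `q_minus` (NA when the CMC- sample
#'   had no tested peak at the stop), `norm_height` (log2 peak height
#'   normalized to the window total in CMC+).
#' @export
call_sites <- function(tests_plus, tests_minus, genome, exons, slop = 0,
                       include_peak_in_height = TRUE) {
  tests_plus <- as.data.table(tests_plus)
  tests_minus <- as.data.table(tests_minus)
  empty <- data.table(
    chrom = character(), psi_pos = integer(), strand = character(),
    stop_pos = integer(), gene_id = character(), region = character(),
    count_plus = integer(), mu_plus = numeric(), p_plus = numeric(),
    q_plus = numeric(), count_minus = integer(), p_minus = numeric(),
    q_minus = numeric(), norm_height = numeric()
  )
  setattr(empty, "class", c("psi_sites", class(empty)))
  sig <- tests_plus[significant == TRUE]
  if (nrow(sig) == 0L) return(empty[])

  # (b) no significant CMC- stop within slop of the CMC+ stop
  msig <- tests_minus[significant == TRUE]
  if (nrow(msig) > 0L) {
    suppressed <- vapply(seq_len(nrow(sig)), function(i) {
      any(msig$chrom == sig$chrom[i] & msig$strand == sig$strand[i] &
            abs(msig$pos - sig$pos[i]) <= slop)
    }, logical(1))
    sig <- sig[!suppressed]
  }
  if (nrow(sig) == 0L) return(empty[])

  # (c) adjacent transcript-sense genomic base must be T and in bounds
  psi <- psi_position(sig$pos, sig$strand)
  len <- genome$lengths[sig$chrom]
  inb <- psi >= 0L & psi < len
  if (any(!inb)) {
    message("call_sites: skipped ", sum(!inb),
            " site(s) whose adjacent position falls outside the chromosome")
  }
  sig <- sig[inb]; psi <- psi[inb]
  if (nrow(sig) == 0L) return(empty[])
  is_t <- fetch_base(genome, sig$chrom, psi, sig$strand) == "T"
  sig <- sig[is_t]; psi <- psi[is_t]
  if (nrow(sig) == 0L) return(empty[])

  # attach CMC- statistics at the exact stop coordinate, when tested
  mm <- tests_minus[sig[, .(chrom, pos, strand)],
                    on = c("chrom", "pos", "strand")]
  region <- vapply(seq_len(nrow(sig)), function(i) {
    annotate_region(exons, sig$chrom[i], psi[i], sig$strand[i],
                    gene_id = sig$gene_id[i])
  }, character(1))
  out <- data.table(
    chrom = sig$chrom, psi_pos = as.integer(psi), strand = sig$strand,
    stop_pos = sig$pos, gene_id = sig$gene_id, region = region,
    count_plus = sig$count, mu_plus = sig$mu, p_plus = sig$p_value,
    q_plus = sig$q_value,
    count_minus = mm$count, p_minus = mm$p_value, q_minus = mm$q_value,
    norm_height = normalized_peak_height(sig$count, sig$window_total,
                                         include_peak = include_peak_in_height)
  )
  setorder(out, chrom, psi_pos, strand)
  setattr(out, "class", c("psi_sites", class(out)))
  out[]
}

#' Intersect pseudouridine calls from two replicates
#'
#' Set operations keyed on (chrom, psi_pos, strand); exact-coordinate
#' matching.
#'
#' @param sites_rep1,sites_rep2 Site tables from [call_sites()] built on the
#'   same reference.
#' @return List with `shared` (rows of replicate 1 also called in replicate
#'   2), `rep1_only`, `rep2_only`.
#' @export
intersect_replicates <- function(sites_rep1, sites_rep2) {
  k <- c("chrom", "psi_pos", "strand")
  s1 <- as.data.table(sites_rep1)
  s2 <- as.data.table(sites_rep2)
  in2 <- !is.na(s2[s1, on = k, which = TRUE])
  in1 <- !is.na(s1[s2, on = k, which = TRUE])
  list(shared = s1[in2], rep1_only = s1[!in2], rep2_only = s2[!in1])
}

#' Write pseudouridine calls as BED6 and TSV
#'
#' The BED interval is the single pseudouridine base; `name` is
#' `gene_id:region` and `score` is `min(1000, round(-10 log10(q_plus)))`
#' (1000 for q = 0). The TSV carries every column of the site table and can
#' be read back with [read_sites()].
#'
#' @param sites A `psi_sites` table.
#' @param bed_path,tsv_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_sites <- function(sites, bed_path, tsv_path) {
  sites <- as.data.table(sites)
  score <- ifelse(sites$q_plus <= 0, 1000L,
                  pmin(1000L, as.integer(round(-10 * log10(sites$q_plus)))))
  score <- pmax(0L, score)
  bed <- data.table(sites$chrom, sites$psi_pos, sites$psi_pos + 1L,
                    paste0(sites$gene_id, ":", sites$region), score,
                    sites$strand)
  if (!file.create(bed_path)) stop("cannot write ", bed_path)
  if (nrow(bed) > 0L) fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  fwrite(sites, tsv_path, sep = "\t", na = "NA", quote = FALSE)
  invisible(c(bed_path, tsv_path))
}

#' Read back a pseudouridine site TSV
#'
#' @param tsv_path File written by [write_sites()].
#' @return A `psi_sites` `data.table`.
#' @export
read_sites <- function(tsv_path) {
  out <- fread(tsv_path, sep = "\t", na.strings = "NA",
               colClasses = list(
                 character = c("chrom", "strand", "gene_id", "region"),
                 integer = c("psi_pos", "stop_pos", "count_plus",
                             "count_minus"),
                 double = c("mu_plus", "p_plus", "q_plus", "p_minus",
                            "q_minus", "norm_height")))
  setattr(out, "class", c("psi_sites", class(out)))
  out[]
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values that parse as numbers are converted; comma-separated values become
#' character vectors.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    if (grepl(",", val)) {
      val <- trimws(strsplit(val, ",")[[1]])
    }
    num <- suppressWarnings(as.numeric(val))
    if (length(val) == 1L && !is.na(num)) val <- num
    out[[key]] <- val
  }
  out
}

.load_coverage_input <- function(x, orientation, min_mapq, read_end) {
  if (length(x) == 2L) {
    read_stranded_bedgraph(x[[1]], x[[2]], orientation = orientation)
  } else if (grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
    coverage_from_bam(x, orientation = orientation, min_mapq = min_mapq,
                      read_end = read_end)
  } else {
    stop("coverage input must be one SAM/BAM file or a (plus, minus) ",
         "bedgraph pair: ", paste(x, collapse = ", "))
  }
}

#' Run the full pseudouridine-calling pipeline
#'
#' Loads the genome and annotation, builds stranded 3'-end coverage for the
#' CMC+ and CMC- samples (from SAM/BAM or from per-strand bedgraph pairs),
#' tests peaks per sample, calls sites, and writes `sites.tsv`, `sites.bed`,
#' and per-sample peak tables into `out_dir`. Deterministic given its inputs.
#' Inputs are validated before any computation; on failure, partial outputs
#' are removed.
#'
#' @param config Named list (or path to a key-value file parsed by
#'   [read_config()]) with entries: `genome`, `annotation`, `cmc_plus`,
#'   `cmc_minus` (each a SAM/BAM path or a length-2 vector of plus/minus
#'   bedgraphs), `out_dir`, and optional `annotation_format`, `min_reads`,
#'   `window_size`, `fdr`, `exclude_peak`, `orientation`, `min_mapq`,
#'   `read_end`, `slop`.
#' @return Invisibly, a list with `sites`, `tests_plus`, `tests_minus`, and
#'   output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  req <- c("genome", "annotation", "cmc_plus", "cmc_minus", "out_dir")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys) > 0L) {
    stop("config is missing required entries: ",
         paste(missing_keys, collapse = ", "))
  }
  paths_in <- c(config$genome, config$annotation,
                unlist(config$cmc_plus), unlist(config$cmc_minus))
  absent <- paths_in[!file.exists(paths_in)]
  if (length(absent) > 0L) {
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  getd <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  min_reads <- getd("min_reads", 10)
  window_size <- getd("window_size", 100)
  fdr <- getd("fdr", 0.05)
  exclude_peak <- isTRUE(as.logical(getd("exclude_peak", TRUE)))
  orientation <- getd("orientation", "antisense")
  min_mapq <- getd("min_mapq", 10)
  read_end <- getd("read_end", "3p")
  slop <- getd("slop", 0)
  fmt <- getd("annotation_format", "auto")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_paths <- file.path(config$out_dir,
                         c("sites.tsv", "sites.bed",
                           "peaks_cmc_plus.tsv", "peaks_cmc_minus.tsv"))
  ok <- FALSE
  on.exit(if (!ok) unlink(out_paths), add = TRUE)

  genome <- load_genome(config$genome)
  exons <- load_exons(config$annotation, format = fmt)
  cov_plus <- .load_coverage_input(config$cmc_plus, orientation, min_mapq, read_end)
  cov_minus <- .load_coverage_input(config$cmc_minus, orientation, min_mapq, read_end)
  tests_plus <- test_peaks(cov_plus, exons, min_reads = min_reads,
                           window_size = window_size, fdr_threshold = fdr,
                           exclude_peak = exclude_peak)
  tests_minus <- test_peaks(cov_minus, exons, min_reads = min_reads,
                            window_size = window_size, fdr_threshold = fdr,
                            exclude_peak = exclude_peak)
  sites <- call_sites(tests_plus, tests_minus, genome, exons, slop = slop)
  write_sites(sites, out_paths[2], out_paths[1])
  fwrite(tests_plus, out_paths[3], sep = "\t", na = "NA", quote = FALSE)
  fwrite(tests_minus, out_paths[4], sep = "\t", na = "NA", quote = FALSE)
  ok <- TRUE
  invisible(list(sites = sites, tests_plus = tests_plus,
                 tests_minus = tests_minus, paths = out_paths))
}
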
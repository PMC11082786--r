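# Stranded single-base 3'-end (RT-stop) coverage: extraction from alignments,
# accumulation, and bedgraph I/O. Coverage is sparse: only positions with at
# least one stop are stored.

#' Construct a stranded coverage object
#'
#' @param counts A `data.frame`/`data.table` with columns `chrom`, `strand`
#'   (`+`/`-`, transcript sense), `pos` (0-based), `count` (positive integer).
#'   Duplicate positions are summed; zero counts are dropped.
#' @param orientation How alignment strand was mapped to transcript strand
#'   when the coverage was built (`"antisense"` or `"sense"`); recorded for
#'   provenance.
#' @return An object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(counts, orientation = "antisense") {
  counts <- as.data.table(counts)
  need <- c("chrom", "strand", "pos", "count")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  counts <- counts[, .(chrom = as.character(chrom),
                       strand = as.character(strand),
                       pos = as.integer(pos),
                       count = as.integer(count))]
  if (!all(counts$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(counts$count < 0L)) stop("counts must be non-negative")
  counts <- counts[count > 0L, .(count = sum(count)), by = .(chrom, strand, pos)]
  setkey(counts, chrom, strand, pos)
  structure(list(counts = counts[], orientation = orientation),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat("stranded_coverage:", nrow(x$counts), "position(s),",
      sum(x$counts$count), "3'-end read(s); orientation =",
      x$orientation, "\n")
  invisible(x)
}

#' Total number of 3'-end reads in a coverage
#'
#' @param cov A `stranded_coverage`.
#' @return Integer total count (conserved: equals the number of alignments
#'   that contributed).
#' @export
coverage_total <- function(cov) {
  stopifnot(inherits(cov, "stranded_coverage"))
  sum(cov$counts$count)
}

#' Per-position counts with zeros filled in
#'
#' @param cov A `stranded_coverage`.
#' @param chrom,strand Scalars identifying one chromosome strand.
#' @param pos Integer vector of 0-based positions.
#' @return Integer vector of counts (0 where no stop was recorded).
#' @export
coverage_at <- function(cov, chrom, strand, pos) {
  stopifnot(inherits(cov, "stranded_coverage"))
  q <- data.table(chrom = chrom, strand = strand, pos = as.integer(pos))
  res <- cov$counts[q, on = c("chrom", "strand", "pos")]
  out <- res$count
  out[is.na(out)] <- 0L
  out
}

#' RT-stop coordinate of aligned reads
#'
#' The RT stop is the 3'-terminal aligned base of the (cDNA-sense) read in
#' genomic coordinates: the highest aligned position for a plus-strand
#' alignment, the lowest for a minus-strand alignment. Soft-clipped bases and
#' splice gaps do not move the endpoint (inputs are aligned reference spans).
#' Under the default `antisense` orientation the reported strand is the
#' opposite of the alignment strand, because the sequenced read is
#' cDNA-sense and the template mRNA is its reverse complement; under `sense`
#' the strands agree. A `read_end = "5p"` escape hatch supports protocols in
#' which the 5' end of the read marks the stop.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 0-based half-open aligned reference span of each read
#'   (soft clips excluded).
#' @param aln_strand Alignment strand, `"+"` or `"-"`.
#' @param orientation `"antisense"` (default) or `"sense"`.
#' @param read_end Which read end marks the RT stop: `"3p"` (default) or
#'   `"5p"`.
#' @return A `data.table` with columns `chrom`, `pos` (0-based stop
#'   coordinate), `strand` (transcript sense).
#' @export
#' @examples
#' rt_stop_coordinate("chr1", 100, 120, "+")   # stop at 119 on "-"
#' rt_stop_coordinate("chr1", 100, 120, "-")   # stop at 100 on "+"
rt_stop_coordinate <- function(chrom, start, end, aln_strand,
                               orientation = c("antisense", "sense"),
                               read_end = c("3p", "5p")) {
  orientation <- match.arg(orientation)
  read_end <- match.arg(read_end)
  n <- max(length(chrom), length(start), length(end), length(aln_strand))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  aln_strand <- rep_len(as.character(aln_strand), n)
  if (!all(aln_strand %in% c("+", "-"))) stop("alignment strand must be '+' or '-'")
  if (any(end <= start)) stop("alignment spans must satisfy start < end")
  plus <- aln_strand == "+"
  pos <- if (read_end == "3p") {
    ifelse(plus, end - 1L, start)
  } else {
    ifelse(plus, start, end - 1L)
  }
  strand <- if (orientation == "antisense") {
    ifelse(plus, "-", "+")
  } else {
    aln_strand
  }
  data.table(chrom = chrom, pos = as.integer(pos), strand = strand)
}

#' Accumulate stranded 3'-end coverage from alignment spans
#'
#' @param alignments A `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open aligned span) and `aln_strand`.
#' @inheritParams rt_stop_coordinate
#' @return A [stranded_coverage()] whose total equals `nrow(alignments)`.
#' @export
accumulate_coverage <- function(alignments, orientation = c("antisense", "sense"),
                                read_end = c("3p", "5p")) {
  orientation <- match.arg(orientation)
  read_end <- match.arg(read_end)
  alignments <- as.data.table(alignments)
  if (nrow(alignments) == 0L) {
    return(stranded_coverage(
      data.table(chrom = character(), strand = character(),
                 pos = integer(), count = integer()),
      orientation = orientation))
  }
  stops <- rt_stop_coordinate(alignments$chrom, alignments$start,
                              alignments$end, alignments$aln_strand,
                              orientation = orientation, read_end = read_end)
  stranded_coverage(stops[, .(count = .N), by = .(chrom, strand, pos)],
                    orientation = orientation)
}

#' Build stranded 3'-end coverage from a SAM/BAM file
#'
#' Reads alignments (converting SAM to BAM on the fly), skips unmapped,
#' secondary, supplementary and duplicate-flagged records as well as records
#' below the mapping-quality floor, and accumulates RT-stop coverage. Skipped
#' record counts are reported with `message()`. Inputs are assumed already
#' UMI-deduplicated and aligned; trimming/dedup/alignment are upstream of
#' this tool.
#'
#' @param path SAM or BAM file.
#' @param min_mapq Mapping-quality floor (default 10); records with missing
#'   MAPQ (255) are kept.
#' @inheritParams rt_stop_coordinate
#' @return A [stranded_coverage()].
#' @export
coverage_from_bam <- function(path, orientation = c("antisense", "sense"),
                              min_mapq = 10, read_end = c("3p", "5p")) {
  orientation <- match.arg(orientation)
  read_end <- match.arg(read_end)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("flag", "mapq")))
  fl <- S4Vectors::mcols(gal)$flag
  mq <- S4Vectors::mcols(gal)$mapq
  sec <- bitwAnd(fl, 256L) > 0L
  supp <- bitwAnd(fl, 2048L) > 0L
  dup <- bitwAnd(fl, 1024L) > 0L
  lowq <- !is.na(mq) & mq != 255L & mq < min_mapq
  keep <- !(sec | supp | dup | lowq)
  message(sprintf(
    "coverage_from_bam: %d mapped record(s); skipped %d secondary, %d supplementary, %d duplicate, %d below MAPQ %d; kept %d",
    length(gal), sum(sec), sum(supp), sum(dup), sum(lowq & !(sec | supp | dup)),
    as.integer(min_mapq), sum(keep)))
  gal <- gal[keep]
  aln <- data.table(
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    start = GenomicAlignments::start(gal) - 1L,
    end = GenomicAlignments::end(gal),
    aln_strand = as.character(GenomicAlignments::strand(gal))
  )
  accumulate_coverage(aln, orientation = orientation, read_end = read_end)
}

#' Write per-strand single-base bedgraphs
#'
#' One bedgraph per strand (a separate file for each strand of each sample),
#' with every non-zero position emitted as a 1-bp interval
#' `chrom<TAB>pos<TAB>pos+1<TAB>count`, sorted by chromosome then position.
#' Strand here means transcript sense.
#'
#' @param cov A `stranded_coverage`.
#' @param prefix Output path prefix; files are `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph`.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_stranded_bedgraph <- function(cov, prefix) {
  stopifnot(inherits(cov, "stranded_coverage"))
  paths <- c(paste0(prefix, ".plus.bedgraph"), paste0(prefix, ".minus.bedgraph"))
  for (i in 1:2) {
    s <- c("+", "-")[i]
    dt <- cov$counts[strand == s, .(chrom, start = pos, end = pos + 1L, count)]
    setorder(dt, chrom, start)
    if (!file.create(paths[i])) stop("cannot write ", paths[i])
    if (nrow(dt) > 0L) {
      fwrite(dt, paths[i], sep = "\t", col.names = FALSE)
    }
  }
  invisible(paths)
}

.parse_bedgraph <- function(path, strand_label) {
  if (!file.exists(path)) stop("bedgraph not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), count = integer()))
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    stop(path, ": malformed bedgraph line ", idx[which(nf != 4L)[1]],
         " (expected 4 columns)")
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  intlike <- function(x) grepl("^[0-9]+$", x)
  bad <- !(intlike(m[, 2]) & intlike(m[, 3]) & intlike(m[, 4]))
  if (any(bad)) {
    stop(path, ": malformed bedgraph line ", idx[which(bad)[1]],
         " (start/end/count must be non-negative integers)")
  }
  dt <- data.table(chrom = m[, 1], start = as.integer(m[, 2]),
                   end = as.integer(m[, 3]), count = as.integer(m[, 4]),
                   line_no = idx)
  if (any(dt$start >= dt$end)) {
    stop(path, ": malformed bedgraph line ",
         dt$line_no[which(dt$start >= dt$end)[1]], " (start must be < end)")
  }
  dt <- dt[count > 0L]
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), count = integer()))
  }
  # expand multi-base intervals to single positions; overlaps sum
  expanded <- dt[, .(pos = start:(end - 1L), count = count),
                 by = .(line_no, chrom)]
  expanded[, .(count = sum(count), strand = strand_label), by = .(chrom, pos)]
}

#' Read per-strand bedgraphs into a stranded coverage
#'
#' Entry point for coverage produced by external tools. Intervals wider than
#' one base expand to per-base counts; overlapping intervals sum.
#'
#' @param plus,minus Bedgraph files for the transcript-sense plus and minus
#'   strands.
#' @param orientation Recorded provenance tag (see [stranded_coverage()]).
#' @return A [stranded_coverage()].
#' @export
read_stranded_bedgraph <- function(plus, minus, orientation = "antisense") {
  dt <- rbind(.parse_bedgraph(plus, "+"), .parse_bedgraph(minus, "-"))
  stranded_coverage(dt[, .(chrom, strand, pos, count)],
                    orientation = orientation)
}
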
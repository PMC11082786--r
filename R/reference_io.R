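# Genome and exon-annotation input. All internal coordinates are 0-based
# half-open; conversion to/from the 1-based closed conventions of FASTA
# indexing and GTF happens only at file boundaries.

#' Load a genome from FASTA
#'
#' Reads a (possibly multi-line) FASTA file into an in-memory genome object.
#' Sequences are uppercased, `U` is converted to `T`, and IUPAC ambiguity
#' codes are collapsed to `N`; any other character is an error. Record names
#' are truncated at the first whitespace and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `psi_genome`: a list with `seq` (named character
#'   vector of chromosome sequences) and `lengths` (named integer vector).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' g <- load_genome(fa)
#' fetch_base(g, "chr1", 3, "+")
load_genome <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop("FASTA file contains no sequences: ", path)
  }
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  s <- toupper(as.character(seqs))
  # U -> T, ambiguity codes -> N
  s <- chartr("URYSWKMBDHV", "TNNNNNNNNNN", s)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    stop("sequence(s) contain characters outside the DNA alphabet: ",
         paste(nm[bad], collapse = ", "))
  }
  names(s) <- nm
  structure(list(seq = s, lengths = stats::setNames(nchar(s), nm)),
            class = "psi_genome")
}

#' @export
print.psi_genome <- function(x, ...) {
  cat("psi_genome with", length(x$seq), "sequence(s);",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `psi_genome`.
#' @return Named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  stopifnot(inherits(genome, "psi_genome"))
  genome$lengths
}

COMPLEMENT_FROM <- "ACGTN"
COMPLEMENT_TO <- "TGCAN"

#' Fetch the transcript-sense base at a genomic position
#'
#' Returns the genome base at `pos` for `strand == "+"`, and its complement
#' for `strand == "-"` (i.e. the base as read in the sense of a minus-strand
#' transcript). Vectorized over `pos` (and over `chrom`/`strand` of matching
#' length).
#'
#' @param genome A `psi_genome`.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s); must lie within the chromosome.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of single bases in `{A,C,G,T,N}`.
#' @export
fetch_base <- function(genome, chrom, pos, strand = "+") {
  stopifnot(inherits(genome, "psi_genome"))
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  unknown <- !(chrom %in% names(genome$seq))
  if (any(unknown)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[unknown]), collapse = ", "))
  }
  len <- genome$lengths[chrom]
  if (any(pos < 0 | pos >= len)) {
    stop("position out of range for chromosome (0-based, must be in [0, length))")
  }
  base <- substring(genome$seq[chrom], pos + 1L, pos + 1L)
  minus <- strand == "-"
  if (any(minus)) base[minus] <- chartr(COMPLEMENT_FROM, COMPLEMENT_TO, base[minus])
  unname(base)
}

#' Fetch a transcript-sense sequence context around a position
#'
#' Extracts `up` bases 5' and `down` bases 3' of `pos` in transcript
#' orientation (total length `up + 1 + down`, the anchored base included).
#' For minus-strand sites the genomic segment is reverse-complemented.
#'
#' @inheritParams fetch_base
#' @param up,down Number of flanking bases 5' / 3' of `pos` (transcript sense).
#' @return A character string, or `NA_character_` when the context would run
#'   off either end of the chromosome.
#' @export
fetch_context <- function(genome, chrom, pos, strand, up, down) {
  stopifnot(inherits(genome, "psi_genome"), up >= 0, down >= 0)
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (strand == "+") {
    lo <- pos - up
    hi <- pos + down
  } else if (strand == "-") {
    lo <- pos - down
    hi <- pos + up
  } else {
    stop("strand must be '+' or '-'")
  }
  if (lo < 0 || hi >= len) return(NA_character_)
  ctx <- substring(genome$seq[[chrom]], lo + 1L, hi + 1L)
  if (strand == "-") ctx <- revcomp(ctx)
  ctx
}

#' Reverse complement of a DNA string
#'
#' IUPAC-aware, pure-character helper used for transcript-sense context
#' extraction on the minus strand.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNRYSWKMBDHVacgtn", "TGCANYRSWMKVHDBtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

REGION_LEVELS <- c("CDS", "5UTR", "3UTR", "exon")

# map GTF/GFF feature types to region labels; anything else is dropped
.gtf_region_map <- c(
  exon = "exon", CDS = "CDS",
  five_prime_utr = "5UTR", five_prime_UTR = "5UTR", `5UTR` = "5UTR",
  three_prime_utr = "3UTR", three_prime_UTR = "3UTR", `3UTR` = "3UTR"
)

#' Load exon intervals from GTF/GFF or BED
#'
#' Parses an annotation into a flat exon table in internal 0-based half-open
#' coordinates. GTF/GFF feature types `exon`, `CDS`, `five_prime_utr` and
#' `three_prime_utr` are kept and mapped to region labels `exon`, `CDS`,
#' `5UTR`, `3UTR`; other features are ignored. BED intervals are labelled
#' `exon` and the BED name column supplies `gene_id`. Identical
#' (chrom, start, end, strand, gene_id, region) tuples arising from multiple
#' transcripts are deduplicated. A missing strand (`.`) is an error: the
#' method is strand-specific throughout.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gtf"` (also GFF) or `"bed"`.
#' @return A `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `region`.
#' @export
load_exons <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
      gtf = "gtf", gff = "gtf", gff3 = "gtf", gff2 = "gtf",
      bed = "bed",
      stop("cannot guess annotation format from extension '.", ext,
           "'; pass format = 'gtf' or 'bed'")
    )
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    type <- as.character(gr$type)
    keep <- type %in% names(.gtf_region_map)
    gr <- gr[keep]
    if (length(gr) == 0L) stop("no exon/CDS/UTR features found in ", path)
    region <- unname(.gtf_region_map[as.character(gr$type)])
    gid <- gr$gene_id
    if (is.null(gid)) stop("GTF features lack a gene_id attribute: ", path)
    dt <- data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = as.character(gid),
      region = region
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) stop("no intervals found in ", path)
    nm <- gr$name
    if (is.null(nm) || anyNA(nm)) {
      stop("BED annotation requires a name column (used as gene_id): ", path)
    }
    dt <- data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = as.character(nm),
      region = "exon"
    )
  }
  if (any(dt$strand == "*")) {
    stop("annotation contains features without strand; ",
         "strand is required for RT-stop analysis")
  }
  if (any(dt$start >= dt$end)) {
    stop("annotation contains empty or inverted interval(s) after ",
         "coordinate conversion")
  }
  dt <- unique(dt)
  setkey(dt, chrom, start, end)
  dt[]
}

#' Write an exon table as GTF
#'
#' Inverse of [load_exons()] for the GTF dialect; used by the simulator and
#' for round-trip checks. Region labels map back to GTF feature types.
#'
#' @param exons Exon `data.table` as returned by [load_exons()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_exons_gtf <- function(exons, path) {
  feat <- c(exon = "exon", CDS = "CDS",
            `5UTR` = "five_prime_utr", `3UTR` = "three_prime_utr")[exons$region]
  lines <- sprintf(
    "%s\tpsiseq\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    exons$chrom, feat, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}
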
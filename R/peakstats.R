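# Strong-stop peak identification and the Poisson background test.
#
# A putative RT-stop peak is any position with >= min_reads 3'-end reads.
# Each peak is assigned to a containing exon, a window of up to window_size
# nucleotides centred on the peak is clipped to that exon, the per-nucleotide
# 3'-end depths in the window are fitted with a Poisson distribution
# (MLE: the sample mean), and the peak count is tested against the upper
# tail of that null. Benjamini-Hochberg adjustment is applied across all
# tested peaks of a sample.

#' Find putative RT-stop peaks
#'
#' Positions whose 3'-end read count reaches `min_reads` (inclusive), per
#' strand, in deterministic (chrom, pos, strand) order. The read-count floor
#' removes stops generated by random reverse-transcriptase termination.
#'
#' @param cov A [stranded_coverage()].
#' @param min_reads Minimum 3'-end reads at a position (default 10).
#' @return `data.table` with columns `chrom`, `pos`, `strand`, `count`.
#' @export
find_peaks <- function(cov, min_reads = 10) {
  stopifnot(inherits(cov, "stranded_coverage"))
  if (min_reads < 1) stop("min_reads must be >= 1")
  peaks <- cov$counts[count >= min_reads, .(chrom, pos, strand, count)]
  setorder(peaks, chrom, pos, strand)
  peaks[]
}

#' Assign peaks to exons
#'
#' Each peak is paired with a strand-matched exon interval containing it.
#' Peaks contained in no exon are dropped. When several intervals contain a
#' peak the longest is chosen; remaining ties go to the lexicographically
#' smallest `gene_id`, then the smallest start.
#'
#' @param peaks Peak table from [find_peaks()].
#' @param exons Exon table from [load_exons()].
#' @return The peak table with `gene_id`, `exon_start`, `exon_end` appended;
#'   unassigned peaks removed.
#' @export
assign_peaks_to_exons <- function(peaks, exons) {
  peaks <- as.data.table(peaks)
  exons <- as.data.table(exons)
  empty <- peaks[0][, `:=`(gene_id = character(), exon_start = integer(),
                           exon_end = integer())]
  if (nrow(peaks) == 0L || nrow(exons) == 0L) return(empty[])
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$pos + 1L, width = 1L),
                                strand = peaks$strand)
  egr <- GenomicRanges::GRanges(exons$chrom,
                                IRanges::IRanges(exons$start + 1L, exons$end),
                                strand = exons$strand)
  ov <- GenomicRanges::findOverlaps(pgr, egr, ignore.strand = FALSE)
  if (length(ov) == 0L) return(empty[])
  hits <- data.table(
    pi = S4Vectors::queryHits(ov),
    gene_id = exons$gene_id[S4Vectors::subjectHits(ov)],
    exon_start = exons$start[S4Vectors::subjectHits(ov)],
    exon_end = exons$end[S4Vectors::subjectHits(ov)]
  )
  hits[, exon_len := exon_end - exon_start]
  setorder(hits, pi, -exon_len, gene_id, exon_start)
  hits <- hits[!duplicated(pi)]
  out <- cbind(peaks[hits$pi],
               hits[, .(gene_id, exon_start, exon_end)])
  setorder(out, chrom, pos, strand)
  out[]
}

#' Exon-clipped background window around a peak
#'
#' The nominal window is `window_size` nucleotides with the peak at the
#' centre (for even sizes the left flank gets the extra base: size 100 spans
#' `[pos - 50, pos + 50)`). It is then clipped to the assigned exon so that
#' read-depleted intronic sequence never enters the background sample; clipped
#' windows may be shorter than `window_size`. Per-nucleotide depths over the
#' clipped interval are taken from the coverage, with zeros for uncovered
#' bases.
#'
#' @param cov A [stranded_coverage()].
#' @param chrom,pos,strand Peak coordinate (0-based, transcript sense).
#' @param exon_start,exon_end Assigned exon (0-based half-open).
#' @param window_size Nominal window length in nucleotides (default 100).
#' @return List with `start`, `end` (0-based half-open window), `depths`
#'   (integer vector over `[start, end)`), and `peak_offset` (0-based index
#'   of the peak within `depths`).
#' @export
build_window <- function(cov, chrom, pos, strand, exon_start, exon_end,
                         window_size = 100) {
  if (pos < exon_start || pos >= exon_end) {
    stop("peak position must lie within its assigned exon")
  }
  left <- window_size %/% 2L
  w_start <- max(exon_start, pos - left)
  w_end <- min(exon_end, pos + (window_size - left))
  depths <- coverage_at(cov, chrom, strand, w_start:(w_end - 1L))
  list(start = as.integer(w_start), end = as.integer(w_end),
       depths = depths, peak_offset = as.integer(pos - w_start))
}

#' Poisson maximum-likelihood fit of the window background
#'
#' The Poisson MLE of the mean is the arithmetic mean of the per-nucleotide
#' depths. By default the depth at the peak position is excluded from the
#' background sample so the signal does not inflate its own null.
#'
#' @param depths Integer vector of per-nucleotide 3'-end depths.
#' @param peak_offset 0-based index of the peak within `depths` (required
#'   when `exclude_peak` is `TRUE`).
#' @param exclude_peak Whether to drop the peak position from the background
#'   sample (default `TRUE`).
#' @return The fitted mean `mu` (>= 0).
#' @export
fit_poisson_mu <- function(depths, peak_offset = NULL, exclude_peak = TRUE) {
  if (any(depths < 0)) stop("depths must be non-negative")
  bg <- depths
  if (isTRUE(exclude_peak)) {
    if (is.null(peak_offset)) stop("peak_offset required when exclude_peak = TRUE")
    if (peak_offset < 0L || peak_offset >= length(depths)) {
      stop("peak_offset outside the window")
    }
    bg <- depths[-(peak_offset + 1L)]
  }
  if (length(bg) == 0L) {
    stop("no background positions remain in the window; widen the window or skip the peak")
  }
  mean(bg)
}

#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(mu)`, computed via the survival function at
#' `k - 1` for numerical stability. The degenerate null `mu = 0` gives 1 for
#' `k = 0` and 0 for `k > 0`.
#'
#' @param k Observed count(s), non-negative integer.
#' @param mu Poisson mean(s), non-negative.
#' @return Upper-tail probability in `[0, 1]`, vectorized.
#' @export
poisson_upper_tail <- function(k, mu) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  if (any(mu < 0)) stop("mu must be non-negative")
  stats::ppois(k - 1, lambda = mu, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m p_(j) / j)` capped at 1,
#' mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Test all putative peaks of a sample against the Poisson background
#'
#' Full per-sample pipeline: peak filtering, exon assignment, exon-clipped
#' window construction, Poisson MLE background fit, upper-tail test, and
#' Benjamini-Hochberg adjustment across all tested peaks of the sample.
#' A peak is flagged significant when its q-value is at or below
#' `fdr_threshold`. Peaks whose window leaves no background position are
#' skipped and reported via `message()`.
#'
#' @param cov A [stranded_coverage()].
#' @param exons Exon table from [load_exons()].
#' @param min_reads Peak read-count floor (default 10).
#' @param window_size Background window size (default 100).
#' @param fdr_threshold BH q-value threshold for significance (default 0.05).
#' @param exclude_peak Drop the peak position from the background fit
#'   (default `TRUE`).
#' @return `data.table` with one row per tested peak: `chrom`, `pos`,
#'   `strand`, `count`, `gene_id`, `exon_start`, `exon_end`, `window_start`,
#'   `window_end`, `window_total` (3'-end reads in the window, peak
#'   included), `mu`, `p_value`, `q_value`, `significant`.
#' @export
test_peaks <- function(cov, exons, min_reads = 10, window_size = 100,
                       fdr_threshold = 0.05, exclude_peak = TRUE) {
  peaks <- assign_peaks_to_exons(find_peaks(cov, min_reads), exons)
  empty <- data.table(
    chrom = character(), pos = integer(), strand = character(),
    count = integer(), gene_id = character(), exon_start = integer(),
    exon_end = integer(), window_start = integer(), window_end = integer(),
    window_total = integer(), mu = numeric(), p_value = numeric(),
    q_value = numeric(), significant = logical()
  )
  if (nrow(peaks) == 0L) return(empty)
  n <- nrow(peaks)
  w_start <- integer(n); w_end <- integer(n); w_total <- integer(n)
  mu_hat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- build_window(cov, peaks$chrom[i], peaks$pos[i], peaks$strand[i],
                      peaks$exon_start[i], peaks$exon_end[i],
                      window_size = window_size)
    w_start[i] <- w$start; w_end[i] <- w$end
    w_total[i] <- sum(w$depths)
    mu_hat[i] <- tryCatch(
      fit_poisson_mu(w$depths, w$peak_offset, exclude_peak = exclude_peak),
      error = function(e) NA_real_)
  }
  skipped <- is.na(mu_hat)
  if (any(skipped)) {
    message("test_peaks: skipped ", sum(skipped),
            " peak(s) with no background positions in their window")
  }
  out <- peaks[!skipped]
  out[, `:=`(window_start = w_start[!skipped], window_end = w_end[!skipped],
             window_total = w_total[!skipped], mu = mu_hat[!skipped])]
  if (nrow(out) == 0L) return(empty)
  out[, p_value := poisson_upper_tail(count, mu)]
  out[, q_value := bh_adjust(p_value)]
  out[, significant := q_value <= fdr_threshold]
  setorder(out, chrom, pos, strand)
  out[]
}
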
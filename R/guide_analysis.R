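# Validation-style analytics: normalized peak heights compared between
# samples, and scanning called sites for matches to a guide-RNA target
# sequence with contiguous-match counting.

#' Normalized peak height
#'
#' log2 of the peak's 3'-end count divided by the total 3'-end reads within
#' its surrounding window. By default the denominator includes the peak's own
#' count (the window contains the peak), so the ratio is at most 1 and the
#' log2 value at most 0; a flag excludes it.
#'
#' @param count Peak 3'-end read count(s).
#' @param window_total Total 3'-end reads in the window (peak included).
#' @param include_peak Keep the peak's count in the denominator (default
#'   `TRUE`).
#' @return log2 ratio(s); `NA` when the denominator is not positive.
#' @export
#' @examples
#' normalized_peak_height(16, 64)   # -2
normalized_peak_height <- function(count, window_total, include_peak = TRUE) {
  denom <- if (include_peak) window_total else window_total - count
  out <- ifelse(denom > 0 & count > 0, log2(count / denom), NA_real_)
  out
}

#' Compare normalized peak heights between two samples
#'
#' Joins two peak-measurement tables on (chrom, pos, strand), computes the
#' normalized height in each, and reports the squared Pearson correlation of
#' the log2 values over pairs where both heights are finite.
#'
#' @param tests_a,tests_b Tables with columns `chrom`, `pos`, `strand`,
#'   `count`, `window_total` — e.g. from [test_peaks()] or
#'   [measure_peak_heights()] (which re-measures a shared coordinate union in
#'   both coverages).
#' @param include_peak Passed to [normalized_peak_height()].
#' @return List with `pairs` (`data.table` of coordinates and both heights),
#'   `r_squared` (NA with fewer than 3 pairs), and `n`.
#' @export
compare_samples <- function(tests_a, tests_b, include_peak = TRUE) {
  a <- as.data.table(tests_a)[, .(chrom, pos, strand, count, window_total)]
  b <- as.data.table(tests_b)[, .(chrom, pos, strand, count, window_total)]
  m <- merge(a, b, by = c("chrom", "pos", "strand"), suffixes = c("_a", "_b"))
  m[, height_a := normalized_peak_height(count_a, window_total_a,
                                         include_peak = include_peak)]
  m[, height_b := normalized_peak_height(count_b, window_total_b,
                                         include_peak = include_peak)]
  pairs <- m[is.finite(height_a) & is.finite(height_b),
             .(chrom, pos, strand, height_a, height_b)]
  r2 <- if (nrow(pairs) >= 3L) stats::cor(pairs$height_a, pairs$height_b)^2
        else NA_real_
  list(pairs = pairs[], r_squared = r2, n = nrow(pairs))
}

#' Re-measure peak heights at fixed coordinates
#'
#' Measures the 3'-end count and window total of a given set of peak
#' coordinates in one coverage, regardless of whether the position reaches
#' the peak-calling floor there. Used to compare the same coordinate union
#' across samples.
#'
#' @param cov A [stranded_coverage()].
#' @param coords Table with `chrom`, `pos`, `strand`.
#' @param exons Exon table ([load_exons()]); coordinates in no exon are
#'   dropped.
#' @param window_size Window size (default 100).
#' @return `data.table` with `chrom`, `pos`, `strand`, `count`,
#'   `window_total`.
#' @export
measure_peak_heights <- function(cov, coords, exons, window_size = 100) {
  coords <- unique(as.data.table(coords)[, .(chrom, pos, strand)])
  coords[, count := coverage_at(cov, chrom[1], strand[1], pos),
         by = .(chrom, strand)]
  assigned <- assign_peaks_to_exons(coords, exons)
  n <- nrow(assigned)
  w_total <- integer(n)
  for (i in seq_len(n)) {
    w <- build_window(cov, assigned$chrom[i], assigned$pos[i],
                      assigned$strand[i], assigned$exon_start[i],
                      assigned$exon_end[i], window_size = window_size)
    w_total[i] <- sum(w$depths)
  }
  assigned[, window_total := w_total]
  assigned[, .(chrom, pos, strand, count, window_total)]
}

#' Compare two coverages over the union of their peaks
#'
#' Convenience wrapper: finds peaks in each coverage, re-measures the
#' coordinate union in both ([measure_peak_heights()]), and compares
#' normalized heights ([compare_samples()]).
#'
#' @param cov_a,cov_b Two [stranded_coverage()] objects on the same reference.
#' @param exons Exon table.
#' @param min_reads Peak floor used in each sample (default 10).
#' @param window_size Window size (default 100).
#' @param include_peak Passed to [normalized_peak_height()].
#' @return As [compare_samples()].
#' @export
compare_coverages <- function(cov_a, cov_b, exons, min_reads = 10,
                              window_size = 100, include_peak = TRUE) {
  u <- unique(rbind(find_peaks(cov_a, min_reads)[, .(chrom, pos, strand)],
                    find_peaks(cov_b, min_reads)[, .(chrom, pos, strand)]))
  ma <- measure_peak_heights(cov_a, u, exons, window_size = window_size)
  mb <- measure_peak_heights(cov_b, u, exons, window_size = window_size)
  compare_samples(ma, mb, include_peak = include_peak)
}

# per-position comparison of a context against a guide, IUPAC-aware.
# Returns "match", "mismatch" or "skip" per guide position; the anchored
# pseudouridine position and N positions are "skip" (uncounted, not
# run-breaking).
guide_match_mask <- function(context, guide, anchor) {
  if (nchar(context) != nchar(guide)) {
    stop("context and guide must have equal length")
  }
  L <- nchar(guide)
  if (anchor < 1L || anchor > L) stop("anchor must lie within the guide")
  gch <- strsplit(toupper(guide), "", fixed = TRUE)[[1]]
  cch <- strsplit(toupper(context), "", fixed = TRUE)[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  out <- character(L)
  for (i in seq_len(L)) {
    if (i == anchor || gch[i] == "N") {
      out[i] <- "skip"
      next
    }
    if (!gch[i] %in% names(map)) stop("invalid guide base: ", gch[i])
    allowed <- strsplit(map[[gch[i]]], "", fixed = TRUE)[[1]]
    out[i] <- if (cch[i] %in% allowed) "match" else "mismatch"
  }
  out
}

#' Longest contiguous guide match
#'
#' Longest run of consecutive guide positions whose context base matches
#' (IUPAC-aware). The anchored pseudouridine position and `N` positions of
#' the guide are not counted and do not break a run — a run may bridge the
#' unpaired pseudouridine-N dinucleotide of the target core.
#'
#' @param context Transcript-sense nucleotide string, same length as the
#'   guide, with the putative pseudouridine aligned to `anchor`.
#' @param guide IUPAC target sequence; the base at `anchor` stands for the
#'   pseudouridine (conventionally written `T`) and is ignored.
#' @param anchor 1-based pseudouridine position within the guide.
#' @return Integer: number of matching nucleotides in the longest run,
#'   uncounted positions excluded.
#' @export
#' @examples
#' contiguous_guide_matches("ACCTAGA", "ACCTNGA", anchor = 4)  # 5
contiguous_guide_matches <- function(context, guide, anchor) {
  mask <- guide_match_mask(context, guide, anchor)
  run <- 0L; best <- 0L
  for (m in mask) {
    if (m == "skip") next
    if (m == "match") {
      run <- run + 1L
      if (run > best) best <- run
    } else {
      run <- 0L
    }
  }
  best
}

#' Scan pseudouridine sites for guide-RNA target matches
#'
#' Extracts the transcript-sense context around each called site, keeps
#' sites matching a minimal core (default `ACCTNGA` with the pseudouridine
#' at position 4, i.e. the ACC-psi-NGA core), and scores retained sites
#' against the full guide target sequence with
#' [contiguous_guide_matches()]. Sites whose context would extend past a
#' chromosome end are skipped with a message. In `context_display`, matched
#' guide positions are uppercase, mismatches lowercase, and the
#' pseudouridine position uppercase `T`.
#'
#' @param sites A `psi_sites` table from [call_sites()].
#' @param genome A [load_genome()] genome.
#' @param guide Full guide target sequence (IUPAC), pseudouridine at
#'   `anchor`. The full target of a given guide RNA must be supplied by the
#'   user.
#' @param anchor 1-based pseudouridine index within `guide`.
#' @param core Minimal core pattern (default `"ACCTNGA"`).
#' @param core_anchor Pseudouridine index within `core` (default 4).
#' @param min_contig Keep only sites with at least this many contiguous
#'   matches (default 0 = keep every core match).
#' @return `data.table`: site columns plus `context`, `context_display`,
#'   `contiguous_matches`, sorted by decreasing `contiguous_matches`.
#' @export
scan_guide_targets <- function(sites, genome, guide, anchor,
                               core = "ACCTNGA", core_anchor = 4L,
                               min_contig = 0L) {
  sites <- as.data.table(sites)
  L <- nchar(guide)
  if (anchor < 1L || anchor > L) stop("anchor must lie within the guide")
  n <- nrow(sites)
  context <- character(n); display <- character(n)
  contig <- integer(n); keep <- logical(n)
  skipped <- 0L
  for (i in seq_len(n)) {
    core_ctx <- fetch_context(genome, sites$chrom[i], sites$psi_pos[i],
                              sites$strand[i], up = core_anchor - 1L,
                              down = nchar(core) - core_anchor)
    if (is.na(core_ctx)) { skipped <- skipped + 1L; next }
    core_mask <- guide_match_mask(core_ctx, core, core_anchor)
    if (any(core_mask == "mismatch")) next
    ctx <- fetch_context(genome, sites$chrom[i], sites$psi_pos[i],
                         sites$strand[i], up = anchor - 1L, down = L - anchor)
    if (is.na(ctx)) { skipped <- skipped + 1L; next }
    mask <- guide_match_mask(ctx, guide, anchor)
    contig[i] <- contiguous_guide_matches(ctx, guide, anchor)
    ch <- strsplit(ctx, "", fixed = TRUE)[[1]]
    ch <- ifelse(mask == "match", toupper(ch), tolower(ch))
    ch[anchor] <- "T"
    context[i] <- ctx
    display[i] <- paste(ch, collapse = "")
    keep[i] <- TRUE
  }
  if (skipped > 0L) {
    message("scan_guide_targets: skipped ", skipped,
            " site(s) whose context extends past a chromosome end")
  }
  out <- sites[keep]
  out[, `:=`(context = context[keep], context_display = display[keep],
             contiguous_matches = contig[keep])]
  out <- out[contiguous_matches >= min_contig]
  setorder(out, -contiguous_matches, chrom, psi_pos)
  out[]
}
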
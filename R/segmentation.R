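# Frequent-variant selection and construction of the window-anchored
# segments of 50 adjacent frequent variants.

#' Select frequent variants
#'
#' Keeps variant `i` when its minor allele frequency, computed from the
#' cohort's alternative-allele counts over `2n` haplotypes, strictly exceeds
#' `maf_threshold`. A variant at exactly the threshold is dropped.
#'
#' @param cohort a [phased_cohort].
#' @param maf_threshold minor allele frequency cut-off (default 0.25).
#' @return integer indices into `cohort$records`.
#' @export
select_frequent <- function(cohort, maf_threshold = 0.25) {
  stopifnot(inherits(cohort, "phased_cohort"))
  n2 <- ncol(cohort$alleles)
  if (n2 == 0L) stop("cohort has no haplotypes")
  f <- cohort$records$alt_count / n2
  which(pmin(f, 1 - f) > maf_threshold)
}

#' Build window-anchored segments of adjacent frequent variants
#'
#' Each chromosome is covered by a grid of windows of `window_bp` bases
#' anchored at coordinate 0 (window starts are 0-based half-open, so a
#' 1-based variant position `p` falls past window start `s` when `p > s`).
#' The segment of a window consists of the first `k` frequent variants with
#' position beyond the window start; the segment is elongated as far as
#' needed, so it may overrun later window starts, and segments of successive
#' windows may overlap or even coincide. A window with fewer than `k`
#' frequent variants remaining downstream emits no segment.
#'
#' @param cohort a [phased_cohort] (records sorted by chrom, pos).
#' @param window_bp window size in bases (default 500000).
#' @param k variants per segment (default 50).
#' @param maf_threshold passed to [select_frequent()].
#' @param dedupe drop a window whose `k`-variant set is identical to the
#'   previous window's (default FALSE).
#' @return data frame of class `segment_set` with columns `chrom`,
#'   `segment_index`, `window_start`, `start_pos`, `end_pos`, `length_kb`
#'   and a list column `gv_indices` of `k` cohort-variant indices each.
#' @export
build_segments <- function(cohort, window_bp = 500000, k = 50,
                           maf_threshold = 0.25, dedupe = FALSE) {
  stopifnot(inherits(cohort, "phased_cohort"), window_bp > 0, k >= 1)
  freq_idx <- select_frequent(cohort, maf_threshold)
  out <- list()
  for (chrom in unique(cohort$records$chrom)) {
    idx <- freq_idx[cohort$records$chrom[freq_idx] == chrom]
    if (length(idx) < k) next
    pos <- cohort$records$pos[idx]
    last_start <- pos[length(pos) - k + 1L] # last window start that can fill
    starts <- seq(0, by = window_bp,
                  length.out = floor((last_start - 1) / window_bp) + 1L)
    seg_i <- 0L
    prev_first <- -1L
    for (s in starts) {
      first <- findInterval(s, pos) + 1L # first frequent variant with pos > s
      if (first + k - 1L > length(idx)) next
      if (dedupe && first == prev_first) next
      prev_first <- first
      seg_i <- seg_i + 1L
      gv <- idx[first:(first + k - 1L)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, segment_index = seg_i, window_start = s,
        start_pos = cohort$records$pos[gv[1L]],
        end_pos = cohort$records$pos[gv[k]],
        length_kb = (cohort$records$pos[gv[k]] -
                     cohort$records$pos[gv[1L]]) / 1000,
        gv_indices = I(list(gv)), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), segment_index = integer(0),
               window_start = numeric(0), start_pos = integer(0),
               end_pos = integer(0), length_kb = numeric(0),
               gv_indices = I(list()))
  class(res) <- c("segment_set", class(res))
  res
}

#' Extract a segment's haplotype strings
#'
#' Returns the `2n` length-`k` haplotype strings of one segment: haplotype
#' `j` is allele column `j` of the cohort restricted to the segment's
#' variants, in genomic order.
#'
#' @param cohort a [phased_cohort].
#' @param seg one row of a [build_segments()] result (or any list with a
#'   `gv_indices` element).
#' @return named character vector of `2n` strings over `{0,1}`.
#' @export
extract_haplotypes <- function(cohort, seg) {
  gv <- if (is.list(seg$gv_indices)) seg$gv_indices[[1L]] else seg$gv_indices
  stopifnot(all(gv >= 1L), all(gv <= nrow(cohort$alleles)))
  sub <- cohort$alleles[gv, , drop = FALSE]
  out <- apply(sub, 2L, function(col) paste(col, collapse = ""))
  names(out) <- colnames(cohort$alleles)
  out
}

#' Write a segment table as TSV
#'
#' Writes the per-segment columns (chrom, segment_index, start_pos,
#' length_kb, n_frequent_gvs) to a tab-separated file.
#'
#' @param segments a [build_segments()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  df <- data.frame(chrom = segments$chrom,
                   segment_index = segments$segment_index,
                   start_pos = segments$start_pos,
                   length_kb = segments$length_kb,
                   n_frequent_gvs = vapply(segments$gv_indices, length, 0L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
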
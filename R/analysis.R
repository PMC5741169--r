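# Cohort-level drivers: run the per-segment classification over a whole
# cohort and produce the genome-wide tables (per-segment summary, per-CH
# detail, threshold sweep, ancestral and archaic reports).

#' Classify every segment of a phased cohort
#'
#' Builds the windowed segments, groups each segment's haplotypes, calls
#' common haplotypes, detects Yin/Yang pairs, and decomposes non-pair CHs
#' into Yin/Yang pieces.
#'
#' @param cohort a [phased_cohort].
#' @param maf frequent-variant threshold (strict, default 0.25).
#' @param k variants per segment (default 50).
#' @param window_bp window size (default 500000).
#' @param max_intra_diff grouping tolerance (default 2).
#' @param min_count,min_freq CH threshold: supply one (default
#'   `min_count = 100`).
#' @param min_diff Yin/Yang Hamming threshold (default 47).
#' @param mosaic_threshold minimal pieces defining a Mosaic (default 12).
#' @param dedupe drop windows duplicating the previous window's variant
#'   set (default FALSE).
#' @return object of class `yyhap_analysis`: list with `segments` (the
#'   [build_segments()] table), `summary` (one [segment_summary()] row per
#'   segment), `ch_detail` (per-CH rows across segments, with derived
#'   counts and piece numbers), `pairs` and `chsets` (per-segment lists),
#'   and the thresholds used.
#' @export
classify_cohort <- function(cohort, maf = 0.25, k = 50, window_bp = 500000,
                            max_intra_diff = 2, min_count = 100,
                            min_freq = NULL, min_diff = 47,
                            mosaic_threshold = 12, dedupe = FALSE) {
  stopifnot(inherits(cohort, "phased_cohort"))
  if (!is.null(min_freq)) min_count <- NULL
  segs <- build_segments(cohort, window_bp = window_bp, k = k,
                         maf_threshold = maf, dedupe = dedupe)
  conts <- haplotype_continents(cohort)
  n_seg <- nrow(segs)
  summaries <- vector("list", n_seg)
  details <- vector("list", n_seg)
  chsets <- vector("list", n_seg)
  pairs <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    seg <- segs[i, ]
    haps <- extract_haplotypes(cohort, seg)
    chs <- common_haplotypes(group_haplotypes(haps, max_intra_diff, conts),
                             min_count = min_count, min_freq = min_freq)
    statuses <- cohort$records$aa_status[seg$gv_indices[[1L]]]
    cls <- classify_segment(chs, statuses, min_diff, mosaic_threshold)
    chsets[[i]] <- chs
    pairs[[i]] <- cls$pairs
    summaries[[i]] <- segment_summary(seg, chs, cls$pairs)
    if (nrow(cls$ch_table)) {
      details[[i]] <- cbind(data.frame(chrom = seg$chrom,
                                       segment_index = seg$segment_index),
                            cls$ch_table)
    }
  }
  structure(list(segments = segs,
                 summary = if (n_seg) do.call(rbind, summaries) else NULL,
                 ch_detail = if (length(details))
                   do.call(rbind, details[!vapply(details, is.null, TRUE)])
                   else NULL,
                 pairs = pairs, chsets = chsets,
                 thresholds = list(maf = maf, k = k, window_bp = window_bp,
                                   max_intra_diff = max_intra_diff,
                                   min_count = min_count,
                                   min_freq = min_freq, min_diff = min_diff,
                                   mosaic_threshold = mosaic_threshold)),
            class = "yyhap_analysis")
}

#' @export
print.yyhap_analysis <- function(x, ...) {
  n_seg <- nrow(x$segments)
  cat("<yyhap_analysis> ", n_seg, " segment(s)\n", sep = "")
  if (n_seg) {
    n_yy <- sum(vapply(x$pairs, nrow, 0L) >= 1L)
    cat("  with >=1 CH: ", sum(x$summary$n_ch >= 1L),
        "; with Yin/Yang pair(s): ", n_yy, "\n", sep = "")
  }
  invisible(x)
}

#' Sweep the frequent-variant threshold
#'
#' Re-runs the whole classification at several minor-allele-frequency
#' cut-offs and tabulates, per threshold: total segments, segments with at
#' least two CHs, segments with Yin/Yang pairs (count and percentage) and
#' segments with Mosaic CHs.
#'
#' @param cohort a [phased_cohort].
#' @param thresholds numeric vector of MAF cut-offs.
#' @param ... further arguments for [classify_cohort()].
#' @return data frame with one row per threshold.
#' @export
maf_sweep <- function(cohort, thresholds = c(0.15, 0.20, 0.25, 0.30), ...) {
  rows <- lapply(thresholds, function(th) {
    an <- classify_cohort(cohort, maf = th, ...)
    n_seg <- nrow(an$segments)
    n_yy <- sum(vapply(an$pairs, nrow, 0L) >= 1L)
    n_mos <- if (is.null(an$ch_detail)) 0L else
      length(unique(an$ch_detail$segment_index[an$ch_detail$role == "mosaic"]))
    data.frame(maf_threshold = th, n_segments = n_seg,
               n_seg_ge2_ch = if (n_seg) sum(an$summary$n_ch >= 2L) else 0L,
               n_seg_yinyang = n_yy,
               pct_seg_yinyang = if (n_seg) 100 * n_yy / n_seg else NA_real_,
               n_seg_mosaic = n_mos)
  })
  do.call(rbind, rows)
}

#' Ancestral-haplotype report over all segments
#'
#' For every segment, deduces the fully ancestral haplotype, counts cohort
#' haplotypes within `max_diff` differences of it (over unmasked
#' positions), classifies abundance (absent/rare/uncommon/common) and
#' continental specificity, and computes per-capita continent rates.
#'
#' @param cohort a [phased_cohort].
#' @param analysis optional [classify_cohort()] result (reused for the
#'   segment list); computed when absent.
#' @param max_diff match tolerance (default 2).
#' @param ... segmentation arguments when `analysis` is absent.
#' @return data frame with one row per segment: `segment_index`,
#'   `n_masked`, `eligible`, `match_count`, `abundance`, `specificity`,
#'   one `n_<continent>` column per continent and the per-capita
#'   `rate_<continent>` columns plus `predominant`.
#' @export
ancestral_report <- function(cohort, analysis = NULL, max_diff = 2, ...) {
  if (is.null(analysis)) analysis <- classify_cohort(cohort, ...)
  segs <- analysis$segments
  conts <- haplotype_continents(cohort)
  levs <- sort(unique(conts))
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    seg <- segs[i, ]
    statuses <- cohort$records$aa_status[seg$gv_indices[[1L]]]
    prof <- ancestral_haplotype(statuses)
    haps <- extract_haplotypes(cohort, seg)
    m <- match_ancestral(haps, prof, max_diff, conts)
    spec <- classify_specificity(m$continent_counts, m$abundance,
                                 panel = cohort$panel,
                                 continent_order = cohort$continent_order)
    nb <- normalize_by_continent(m$continent_counts, cohort$panel,
                                 cohort$continent_order)
    out <- data.frame(segment_index = seg$segment_index,
                      n_masked = prof$n_masked, eligible = m$eligible,
                      match_count = m$count, abundance = m$abundance,
                      specificity = spec, predominant = nb$predominant,
                      stringsAsFactors = FALSE)
    for (l in levs) out[[paste0("n_", l)]] <- m$continent_counts[[l]]
    for (l in names(nb$rates)) out[[paste0("rate_", l)]] <- nb$rates[[l]]
    out
  })
  do.call(rbind, rows)
}

#' Archaic-diplotype report over all segments
#'
#' Converts the archaic diplotype to a haplotype (homozygous positions
#' only) and compares it with every segment's common haplotypes:
#' difference counts over resolved positions, near-identity flags, and the
#' archaic derived-allele fraction per segment.
#'
#' @param cohort a [phased_cohort].
#' @param archaic an `archaic_diplotype` aligned to the cohort (from
#'   [read_archaic_vcf()]).
#' @param analysis a [classify_cohort()] result.
#' @param max_diff near-identity threshold (default 2).
#' @param min_resolved minimum resolved positions (default 45).
#' @return list with `segments` (per-segment `excluded`, `n_resolved`,
#'   `archaic_derived_fraction`, `near_identical_roles`) and `ch_detail`
#'   (per-CH rows with `n_diff`, `near_identical`, `role`).
#' @export
archaic_report <- function(cohort, archaic, analysis, max_diff = 2,
                           min_resolved = 45) {
  stopifnot(length(archaic) == nrow(cohort$records))
  segs <- analysis$segments
  seg_rows <- vector("list", nrow(segs))
  ch_rows <- list()
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    gv <- seg$gv_indices[[1L]]
    statuses <- cohort$records$aa_status[gv]
    ahap <- archaic_to_haplotype(unclass(archaic)[gv])
    cmp <- compare_archaic(ahap, analysis$chsets[[i]], statuses, max_diff,
                           min_resolved)
    roles <- character(0)
    if (!is.null(cmp$ch_table) && nrow(cmp$ch_table)) {
      det <- analysis$ch_detail
      det <- det[det$segment_index == seg$segment_index, , drop = FALSE]
      role <- det$role[match(cmp$ch_table$representative,
                             det$representative)]
      ch_rows[[length(ch_rows) + 1L]] <-
        cbind(data.frame(segment_index = seg$segment_index),
              cmp$ch_table, role = role)
      roles <- unique(role[cmp$ch_table$near_identical])
    }
    seg_rows[[i]] <- data.frame(
      segment_index = seg$segment_index, excluded = cmp$excluded,
      n_resolved = cmp$n_resolved,
      archaic_derived_fraction = cmp$archaic_derived_fraction,
      near_identical_roles = paste(roles, collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(segments = do.call(rbind, seg_rows),
       ch_detail = if (length(ch_rows)) do.call(rbind, ch_rows) else NULL)
}
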
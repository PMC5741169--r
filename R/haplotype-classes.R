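# Haplotype grouping, common-haplotype calling, Yin/Yang pair detection,
# minimal-piece Mosaic decomposition and derived-allele accounting.

#' Hamming distance between two haplotype strings
#'
#' @param a,b equal-length strings over `{0,1}` (any single-byte alphabet
#'   is accepted; positions are compared character-wise).
#' @return integer count of differing positions.
#' @export
#' @examples
#' hamming("00110", "01100") # 2
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: strings differ in length")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Group near-identical haplotypes
#'
#' Counts exact occurrences of each distinct haplotype string, then scans the
#' distinct strings in (count descending, lexicographic ascending) order:
#' each string joins the first previously founded group whose representative
#' is within `max_intra_diff` differences, otherwise it founds a new group
#' with itself as representative. The deterministic scan order makes the
#' partition reproducible without any seed; because representatives are
#' scanned most-frequent-first, a string within reach of two representatives
#' joins the more frequent one. Groups are finally ranked by
#' (count descending, representative ascending).
#'
#' @param haps character vector of equal-length `{0,1}` strings (typically
#'   the `2n` haplotypes of a segment).
#' @param max_intra_diff maximum differences between a member and its group
#'   representative (default 2, tolerating a couple of genotyping errors).
#' @param continents optional character vector parallel to `haps` giving the
#'   continent of each haplotype's carrier; enables per-group continent
#'   counts.
#' @return object of class `chset`: a list with elements
#'   `representative` (character), `count` (integer), `members` (list of
#'   data frames `string`/`count`), `continent_counts` (matrix or NULL),
#'   `k` (string length) and `n_haps`.
#' @export
group_haplotypes <- function(haps, max_intra_diff = 2, continents = NULL) {
  if (length(haps) == 0L) {
    return(structure(list(representative = character(0), count = integer(0),
                          members = list(), continent_counts = NULL,
                          k = 0L, n_haps = 0L),
                     class = "chset"))
  }
  if (!is.null(continents)) stopifnot(length(continents) == length(haps))
  k <- nchar(haps[1L])
  tab <- table(haps)
  distinct <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, distinct)
  distinct <- distinct[ord]
  cnt <- cnt[ord]
  dm <- haps_to_matrix(distinct)
  n_d <- length(distinct)
  rep_idx <- integer(0)            # indices (into distinct) of founders
  assign_grp <- integer(n_d)       # group id per distinct string
  for (i in seq_len(n_d)) {
    g <- 0L
    if (length(rep_idx)) {
      # distance of string i to every representative so far
      d <- colSums(t(dm[rep_idx, , drop = FALSE]) != dm[i, ])
      hit <- which(d <= max_intra_diff)
      if (length(hit)) g <- hit[1L]
    }
    if (g == 0L) {
      rep_idx <- c(rep_idx, i)
      g <- length(rep_idx)
    }
    assign_grp[i] <- g
  }
  n_g <- length(rep_idx)
  g_count <- vapply(seq_len(n_g), function(g) sum(cnt[assign_grp == g]), 0L)
  g_rep <- distinct[rep_idx]
  members <- lapply(seq_len(n_g), function(g) {
    sel <- which(assign_grp == g)
    data.frame(string = distinct[sel], count = cnt[sel],
               stringsAsFactors = FALSE)
  })
  cc <- NULL
  if (!is.null(continents)) {
    levs <- sort(unique(continents))
    cc <- matrix(0L, nrow = n_g, ncol = length(levs),
                 dimnames = list(NULL, levs))
    grp_of_string <- assign_grp[match(haps, distinct)]
    t2 <- table(factor(grp_of_string, levels = seq_len(n_g)),
                factor(continents, levels = levs))
    cc[] <- as.integer(t2)
  }
  # final ranking by (count desc, representative asc)
  ord2 <- order(-g_count, g_rep)
  structure(list(representative = g_rep[ord2],
                 count = g_count[ord2],
                 members = members[ord2],
                 continent_counts = if (is.null(cc)) NULL
                                    else cc[ord2, , drop = FALSE],
                 k = k, n_haps = length(haps)),
            class = "chset")
}

#' @export
print.chset <- function(x, ...) {
  cat("<chset> ", length(x$representative), " group(s) over ",
      x$n_haps, " haplotypes of length ", x$k, "\n", sep = "")
  n <- min(length(x$representative), 10L)
  for (i in seq_len(n)) {
    cat(sprintf("  [%d] n=%-5d %s\n", i, x$count[i], x$representative[i]))
  }
  if (length(x$representative) > n) cat("  ...\n")
  invisible(x)
}

#' @keywords internal
chset_subset <- function(chset, idx) {
  structure(list(representative = chset$representative[idx],
                 count = chset$count[idx],
                 members = chset$members[idx],
                 continent_counts = if (is.null(chset$continent_counts)) NULL
                   else chset$continent_counts[idx, , drop = FALSE],
                 k = chset$k, n_haps = chset$n_haps),
            class = "chset")
}

#' Select common haplotypes from a grouped set
#'
#' A group is a common haplotype (CH) if it occurs at least `min_count`
#' times (the cohort convention: 100 occurrences among 2184 haplotypes), or
#' with frequency at least `min_freq` of all haplotypes (the simulation
#' convention: 5%). Exactly one of the two thresholds must be given.
#'
#' @param chset output of [group_haplotypes()].
#' @param min_count absolute occurrence threshold.
#' @param min_freq frequency threshold over `chset$n_haps`.
#' @return a `chset` containing only the common groups (rank order kept).
#' @export
common_haplotypes <- function(chset, min_count = NULL, min_freq = NULL) {
  stopifnot(inherits(chset, "chset"))
  if (!is.null(min_count) && !is.null(min_freq)) {
    stop("supply only one of min_count and min_freq")
  }
  if (is.null(min_count) && is.null(min_freq)) min_count <- 100
  keep <- if (!is.null(min_count)) chset$count >= min_count
          else chset$count / chset$n_haps >= min_freq
  chset_subset(chset, which(keep))
}

#' Detect Yin/Yang pairs among common haplotypes
#'
#' Pairs CHs greedily by rank: the most frequent unpaired CH is paired with
#' the most frequent other unpaired CH whose representative differs at
#' `min_diff` or more positions; both are then removed and the scan
#' continues, so one segment can yield several pairs. Within a pair, Yin is
#' the more frequent CH.
#'
#' @param chs a ranked `chset` of common haplotypes.
#' @param min_diff minimum Hamming distance between paired representatives
#'   (default 47 of 50, i.e. at least 94% complementary, tolerating a few
#'   errors or gene-conversion "jumps").
#' @return data frame with one row per pair: `yin`, `yang`, `yin_count`,
#'   `yang_count`, `n_diff`.
#' @export
find_yinyang <- function(chs, min_diff = 47) {
  stopifnot(inherits(chs, "chset"))
  n <- length(chs$representative)
  out <- data.frame(yin = character(0), yang = character(0),
                    yin_count = integer(0), yang_count = integer(0),
                    n_diff = integer(0), stringsAsFactors = FALSE)
  if (n < 2L) return(out)
  unpaired <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!unpaired[i]) next
    js <- which(unpaired)
    js <- js[js != i]
    for (j in js) { # js is already in rank order
      if (hamming(chs$representative[i], chs$representative[j]) >= min_diff) {
        unpaired[i] <- unpaired[j] <- FALSE
        out <- rbind(out, data.frame(
          yin = chs$representative[i], yang = chs$representative[j],
          yin_count = chs$count[i], yang_count = chs$count[j],
          n_diff = hamming(chs$representative[i], chs$representative[j]),
          stringsAsFactors = FALSE))
        break
      }
    }
  }
  out
}

#' Minimal number of Yin/Yang pieces needed to rebuild a haplotype
#'
#' Each position of `h` is labelled Y if it matches only `yin`, G if it
#' matches only `yang`, and wildcard where `yin` and `yang` agree (there `h`
#' matches both or neither, and the position never forces a breakpoint).
#' The minimum number of maximal constant-label runs over all wildcard
#' resolutions is the number of forced Y-G alternations plus one, computed
#' in a single left-to-right pass.
#'
#' @param h,yin,yang equal-length `{0,1}` strings.
#' @return integer piece count in `[1, nchar(h)]`.
#' @export
#' @examples
#' min_pieces("0000011111", "0000000000", "1111111111") # 2
min_pieces <- function(h, yin, yang) {
  if (nchar(h) != nchar(yin) || nchar(h) != nchar(yang)) {
    stop("min_pieces: strings differ in length")
  }
  hv <- utf8ToInt(h); yv <- utf8ToInt(yin); gv <- utf8ToInt(yang)
  lab <- ifelse(yv == gv, NA_integer_, ifelse(hv == yv, 1L, 2L))
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0L) return(1L)
  1L + sum(lab[-1L] != lab[-length(lab)])
}

#' Derived-allele fraction of a haplotype
#'
#' A position carries a derived allele when the haplotype has the
#' alternative allele at a position where the reference allele is ancestral
#' (status `R`), or the reference allele where the alternative is ancestral
#' (status `M`). Positions of unknown status (`X`) are excluded from both
#' numerator and denominator.
#'
#' @param h `{0,1}` string.
#' @param statuses character vector over `{R,M,X}`, one per position.
#' @return fraction in `[0,1]`, or `NA_real_` when every position is `X`.
#' @export
derived_fraction <- function(h, statuses) {
  d <- derived_positions(h, statuses)
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

# logical per-position derived indicator; NA at X positions
#' @keywords internal
derived_positions <- function(h, statuses) {
  hv <- str_to_int(h)
  if (length(hv) != length(statuses)) {
    stop("statuses length must match haplotype length")
  }
  if (!all(statuses %in% c("R", "M", "X"))) {
    stop("statuses must be in {R, M, X}")
  }
  out <- (hv == 1L & statuses == "R") | (hv == 0L & statuses == "M")
  out[statuses == "X"] <- NA
  out
}

#' Attribute a Mosaic's derived alleles to the Yin or Yang haplotype
#'
#' Every derived allele of `mosaic` at a position where `yin` and `yang`
#' disagree is credited to whichever of the two carries that allele; derived
#' alleles at positions where they agree are counted as `n_other`.
#'
#' @param mosaic,yin,yang equal-length `{0,1}` strings.
#' @param statuses per-position `{R,M,X}` vector.
#' @return named integer vector `c(n_yin_derived, n_yang_derived, n_other)`.
#' @export
mosaic_source_split <- function(mosaic, yin, yang, statuses) {
  d <- derived_positions(mosaic, statuses)
  mv <- str_to_int(mosaic); yv <- str_to_int(yin); gv <- str_to_int(yang)
  der <- which(!is.na(d) & d)
  informative <- yv != gv
  n_yin <- sum(der %in% which(informative & yv == mv))
  n_yang <- sum(der %in% which(informative & gv == mv))
  n_other <- length(der) - n_yin - n_yang
  c(n_yin_derived = n_yin, n_yang_derived = n_yang, n_other = n_other)
}

#' Null distribution of the one-sided Mosaic derived-allele split
#'
#' Randomly assigns `n_derived` derived alleles independently to the Yin
#' side (probability `p_yin`), Yang side (`p_yang`) or neither, and records
#' per replicate the fraction carried by the majority side. The returned
#' `p_one_sided` is the fraction of replicates in which at least
#' `threshold` (80%) of the alleles fall on one side -- the "expected"
#' reference curve against which the observed unimodal excess is judged.
#'
#' @param n_derived number of derived alleles to assign.
#' @param p_yin,p_yang assignment probabilities (defaults 0.546 and 0.438,
#'   the observed genome-wide shares; must sum to at most 1).
#' @param reps number of replicates (must be positive).
#' @param seed optional integer seed for reproducibility.
#' @param threshold majority fraction defining "one-sided" (default 0.8).
#' @return list with `max_side_fraction` (numeric vector, NA when a
#'   replicate assigns every allele to neither side) and `p_one_sided`.
#' @export
expected_split_null <- function(n_derived, p_yin = 0.546, p_yang = 0.438,
                                reps = 10000, seed = NULL, threshold = 0.8) {
  stopifnot(n_derived >= 1, p_yin >= 0, p_yang >= 0, p_yin + p_yang <= 1)
  if (reps <= 0) stop("reps must be positive")
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(reps, n_derived, c(p_yin, p_yang,
                                               1 - p_yin - p_yang))
  maxside <- pmax(draws[1L, ], draws[2L, ]) / n_derived
  list(max_side_fraction = maxside,
       p_one_sided = mean(maxside >= threshold))
}

#' Classify the common haplotypes of one segment
#'
#' Runs the full per-segment classification: Yin/Yang pairing among the CHs,
#' then for every CH outside a pair the minimal-piece decomposition against
#' the top-ranked pair; CHs needing `mosaic_threshold` or more pieces are
#' Mosaic. Derived-allele counts use the segment's ancestral statuses.
#'
#' @param chs `chset` of common haplotypes (ranked).
#' @param statuses per-position `{R,M,X}` vector (optional; derived columns
#'   are NA without it).
#' @param min_diff Yin/Yang Hamming threshold (default 47).
#' @param mosaic_threshold minimal pieces defining a Mosaic (default 12).
#' @return list with `pairs` (from [find_yinyang()]) and `ch_table`, a data
#'   frame with one row per CH: `rank`, `representative`, `count`, `role`
#'   (yin/yang/mosaic/other), `pieces`, `n_derived`, `derived_fraction`,
#'   `n_yin_derived`, `n_yang_derived`.
#' @export
classify_segment <- function(chs, statuses = NULL, min_diff = 47,
                             mosaic_threshold = 12) {
  stopifnot(inherits(chs, "chset"))
  pairs <- find_yinyang(chs, min_diff = min_diff)
  n <- length(chs$representative)
  role <- rep("other", n)
  pieces <- rep(NA_integer_, n)
  nd <- rep(NA_integer_, n); df <- rep(NA_real_, n)
  ndy <- rep(NA_integer_, n); ndg <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    role[match(pairs$yin, chs$representative)] <- "yin"
    role[match(pairs$yang, chs$representative)] <- "yang"
  }
  for (i in seq_len(n)) {
    if (!is.null(statuses)) {
      dpos <- derived_positions(chs$representative[i], statuses)
      nd[i] <- sum(dpos, na.rm = TRUE)
      df[i] <- if (all(is.na(dpos))) NA_real_ else mean(dpos, na.rm = TRUE)
    }
    if (nrow(pairs) && role[i] == "other") {
      pieces[i] <- min_pieces(chs$representative[i], pairs$yin[1L],
                              pairs$yang[1L])
      if (pieces[i] >= mosaic_threshold) role[i] <- "mosaic"
      if (!is.null(statuses)) {
        sp <- mosaic_source_split(chs$representative[i], pairs$yin[1L],
                                  pairs$yang[1L], statuses)
        ndy[i] <- sp[["n_yin_derived"]]; ndg[i] <- sp[["n_yang_derived"]]
      }
    }
  }
  list(pairs = pairs,
       ch_table = data.frame(rank = seq_len(n),
                             representative = chs$representative,
                             count = chs$count, role = role, pieces = pieces,
                             n_derived = nd, derived_fraction = df,
                             n_yin_derived = ndy, n_yang_derived = ndg,
                             stringsAsFactors = FALSE))
}

#' One summary row for a segment
#'
#' Mirrors the columns of the genome-wide segment table: chromosome, segment
#' index, start, length, CH count, total CH occurrences, maximum pairwise
#' difference between CH representatives ("NA" when fewer than two CHs) and
#' the number of CHs involved in Yin/Yang pairs.
#'
#' @param seg one-row segment specification (see [build_segments()]).
#' @param chs `chset` of the segment's common haplotypes.
#' @param pairs data frame from [find_yinyang()].
#' @return one-row data frame.
#' @export
segment_summary <- function(seg, chs, pairs) {
  n_ch <- length(chs$representative)
  maxdiff <- NA_integer_
  if (n_ch >= 2L) {
    m <- haps_to_matrix(chs$representative)
    dmax <- 0L
    for (i in seq_len(n_ch - 1L)) {
      d <- colSums(t(m[(i + 1L):n_ch, , drop = FALSE]) != m[i, ])
      dmax <- max(dmax, max(d))
    }
    maxdiff <- as.integer(dmax)
  }
  data.frame(chrom = seg$chrom, segment_index = seg$segment_index,
             start_pos = seg$start_pos, length_kb = seg$length_kb,
             n_ch = n_ch, ch_occurrences = sum(chs$count),
             max_diff = maxdiff, n_yinyang_ch = 2L * nrow(pairs),
             stringsAsFactors = FALSE)
}
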
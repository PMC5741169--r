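# Deduced 100%-ancestral haplotypes, their abundance and continental
# specificity, and comparison of common haplotypes with an archaic
# diplotype.

#' Deduce the fully ancestral haplotype of a segment
#'
#' Maps per-position ancestral statuses to the ancestral allele: `R` gives
#' the reference allele (0), `M` the alternative (1), `X` a mask. The
#' result's derived-allele fraction is 0 by construction.
#'
#' @param statuses character vector over `{R,M,X}` for the segment's
#'   variants, in genomic order.
#' @return list of class `ancestral_profile` with `profile` (a string over
#'   `{0,1,.}`, `.` marking masked positions) and `n_masked`.
#' @export
ancestral_haplotype <- function(statuses) {
  stopifnot(all(statuses %in% c("R", "M", "X")))
  ch <- ifelse(statuses == "R", "0", ifelse(statuses == "M", "1", "."))
  structure(list(profile = paste(ch, collapse = ""),
                 n_masked = sum(statuses == "X")),
            class = "ancestral_profile")
}

#' Count cohort haplotypes matching the ancestral profile
#'
#' A haplotype matches when it differs from the profile at no more than
#' `max_diff` unmasked positions. Segments whose profile is masked at more
#' than half the positions are flagged ineligible (the distance threshold
#' becomes meaningless), and counts are still returned for reference.
#'
#' @param haps `2n` haplotype strings of the segment.
#' @param profile an [ancestral_haplotype()] result.
#' @param max_diff allowed differences (default 2).
#' @param continents optional per-haplotype continent labels for the
#'   per-continent breakdown.
#' @return list with `count`, `continent_counts` (named integer vector or
#'   NULL), `eligible` (logical), `abundance` (see [classify_abundance()]).
#' @export
match_ancestral <- function(haps, profile, max_diff = 2, continents = NULL) {
  stopifnot(inherits(profile, "ancestral_profile"))
  pv <- utf8ToInt(profile$profile)
  mask <- pv == utf8ToInt(".")
  eligible <- mean(mask) <= 0.5
  hm <- haps_to_matrix(haps) + utf8ToInt("0")
  use <- !mask
  d <- colSums(t(hm[, use, drop = FALSE]) != pv[use])
  hit <- d <= max_diff
  cc <- NULL
  if (!is.null(continents)) {
    stopifnot(length(continents) == length(haps))
    levs <- sort(unique(continents))
    cc <- vapply(levs, function(l) sum(hit & continents == l), 0L)
  }
  count <- sum(hit)
  list(count = count, continent_counts = cc, eligible = eligible,
       abundance = classify_abundance(count))
}

#' Abundance class of an ancestral haplotype
#'
#' `absent` for 0 matches, `rare` for 1-3, `uncommon` for 4-99 and `common`
#' for 100 or more (the boundaries are configurable; 4-99/>=100 keeps the
#' classes disjoint).
#'
#' @param count number of matching haplotypes.
#' @param rare_max,uncommon_max upper bounds of the rare and uncommon
#'   classes.
#' @return one of `"absent"`, `"rare"`, `"uncommon"`, `"common"`.
#' @export
classify_abundance <- function(count, rare_max = 3, uncommon_max = 99) {
  stopifnot(count >= 0)
  if (count == 0) "absent"
  else if (count <= rare_max) "rare"
  else if (count <= uncommon_max) "uncommon"
  else "common"
}

#' Continental specificity of an ancestral haplotype
#'
#' Rare haplotypes are continent-specific when a single continent holds
#' 100% of the matches; uncommon ones when one continent holds strictly
#' more than 90%. Common haplotypes use per-capita predominance instead
#' (see [normalize_by_continent()]), since proportion rules are not
#' meaningful for haplotypes present everywhere. Anything else is
#' `"multi-continent"`.
#'
#' @param continent_counts named integer vector of matches per continent.
#' @param abundance class from [classify_abundance()].
#' @param panel cohort panel (required for the common class).
#' @param continent_order tie-break order for predominance.
#' @return a continent label, `"<continent>-predominant"` for the common
#'   class, or `"multi-continent"`; `NA` for the absent class.
#' @export
classify_specificity <- function(continent_counts, abundance, panel = NULL,
                                 continent_order = NULL) {
  if (abundance == "absent") return(NA_character_)
  total <- sum(continent_counts)
  if (abundance == "rare") {
    top <- names(continent_counts)[continent_counts == total]
    return(if (length(top) == 1L && total > 0) top else "multi-continent")
  }
  if (abundance == "uncommon") {
    frac <- continent_counts / total
    top <- which(frac > 0.9)
    return(if (length(top) == 1L) names(continent_counts)[top]
           else "multi-continent")
  }
  if (is.null(panel)) stop("panel required for common-class specificity")
  nb <- normalize_by_continent(continent_counts, panel, continent_order)
  paste0(nb$predominant, "-predominant")
}

#' Per-capita continent rates and predominant continent
#'
#' Divides each continent's match count by its number of sampled
#' haplotypes (2 x samples), correcting for uneven panel sizes. The
#' predominant continent is the one with the highest rate; exact ties are
#' broken deterministically by `continent_order`.
#'
#' @param counts named integer vector of matches per continent.
#' @param panel cohort panel data frame (`sample`, `population`,
#'   `continent`).
#' @param continent_order tie-break order (default: sorted continent
#'   names).
#' @return list with `rates` (named numeric) and `predominant`.
#' @export
normalize_by_continent <- function(counts, panel, continent_order = NULL) {
  sizes <- table(panel$continent)
  if (is.null(continent_order)) continent_order <- sort(names(sizes))
  cont <- continent_order[continent_order %in% names(counts)]
  rates <- vapply(cont, function(l) {
    if (is.na(sizes[l]) || sizes[l] == 0) return(NA_real_)
    unname(counts[l] / (2 * sizes[l]))
  }, 0)
  names(rates) <- cont
  best <- cont[which.max(rates)] # which.max takes the first maximum
  list(rates = rates, predominant = best)
}

#' Convert an archaic diplotype to a haplotype string
#'
#' Valid because the archaic genome is almost entirely homozygous at the
#' analyzed frequent variants: homozygous codes map directly (`0` to the
#' reference allele, `2` to the alternative), while heterozygous (`1`) and
#' uncallable (`x`) positions become missing (`.`).
#'
#' @param codes `archaic_diplotype` or character vector over `{0,1,2,x}`.
#' @return string over `{0,1,.}`.
#' @export
archaic_to_haplotype <- function(codes) {
  stopifnot(all(codes %in% c("0", "1", "2", "x")))
  paste(c(`0` = "0", `1` = ".", `2` = "1", x = ".")[codes], collapse = "")
}

#' Compare an archaic haplotype with a segment's common haplotypes
#'
#' Differences are counted only over mutually resolved positions (archaic
#' non-missing). A CH is near-identical to the archaic haplotype when it
#' differs at `max_diff` or fewer resolved positions and at least
#' `min_resolved` positions are resolved; segments below the floor are
#' excluded. The archaic derived-allele fraction is computed over resolved,
#' non-`X` positions.
#'
#' @param archaic_hap string over `{0,1,.}` from [archaic_to_haplotype()].
#' @param chs `chset` of the segment's common haplotypes.
#' @param statuses per-position `{R,M,X}` vector.
#' @param max_diff near-identity threshold (default 2).
#' @param min_resolved minimum resolved positions (default 45).
#' @return list with `excluded` (logical), `n_resolved`,
#'   `archaic_derived_fraction`, and `ch_table` (per-CH `representative`,
#'   `count`, `n_diff`, `near_identical`).
#' @export
compare_archaic <- function(archaic_hap, chs, statuses, max_diff = 2,
                            min_resolved = 45) {
  stopifnot(inherits(chs, "chset"))
  av <- utf8ToInt(archaic_hap) - utf8ToInt("0")
  resolved <- av %in% c(0L, 1L)
  n_res <- sum(resolved)
  excluded <- n_res < min_resolved
  adf <- NA_real_
  if (n_res > 0L) {
    st <- statuses[resolved]
    hv <- av[resolved]
    der <- (hv == 1L & st == "R") | (hv == 0L & st == "M")
    der[st == "X"] <- NA
    if (!all(is.na(der))) adf <- mean(der, na.rm = TRUE)
  }
  tab <- NULL
  if (length(chs$representative)) {
    m <- haps_to_matrix(chs$representative)
    nd <- as.integer(colSums(t(m[, resolved, drop = FALSE]) != av[resolved]))
    tab <- data.frame(representative = chs$representative,
                      count = chs$count, n_diff = nd,
                      near_identical = !excluded & nd <= max_diff,
                      stringsAsFactors = FALSE)
  }
  list(excluded = excluded, n_resolved = n_res,
       archaic_derived_fraction = adf, ch_table = tab)
}
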
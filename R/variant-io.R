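# Reading and writing the standard formats: phased VCF v4.1 with INFO/AA
# ancestral annotations, the sample panel table, and an archaic (unphased)
# VCF mapped onto a cohort's variant set.

#' Construct a phased cohort
#'
#' Internal constructor validating the cohort invariants: a biallelic,
#' position-sorted variant table, a `{0,1}` allele matrix with two haplotype
#' columns per sample (columns `2i-1`, `2i` belong to sample `i`), and a
#' panel mapping every sample to a population and continent.
#'
#' @param records data frame with columns `chrom`, `pos`, `vid`, `ref`,
#'   `alt`, `aa_status` (in `{R,M,X}`), `alt_count`.
#' @param alleles integer matrix (variants x 2n) over `{0,1}`.
#' @param samples character vector of sample ids, length `n`.
#' @param panel data frame with columns `sample`, `population`, `continent`.
#' @param continent_order optional character vector fixing the continent
#'   order used for deterministic tie-breaks.
#' @return object of class `phased_cohort`.
#' @export
phased_cohort <- function(records, alleles, samples, panel,
                          continent_order = NULL) {
  stopifnot(is.data.frame(records), is.matrix(alleles),
            nrow(records) == nrow(alleles),
            ncol(alleles) == 2L * length(samples))
  if (any(records$pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (!all(records$aa_status %in% c("R", "M", "X"))) {
    stop("aa_status must be in {R, M, X}")
  }
  if (length(alleles) && !all(alleles %in% c(0L, 1L))) {
    stop("allele matrix must be over {0,1}")
  }
  cs <- if (nrow(alleles)) as.integer(rowSums(alleles)) else integer(0)
  if (!identical(cs, as.integer(records$alt_count))) {
    stop("alt_count inconsistent with allele matrix")
  }
  missing_panel <- setdiff(samples, panel$sample)
  if (length(missing_panel)) {
    stop("sample(s) absent from panel: ", paste(missing_panel, collapse = ", "))
  }
  panel <- panel[match(samples, panel$sample), , drop = FALSE]
  rownames(panel) <- NULL
  colnames(alleles) <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
  if (is.null(continent_order)) continent_order <- sort(unique(panel$continent))
  structure(list(records = records, alleles = alleles, samples = samples,
                 panel = panel, continent_order = continent_order),
            class = "phased_cohort")
}

#' @export
print.phased_cohort <- function(x, ...) {
  cat("<phased_cohort> ", nrow(x$records), " variant(s), ",
      length(x$samples), " sample(s) (", ncol(x$alleles),
      " haplotypes)\n", sep = "")
  cat("  continents:",
      paste(sprintf("%s=%d", names(table(x$panel$continent)),
                    table(x$panel$continent)), collapse = " "), "\n")
  invisible(x)
}

#' Continent of each haplotype column
#'
#' @param cohort a [phased_cohort].
#' @return character vector of length `2n`.
#' @export
haplotype_continents <- function(cohort) {
  rep(cohort$panel$continent, each = 2L)
}

#' Parse an ancestral-allele annotation
#'
#' Compares the `AA=` value against the reference and alternative alleles,
#' case-insensitively: a match to the reference gives status `R` (reference
#' allele ancestral), a match to the alternative gives `M` (the mutant
#' allele is ancestral), and anything else -- absent value, `.`, `-`, `N`,
#' another base, an indel mismatch -- gives `X` (unknown). Total function:
#' never errors.
#'
#' @param aa_field the annotation value (possibly `NA` or empty).
#' @param ref_allele,alt_allele allele strings.
#' @return one of `"R"`, `"M"`, `"X"`.
#' @export
#' @examples
#' parse_ancestral("a", "A", "G") # "R"
#' parse_ancestral(".", "A", "G") # "X"
parse_ancestral <- function(aa_field, ref_allele, alt_allele) {
  if (length(aa_field) != 1L || is.na(aa_field)) return("X")
  aa <- toupper(as.character(aa_field))
  if (!is.na(ref_allele) && aa == toupper(as.character(ref_allele))) {
    return("R")
  }
  if (!is.na(alt_allele) && aa == toupper(as.character(alt_allele))) {
    return("M")
  }
  "X"
}

#' @keywords internal
read_panel_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("panel file is empty: ", path)
  if (grepl("sample|population|continent", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
  }
  parts <- strsplit(lines, "\t| +")
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad)) stop("panel line ", bad[1L], " has fewer than 3 columns")
  data.frame(sample = vapply(parts, `[[`, "", 1L),
             population = vapply(parts, `[[`, "", 2L),
             continent = vapply(parts, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Read a phased VCF into a cohort
#'
#' Reads a VCF v4.1 with phased GT fields and `AA=` INFO annotations.
#' Multi-allelic records are dropped (haplotype strings are binary by
#' construction); biallelic indels are kept unless `snps_only`. Any
#' unphased (`/`-separated) or missing genotype in a retained record is a
#' hard error naming the record, as is a VCF sample missing from the panel.
#'
#' @param path VCF file (plain text).
#' @param panel panel file path (TSV: sample, population, continent; header
#'   optional) or an equivalent data frame.
#' @param region optional region filter, `"chrom"` or `"chrom:start-end"`
#'   (1-based inclusive).
#' @param snps_only drop biallelic indels too (default FALSE).
#' @param continent_order passed to [phased_cohort()].
#' @return a [phased_cohort].
#' @export
read_phased_vcf <- function(path, panel, region = NULL, snps_only = FALSE,
                            continent_order = NULL) {
  pan <- if (is.data.frame(panel)) panel else read_panel_file(panel)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  info <- v@fix[, "INFO"]
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  missing_panel <- setdiff(samples, pan$sample)
  if (length(missing_panel)) {
    stop("VCF sample(s) absent from panel: ",
         paste(missing_panel, collapse = ", "))
  }
  keep <- !grepl(",", fix[, "ALT"], fixed = TRUE) & !is.na(fix[, "ALT"]) &
          !is.na(fix[, "REF"])
  if (snps_only) {
    keep <- keep & nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  }
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (!length(m)) stop("bad region: ", region)
    keep <- keep & fix[, "CHROM"] == m[2L]
    if (nzchar(m[3L])) {
      p <- as.integer(fix[, "POS"])
      keep <- keep & p >= as.integer(m[4L]) & p <= as.integer(m[5L])
    }
  }
  fix <- fix[keep, , drop = FALSE]
  info <- info[keep]
  gt <- gt[keep, -1L, drop = FALSE]
  n_rec <- nrow(fix)
  rec_label <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  # genotypes: strict "a|b" with a,b in {0,1}
  gtv <- sub(":.*$", "", as.vector(gt))
  unphased <- grepl("/", gtv, fixed = TRUE)
  if (any(unphased)) {
    bad <- ((which(unphased)[1L] - 1L) %% n_rec) + 1L
    stop("unphased genotype at ", rec_label[bad])
  }
  ok <- gtv %in% c("0|0", "0|1", "1|0", "1|1")
  if (!all(ok)) {
    bad <- ((which(!ok)[1L] - 1L) %% n_rec) + 1L
    stop("missing or malformed genotype at ", rec_label[bad])
  }
  a1 <- as.integer(substr(gtv, 1L, 1L))
  a2 <- as.integer(substr(gtv, 3L, 3L))
  # interleave: columns 2i-1, 2i are sample i's haplotypes
  alleles <- matrix(0L, nrow = n_rec, ncol = 2L * length(samples))
  alleles[, seq(1L, 2L * length(samples), by = 2L)] <-
    matrix(a1, nrow = n_rec)
  alleles[, seq(2L, 2L * length(samples), by = 2L)] <-
    matrix(a2, nrow = n_rec)
  aa_raw <- rep(NA_character_, n_rec)
  m <- regexpr("(^|;)AA=[^;]*", info)
  aa_raw[m > 0L] <- sub("^;?AA=", "", regmatches(info, m))
  aa <- vapply(seq_len(n_rec), function(i)
    parse_ancestral(aa_raw[i], fix[i, "REF"], fix[i, "ALT"]), "")
  records <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        vid = fix[, "ID"], ref = fix[, "REF"],
                        alt = fix[, "ALT"], aa_status = aa,
                        alt_count = as.integer(rowSums(alleles)),
                        stringsAsFactors = FALSE)
  ord <- order(records$chrom, records$pos)
  phased_cohort(records[ord, , drop = FALSE],
                alleles[ord, , drop = FALSE],
                samples, pan, continent_order)
}

#' Write a cohort as a phased VCF
#'
#' Emits a minimal plain-text VCF v4.1 with an `AA=` INFO field encoding the
#' ancestral status (`AA=<ref>` for status R, `AA=<alt>` for M, `AA=.` for
#' X) and phased GT genotypes, suitable for [read_phased_vcf()] round trips.
#'
#' @param cohort a [phased_cohort].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phased_vcf <- function(cohort, path) {
  rec <- cohort$records
  n <- length(cohort$samples)
  hdr <- c("##fileformat=VCFv4.1",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cohort$samples), collapse = "\t"))
  aa_val <- ifelse(rec$aa_status == "R", rec$ref,
                   ifelse(rec$aa_status == "M", rec$alt, "."))
  a1 <- cohort$alleles[, seq(1L, 2L * n, by = 2L), drop = FALSE]
  a2 <- cohort$alleles[, seq(2L, 2L * n, by = 2L), drop = FALSE]
  gtm <- matrix(paste0(a1, "|", a2), nrow = nrow(rec))
  body <- vapply(seq_len(nrow(rec)), function(i) {
    paste(c(rec$chrom[i], rec$pos[i], rec$vid[i], rec$ref[i], rec$alt[i],
            ".", "PASS", paste0("AA=", aa_val[i]), "GT", gtm[i, ]),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a sample panel TSV
#'
#' @param panel data frame with `sample`, `population`, `continent`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel[, c("sample", "population", "continent")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an archaic VCF as a diplotype over a cohort's variants
#'
#' Maps each cohort variant to a diplotype code: `0`, `1` or `2` copies of
#' the alternative allele in the archaic genotype (first sample of the
#' file; phasing is not required), or `x` when the variant is absent from
#' the archaic file, has mismatching alleles, or its genotype is missing.
#'
#' @param path archaic VCF path (plain text).
#' @param cohort a [phased_cohort] defining the target variant set.
#' @return object of class `archaic_diplotype`: character vector over
#'   `{0,1,2,x}` aligned to `cohort$records`.
#' @export
read_archaic_vcf <- function(path, cohort) {
  stopifnot(inherits(cohort, "phased_cohort"))
  lines <- readLines(path)
  datal <- which(!startsWith(lines, "#") & nzchar(lines))
  codes <- rep("x", nrow(cohort$records))
  key <- paste(cohort$records$chrom, cohort$records$pos,
               cohort$records$ref, cohort$records$alt)
  for (ln in datal) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) {
      stop("malformed VCF line ", ln, " in ", path,
           ": expected at least 10 tab-separated fields")
    }
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos)) stop("malformed VCF line ", ln, " in ", path,
                         ": bad POS field")
    i <- match(paste(f[1L], pos, f[4L], f[5L]), key)
    if (is.na(i)) next
    gt <- sub(":.*$", "", f[10L])
    al <- strsplit(gt, "[/|]")[[1L]]
    if (length(al) == 2L && all(al %in% c("0", "1"))) {
      codes[i] <- as.character(sum(as.integer(al)))
    } # anything else (./., haploid, other alleles) stays "x"
  }
  structure(codes, class = "archaic_diplotype")
}

#' Write an archaic diplotype as a VCF
#'
#' Inverse of [read_archaic_vcf()] for synthetic data: codes 0/1/2 become
#' genotypes `0/0`, `0/1`, `1/1`; `x` variants are written with a missing
#' genotype `./.`.
#'
#' @param codes `archaic_diplotype` (or character vector over `{0,1,2,x}`)
#'   aligned to `cohort$records`.
#' @param cohort the [phased_cohort] the codes are aligned to.
#' @param path output path.
#' @param sample_name sample column name (default "archaic").
#' @return the path, invisibly.
#' @export
write_archaic_vcf <- function(codes, cohort, path, sample_name = "archaic") {
  stopifnot(length(codes) == nrow(cohort$records),
            all(codes %in% c("0", "1", "2", "x")))
  rec <- cohort$records
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1", x = "./.")[codes]
  hdr <- c("##fileformat=VCFv4.1",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_name), collapse = "\t"))
  body <- paste(rec$chrom, rec$pos, rec$vid, rec$ref, rec$alt, ".", "PASS",
                ".", "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
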
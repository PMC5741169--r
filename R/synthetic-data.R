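# Constructive generator of phased cohorts with exact planted ground truth:
# per-segment Yin/Yang pairs, Mosaic haplotypes with a prescribed minimal
# piece count, rare/common ancestral haplotypes with African enrichment,
# ancestral-status annotations with an unknown fraction, and a nearly
# homozygous archaic individual with a prescribed derived-allele fraction.

#' Synthetic-cohort configuration
#'
#' Defaults emulate the regime the analysis is designed for: a phased
#' cohort of about 1000 diploids from four continents, segments of 50
#' frequent variants, Yin/Yang pairs complementary at >= 47/50 positions,
#' Mosaics needing >= 12 pieces with most derived alleles matching Yin,
#' ancestral haplotypes enriched in Africa (and Yin depleted there), and an
#' archaic genome that is > 99% homozygous with 18% derived alleles.
#'
#' @param n_samples named integer vector of diploid sample counts per
#'   continent.
#' @param n_segments number of segments to plant.
#' @param scenarios character vector (recycled over segments) from
#'   `{"yinyang", "yinyang_mosaic", "single_ch", "ancestral_rich",
#'   "no_ch"}`; default cycles through all five.
#' @param yin_freq,yang_freq planted Yin/Yang haplotype frequencies.
#' @param mosaic_freq planted Mosaic frequency (yinyang_mosaic scenario).
#' @param single_ch_freq planted frequency of the lone CH (single_ch).
#' @param ancestral_common_freq planted ancestral-haplotype frequency in
#'   the ancestral_rich scenario.
#' @param n_rare_ancestral ancestral copies planted in yinyang scenarios
#'   (rare class).
#' @param d_yin derived alleles carried by Yin (of `k = 50`; Yang carries
#'   the complementary `50 - d_yin`).
#' @param mosaic_pieces,mosaic_derived,mosaic_yin_derived Mosaic layout:
#'   minimal piece count, total derived alleles, and how many of them match
#'   Yin.
#' @param jumps positions where Yang is set equal to Yin (degrading the
#'   pair's complementarity from 50 to `50 - jumps`; at most 3).
#' @param epsilon per-allele flip noise probability.
#' @param x_fraction fraction of variants with unknown ancestral status.
#' @param p_alt_ancestral probability the alternative allele is the
#'   ancestral one (status M).
#' @param archaic_derived,archaic_het,archaic_missing archaic genome
#'   parameters: derived-allele fraction, heterozygosity rate, missing
#'   rate.
#' @param afr_ancestral_share continent weight of Africa for ancestral and
#'   Mosaic haplotypes (rest shared equally); `afr_yin_share` likewise for
#'   Yin (small: Yin avoids Africa).
#' @param afr_yin_share see above.
#' @param spacing_bp base-pair spacing of planted variants.
#' @param window_bp window size the positions are laid out for (one
#'   segment per window).
#' @param chrom chromosome name.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_samples = c(AFR = 250, AMR = 250, ASN = 250,
                                       EUR = 250),
                         n_segments = 5,
                         scenarios = NULL,
                         yin_freq = 0.35, yang_freq = 0.25,
                         mosaic_freq = 0.08, single_ch_freq = 0.40,
                         ancestral_common_freq = 0.15,
                         n_rare_ancestral = 3,
                         d_yin = 28, mosaic_pieces = 14,
                         mosaic_derived = 12, mosaic_yin_derived = 10,
                         jumps = 0, epsilon = 0, x_fraction = 0.05,
                         p_alt_ancestral = 0.3,
                         archaic_derived = 0.18, archaic_het = 0.005,
                         archaic_missing = 0,
                         afr_ancestral_share = 0.7, afr_yin_share = 0.05,
                         spacing_bp = 1000, window_bp = 500000,
                         chrom = "1", seed = 1) {
  stopifnot(length(n_samples) >= 1, !is.null(names(n_samples)),
            all(n_samples >= 1), n_segments >= 1,
            yin_freq > 0, yang_freq > 0, yin_freq + yang_freq < 1,
            jumps >= 0, jumps <= 3, epsilon >= 0, epsilon < 0.04,
            x_fraction >= 0, x_fraction < 0.5,
            archaic_derived >= 0, archaic_derived <= 1,
            d_yin >= 1, d_yin <= 49)
  scenarios <- scenarios %||% c("yinyang", "yinyang_mosaic", "single_ch",
                                "ancestral_rich", "no_ch")
  stopifnot(all(scenarios %in% c("yinyang", "yinyang_mosaic", "single_ch",
                                 "ancestral_rich", "no_ch")))
  structure(as.list(environment()), class = "synth_config")
}

# alternating-block layout for a Mosaic with an exact minimal piece count.
# D marks positions where Yin carries the derived allele; labels Y/G say
# whether the Mosaic copies Yin or Yang there. Y blocks jointly hold
# exactly `mosaic_yin_derived` D positions; G blocks jointly hold exactly
# `mosaic_derived - mosaic_yin_derived` non-D positions (where Yang is the
# derived carrier).
#' @keywords internal
mosaic_layout <- function(pieces, d_yin, mosaic_derived, mosaic_yin_derived,
                          k = 50) {
  nY <- ceiling(pieces / 2); nG <- floor(pieces / 2)
  gD <- d_yin - mosaic_yin_derived          # D positions inside G blocks
  gA <- mosaic_derived - mosaic_yin_derived # non-D positions inside G blocks
  yD <- mosaic_yin_derived
  yA <- (k - d_yin) - gA
  if (min(gD, gA, yD, yA) < 0 || gD + gA < nG || yD + yA < nY ||
      pieces < 1 || pieces > k) {
    stop("unconstructible mosaic configuration: pieces=", pieces,
         ", d_yin=", d_yin, ", mosaic_derived=", mosaic_derived,
         ", mosaic_yin_derived=", mosaic_yin_derived)
  }
  fill <- function(n_blocks, nd, na) {
    # distribute nd 'D' and na 'A' symbols over n_blocks non-empty blocks
    blocks <- vector("list", n_blocks)
    sizes <- rep(0L, n_blocks)
    syms <- c(rep("D", nd), rep("A", na))
    for (i in seq_along(syms)) {
      b <- ((i - 1L) %% n_blocks) + 1L
      blocks[[b]] <- c(blocks[[b]], syms[i])
    }
    blocks
  }
  yblocks <- fill(nY, yD, yA)
  gblocks <- fill(nG, gD, gA)
  lab <- character(0); isD <- character(0)
  for (i in seq_len(max(nY, nG))) {
    if (i <= nY) { lab <- c(lab, rep("Y", length(yblocks[[i]])))
                   isD <- c(isD, yblocks[[i]]) }
    if (i <= nG) { lab <- c(lab, rep("G", length(gblocks[[i]])))
                   isD <- c(isD, gblocks[[i]]) }
  }
  stopifnot(length(lab) == k)
  list(label = lab, is_D = isD == "D")
}

# exhaustive minimal-piece count over all wildcard resolutions; used as a
# generation-time self-check (and cheap for few wildcards)
#' @keywords internal
min_pieces_exhaustive <- function(h, yin, yang) {
  hv <- utf8ToInt(h); yv <- utf8ToInt(yin); gv <- utf8ToInt(yang)
  lab <- ifelse(yv == gv, NA_integer_, ifelse(hv == yv, 1L, 2L))
  wild <- which(is.na(lab))
  runs <- function(x) if (!length(x)) 1L else
    1L + sum(x[-1L] != x[-length(x)])
  if (!length(wild)) return(runs(lab))
  best <- .Machine$integer.max
  for (mask in 0:(2^length(wild) - 1L)) {
    lab2 <- lab
    lab2[wild] <- 1L + bitwAnd(bitwShiftR(mask, seq_along(wild) - 1L), 1L)
    best <- min(best, runs(lab2))
  }
  best
}

#' Generate a synthetic phased cohort with planted ground truth
#'
#' Builds, per segment, an ancestral haplotype, a Yin haplotype carrying
#' `d_yin` derived alleles, its (near-)complementary Yang, optionally a
#' Mosaic whose minimal piece count is exactly as configured (self-checked
#' against an exhaustive decomposition at generation time), random
#' background haplotypes, and per-continent allocations with African
#' enrichment of ancestral/Mosaic haplotypes and African avoidance of Yin.
#' Every planted variant has minor allele frequency above 0.25 (asserted),
#' so the windowed segmentation recovers exactly one segment per window.
#'
#' @param cfg a [synth_config()].
#' @return list with `cohort` (a [phased_cohort]), `archaic` (an
#'   `archaic_diplotype` aligned to the cohort), and `truth`: a list with
#'   `segments` (data frame of planted strings, counts and piece numbers)
#'   and `detail` (per-segment list: scenario, class strings, statuses,
#'   per-continent allocation matrix).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  k <- 50L
  conts <- names(cfg$n_samples)
  n <- sum(cfg$n_samples)
  n_h <- 2L * n
  cont_of_sample <- rep(conts, times = cfg$n_samples)
  samples <- sprintf("%s%04d", cont_of_sample,
                     unlist(lapply(cfg$n_samples, seq_len)))
  panel <- data.frame(sample = samples,
                      population = paste0(cont_of_sample, "1"),
                      continent = cont_of_sample, stringsAsFactors = FALSE)
  hap_cont <- rep(cont_of_sample, each = 2L)
  cap0 <- as.integer(table(factor(hap_cont, levels = conts)))
  scen <- rep(cfg$scenarios, length.out = cfg$n_segments)
  S <- cfg$n_segments
  alleles <- matrix(0L, nrow = S * k, ncol = n_h)
  statuses_all <- character(S * k)
  archaic <- character(S * k)
  detail <- vector("list", S)
  seg_rows <- vector("list", S)
  other_share <- function(afr) {
    if (!"AFR" %in% conts || length(conts) == 1L) {
      return(stats::setNames(rep(1 / length(conts), length(conts)), conts))
    }
    w <- rep((1 - afr) / (length(conts) - 1), length(conts))
    names(w) <- conts
    w["AFR"] <- afr
    w
  }
  w_anc <- other_share(cfg$afr_ancestral_share)
  w_yin <- other_share(cfg$afr_yin_share)
  for (s in seq_len(S)) {
    rows <- ((s - 1L) * k + 1L):(s * k)
    anc_allele <- stats::rbinom(k, 1L, cfg$p_alt_ancestral)
    status_true <- ifelse(anc_allele == 0L, "R", "M")
    xmask <- stats::runif(k) < cfg$x_fraction
    statuses <- ifelse(xmask, "X", status_true)
    has_mosaic <- scen[s] == "yinyang_mosaic"
    if (has_mosaic) {
      lay <- mosaic_layout(cfg$mosaic_pieces, cfg$d_yin, cfg$mosaic_derived,
                           cfg$mosaic_yin_derived, k)
      yin_der <- as.integer(lay$is_D)
    } else {
      yin_der <- integer(k)
      yin_der[sample.int(k, cfg$d_yin)] <- 1L
    }
    yin_al <- bitwXor(anc_allele, yin_der)
    yang_al <- 1L - yin_al
    jump_pos <- integer(0)
    if (cfg$jumps > 0L) {
      cand <- if (has_mosaic) which(lay$label == "Y" & !lay$is_D)
              else which(yin_der == 0L)
      jump_pos <- cand[seq_len(min(cfg$jumps, length(cand)))]
      yang_al[jump_pos] <- yin_al[jump_pos]
    }
    mosaic_al <- NULL
    if (has_mosaic) {
      mosaic_al <- ifelse(lay$label == "Y", yin_al, yang_al)
      got <- min_pieces_exhaustive(paste(mosaic_al, collapse = ""),
                                   paste(yin_al, collapse = ""),
                                   paste(yang_al, collapse = ""))
      if (got != cfg$mosaic_pieces) {
        stop("mosaic self-check failed: planted layout decomposes into ",
             got, " pieces, expected ", cfg$mosaic_pieces)
      }
    }
    # class counts for this segment
    counts <- c(yin = 0L, yang = 0L, mosaic = 0L, ancestral = 0L)
    if (scen[s] %in% c("yinyang", "yinyang_mosaic", "ancestral_rich")) {
      counts["yin"] <- round((if (scen[s] == "ancestral_rich") 0.30
                              else cfg$yin_freq) * n_h)
      counts["yang"] <- round(cfg$yang_freq * n_h)
    }
    if (scen[s] == "yinyang_mosaic") {
      counts["mosaic"] <- round(cfg$mosaic_freq * n_h)
    }
    if (scen[s] == "single_ch") {
      counts["yin"] <- round(cfg$single_ch_freq * n_h)
    }
    counts["ancestral"] <- switch(scen[s],
      yinyang = , yinyang_mosaic = cfg$n_rare_ancestral,
      ancestral_rich = round(cfg$ancestral_common_freq * n_h), 0L)
    # continent allocation, classes placed in order of specificity
    capacity <- cap0
    alloc <- matrix(0L, nrow = 5L, ncol = length(conts),
                    dimnames = list(c("ancestral", "mosaic", "yin", "yang",
                                      "background"), conts))
    for (cls in c("ancestral", "mosaic", "yin", "yang")) {
      cnt <- counts[[if (cls == "ancestral") "ancestral" else cls]]
      if (cnt == 0L) next
      w <- switch(cls, ancestral = w_anc, mosaic = w_anc, yin = w_yin,
                  yang = rep(1 / length(conts), length(conts)))
      a <- apportion(cnt, w, capacity)
      alloc[cls, ] <- a
      capacity <- capacity - a
    }
    alloc["background", ] <- capacity
    # background alleles: per variant, a random permutation whose ones
    # count pulls the total allele frequency toward 1/2, so every planted
    # variant stays safely inside the frequent band whatever the scenario
    class_strings <- list(ancestral = anc_allele,
                          mosaic = mosaic_al,
                          yin = yin_al, yang = yang_al)
    planted_mass <- integer(k)
    for (cls in names(class_strings)) {
      tot <- sum(alloc[cls, ])
      if (tot > 0L) planted_mass <- planted_mass + tot * class_strings[[cls]]
    }
    bg_n <- sum(alloc["background", ])
    bg_ones <- pmin(pmax(round(n_h / 2) - planted_mass, 0L), bg_n)
    bg_mat <- matrix(0L, nrow = k, ncol = bg_n)
    for (i in seq_len(k)) {
      if (bg_ones[i] > 0L) {
        bg_mat[i, sample.int(bg_n, bg_ones[i])] <- 1L
      }
    }
    bg_at <- 0L
    for (ci in seq_along(conts)) {
      cols <- which(hap_cont == conts[ci])
      at <- 0L
      for (cls in rownames(alloc)) {
        cnt <- alloc[cls, ci]
        if (cnt == 0L) next
        use <- cols[(at + 1L):(at + cnt)]
        at <- at + cnt
        if (cls == "background") {
          alleles[rows, use] <- bg_mat[, bg_at + seq_len(cnt), drop = FALSE]
          bg_at <- bg_at + cnt
        } else {
          alleles[rows, use] <- class_strings[[cls]]
        }
      }
    }
    # archaic diplotype for this segment
    u <- stats::runif(k)
    arch <- character(k)
    miss <- u < cfg$archaic_missing
    het <- !miss & u < cfg$archaic_missing + cfg$archaic_het
    der <- !miss & !het &
      stats::runif(k) < cfg$archaic_derived
    arch[miss] <- "x"
    arch[het] <- "1"
    arch[!miss & !het] <- as.character(2L * anc_allele[!miss & !het])
    arch[der] <- as.character(2L * (1L - anc_allele[der]))
    archaic[rows] <- arch
    statuses_all[rows] <- statuses
    detail[[s]] <- list(segment = s, scenario = scen[s],
                        yin = paste(yin_al, collapse = ""),
                        yang = paste(yang_al, collapse = ""),
                        mosaic = if (has_mosaic)
                          paste(mosaic_al, collapse = "") else NA_character_,
                        pieces = if (has_mosaic) cfg$mosaic_pieces
                                 else NA_integer_,
                        ancestral_allele = paste(anc_allele, collapse = ""),
                        statuses = statuses, allocation = alloc,
                        jump_positions = jump_pos)
    seg_rows[[s]] <- data.frame(
      segment = s, scenario = scen[s],
      yin = detail[[s]]$yin, yang = detail[[s]]$yang,
      mosaic = detail[[s]]$mosaic, pieces = detail[[s]]$pieces,
      yin_count = counts[["yin"]], yang_count = counts[["yang"]],
      mosaic_count = counts[["mosaic"]],
      ancestral_count = counts[["ancestral"]], stringsAsFactors = FALSE)
  }
  if (cfg$epsilon > 0) {
    flips <- matrix(stats::rbinom(length(alleles), 1L, cfg$epsilon) == 1L,
                    nrow = nrow(alleles))
    alleles[flips] <- 1L - alleles[flips]
  }
  pos <- as.integer(rep((seq_len(S) - 1L) * cfg$window_bp, each = k) +
                    cfg$spacing_bp * rep(seq_len(k), S))
  records <- data.frame(
    chrom = cfg$chrom, pos = pos,
    vid = sprintf("s%03d_v%02d", rep(seq_len(S), each = k),
                  rep(seq_len(k), S)),
    ref = "A", alt = "G", aa_status = statuses_all,
    alt_count = as.integer(rowSums(alleles)), stringsAsFactors = FALSE)
  f <- records$alt_count / n_h
  if (any(pmin(f, 1 - f) <= 0.25)) {
    stop("planted variant fails the frequent-variant threshold; ",
         "check frequency settings")
  }
  cohort <- phased_cohort(records, alleles, samples, panel,
                          continent_order = conts)
  list(cohort = cohort,
       archaic = structure(archaic, class = "archaic_diplotype"),
       truth = list(segments = do.call(rbind, seg_rows), detail = detail),
       config = cfg)
}

#' Write a synthetic cohort to standard files
#'
#' @param synth a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named list of paths (`vcf`, `panel`, `archaic_vcf`, `truth`),
#'   invisibly.
#' @export
write_synth <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                panel = file.path(dir, "panel.tsv"),
                archaic_vcf = file.path(dir, "archaic.vcf"),
                truth = file.path(dir, "truth_segments.tsv"))
  write_phased_vcf(synth$cohort, paths$vcf)
  write_panel(synth$cohort$panel, paths$panel)
  write_archaic_vcf(synth$archaic, synth$cohort, paths$archaic_vcf)
  utils::write.table(synth$truth$segments, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write the tiny deterministic toy fixture
#'
#' A hand-written byte-stable fixture (6 usable variants, one triallelic
#' record, 3 samples, an archaic file) used for exact input/output and
#' windowing assertions.
#'
#' @param dir output directory.
#' @return named list of paths (`vcf`, `panel`, `archaic_vcf`).
#' @export
generate_toy_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\tv1\tA\tG\t.\tPASS\tAA=A\tGT\t0|0\t0|1\t1|1",
    "1\t200\tv2\tC\tT\t.\tPASS\tAA=t\tGT\t0|1\t0|1\t0|1",
    "1\t300\tv3\tG\tA,T\t.\tPASS\tAA=G\tGT\t0|1\t0|2\t0|0",
    "1\t400\tv4\tT\tC\t.\tPASS\tAA=.\tGT\t1|0\t0|0\t0|1",
    "1\t500\tv5\tA\tAC\t.\tPASS\tDP=3\tGT\t0|0\t1|1\t0|0",
    "1\t600\tv6\tG\tC\t.\tPASS\tAA=T\tGT\t1|1\t1|1\t0|1")
  panel <- c("S1\tYRI\tAFR", "S2\tCEU\tEUR", "S3\tCHB\tASN")
  arch <- c(
    "##fileformat=VCFv4.1",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tD1",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t1/1",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0/0",
    "1\t400\tv4\tT\tC\t.\tPASS\t.\tGT\t0/1",
    "1\t600\tv6\tG\tC\t.\tPASS\t.\tGT\t./.",
    "1\t700\tv7\tA\tT\t.\tPASS\t.\tGT\t1/1")
  paths <- list(vcf = file.path(dir, "toy.vcf"),
                panel = file.path(dir, "toy_panel.tsv"),
                archaic_vcf = file.path(dir, "toy_archaic.vcf"))
  writeLines(vcf, paths$vcf)
  writeLines(panel, paths$panel)
  writeLines(arch, paths$archaic_vcf)
  paths
}
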
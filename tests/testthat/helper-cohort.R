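# Shared fixture builders: small cohorts constructed in code.

# cohort from an allele matrix (variants x 2n); samples get round-robin
# continents unless a panel is supplied
make_test_cohort <- function(alleles, pos = NULL, chrom = "1",
                             statuses = NULL, panel = NULL,
                             continent_order = NULL) {
  storage.mode(alleles) <- "integer"
  nv <- nrow(alleles)
  n <- ncol(alleles) / 2L
  stopifnot(ncol(alleles) %% 2L == 0L)
  pos <- pos %||% (seq_len(nv) * 1000L)
  statuses <- statuses %||% rep("X", nv)
  samples <- sprintf("S%03d", seq_len(n))
  if (is.null(panel)) {
    conts <- rep(c("AFR", "EUR", "ASN"), length.out = n)
    panel <- data.frame(sample = samples, population = paste0(conts, "1"),
                        continent = conts, stringsAsFactors = FALSE)
  }
  records <- data.frame(chrom = chrom, pos = as.integer(pos),
                        vid = sprintf("v%04d", seq_len(nv)),
                        ref = "A", alt = "G", aa_status = statuses,
                        alt_count = as.integer(rowSums(alleles)),
                        stringsAsFactors = FALSE)
  phased_cohort(records, alleles, samples, panel, continent_order)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random haplotype string of length k
rand_hap <- function(k) paste(sample(0:1, k, replace = TRUE), collapse = "")

# flip given (1-based) positions of a {0,1} string
flip_at <- function(h, at) {
  v <- as.integer(strsplit(h, "")[[1L]])
  v[at] <- 1L - v[at]
  paste(v, collapse = "")
}

complement_hap <- function(h) {
  chartr("01", "10", h)
}

# independent reference implementation of the grouping rule, written
# directly from its definition (exact counting; distinct strings in
# (count desc, lexicographic asc) order; first group whose representative
# is within max_diff; else new group)
oracle_group <- function(haps, max_diff = 2) {
  tab <- table(haps)
  d <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, d)
  d <- d[ord]; cnt <- cnt[ord]
  reps <- character(0)
  grp <- integer(length(d))
  for (i in seq_along(d)) {
    found <- 0L
    for (g in seq_along(reps)) {
      if (hamming(d[i], reps[g]) <= max_diff) { found <- g; break }
    }
    if (found == 0L) { reps <- c(reps, d[i]); found <- length(reps) }
    grp[i] <- found
  }
  counts <- vapply(seq_along(reps), function(g) sum(cnt[grp == g]), 0L)
  ord2 <- order(-counts, reps)
  list(representative = reps[ord2], count = counts[ord2])
}

# independent exhaustive minimal-piece oracle: enumerate every wildcard
# resolution, count label runs, take the minimum
oracle_min_pieces <- function(h, yin, yang) {
  hv <- strsplit(h, "")[[1L]]
  yv <- strsplit(yin, "")[[1L]]
  gv <- strsplit(yang, "")[[1L]]
  lab <- character(length(hv))
  for (i in seq_along(hv)) {
    my <- hv[i] == yv[i]; mg <- hv[i] == gv[i]
    lab[i] <- if (my && !mg) "Y" else if (mg && !my) "G" else "W"
  }
  wild <- which(lab == "W")
  count_runs <- function(l) {
    l <- l[l != "W"]
    if (!length(l)) return(1L)
    1L + sum(l[-1L] != l[-length(l)])
  }
  if (!length(wild)) return(count_runs(lab))
  best <- Inf
  for (m in 0:(2^length(wild) - 1)) {
    l2 <- lab
    bits <- as.integer(intToBits(m))[seq_along(wild)]
    l2[wild] <- ifelse(bits == 1L, "Y", "G")
    best <- min(best, count_runs(l2))
  }
  as.integer(best)
}
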
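# Forward-time diploid simulator: infinite-sites mutation on an abstract
# genome of length L, exactly-r crossover recombination per gamete,
# permanent-pair mating within each generation, and truncation selection
# (the alpha*N/2 offspring are ranked by multiplicative fitness and the top
# N survive; alpha = 2 means no selection). Haplotypes are sets of mutation
# ids; a per-run registry records each mutation's position, selection
# coefficient, origin generation and fate.

#' Simulation configuration
#'
#' @param N diploid population size (even; constant across generations).
#' @param mu mean novel mutations per gamete (Poisson).
#' @param r crossovers per gamete (exact count, uniform positions).
#' @param alpha offspring per mating pair; 2 reproduces the population
#'   exactly (no selection), larger values enable truncation selection.
#' @param h dominance coefficient (default 0.5, co-dominant).
#' @param effect_mix probabilities of mutation classes, named
#'   `deleterious`, `beneficial`, `neutral` (default 81%/9%/10%); use
#'   `c(deleterious = 0, beneficial = 0, neutral = 1)` for neutral runs.
#' @param s_del_mean,s_ben_mean mean effect magnitudes (exponential).
#' @param L genome length in abstract units (default 1).
#' @param generations number of generations to simulate.
#' @param burn_in generations excluded from reported statistics.
#' @param seed integer seed; every run is fully reproducible from it.
#' @param max_segregating guard against runaway memory: the run stops with
#'   an error if the segregating-site count exceeds this cap.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(N, mu, r = 0, alpha = 2, h = 0.5,
                       effect_mix = c(deleterious = 0.81, beneficial = 0.09,
                                      neutral = 0.10),
                       s_del_mean = 1e-3, s_ben_mean = 1e-3, L = 1,
                       generations = 0, burn_in = 0, seed = NULL,
                       max_segregating = 5e6) {
  if (N %% 2L != 0L) stop("N must be even (permanent-pair mating)")
  stopifnot(N >= 2, mu >= 0, r >= 0, alpha >= 2, h >= 0, h <= 1, L > 0,
            generations >= 0, burn_in >= 0, burn_in <= generations)
  effect_mix <- effect_mix[c("deleterious", "beneficial", "neutral")]
  if (any(is.na(effect_mix)) || abs(sum(effect_mix) - 1) > 1e-9) {
    stop("effect_mix must be named probabilities summing to 1")
  }
  structure(list(N = as.integer(N), mu = mu, r = as.integer(r),
                 alpha = as.integer(alpha), h = h, effect_mix = effect_mix,
                 s_del_mean = s_del_mean, s_ben_mean = s_ben_mean, L = L,
                 generations = as.integer(generations),
                 burn_in = as.integer(burn_in), seed = seed,
                 max_segregating = max_segregating),
            class = "sim_config")
}

# mutation registry: growable parallel vectors in an environment.
# fate codes: 0 segregating, 1 fixed, 2 lost.
#' @keywords internal
new_registry <- function(cap = 65536L) {
  reg <- new.env(parent = baseenv())
  reg$pos <- numeric(cap); reg$s <- numeric(cap)
  reg$origin <- integer(cap); reg$fate <- integer(cap)
  reg$loss_gen <- integer(cap); reg$fix_gen <- integer(cap)
  reg$n <- 0L; reg$cap <- cap
  reg
}

#' @keywords internal
reg_clone <- function(reg) {
  out <- new_registry(reg$cap)
  for (f in c("pos", "s", "origin", "fate", "loss_gen", "fix_gen", "n", "cap"))
    assign(f, get(f, envir = reg), envir = out)
  out
}

#' @keywords internal
reg_grow <- function(reg, need) {
  while (reg$cap < need) {
    extra <- reg$cap
    reg$pos <- c(reg$pos, numeric(extra)); reg$s <- c(reg$s, numeric(extra))
    reg$origin <- c(reg$origin, integer(extra))
    reg$fate <- c(reg$fate, integer(extra))
    reg$loss_gen <- c(reg$loss_gen, integer(extra))
    reg$fix_gen <- c(reg$fix_gen, integer(extra))
    reg$cap <- reg$cap + extra
  }
  invisible(reg)
}

# register k new mutations arisen at generation `gen`; returns their ids.
# Field updates run inside the registry environment so R's reference
# counting can modify the (unshared) vectors in place instead of copying
# them on every call.
#' @keywords internal
reg_add <- function(reg, k, gen, cfg) {
  if (k == 0L) return(integer(0))
  reg_grow(reg, reg$n + k)
  ids <- reg$n + seq_len(k)
  type <- sample.int(3L, k, replace = TRUE, prob = cfg$effect_mix)
  sval <- numeric(k)
  ndel <- sum(type == 1L); nben <- sum(type == 2L)
  if (ndel) sval[type == 1L] <- stats::rexp(ndel, 1 / cfg$s_del_mean)
  if (nben) sval[type == 2L] <- -stats::rexp(nben, 1 / cfg$s_ben_mean)
  reg$.ids <- ids
  reg$.pos <- stats::runif(k, 0, cfg$L)
  reg$.s <- sval
  reg$.gen <- as.integer(gen)
  evalq({
    pos[.ids] <- .pos
    s[.ids] <- .s
    origin[.ids] <- .gen
    fate[.ids] <- 0L
  }, reg)
  reg$n <- reg$n + k
  ids
}

# in-place fate updates
#' @keywords internal
reg_mark_fixed <- function(reg, ids, gen) {
  reg$.ids <- ids; reg$.gen <- as.integer(gen)
  evalq({ fate[.ids] <- 1L; fix_gen[.ids] <- .gen }, reg)
}

#' @keywords internal
reg_mark_lost <- function(reg, ids, gen) {
  reg$.ids <- ids; reg$.gen <- as.integer(gen)
  evalq({ fate[.ids] <- 2L; loss_gen[.ids] <- .gen }, reg)
}

#' Registry as a data frame
#'
#' @param sim a `sim_result` (or a registry environment).
#' @return data frame with `id`, `position`, `s`, `origin`, `fate`
#'   (`"segregating"`, `"fixed"`, `"lost"`), `fix_gen`, `loss_gen`.
#' @export
registry_table <- function(sim) {
  reg <- if (is.environment(sim)) sim else sim$registry
  n <- reg$n
  data.frame(id = seq_len(n), position = reg$pos[seq_len(n)],
             s = reg$s[seq_len(n)], origin = reg$origin[seq_len(n)],
             fate = c("segregating", "fixed", "lost")[reg$fate[seq_len(n)] + 1L],
             fix_gen = ifelse(reg$fate[seq_len(n)] == 1L,
                              reg$fix_gen[seq_len(n)], NA_integer_),
             loss_gen = ifelse(reg$fate[seq_len(n)] == 2L,
                               reg$loss_gen[seq_len(n)], NA_integer_))
}

#' Make one gamete from a parent
#'
#' Draws exactly `r` crossover points uniformly on `[0, L)`, alternates the
#' source haplotype between consecutive intervals starting from a random
#' one, then adds `Poisson(mu)` novel mutations at fresh uniform positions
#' (registered in `reg` with effects drawn from the configured mix). With
#' zero crossovers the gamete is one parental haplotype, intact apart from
#' new mutations.
#'
#' @param parent list of two haplotypes (integer vectors of mutation ids).
#' @param cfg a [sim_config()].
#' @param reg registry environment (from an ongoing run); a fresh one is
#'   created when omitted.
#' @param gen generation stamp for new mutations.
#' @return integer vector of mutation ids.
#' @export
make_gamete <- function(parent, cfg, reg = new_registry(), gen = 0L) {
  gam <- recombine(parent[[1L]], parent[[2L]], reg$pos, cfg$r, cfg$L)
  k <- stats::rpois(1L, cfg$mu)
  if (k > 0L) gam <- c(gam, reg_add(reg, k, gen, cfg))
  gam
}

# crossover only: exactly r uniform breakpoints, alternating source
#' @keywords internal
recombine <- function(h1, h2, posvec, r, L) {
  if (r > 0L) {
    br <- sort(stats::runif(r, 0, L))
    s0 <- sample.int(2L, 1L) - 1L
    take1 <- (findInterval(posvec[h1], br) + s0) %% 2L == 0L
    take2 <- (findInterval(posvec[h2], br) + s0) %% 2L == 1L
    c(h1[take1], h2[take2])
  } else {
    if (stats::runif(1) < 0.5) h1 else h2
  }
}

#' Multiplicative fitness of a diploid individual
#'
#' The fitness is the product over carried mutations of `(1 - h*s)` for
#' heterozygous and `(1 - s)` for homozygous mutations (beneficial
#' mutations have negative `s`, raising fitness), clipped below at 0.
#'
#' @param ind list of two haplotypes (mutation-id vectors).
#' @param reg registry environment holding per-mutation `s`.
#' @param h dominance coefficient.
#' @return non-negative fitness value.
#' @export
fitness <- function(ind, reg, h = 0.5) {
  ids <- c(ind[[1L]], ind[[2L]])
  if (!length(ids)) return(1)
  sv <- reg$s[ids]
  nz <- sv != 0
  if (!any(nz)) return(1)
  ids <- ids[nz]
  hom <- unique(ids[duplicated(ids)])
  het <- setdiff(unique(ids), hom)
  w <- prod(1 - h * reg$s[het]) * prod(1 - reg$s[hom])
  max(w, 0)
}

# one generation: permanent pairs, alpha offspring per pair, truncation
# selection of the top N offspring. Returns the new population (list of 2N
# haplotypes; offspring i holds columns 2i-1, 2i) plus bookkeeping.
#' @keywords internal
next_generation <- function(pop, reg, cfg, gen) {
  N <- cfg$N
  stopifnot(length(pop) == 2L * N)
  perm <- sample.int(N)
  n_off <- cfg$alpha * N %/% 2L
  # batch-register this generation's novel mutations (one registry append)
  nnew <- stats::rpois(2L * n_off, cfg$mu)
  new_ids <- reg_add(reg, sum(nnew), gen, cfg)
  ends <- cumsum(nnew)
  slice <- function(g) if (nnew[g] > 0L)
    new_ids[(ends[g] - nnew[g] + 1L):ends[g]] else integer(0)
  posvec <- reg$pos
  gam1 <- vector("list", n_off); gam2 <- vector("list", n_off)
  oi <- 0L
  influx0 <- reg$n - length(new_ids)
  for (p in seq_len(N %/% 2L)) {
    i1 <- perm[2L * p - 1L]; i2 <- perm[2L * p]
    h1a <- pop[[2L * i1 - 1L]]; h1b <- pop[[2L * i1]]
    h2a <- pop[[2L * i2 - 1L]]; h2b <- pop[[2L * i2]]
    for (o in seq_len(cfg$alpha)) {
      oi <- oi + 1L
      gam1[[oi]] <- c(recombine(h1a, h1b, posvec, cfg$r, cfg$L),
                      slice(2L * oi - 1L))
      gam2[[oi]] <- c(recombine(h2a, h2b, posvec, cfg$r, cfg$L),
                      slice(2L * oi))
    }
  }
  if (cfg$alpha > 2L) {
    w <- vapply(seq_len(n_off),
                function(i) fitness(list(gam1[[i]], gam2[[i]]), reg, cfg$h),
                0)
    keep <- order(-w, sample.int(n_off))[seq_len(N)]
  } else {
    keep <- seq_len(N)
  }
  newpop <- vector("list", 2L * N)
  newpop[seq(1L, 2L * N, by = 2L)] <- gam1[keep]
  newpop[seq(2L, 2L * N, by = 2L)] <- gam2[keep]
  list(pop = newpop, influx = reg$n - influx0)
}

#' Run the forward simulation
#'
#' Starts from a mutation-free population (or from `init`) and simulates
#' `cfg$generations` generations. After each generation the registry is
#' updated: mutations reaching `2N` copies are recorded as fixed and
#' removed from all genomes (they join the monomorphic background),
#' mutations at 0 copies are recorded as lost. Per-generation statistics
#' are reported for generations after `cfg$burn_in`. Identical
#' configuration and seed give bit-identical results.
#'
#' @param cfg a [sim_config()].
#' @param init optional state to continue from: a previous `sim_result`
#'   (or a list with `pop`, `registry`, `seg_ids`, `gen`). The registry is
#'   cloned, so the initial state is not mutated.
#' @param seed overrides `cfg$seed`.
#' @return object of class `sim_result`: list with `stats` (per-generation
#'   data frame: `gen`, `influx`, `fixations`, `losses`, `segregating`,
#'   `frequent`), `pop`, `registry`, `seg_ids`, `fixed_ids` (ids fixed
#'   during this run), `gen` (final generation), `final_counts` (copy
#'   counts of segregating mutations) and `cfg`.
#' @export
run_sim <- function(cfg, init = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  twoN <- 2L * cfg$N
  if (is.null(init)) {
    pop <- replicate(twoN, integer(0), simplify = FALSE)
    reg <- new_registry()
    seg_ids <- integer(0)
    gen0 <- 0L
  } else {
    pop <- init$pop
    reg <- reg_clone(init$registry)
    seg_ids <- init$seg_ids
    gen0 <- init$gen %||% 0L
    stopifnot(length(pop) == twoN)
  }
  gens <- cfg$generations
  stats_gen <- integer(gens); stats_influx <- integer(gens)
  stats_fix <- integer(gens); stats_loss <- integer(gens)
  stats_seg <- integer(gens); stats_freq <- integer(gens)
  fixed_all <- integer(0)
  for (g in seq_len(gens)) {
    gen <- gen0 + g
    step <- next_generation(pop, reg, cfg, gen)
    pop <- step$pop
    new_ids <- if (step$influx > 0L)
      (reg$n - step$influx + 1L):reg$n else integer(0)
    cnt <- tabulate(unlist(pop, use.names = FALSE), nbins = reg$n)
    cand <- c(seg_ids, new_ids)
    cc <- cnt[cand]
    fixed <- cand[cc == twoN]
    lost <- cand[cc == 0L]
    if (length(fixed)) {
      reg_mark_fixed(reg, fixed, gen)
      pop <- lapply(pop, function(h) h[!(h %in% fixed)])
      fixed_all <- c(fixed_all, fixed)
    }
    if (length(lost)) {
      reg_mark_lost(reg, lost, gen)
    }
    seg_ids <- cand[cc > 0L & cc < twoN]
    if (length(seg_ids) > cfg$max_segregating) {
      stop("segregating-site count (", length(seg_ids),
           ") exceeded max_segregating (", cfg$max_segregating,
           "); reduce N, mu or generations, or raise the cap")
    }
    stats_gen[g] <- gen; stats_influx[g] <- step$influx
    stats_fix[g] <- length(fixed); stats_loss[g] <- length(lost)
    stats_seg[g] <- length(seg_ids)
    fc <- cnt[seg_ids]
    stats_freq[g] <- sum(fc > 0.25 * twoN & fc < 0.75 * twoN)
  }
  observe <- if (gens > cfg$burn_in) seq.int(cfg$burn_in + 1L, gens)
             else integer(0)
  stats <- data.frame(gen = stats_gen, influx = stats_influx,
                      fixations = stats_fix, losses = stats_loss,
                      segregating = stats_seg, frequent = stats_freq)[observe, ]
  rownames(stats) <- NULL
  final_counts <- if (length(seg_ids))
    tabulate(unlist(pop, use.names = FALSE), nbins = reg$n)[seg_ids]
    else integer(0)
  structure(list(stats = stats, pop = pop, registry = reg,
                 seg_ids = seg_ids, fixed_ids = fixed_all,
                 gen = gen0 + gens, final_counts = final_counts, cfg = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> N=", x$cfg$N, " mu=", x$cfg$mu, " r=", x$cfg$r,
      " alpha=", x$cfg$alpha, "; ", x$gen, " generation(s)\n", sep = "")
  cat("  segregating: ", length(x$seg_ids),
      "  fixed this run: ", length(x$fixed_ids), "\n", sep = "")
  if (nrow(x$stats)) {
    cat("  mean fixations/gen (observed window): ",
        round(mean(x$stats$fixations), 3), "\n", sep = "")
  }
  invisible(x)
}

#' Derived-allele site frequency spectrum of the final population
#'
#' @param sim a `sim_result`.
#' @return integer vector `sfs` where `sfs[i]` is the number of
#'   segregating mutations present in `i` of the `2N` haplotypes.
#' @export
sim_sfs <- function(sim) {
  tabulate(sim$final_counts, nbins = 2L * sim$cfg$N - 1L)
}

#' Fraction of new mutations lost soon after origin
#'
#' For mutation cohorts originating in `[from, to]`, the fraction whose
#' lineage is recorded lost within `within` generations of origin.
#'
#' @param sim a `sim_result`.
#' @param within generations after origin (default 3).
#' @param from,to origin-generation window (defaults: the observed window,
#'   truncated so every cohort has `within` full generations of follow-up).
#' @return fraction in `[0,1]`.
#' @export
early_loss_fraction <- function(sim, within = 3, from = NULL, to = NULL) {
  reg <- sim$registry
  n <- reg$n
  from <- from %||% (sim$cfg$burn_in + 1L)
  to <- to %||% (sim$gen - within)
  org <- reg$origin[seq_len(n)]
  sel <- org >= from & org <= to
  if (!any(sel)) stop("no mutation cohorts in the requested window")
  lost <- reg$fate[seq_len(n)][sel] == 2L &
    (reg$loss_gen[seq_len(n)][sel] - org[sel]) <= within
  mean(lost)
}

#' Haplotype-architecture statistics of a simulated population
#'
#' Converts the population's frequent segregating mutations (minor allele
#' frequency above `maf`) into positional haplotype strings, cuts them into
#' consecutive non-overlapping blocks of `k`, and runs the common-haplotype
#' / Yin-Yang classification on every block with the frequency threshold
#' convention (`min_freq`, default 5%).
#'
#' @param sim a `sim_result` (or a list with `pop` and `registry`).
#' @param maf frequent-variant threshold (default 0.25, strict).
#' @param k variants per block (default 50).
#' @param min_freq common-haplotype frequency threshold (default 0.05).
#' @param max_intra_diff grouping tolerance (default 2).
#' @param min_diff Yin/Yang threshold (default 47).
#' @return list with `n_frequent`, `n_segments`, `pct_ch`, `pct_yinyang`
#'   (percentages of blocks with at least one CH / at least one Yin-Yang
#'   pair) and `per_segment` (data frame: `segment`, `n_ch`,
#'   `n_yinyang_pairs`).
#' @export
analyze_population <- function(sim, maf = 0.25, k = 50, min_freq = 0.05,
                               max_intra_diff = 2, min_diff = 47) {
  pop <- sim$pop; reg <- sim$registry
  twoN <- length(pop)
  cnt <- tabulate(unlist(pop, use.names = FALSE), nbins = reg$n)
  freq_ids <- which(cnt > maf * twoN & cnt < (1 - maf) * twoN)
  freq_ids <- freq_ids[order(reg$pos[freq_ids])]
  nf <- length(freq_ids)
  n_seg <- nf %/% k
  if (n_seg == 0L) {
    return(list(n_frequent = nf, n_segments = 0L, pct_ch = NA_real_,
                pct_yinyang = NA_real_,
                per_segment = data.frame(segment = integer(0),
                                         n_ch = integer(0),
                                         n_yinyang_pairs = integer(0))))
  }
  used <- freq_ids[seq_len(n_seg * k)]
  # membership matrix: frequent variants x haplotypes
  memb <- matrix(0L, nrow = length(used), ncol = twoN)
  for (j in seq_len(twoN)) {
    hit <- match(pop[[j]], used)
    hit <- hit[!is.na(hit)]
    if (length(hit)) memb[hit, j] <- 1L
  }
  n_ch <- integer(n_seg); n_pairs <- integer(n_seg)
  for (sgi in seq_len(n_seg)) {
    rows <- ((sgi - 1L) * k + 1L):(sgi * k)
    haps <- apply(memb[rows, , drop = FALSE], 2L,
                  function(col) paste(col, collapse = ""))
    chs <- common_haplotypes(group_haplotypes(haps, max_intra_diff),
                             min_freq = min_freq)
    n_ch[sgi] <- length(chs$representative)
    n_pairs[sgi] <- nrow(find_yinyang(chs, min_diff))
  }
  list(n_frequent = nf, n_segments = n_seg,
       pct_ch = 100 * mean(n_ch >= 1L),
       pct_yinyang = 100 * mean(n_pairs >= 1L),
       per_segment = data.frame(segment = seq_len(n_seg), n_ch = n_ch,
                                n_yinyang_pairs = n_pairs))
}

#' Two-population admixture experiment with panmictic control
#'
#' Evolves one founder population for `burn_in` generations, duplicates it,
#' evolves the two copies independently for `t_split` generations, then
#' merges them at proportions (`mix`, `1 - mix`) into a population of size
#' `N`. Mutations fixed privately within a lineage during the separation
#' rejoin the merged genomes (they are variants of the merged population).
#' A control population is the same founder evolved for `t_split` further
#' generations (the same total number of generations). Both populations are
#' analyzed with [analyze_population()].
#'
#' @param cfg a [sim_config()]; `cfg$generations` is ignored in favour of
#'   `burn_in`/`t_split`, `cfg$seed` seeds the whole experiment.
#' @param t_split generations of independent evolution after the split.
#' @param mix fraction of the merged population drawn from lineage A.
#' @param burn_in founder generations before the split (default
#'   `cfg$burn_in`).
#' @param ... passed to [analyze_population()].
#' @return list with `admixed` and `control` (each an
#'   [analyze_population()] result), `n_fixed_a`/`n_fixed_b` and
#'   `fixed_ids_a`/`fixed_ids_b` (mutations fixed per lineage during the
#'   separation), `merged_pop` and `merged_registry` (for registry
#'   accounting), and `control_n_frequent`.
#' @export
admixture_experiment <- function(cfg, t_split, mix = 0.5, burn_in = NULL,
                                 ...) {
  stopifnot(inherits(cfg, "sim_config"), t_split >= 0, mix > 0, mix < 1)
  burn_in <- burn_in %||% cfg$burn_in
  seed <- cfg$seed %||% 1L
  base <- sim_config(N = cfg$N, mu = cfg$mu, r = cfg$r, alpha = cfg$alpha,
                     h = cfg$h, effect_mix = cfg$effect_mix,
                     s_del_mean = cfg$s_del_mean, s_ben_mean = cfg$s_ben_mean,
                     L = cfg$L, generations = burn_in,
                     max_segregating = cfg$max_segregating)
  founder <- run_sim(base, seed = seed)
  split_cfg <- base; split_cfg$generations <- as.integer(t_split)
  lineage_a <- run_sim(split_cfg, init = founder, seed = seed + 1L)
  # lineage B restarts from the founder state but must draw fresh mutation
  # ids: clone A's final registry (superset of ids) and reopen the founder's
  # segregating mutations
  reg_b <- reg_clone(lineage_a$registry)
  reg_b$fate[founder$seg_ids] <- 0L
  init_b <- list(pop = founder$pop, registry = reg_b,
                 seg_ids = founder$seg_ids, gen = founder$gen)
  lineage_b <- run_sim(split_cfg, init = init_b, seed = seed + 2L)
  control <- run_sim(split_cfg, init = founder, seed = seed + 3L)
  # merge: per-lineage private fixations rejoin the genomes
  set.seed(seed + 4L)
  n_a <- round(mix * cfg$N)
  pick_a <- sample.int(cfg$N, n_a)
  pick_b <- sample.int(cfg$N, cfg$N - n_a)
  take_ind <- function(pop, i) pop[c(2L * i - 1L, 2L * i)]
  merged <- vector("list", 2L * cfg$N)
  oi <- 0L
  for (i in pick_a) {
    merged[oi + 1:2] <- lapply(take_ind(lineage_a$pop, i),
                               function(h) c(h, lineage_a$fixed_ids))
    oi <- oi + 2L
  }
  for (i in pick_b) {
    merged[oi + 1:2] <- lapply(take_ind(lineage_b$pop, i),
                               function(h) c(h, lineage_b$fixed_ids))
    oi <- oi + 2L
  }
  adm <- analyze_population(list(pop = merged, registry = lineage_b$registry),
                            ...)
  ctl <- analyze_population(control, ...)
  list(admixed = adm, control = ctl,
       n_fixed_a = length(lineage_a$fixed_ids),
       n_fixed_b = length(lineage_b$fixed_ids),
       fixed_ids_a = lineage_a$fixed_ids, fixed_ids_b = lineage_b$fixed_ids,
       merged_pop = merged, merged_registry = lineage_b$registry,
       control_n_frequent = ctl$n_frequent)
}
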
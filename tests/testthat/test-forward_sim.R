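neutral_mix <- c(deleterious = 0, beneficial = 0, neutral = 1)

test_that("simulation configuration validates its invariants", {
  expect_error(sim_config(N = 99, mu = 1), "even")
  expect_error(sim_config(N = 10, mu = 1, alpha = 1), "alpha")
  expect_error(sim_config(N = 10, mu = 1,
                          effect_mix = c(deleterious = 0.5, beneficial = 0.5,
                                         neutral = 0.5)), "effect_mix")
  cfg <- sim_config(N = 10, mu = 1, generations = 5)
  expect_s3_class(cfg, "sim_config")
})

test_that("gametes preserve parental haplotypes without recombination or mutation", {
  cfg <- sim_config(N = 2, mu = 0, r = 0)
  reg <- yyhap:::new_registry()
  ids <- yyhap:::reg_add(reg, 10L, 0L, cfg)
  h1 <- ids[1:4]; h2 <- ids[5:10]
  set.seed(1)
  for (i in 1:10) {
    g <- make_gamete(list(h1, h2), cfg, reg)
    expect_true(identical(g, h1) || identical(g, h2))
  }
  # with r > 0 every output id comes from one of the parents
  cfg2 <- sim_config(N = 2, mu = 0, r = 3)
  for (i in 1:10) {
    g <- make_gamete(list(h1, h2), cfg2, reg)
    expect_true(all(g %in% c(h1, h2)))
    expect_false(any(duplicated(g)))
  }
})

test_that("mutation influx is Poisson with the configured per-gamete mean", {
  cfg <- sim_config(N = 2, mu = 5, r = 0)
  reg <- yyhap:::new_registry()
  set.seed(2)
  k <- vapply(1:2000, function(i)
    length(make_gamete(list(integer(0), integer(0)), cfg, reg)), 0L)
  expect_equal(mean(k), 5, tolerance = 0.05)
  expect_equal(var(k), 5, tolerance = 0.15)
})

test_that("fitness is multiplicative with dominance 0.5", {
  cfg <- sim_config(N = 2, mu = 0)
  reg <- yyhap:::new_registry()
  yyhap:::reg_grow(reg, 10L)
  reg$n <- 10L
  reg$s[1:10] <- 0
  expect_equal(fitness(list(integer(0), integer(0)), reg), 1)
  reg$s[1] <- 0.01
  expect_equal(fitness(list(1L, integer(0)), reg, h = 0.5), 0.995)
  expect_equal(fitness(list(1L, 1L), reg, h = 0.5), 0.99)
  # several mutations: product formula against a log-sum recomputation
  set.seed(4)
  reg$s[1:10] <- runif(10, -0.05, 0.05)
  h1 <- c(1L, 2L, 3L, 7L); h2 <- c(2L, 5L, 7L)
  w <- fitness(list(h1, h2), reg, h = 0.5)
  het <- c(1L, 3L, 5L); hom <- c(2L, 7L)
  w_ref <- exp(sum(log(1 - 0.5 * reg$s[het])) + sum(log(1 - reg$s[hom])))
  expect_equal(w, w_ref)
  # beneficial mutations raise fitness above 1
  reg$s[1:10] <- -0.01
  expect_gt(fitness(list(1L, integer(0)), reg), 1)
})

test_that("population size is conserved and lethal carriers are purged", {
  cfg <- sim_config(N = 20, mu = 1, r = 1, alpha = 2,
                    effect_mix = neutral_mix, generations = 30, seed = 5)
  sim <- run_sim(cfg)
  expect_length(sim$pop, 40L)
  expect_equal(nrow(sim$stats), 30L)
  # strong truncation selection removes a planted lethal
  cfg2 <- sim_config(N = 20, mu = 0, r = 0, alpha = 10, seed = 6,
                     generations = 0)
  reg <- yyhap:::new_registry()
  yyhap:::reg_grow(reg, 1L); reg$n <- 1L
  reg$s[1] <- 1; reg$pos[1] <- 0.5
  pop <- replicate(40, integer(0), simplify = FALSE)
  for (i in seq(1, 19, by = 2)) pop[[i]] <- 1L # 10 het carriers
  set.seed(6)
  step <- yyhap:::next_generation(pop, reg, cfg2, 1L)
  expect_length(step$pop, 40L)
  expect_false(any(vapply(step$pop, function(h) 1L %in% h, TRUE)))
})

test_that("registry accounting balances influx, fixations, losses and segregation", {
  cfg <- sim_config(N = 20, mu = 2, r = 1, alpha = 2,
                    effect_mix = neutral_mix, generations = 200, seed = 7)
  sim <- run_sim(cfg)
  st <- sim$stats
  expect_equal(sum(st$influx),
               sum(st$fixations) + sum(st$losses) + st$segregating[200])
  # per-generation balance
  running <- cumsum(st$influx) - cumsum(st$fixations) - cumsum(st$losses)
  expect_equal(running, st$segregating)
  # registry fates agree with the stats
  rt <- registry_table(sim)
  expect_equal(sum(rt$fate == "fixed"), sum(st$fixations))
  expect_equal(sum(rt$fate == "lost"), sum(st$losses))
  expect_equal(sum(rt$fate == "segregating"), st$segregating[200])
  expect_equal(nrow(rt), sum(st$influx))
  # no fixed mutation remains in any genome
  fixed <- rt$id[rt$fate == "fixed"]
  expect_false(any(unlist(sim$pop) %in% fixed))
})

test_that("runs are bit-identical under the same seed and empty at zero generations", {
  cfg <- sim_config(N = 10, mu = 1, r = 1, generations = 50,
                    effect_mix = neutral_mix, seed = 11)
  a <- run_sim(cfg); b <- run_sim(cfg)
  expect_identical(a$stats, b$stats)
  expect_identical(a$pop, b$pop)
  expect_identical(registry_table(a), registry_table(b))
  z <- run_sim(sim_config(N = 10, mu = 1, generations = 0, seed = 1))
  expect_equal(nrow(z$stats), 0L)
  expect_length(z$fixed_ids, 0L)
})

test_that("the segregating-site guard stops runaway configurations", {
  cfg <- sim_config(N = 10, mu = 5, generations = 50, seed = 3,
                    effect_mix = neutral_mix, max_segregating = 20)
  expect_error(run_sim(cfg), "max_segregating")
})

test_that("population analysis finds no segments in a monomorphic population", {
  cfg <- sim_config(N = 10, mu = 0, generations = 5, seed = 1)
  sim <- run_sim(cfg)
  an <- analyze_population(sim)
  expect_equal(an$n_frequent, 0L)
  expect_equal(an$n_segments, 0L)
  expect_true(is.na(an$pct_yinyang))
})

test_that("site frequency spectrum is dominated by rare derived alleles", {
  cfg <- sim_config(N = 50, mu = 2, r = 1, alpha = 2,
                    effect_mix = neutral_mix, generations = 600,
                    burn_in = 300, seed = 9)
  sim <- run_sim(cfg)
  sfs <- sim_sfs(sim)
  expect_equal(sum(sfs), length(sim$seg_ids))
  # singletons are the largest class; binned spectrum decreases
  expect_equal(which.max(sfs), 1L)
  bins <- c(sum(sfs[1:5]), sum(sfs[6:25]), sum(sfs[26:70]))
  expect_true(all(diff(bins) < 0))
})

test_that("admixture with no separation time behaves like its control", {
  cfg <- sim_config(N = 20, mu = 2, r = 1, alpha = 2,
                    effect_mix = neutral_mix, seed = 15)
  res <- admixture_experiment(cfg, t_split = 0, burn_in = 150)
  expect_equal(res$n_fixed_a, 0L)
  expect_equal(res$n_fixed_b, 0L)
  # same founder population, so identical frequent-variant counts
  expect_equal(res$admixed$n_frequent, res$control$n_frequent,
               tolerance = 0.5)
})

test_that("admixed frequent variants include every lineage-private fixation", {
  cfg <- sim_config(N = 20, mu = 2, r = 1, alpha = 2,
                    effect_mix = neutral_mix, seed = 16)
  res <- admixture_experiment(cfg, t_split = 300, burn_in = 100, mix = 0.5)
  private <- c(setdiff(res$fixed_ids_a, res$fixed_ids_b),
               setdiff(res$fixed_ids_b, res$fixed_ids_a))
  # mutations that arose after the split sit in exactly one lineage, so
  # every one fixed there has frequency `mix` in the merged population
  # (founder-era mutations can be fixed in one lineage and near-fixed in
  # the other, landing above the frequent band)
  private <- private[res$merged_registry$origin[private] > 100]
  cnt <- tabulate(unlist(res$merged_pop), nbins = res$merged_registry$n)
  twoN <- length(res$merged_pop)
  freq_ids <- which(cnt > 0.25 * twoN & cnt < 0.75 * twoN)
  expect_gt(length(private), 0)
  expect_true(all(private %in% freq_ids))
  # and they make up most of the admixed frequent set
  expect_gt(res$admixed$n_frequent, 0.8 * length(private))
})
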
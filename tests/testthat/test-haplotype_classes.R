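test_that("hamming distance counts differing positions", {
  x <- rand_hap(50)
  expect_equal(hamming(x, x), 0L)
  expect_equal(hamming(strrep("0", 50), strrep("1", 50)), 50L)
  set.seed(3)
  for (i in 1:20) {
    a <- rand_hap(30); b <- rand_hap(30)
    naive <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(hamming(a, b), naive)
  }
  expect_error(hamming("01", "011"), "length")
})

test_that("haplotype grouping absorbs near-identical strings deterministically", {
  set.seed(7)
  a <- rand_hap(50)
  b <- complement_hap(a)
  haps <- c(rep(a, 300), rep(flip_at(a, 5), 5), rep(b, 120))
  chs <- group_haplotypes(sample(haps)) # input order must not matter
  expect_equal(chs$count, c(305L, 120L))
  expect_equal(chs$representative, c(a, b))
  expect_equal(sum(chs$count), length(haps)) # partition property
  # equidistant string joins the more frequent representative
  r1 <- strrep("0", 50)
  r2 <- flip_at(r1, c(1, 2, 3, 4))           # hamming(r1, r2) = 4
  mid <- flip_at(r1, c(1, 2))                # 2 from both
  haps2 <- c(rep(r1, 40), rep(r2, 30), mid)
  chs2 <- group_haplotypes(haps2)
  expect_equal(chs2$count, c(41L, 30L))
  expect_equal(chs2$representative[1], r1)
  # empty input
  empty <- group_haplotypes(character(0))
  expect_s3_class(empty, "chset")
  expect_length(empty$representative, 0)
})

test_that("grouping matches an independent reference implementation", {
  set.seed(21)
  for (rep_i in 1:5) {
    base <- replicate(4, rand_hap(20))
    haps <- unlist(lapply(base, function(b) {
      c(rep(b, sample(3:40, 1)),
        replicate(5, flip_at(b, sample(20, sample(0:3, 1)))))
    }))
    got <- group_haplotypes(haps)
    want <- oracle_group(haps)
    expect_equal(got$representative, want$representative)
    expect_equal(got$count, want$count)
    expect_equal(sum(got$count), length(haps))
  }
})

test_that("grouping records per-continent occurrence counts", {
  a <- strrep("0", 10); b <- strrep("1", 10)
  haps <- c(rep(a, 4), rep(b, 2))
  conts <- c("AFR", "AFR", "EUR", "ASN", "EUR", "EUR")
  chs <- group_haplotypes(haps, continents = conts)
  expect_equal(chs$continent_counts[1, ], c(AFR = 2L, ASN = 1L, EUR = 1L))
  expect_equal(chs$continent_counts[2, ], c(AFR = 0L, ASN = 0L, EUR = 2L))
})

test_that("common-haplotype thresholds work by count or frequency, not both", {
  a <- strrep("0", 50)
  haps <- c(rep(a, 305), rep(complement_hap(a), 120),
            rep(flip_at(a, 1:25), 80))
  chs <- group_haplotypes(haps)
  expect_equal(common_haplotypes(chs, min_count = 100)$count, c(305L, 120L))
  # 2n = 505 here; 5% = 25.25 -> all three groups pass
  expect_length(common_haplotypes(chs, min_freq = 0.05)$count, 3)
  expect_length(common_haplotypes(chs, min_freq = 0.5)$count, 1)
  expect_error(common_haplotypes(chs, min_count = 100, min_freq = 0.05),
               "only one")
  expect_length(common_haplotypes(group_haplotypes(character(0)),
                                  min_count = 100)$count, 0)
})

test_that("Yin/Yang pairing is greedy by rank with Yin the more frequent", {
  set.seed(13)
  a <- rand_hap(50)
  ac <- complement_hap(a)
  mk <- function(reps) {
    g <- group_haplotypes(unlist(mapply(rep, names(reps), reps)))
    g
  }
  chs <- mk(stats::setNames(c(800, 400), c(a, ac)))
  pairs <- find_yinyang(chs)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$yin, a)
  expect_equal(pairs$yang, ac)
  expect_equal(pairs$n_diff, 50L)

  # greedy trace: B close to A stays unpaired
  b <- flip_at(a, c(2, 9))  # hamming(a,b)=2, hamming(b,ac)=48
  chs2 <- mk(stats::setNames(c(800, 700, 400), c(a, b, ac)))
  pairs2 <- find_yinyang(chs2)
  expect_equal(nrow(pairs2), 1L)
  expect_equal(pairs2$yin, a)
  expect_equal(pairs2$yang, ac)

  # two complementary pairs in one segment -> 4 Yin/Yang CHs
  c1 <- flip_at(a, 1:25)
  c1c <- complement_hap(c1)
  chs3 <- mk(stats::setNames(c(1000, 900, 800, 700), c(a, c1, ac, c1c)))
  pairs3 <- find_yinyang(chs3)
  expect_equal(nrow(pairs3), 2L)
  expect_equal(2L * nrow(pairs3), 4L)
  expect_equal(sort(c(pairs3$yin, pairs3$yang)), sort(c(a, ac, c1, c1c)))

  # raising min_diff never increases the number of pairs
  set.seed(31)
  for (i in 1:10) {
    strs <- replicate(6, rand_hap(50))
    strs <- c(strs, complement_hap(strs[1]), complement_hap(strs[2]))
    chs_r <- mk(stats::setNames(sample(100:900, 8), strs))
    expect_lte(nrow(find_yinyang(chs_r, min_diff = 50)),
               nrow(find_yinyang(chs_r, min_diff = 47)))
  }
})

test_that("minimal-piece decomposition matches the exhaustive oracle", {
  yin <- strrep("0", 50); yang <- strrep("1", 50)
  expect_equal(min_pieces(yin, yin, yang), 1L)
  h2 <- paste0(strrep("0", 25), strrep("1", 25))
  expect_equal(min_pieces(h2, yin, yang), 2L)
  expect_error(min_pieces("01", yin, yang), "length")

  # random instances with wildcards, length <= 20, exhaustive enumeration
  set.seed(17)
  for (i in 1:300) {
    k <- sample(4:20, 1)
    yin_i <- rand_hap(k)
    yang_i <- complement_hap(yin_i)
    nw <- sample(0:min(6, k - 1), 1)
    if (nw > 0) { # wildcard positions where yin == yang
      at <- sample(k, nw)
      yv <- strsplit(yang_i, "")[[1]]
      yv[at] <- strsplit(yin_i, "")[[1]][at]
      yang_i <- paste(yv, collapse = "")
    }
    h <- rand_hap(k)
    expect_equal(min_pieces(h, yin_i, yang_i),
                 oracle_min_pieces(h, yin_i, yang_i))
  }
})

test_that("a haplotype is one piece exactly when it matches a side everywhere", {
  set.seed(23)
  for (i in 1:50) {
    k <- sample(5:15, 1)
    yin <- rand_hap(k)
    yang <- complement_hap(yin)
    h <- rand_hap(k)
    p <- min_pieces(h, yin, yang)
    matches_side <- identical(h, yin) || identical(h, yang)
    expect_equal(p == 1L, matches_side)
  }
})

test_that("derived-allele accounting excludes unknown-status positions", {
  st_r <- rep("R", 50)
  expect_equal(derived_fraction(strrep("0", 50), st_r), 0)
  expect_equal(derived_fraction(strrep("1", 50), st_r), 1)
  # M status: reference allele is the derived one
  expect_equal(derived_fraction(strrep("0", 10), rep("M", 10)), 1)
  # 12 derived among 50 informative
  h <- flip_at(strrep("0", 50), 1:12)
  expect_equal(derived_fraction(h, st_r), 0.24)
  # X positions drop out of numerator and denominator
  st_x <- st_r; st_x[1:10] <- "X"
  h2 <- flip_at(strrep("0", 50), 1:10) # derived only at X positions
  expect_equal(derived_fraction(h2, st_x), 0)
  expect_true(is.na(derived_fraction("01", c("X", "X"))))
  expect_error(derived_fraction("01", c("R", "Q")), "R, M, X")
})

test_that("Mosaic derived alleles are credited to the carrying side", {
  set.seed(29)
  yin <- strrep("1", 50); yang <- strrep("0", 50)
  st <- rep("R", 50)
  expect_equal(mosaic_source_split(yin, yin, yang, st),
               c(n_yin_derived = 50L, n_yang_derived = 0L, n_other = 0L))
  # planted 10/2 split: mosaic carries 10 of yin's derived alleles and 2
  # derived alleles where yang is the carrier
  yin2 <- flip_at(strrep("0", 50), 1:28)  # derived (alt) at 1..28
  yang2 <- complement_hap(yin2)           # derived at 29..50
  mosaic <- flip_at(strrep("0", 50), c(1:10, 29, 30))
  expect_equal(mosaic_source_split(mosaic, yin2, yang2, st),
               c(n_yin_derived = 10L, n_yang_derived = 2L, n_other = 0L))
  # wildcard positions (yin == yang) count as other
  yang3 <- flip_at(yang2, 1)  # now yang3[1] == yin2[1] = 1
  expect_equal(mosaic_source_split(mosaic, yin2, yang3, st)[["n_other"]], 1L)
})

test_that("the null split distribution matches closed-form multinomial tails", {
  # single derived allele: one-sided probability is p_yin + p_yang
  null1 <- expected_split_null(1, reps = 2e5, seed = 1)
  expect_equal(null1$p_one_sided, 0.546 + 0.438, tolerance = 0.01)
  # degenerate: everything on one side
  expect_equal(expected_split_null(3, p_yin = 1, p_yang = 0, reps = 100,
                                   seed = 1)$p_one_sided, 1)
  # n = 3: >= 80% on one side means all three (exact enumeration)
  exact3 <- 0.546^3 + 0.438^3
  null3 <- expected_split_null(3, reps = 2e5, seed = 2)
  expect_equal(null3$p_one_sided, exact3, tolerance = 0.01)
  # n = 5: >= 4 of 5 on one side; exact multinomial enumeration
  exact5 <- 0
  for (a in 0:5) for (b in 0:(5 - a)) {
    c3 <- 5 - a - b
    pr <- factorial(5) / (factorial(a) * factorial(b) * factorial(c3)) *
      0.546^a * 0.438^b * 0.016^c3
    if (max(a, b) / 5 >= 0.8) exact5 <- exact5 + pr
  }
  null5 <- expected_split_null(5, reps = 2e5, seed = 3)
  expect_equal(null5$p_one_sided, exact5, tolerance = 0.01)
  expect_error(expected_split_null(2, reps = 0), "reps")
  # reproducible under a seed
  expect_identical(expected_split_null(4, reps = 50, seed = 9),
                   expected_split_null(4, reps = 50, seed = 9))
})

test_that("segment summary reports CH structure with NA for empty segments", {
  seg <- list(chrom = "1", segment_index = 1L, start_pos = 1000,
              length_kb = 49)
  empty <- group_haplotypes(character(0))
  row <- segment_summary(seg, empty, find_yinyang(empty))
  expect_equal(row$n_ch, 0L)
  expect_true(is.na(row$max_diff))
  expect_equal(row$n_yinyang_ch, 0L)
  set.seed(37)
  a <- rand_hap(50)
  haps <- c(rep(a, 300), rep(complement_hap(a), 150))
  chs <- group_haplotypes(haps)
  pairs <- find_yinyang(chs)
  row2 <- segment_summary(seg, chs, pairs)
  expect_equal(row2$n_ch, 2L)
  expect_equal(row2$max_diff, 50L)
  expect_equal(row2$n_yinyang_ch, 2L)
  expect_equal(row2$ch_occurrences, 450L)
})

test_that("per-segment classification assigns roles and piece counts", {
  set.seed(41)
  yin <- flip_at(strrep("0", 50), 1:28)
  yang <- complement_hap(yin)
  # mosaic: alternate yin/yang in 13 forced blocks
  blocks <- rep(rep(c("Y", "G"), length.out = 13),
                times = c(rep(4, 11), 3, 3))
  mv <- ifelse(blocks == "Y", strsplit(yin, "")[[1]],
               strsplit(yang, "")[[1]])
  mosaic <- paste(mv, collapse = "")
  haps <- c(rep(yin, 300), rep(yang, 200), rep(mosaic, 120))
  chs <- common_haplotypes(group_haplotypes(haps), min_count = 100)
  cls <- classify_segment(chs, statuses = rep("R", 50))
  expect_equal(cls$ch_table$role[match(c(yin, yang, mosaic),
                                       cls$ch_table$representative)],
               c("yin", "yang", "mosaic"))
  expect_equal(cls$ch_table$pieces[cls$ch_table$role == "mosaic"], 13L)
})
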
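test_that("ancestral haplotype deduction maps statuses to alleles with masks", {
  prof <- ancestral_haplotype(rep("R", 6))
  expect_equal(prof$profile, "000000")
  expect_equal(prof$n_masked, 0L)
  prof2 <- ancestral_haplotype(c("R", "M", "X", "M", "R"))
  expect_equal(prof2$profile, "01.10")
  expect_equal(prof2$n_masked, 1L)
  # the deduced profile carries zero derived alleles by construction
  st <- c("R", "M", "M", "R")
  p3 <- ancestral_haplotype(st)
  expect_equal(derived_fraction(p3$profile, st), 0)
  expect_error(ancestral_haplotype(c("R", "Z")), "R")
})

test_that("ancestral matching counts near-matches over unmasked positions", {
  st <- rep("R", 10)
  prof <- ancestral_haplotype(st)
  anc <- strrep("0", 10)
  near <- flip_at(anc, c(1, 5))     # 2 differences: still a match
  far <- flip_at(anc, 1:3)          # 3 differences: no match
  haps <- c(anc, rep(near, 6), rep(far, 4))
  m <- match_ancestral(haps, prof, max_diff = 2)
  expect_equal(m$count, 7L)
  expect_equal(m$abundance, "uncommon")
  expect_true(m$eligible)
  # absent class
  m0 <- match_ancestral(rep(far, 3), prof)
  expect_equal(m0$count, 0L)
  expect_equal(m0$abundance, "absent")
  # masked positions are ignored in the distance
  st2 <- c(rep("X", 3), rep("R", 7))
  prof2 <- ancestral_haplotype(st2)
  h <- flip_at(strrep("0", 10), 1:3) # differs only at masked positions
  expect_equal(match_ancestral(h, prof2)$count, 1L)
  # > 50% masked makes the segment ineligible
  st3 <- c(rep("X", 6), rep("R", 4))
  expect_false(match_ancestral(h, ancestral_haplotype(st3))$eligible)
  # per-continent breakdown
  m2 <- match_ancestral(haps, prof,
                        continents = rep(c("AFR", "EUR"), c(7, 4)))
  expect_equal(m2$continent_counts, c(AFR = 7L, EUR = 0L))
})

test_that("abundance classes partition counts disjointly", {
  expect_equal(classify_abundance(0), "absent")
  expect_equal(classify_abundance(1), "rare")
  expect_equal(classify_abundance(3), "rare")
  expect_equal(classify_abundance(4), "uncommon")
  expect_equal(classify_abundance(99), "uncommon")
  expect_equal(classify_abundance(100), "common")
})

test_that("continent specificity uses 100% for rare and strict >90% for uncommon", {
  expect_equal(classify_specificity(c(AFR = 5, EUR = 0, ASN = 0), "rare"),
               "AFR")
  expect_equal(classify_specificity(c(AFR = 2, EUR = 1, ASN = 0), "rare"),
               "multi-continent")
  # exactly 90% fails the strict rule
  expect_equal(classify_specificity(c(AFR = 90, EUR = 9, ASN = 1),
                                    "uncommon"), "multi-continent")
  expect_equal(classify_specificity(c(AFR = 91, EUR = 9, ASN = 0),
                                    "uncommon"), "AFR")
  expect_true(is.na(classify_specificity(c(AFR = 0), "absent")))
  # common class uses per-capita predominance
  panel <- data.frame(sample = sprintf("S%d", 1:30),
                      population = "P",
                      continent = rep(c("AFR", "EUR"), c(10, 20)))
  out <- classify_specificity(c(AFR = 60, EUR = 60), "common", panel)
  expect_equal(out, "AFR-predominant")
  expect_error(classify_specificity(c(AFR = 120), "common"), "panel")
})

test_that("per-capita normalization corrects panel sizes and breaks ties", {
  panel <- data.frame(sample = sprintf("S%d", 1:30),
                      population = "P",
                      continent = rep(c("AFR", "EUR"), c(10, 20)))
  # equal counts, unequal sizes: the smaller continent predominates
  nb <- normalize_by_continent(c(AFR = 10, EUR = 10), panel)
  expect_equal(nb$rates, c(AFR = 0.5, EUR = 0.25))
  expect_equal(nb$predominant, "AFR")
  # equal rates: first continent in the configured order wins
  nb2 <- normalize_by_continent(c(AFR = 10, EUR = 20), panel,
                                continent_order = c("EUR", "AFR"))
  expect_equal(unname(nb2$rates), c(0.5, 0.5))
  expect_equal(nb2$predominant, "EUR")
})

test_that("archaic diplotypes convert to haplotypes via homozygous codes", {
  expect_equal(archaic_to_haplotype(rep("0", 5)), "00000")
  expect_equal(archaic_to_haplotype(c("0", "2", "1", "x", "0")), "01..0")
})

test_that("archaic comparison flags near-identity over resolved positions", {
  set.seed(19)
  st <- rep("R", 50)
  yin <- flip_at(strrep("0", 50), 1:28)
  yang <- complement_hap(yin)
  mosaic <- flip_at(strrep("0", 50), 1:10)
  haps <- c(rep(yin, 300), rep(yang, 200), rep(mosaic, 150))
  chs <- common_haplotypes(group_haplotypes(haps), min_count = 100)
  arch_hap <- mosaic # archaic equals the planted mosaic
  cmp <- compare_archaic(arch_hap, chs, st)
  expect_false(cmp$excluded)
  ni <- cmp$ch_table$near_identical
  expect_equal(cmp$ch_table$representative[ni], mosaic)
  expect_equal(cmp$ch_table$n_diff[cmp$ch_table$representative == mosaic], 0L)
  expect_equal(cmp$archaic_derived_fraction, 10 / 50)
  # all-missing archaic: excluded
  cmp2 <- compare_archaic(strrep(".", 50), chs, st)
  expect_true(cmp2$excluded)
  expect_equal(cmp2$n_resolved, 0L)
  # fewer than 45 resolved positions: excluded even if identical
  arch3 <- paste0(substr(mosaic, 1, 40), strrep(".", 10))
  expect_true(compare_archaic(arch3, chs, st)$excluded)
})

test_that("synthetic archaic genome recovers the planted derived fraction", {
  synth <- generate_cohort(synth_config(
    n_samples = c(AFR = 30, EUR = 30, ASN = 30), n_segments = 10,
    x_fraction = 0, seed = 5))
  an <- classify_cohort(synth$cohort, min_count = 30)
  rep <- archaic_report(synth$cohort, synth$archaic, an)
  adf <- rep$segments$archaic_derived_fraction
  # pooled over 500 variants the binomial error is ~1.7%
  expect_equal(mean(adf), 0.18, tolerance = 0.2)
  # near-total homozygosity: heterozygous-missing rate below 1%
  expect_lt(mean(unclass(synth$archaic) == "1"), 0.01)
})

test_that("ancestral report recovers African enrichment on the default cohort", {
  synth <- generate_cohort(synth_config(n_segments = 4, seed = 23))
  an <- classify_cohort(synth$cohort)
  rep <- ancestral_report(synth$cohort, an)
  withm <- rep[rep$match_count > 0, ]
  expect_gt(nrow(withm), 0)
  # African per-capita rate tops every other continent where matches exist
  expect_true(all(withm$predominant == "AFR"))
  rate_cols <- grep("^rate_", names(withm), value = TRUE)
  other <- setdiff(rate_cols, "rate_AFR")
  expect_true(all(withm$rate_AFR >= apply(withm[other], 1, max)))
})
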
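---
title: "Yin/Yang haplotype architecture: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yin/Yang haplotype architecture: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yyhap)
```

## The analysis in one page

Phased diploid cohorts show striking block structure at common variants.
`yyhap` formalizes one way of looking at it. Each chromosome is covered by
a grid of 500-kb windows anchored at coordinate 0; from each window start,
the first 50 adjacent *frequent* variants (minor allele frequency strictly
above 0.25) form a **segment**, elongated as far as necessary, so
consecutive windows may yield overlapping segments. Restricted to one
segment, each of the cohort's \(2n\) phased haplotypes is a binary string
of length 50 ("0" = reference allele, "1" = alternative).

Strings are grouped by near-identity: exact occurrences are counted,
distinct strings are scanned in (count descending, lexicographic) order,
and each joins the first group whose representative differs at no more
than 2 of the 50 positions (tolerating occasional genotyping errors), or
founds a new group. A group with at least 100 occurrences (out of 2184
haplotypes in the motivating cohort; at least 5% in simulated populations)
is a **common haplotype** (CH). Two CHs of one segment differing at 47 or
more positions (at least 94% mutual exclusivity, again leaving slack for
errors and occasional gene-conversion "jumps") form a **Yin/Yang pair**,
Yin being the more frequent; pairing is greedy by rank, so a segment can
hold several pairs. Every other CH is decomposed against the segment's
top-ranked pair into the minimal number of contiguous Yin/Yang fragments
(`min_pieces()`); a CH needing 12 or more pieces is a **Mosaic**
haplotype.

Ancestral-allele annotations (`AA=` INFO values; `R` when the reference
allele is ancestral, `M` when the alternative is, `X` unknown) polarize
each variant. From them the package deduces each segment's fully
**ancestral haplotype**, counts cohort haplotypes within 2 differences of
it (rare = 1-3 matches, uncommon = 4-99, common = 100 or more), assesses
continental specificity, and converts a (almost entirely homozygous)
archaic genome into a haplotype comparable with every CH.

## The minimal-piece decomposition

For a haplotype \(h\) and a pair (yin, yang), label each position `Y` if
\(h\) matches yin only, `G` if yang only, and *wildcard* where yin and
yang agree (possible because pairs need only 47/50 complementarity).
Wildcards can be absorbed into either neighbouring fragment, so the
minimum over all wildcard resolutions is the number of forced
`Y`–`G` alternations plus one, computed in a single pass. The test suite
checks this closed form against an exhaustive enumeration of all wildcard
resolutions on 10^4 random instances.

## Derived-allele accounting

A haplotype's derived-allele fraction is the share of non-`X` positions
carrying the non-ancestral allele. Each derived allele of a Mosaic at a
position where yin and yang disagree is credited to the side carrying it;
`expected_split_null()` gives the reference distribution of the
majority-side share under independent random assignment (defaults 54.6%
Yin / 43.8% Yang, the observed genome-wide shares), against which an
observed excess of one-sided Mosaics can be judged.

## The forward simulator

`run_sim()` is an infinite-sites, abstract-genome (unit interval) diploid
simulator designed around the mechanics the package's claims depend on,
not around genomic realism:

* **Mutation.** Each gamete receives Poisson(\(\mu\)) novel mutations at
  fresh uniform positions. Effects: 81% slightly deleterious, 9%
  beneficial, 10% neutral by default, with exponential magnitudes (means
  10^-3; the magnitudes are package choices, exposed in
  `sim_config()`, since "slightly deleterious" fixes no number).
* **Recombination.** Exactly \(r\) crossovers per gamete at uniform
  positions (a fixed count, matching the fixed-\(r\) experimental sweeps,
  rather than a Poisson number).
* **Mating.** Random permanent pairs re-drawn each generation: all
  \(\alpha\) offspring of a pair take both gametes from the same two
  parents. Under monogamy, "\(\alpha\) offspring per pair" and
  "\(\alpha\) offspring per individual" coincide (each offspring has both
  parents in the pair), which is why \(\alpha = 2\) is exactly
  reproduction without selection.
* **Selection.** The \(\alpha N/2\) offspring are ranked by
  multiplicative fitness \(\prod (1 - h s)\) over heterozygous and
  \(\prod (1 - s)\) over homozygous mutations (\(h = 0.5\)), ties broken
  by a seeded shuffle, and the top \(N\) survive (truncation selection).
* **Bookkeeping.** A registry records every mutation's position, effect,
  origin generation and fate. Mutations reaching \(2N\) copies are
  recorded as fixed and removed from genomes; mutations at 0 copies are
  recorded as lost. Influx = fixed + lost + segregating holds every
  generation, and runs are bit-identical given a seed.

### What the neutral run shows about the fixation clock

The admixture arithmetic in `fixation_rate()` follows the published
convention \(k = 2\mu\) with \(\mu\) per gamete (so \(k \approx 100\) for
humans). Standard neutral theory, however, predicts that the long-run
substitution rate equals the *per-gamete* mutation rate: \(2N\mu\) new
mutations per generation each fix with probability \(1/2N\), giving
\(k = \mu\). The simulator — which implements no clock, only mutation,
Mendelian transmission and drift — measures fixations/generation
\(\approx \mu\) (ratio to \(\mu\) of about 0.96 over 2000 observed
generations at \(N = 100\), \(\mu = 5\)), consistent with theory and at
half the \(k = 2\mu\) convention. Both numbers are reported side by side
rather than reconciled: the closed-form calculators reproduce the
published arithmetic; the simulator reports what the dynamics produce.
The early-loss statistic is clock-independent: with exactly-two-offspring
pairs, a new mutation's copy number follows a Binomial(2, 1/2) branching
process, whose extinction probability by generation three is 48.3% —
the simulator measures ~48%, matching the "about half of new mutations
are promptly lost" picture.

### Population-size sweeps and the admixture experiment

`analyze_population()` turns a simulated population's frequent
segregating mutations into positional haplotype strings, cuts them into
consecutive blocks of 50 and reuses the CH/Yin-Yang machinery with the 5%
frequency convention. The packaged study conditions (all chosen once and
fixed in the acceptance tests) are:

* **Sweep:** \(N \in \{50, 100, 200, 400\}\), \(\mu = 2\), \(r = 1\),
  \(\alpha = 2\), a fixed 1000-generation horizon from a monomorphic
  founder. A fixed horizon mirrors how fixed-duration simulation
  campaigns are actually run, and it matters: equilibration takes
  \(\sim 4N_e\) generations (and \(N_e \approx 2N\) here, because
  constant pair offspring halves the drift variance), so larger
  populations are progressively farther from mutation-drift equilibrium
  at the same horizon. That is precisely the regime in which Yin/Yang
  pairs — which require two deeply diverged haplotype clades to coexist —
  become rare in large populations, while frequent-variant counts still
  grow with \(N\) but sublinearly (a square-root curve beats a straight
  line). Because the largest population is still ramping at generation
  1000, its frequent-variant count can sit slightly below the
  \(N = 200\) point; the acceptance criteria therefore test growth as a
  trend (endpoint and rank correlation) rather than strict adjacent
  monotonicity, alongside the square-root-versus-linear fit and the
  decline of %CH and %Yin/Yang with \(N\).
* **Admixture:** one founder (\(N = 50\)) evolved 100 generations,
  duplicated, evolved independently for 1500 generations (30 times
  \(N\)), merged 50/50, versus a panmictic control evolved the same
  total time. Mutations fixed privately in one lineage re-enter the
  merged genomes at frequency 1/2 and become frequent variants; with
  \(\approx 2\mu T\) private fixations per lineage dwarfing the
  \(\approx 1.1\theta\) segregating baseline, merged segments are
  dominated by lineage-diagnostic sites and Yin/Yang pairs appear in
  essentially every block, far above the control. This is the package's
  desk-scale version of the admixture argument.

## The synthetic-data generator

`generate_cohort()` builds cohorts constructively — not by coalescent
simulation — so ground truth is exact: per segment it draws an ancestral
allele per position (alternative allele ancestral with probability 0.3),
plants Yin with 28/50 derived alleles (56%, matching the observed Yin
55% / Yang 43% regime), Yang as its complement (degradable to 47-49/50
via "jumped" positions), optionally a Mosaic assembled from alternating
Yin/Yang blocks whose minimal piece count is *constructed* to equal the
configuration and re-verified against the exhaustive decomposition at
generation time, a configurable number of ancestral copies, and random
background haplotypes. Default frequencies (Yin 35%, Yang 25%, Mosaic 8%,
1000 diploids from four continents) keep every planted class above or
below the CH threshold as intended. Continent allocation is a
deterministic largest-remainder apportionment with African weight 0.7 for
ancestral and Mosaic haplotypes and 0.05 for Yin (the African-enrichment
/ Yin-avoidance regime); the archaic individual is homozygous apart from
a 0.5% heterozygosity rate, with 18% derived alleles.

Background haplotypes are random per variant but their allele count is
chosen to pull each variant's frequency toward 1/2, so every planted
variant is guaranteed frequent (asserted at generation time) and the
windowed segmentation recovers exactly one segment per planted window.
This frequency stabilization is the one place the background is not
i.i.d.; individual background strings remain effectively unique random
strings.

What passing these tests does *not* show: the generator has no linkage
decay, no recombination maps, no demography, and its noise is symmetric
allele flipping. Recovery results on it validate the machinery
(windowing, grouping, pairing, decomposition, polarization, reporting),
not robustness to the correlation structure of real cohorts.

## Numerical and design choices

* Thresholds are strict where the definitions are strict: MAF "above
  0.25" drops a variant at exactly 0.25; continent specificity for
  uncommon haplotypes requires strictly more than 90% of matches.
* Grouping is order-dependent by design; the deterministic
  (count descending, lexicographic) scan makes it canonical and seedless.
  A string within reach of two representatives joins the more frequent
  one.
* Ancestral abundance classes use 1-3 / 4-99 / >=100 so the classes are
  disjoint. Masked (`X`) positions are excluded from distances rather
  than imputed; archaic comparisons additionally require at least 45
  mutually resolved positions so a <=2-difference call stays meaningful.
* The per-capita continent rate (matches divided by sampled haplotypes)
  is the package's explicit choice of normalization; predominance ties
  break by the configured continent order.
* Values of an `AA=` field matching neither allele map to `X` rather than
  guessing a strand or ancestral state.
* Multi-allelic records are dropped (haplotype strings are binary);
  biallelic indels are kept unless `snps_only`. Missing or unphased
  genotypes in the diploid cohort are hard errors, not imputed.
* Window grids anchor at coordinate 0 per chromosome; window starts are
  0-based half-open, VCF positions 1-based, and a variant at exactly a
  window start belongs to the previous window.
* The simulator caps segregating sites (`max_segregating`) and fails
  loudly rather than exhausting memory.
* Problem sizes in the packaged experiments (cohorts of ~1000 diploids
  and 4-10 segments; simulations of N <= 400 and <= 3000 generations) are
  the package's chosen desk-scale study conditions; all are configurable.

## Known limitations

* Genome-scale claims (millions of frequent variants, thousands of
  segments) are out of desk-scale reach; the package reproduces the
  *mechanisms* at reduced size and the closed-form arithmetic exactly.
* The simulator is an abstraction: abstract genome, no gene structure,
  no dominance distribution beyond a single \(h\), truncation rather
  than probabilistic selection. Divergences that matter to the tested
  claims are listed above; absolute simulated table values are not
  reproduced, only trends.
* The equilibrated regime reverses one trend: once every \(N\) in a
  sweep reaches mutation-drift equilibrium, %Yin/Yang no longer declines
  with \(N\) (per-block diversity becomes scale-free while per-block
  recombination falls). The packaged fixed-horizon conditions are the
  regime in which the published decline is reproducible.
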
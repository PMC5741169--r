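# Closed-form calculators for the fixation-clock arithmetic used in the
# admixture argument: Kimura-style fixation rate, diversity-based effective
# population size, a linear derived-allele clock, and the expected yield of
# frequent variants from merging two long-separated lineages.

#' Fixation rate from the per-gamete mutation rate
#'
#' Returns the number of fixed mutations per generation as `k = 2 * mu`,
#' with `mu` the mean number of novel mutations per gamete. This is the
#' convention used by the admixture-yield arithmetic in this package, where
#' `mu` in humans is taken as 20-50 and `k` as "around 100". Note that
#' standard neutral theory gives a substitution rate equal to the per-gamete
#' (haploid-genome) mutation rate, i.e. half this value; see the methods
#' vignette and [run_sim()] for the empirical rate measured by the
#' forward simulator.
#'
#' @param mu_per_gamete mean novel mutations per gamete per generation.
#' @return fixed mutations per generation.
#' @seealso [admixture_yield()], [generations_to_fix()]
#' @export
#' @examples
#' fixation_rate(50) # 100
fixation_rate <- function(mu_per_gamete) {
  stopifnot(is.numeric(mu_per_gamete), mu_per_gamete >= 0)
  2 * mu_per_gamete
}

#' Generations required to fix a given number of mutations
#'
#' @param n_mutations number of mutations to fix.
#' @param k fixation rate (mutations fixed per generation).
#' @return number of generations, `n_mutations / k`.
#' @export
#' @examples
#' generations_to_fix(1e6, 100) # 10000
generations_to_fix <- function(n_mutations, k) {
  stopifnot(n_mutations >= 0, k > 0)
  n_mutations / k
}

#' Convert generations to years
#'
#' @param generations number of generations.
#' @param generation_time years per generation (default 25).
#' @return years.
#' @export
to_years <- function(generations, generation_time = 25) {
  stopifnot(generations >= 0, generation_time > 0)
  generations * generation_time
}

#' Effective population size from pairwise diversity
#'
#' Inverts `theta = 4 * mu * N_eff`.
#'
#' @param theta pairwise genetic diversity (e.g. about 4e6 differences
#'   between two human genomes).
#' @param mu_per_person novel mutations per person (diploid) per generation
#'   (e.g. 100).
#' @return effective population size `theta / (4 * mu_per_person)`.
#' @export
#' @examples
#' neff_from_theta(4e6, 100) # 1e4
neff_from_theta <- function(theta, mu_per_person) {
  stopifnot(theta >= 0, mu_per_person > 0)
  theta / (4 * mu_per_person)
}

#' Calibration for the linear derived-allele clock
#'
#' The clock assumes the mean derived-allele fraction of frequent variants
#' declines linearly going back in time, anchored at two points: modern
#' humans (`f_modern`, about 50%) and an archaic reference genome
#' (`f_archaic`, 18% derived, at the `t_archaic` = 0.7 Mya separation of the
#' Neanderthal lineage from modern humans).
#'
#' @param f_modern derived fraction of frequent variants in modern genomes.
#' @param f_archaic derived fraction at the archaic reference point.
#' @param t_archaic age of the archaic reference point, Mya.
#' @param generation_time years per generation.
#' @return object of class `clock_calibration`.
#' @export
clock_calibration <- function(f_modern = 0.50, f_archaic = 0.18,
                              t_archaic = 0.7, generation_time = 25) {
  stopifnot(f_archaic >= 0, f_archaic < f_modern, f_modern <= 1,
            t_archaic > 0, generation_time > 0)
  structure(list(f_modern = f_modern, f_archaic = f_archaic,
                 t_archaic = t_archaic, generation_time = generation_time),
            class = "clock_calibration")
}

#' Linear derived-allele clock
#'
#' Maps a derived-allele fraction `f` to a time in Mya by linear
#' interpolation/extrapolation through the two calibration points:
#' `t(f) = t_archaic * (f_modern - f) / (f_modern - f_archaic)`.
#' By construction `t(f_modern) = 0` and `t(f_archaic) = t_archaic`.
#'
#' @param f derived-allele fraction, in `[0, f_modern]`.
#' @param cal a [clock_calibration()].
#' @return time in Mya.
#' @export
#' @examples
#' derived_clock(0.31) # ~0.416 Mya, the Mosaic formation-time estimate
#' derived_clock(0)    # extrapolated lineage-separation time, ~1.09 Mya
derived_clock <- function(f, cal = clock_calibration()) {
  stopifnot(inherits(cal, "clock_calibration"))
  if (any(f < 0 | f > cal$f_modern)) {
    stop("derived fraction must lie in [0, ", cal$f_modern, "]")
  }
  cal$t_archaic * (cal$f_modern - f) / (cal$f_modern - cal$f_archaic)
}

#' Frequent-variant yield of an admixture of long-separated lineages
#'
#' When lineages that were separated for `separation_years` merge in
#' comparable proportions, the mutations fixed privately in each lineage
#' become frequent variants of the merged population. The yield is
#' `n_lineages * (separation_years / generation_time) * k`.
#'
#' @param separation_years separation time in years.
#' @param k fixation rate per generation per lineage (default 100, see
#'   [fixation_rate()]).
#' @param generation_time years per generation.
#' @param n_lineages number of merging lineages.
#' @return expected count of newly frequent variants.
#' @export
#' @examples
#' admixture_yield(250000) # 2e6
admixture_yield <- function(separation_years, k = 100, generation_time = 25,
                            n_lineages = 2) {
  stopifnot(separation_years >= 0, k > 0, generation_time > 0, n_lineages >= 1)
  n_lineages * (separation_years / generation_time) * k
}

#' Labelled report of the fixation-clock arithmetic
#'
#' Computes, from one calibration, the quantities used by the admixture
#' argument: the fixation rate for a given per-gamete mutation rate, the
#' generations/years needed to fix one million mutations, the effective
#' population size implied by a diversity value, the Mosaic formation time
#' from its derived-allele fraction, the extrapolated lineage-separation
#' time, and the frequent-variant yield of a two-lineage admixture.
#'
#' @param cal a [clock_calibration()].
#' @param mu_per_gamete per-gamete mutation rate (default 50).
#' @param theta pairwise diversity for the effective-size estimate.
#' @param mu_per_person per-person mutation rate for the effective-size
#'   estimate.
#' @param f_mosaic mean derived fraction of Mosaic haplotypes.
#' @param n_to_fix number of mutations for the fixation-time example.
#' @return named list of computed quantities (invisibly); printed as a
#'   labelled report.
#' @export
theory_report <- function(cal = clock_calibration(), mu_per_gamete = 50,
                          theta = 4e6, mu_per_person = 100, f_mosaic = 0.31,
                          n_to_fix = 1e6) {
  k <- fixation_rate(mu_per_gamete)
  gens <- generations_to_fix(n_to_fix, k)
  yrs <- to_years(gens, cal$generation_time)
  neff <- neff_from_theta(theta, mu_per_person)
  t_mosaic <- derived_clock(f_mosaic, cal)
  t_split <- derived_clock(0, cal)
  yield <- admixture_yield(yrs, k, cal$generation_time, 2)
  out <- list(
    k = k, generations_to_fix = gens, years_to_fix = yrs, n_eff = neff,
    t_mosaic_mya = t_mosaic, t_split_mya = t_split,
    t_split_ratio = t_split / cal$t_archaic, admixture_yield = yield
  )
  cat(sprintf("fixation rate k (mu=%g/gamete):        %g per generation\n",
              mu_per_gamete, k))
  cat(sprintf("generations to fix %.3g mutations:     %g (= %g years)\n",
              n_to_fix, gens, yrs))
  cat(sprintf("N_eff from theta=%.3g, mu=%g/person:   %g\n",
              theta, mu_per_person, neff))
  cat(sprintf("Mosaic formation time (f=%.2f):        %.1f Mya\n",
              f_mosaic, t_mosaic))
  cat(sprintf("lineage separation time (f=0):         %.2f Mya (%.4fx archaic)\n",
              t_split, t_split / cal$t_archaic))
  cat(sprintf("frequent variants from 2-way admixture after %g years: %.3g\n",
              yrs, yield))
  invisible(out)
}
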
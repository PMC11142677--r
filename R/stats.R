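#' PRDM9 site occupancy at chemical equilibrium
#'
#' Probability that a target site of rescaled affinity `y` is occupied by
#' PRDM9, `x = c*y / (1 + c*y)`. The rescaled affinity is the product of the
#' binding constant and the total PRDM9 concentration attributed to one gene
#' copy; `c` multiplies that concentration to account for gene dosage
#' (`c = 1` for a single copy, `c_hom` — typically 2 — for a homozygote).
#'
#' @param y Non-negative numeric vector of rescaled affinities.
#' @param c Positive dosage multiplier (scalar).
#' @return Numeric vector of occupancy probabilities in `[0, 1)`.
#' @examples
#' occupancy(1, 1)    # 0.5
#' occupancy(6, 2)    # 12/13
#' @export
occupancy <- function(y, c = 1) {
  if (any(y < 0)) stop("affinities must be non-negative")
  if (length(c) != 1L || c <= 0) stop("`c` must be a single positive number")
  c * y / (1 + c * y)
}

#' Draw target-site affinities
#'
#' Affinities of the targets of a new PRDM9 allele follow an exponential law;
#' `mean_affinity` is its mean. Uses R's RNG (set the seed with [set.seed()]).
#'
#' @param n Number of sites.
#' @param mean_affinity Mean of the exponential affinity distribution.
#' @return Numeric vector of `n` positive affinities.
#' @export
raffinity <- function(n, mean_affinity) {
  if (mean_affinity <= 0) stop("`mean_affinity` must be positive")
  rexp(n, rate = 1 / mean_affinity)
}

#' Occupancy moments of a set of target sites
#'
#' First three moments of site occupancy `x` over a set of sites, under
#' dosage multiplier `c`. These are the building blocks of the closed-form
#' symmetric-binding rate: for an active-site set, the homozygous symmetric
#' binding rate is `(2<x^2> - <x^3>) / <x>`.
#'
#' @param y Affinities of the (active) sites.
#' @param c Dosage multiplier.
#' @return An object of class `rq_moments`: list with `m1`, `m2`, `m3`
#'   (means of `x`, `x^2`, `x^3`) and `n` (number of sites).
#' @export
site_moments <- function(y, c = 1) {
  x <- occupancy(y, c)
  structure(
    list(m1 = mean(x), m2 = mean(x^2), m3 = mean(x^3), n = length(x)),
    class = "rq_moments"
  )
}

#' @export
print.rq_moments <- function(x, ...) {
  cat(sprintf("occupancy moments over %d sites: <x> = %.4g, <x^2> = %.4g, <x^3> = %.4g\n",
              x$n, x$m1, x$m2, x$m3))
  invisible(x)
}

#' Symmetric-binding rate of a homozygote
#'
#' Probability that a DSB falls at a site also bound by PRDM9 on at least one
#' chromatid of the homologue, for an individual homozygous for the allele:
#' `q = (2<x^2> - <x^3>) / <x>`, with moments taken over the allele's active
#' sites at the homozygous dosage.
#'
#' @param moments An [site_moments()] object (or list with `m1`, `m2`, `m3`).
#' @return Symmetric-binding probability in `[0, 1]`; 0 (with a
#'   `"sterile"` attribute) if the allele has no bindable site (`<x> = 0`).
#' @export
q_hom <- function(moments) {
  if (moments$m1 <= 0) return(structure(0, sterile = TRUE))
  (2 * moments$m2 - moments$m3) / moments$m1
}

#' Symmetric-binding rate of a heterozygote
#'
#' Both alleles contribute bound sites and DSBs; moments must be computed at
#' single-copy dosage (`c = 1`).
#'
#' @param moments_i,moments_j [site_moments()] objects for the two alleles.
#' @return Symmetric-binding probability; 0 with a `"sterile"` attribute if
#'   neither allele has bindable sites.
#' @export
q_het <- function(moments_i, moments_j) {
  den <- moments_i$m1 + moments_j$m1
  if (den <= 0) return(structure(0, sterile = TRUE))
  (2 * moments_i$m2 - moments_i$m3 + 2 * moments_j$m2 - moments_j$m3) / den
}

#' Fertility from the symmetric-binding rate
#'
#' The number of DSBs at symmetrically bound sites is approximately Poisson
#' with mean `d*q`; meiosis succeeds when at least one occurs, so
#' `w = 1 - exp(-d*q)`.
#'
#' @param q Symmetric-binding probability.
#' @param d Mean number of DSBs per meiocyte.
#' @return Meiosis success probability.
#' @export
fertility <- function(q, d) {
  if (any(q < 0 | q > 1)) stop("`q` must be in [0, 1]")
  if (any(d <= 0)) stop("`d` must be positive")
  1 - exp(-d * q)
}

#' Haplo-insufficiency coefficient
#'
#' Relative fertility difference between a homozygote (two copies, dosage
#' `c_hom`) and a hemizygote (one copy, dosage 1) for the same allele.
#'
#' @param w_hom,w_hemi Fertilities of the homozygote and hemizygote.
#' @return `(w_hom - w_hemi) / w_hemi`; `NA` (flagged) when `w_hemi = 0`.
#' @export
haplo_insufficiency <- function(w_hom, w_hemi) {
  out <- ifelse(w_hemi > 0, (w_hom - w_hemi) / w_hemi, NA_real_)
  if (anyNA(out)) attr(out, "undefined") <- TRUE
  out
}

#' Haplo-insufficiency of one fresh allele
#'
#' For a newly created allele (all sites active) with the given affinities:
#' fertility of a homozygote at dosage `c_hom` versus a hemizygote at
#' dosage 1, both with `d` DSBs.
#'
#' @param y Affinities of the allele's sites.
#' @param d Mean DSB number per meiocyte.
#' @param c_hom Homozygous dosage multiplier.
#' @return The haplo-insufficiency coefficient sigma for this allele.
#' @export
sigma_fresh <- function(y, d, c_hom) {
  w_hom <- fertility(q_hom(site_moments(y, c_hom)), d)
  w_hemi <- fertility(q_hom(site_moments(y, 1)), d)
  haplo_insufficiency(w_hom, w_hemi)
}

#' Mean haplo-insufficiency of new alleles (sigma_0)
#'
#' Draws `n_rep` fresh alleles (each with `h` affinities from the exponential
#' law of mean `mean_affinity`), computes the haplo-insufficiency of each at
#' zero erosion, and returns the average. Uses R's RNG.
#'
#' @param mean_affinity Mean of the affinity distribution.
#' @param h Number of target sites per allele.
#' @param d Mean DSB number per meiocyte.
#' @param c_hom Homozygous dosage multiplier.
#' @param n_rep Number of fresh alleles to average over (default 100).
#' @return Estimate of sigma_0.
#' @examples
#' set.seed(1)
#' sigma0(0.2, h = 800, d = 8, c_hom = 2)  # about 2.9e-2
#' @export
sigma0 <- function(mean_affinity, h, d, c_hom, n_rep = 100) {
  if (c_hom == 1) return(0)
  mean(vapply(seq_len(n_rep), function(i) {
    sigma_fresh(raffinity(h, mean_affinity), d, c_hom)
  }, numeric(1)))
}

#' PRDM9 diversity (effective number of alleles)
#'
#' Inverse of the homozygosity: `D = 1 / sum(f_i^2)`. Equal to K when K
#' alleles segregate at frequency 1/K each.
#'
#' @param frequencies Allele frequencies (must sum to 1).
#' @return Diversity `D >= 1`.
#' @export
diversity <- function(frequencies) {
  if (length(frequencies) == 0) stop("empty frequency vector")
  if (abs(sum(frequencies) - 1) > 1e-8)
    stop("frequencies must sum to 1")
  1 / sum(frequencies^2)
}

#' Exact symmetric-binding rate of a diploid genotype
#'
#' Computes q for a genotype from the realized per-haplotype active patterns,
#' without assuming the two haplotypes share the same active set: a DSB on a
#' chromatid of one haplotype is symmetric when the site is active on the
#' other haplotype and bound on at least one of its two chromatids. Reduces
#' to [q_hom()] / [q_het()] when the patterns coincide.
#'
#' @param alleles List of one (homozygote) or two (heterozygote) affinity
#'   vectors.
#' @param active_a,active_b Lists of logical vectors (parallel to `alleles`):
#'   the active pattern of each haplotype at each allele's sites.
#' @param c_hom Homozygous dosage multiplier.
#' @return The genotype's symmetric-binding probability.
#' @export
genotype_q <- function(alleles, active_a, active_b, c_hom = 1) {
  hom <- length(alleles) == 1L
  cc <- if (hom) c_hom else 1
  num <- 0
  den <- 0
  for (s in seq_along(alleles)) {
    x <- occupancy(alleles[[s]], cc)
    a <- active_a[[s]]
    b <- active_b[[s]]
    sym <- x * (2 - x)
    num <- num + sum(x[a & b] * sym[a & b]) * 2
    den <- den + sum(x[a]) + sum(x[b])
  }
  if (den <= 0) return(structure(0, sterile = TRUE))
  num / den
}
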
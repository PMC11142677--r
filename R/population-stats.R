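# Closed-form statistics evaluated on population snapshots. The engine
# computes the same quantities internally during a run; these R versions
# operate on any snapshot and serve as the reference implementation.

hap_active <- function(population, hp, allele_index) {
  h <- length(population$alleles[[allele_index]]$loci)
  act <- rep(TRUE, h)
  act[hp$inactive[[allele_index]]] <- FALSE
  act
}

allele_index_of <- function(population, allele_id) {
  ids <- vapply(population$alleles, `[[`, integer(1), "id")
  idx <- match(allele_id, ids)
  if (is.na(idx)) stop("allele ", allele_id, " not present in the registry")
  idx
}

genotype_q_snapshot <- function(population, hap_a, hap_b, c_hom) {
  ia <- allele_index_of(population, hap_a$allele)
  ib <- allele_index_of(population, hap_b$allele)
  idx <- unique(c(ia, ib))
  genotype_q(
    alleles = lapply(idx, function(a) population$alleles[[a]]$affinities),
    active_a = lapply(idx, function(a) hap_active(population, hap_a, a)),
    active_b = lapply(idx, function(a) hap_active(population, hap_b, a)),
    c_hom = c_hom
  )
}

#' Background-averaged statistic of an allele
#'
#' Averages a per-genotype statistic (symmetric-binding rate `q` or
#' fertility `w`) over all diploid carriers of the allele, with weight 1 for
#' heterozygous and 2 for homozygous carriers.
#'
#' @param population A population snapshot.
#' @param allele_id Allele to evaluate.
#' @param stat `"q"` or `"w"`.
#' @param d Mean DSB number per meiocyte.
#' @param c_hom Homozygous dosage multiplier.
#' @return The weighted mean over carriers.
#' @export
allele_background_average <- function(population, allele_id,
                                      stat = c("q", "w"), d, c_hom = 1) {
  stat <- match.arg(stat)
  haps <- population$haplotypes
  n_ind <- length(haps) %/% 2L
  total <- 0
  weight <- 0
  for (i in seq_len(n_ind)) {
    a <- haps[[2L * i - 1L]]
    b <- haps[[2L * i]]
    if (a$allele != allele_id && b$allele != allele_id) next
    q <- genotype_q_snapshot(population, a, b, c_hom)
    val <- if (stat == "w") fertility(q, d) else q
    wgt <- if (a$allele == b$allele) 2 else 1
    total <- total + wgt * val
    weight <- weight + wgt
  }
  if (weight == 0) stop("allele ", allele_id, " has no carriers")
  total / weight
}

#' Selection coefficient on new PRDM9 alleles
#'
#' Instantiates `n_probes` fresh probe alleles (not inserted into the
#' population), combines each with every individual's genetic background (the
#' probe replaces the PRDM9 allele of the first haplotype; all probe sites
#' are active, the resident target states are kept), and returns the mean
#' log fitness of the probes minus the population mean log fitness. With
#' `n_mei` meiosis attempts per parent draw, fitness is
#' `1 - (1 - w)^n_mei`. Uses R's RNG for the probe affinities.
#'
#' @param population A population snapshot.
#' @param mean_affinity,h,d,c_hom,n_mei Model parameters.
#' @param n_probes Number of probe alleles.
#' @return The selection coefficient s0 at this generation.
#' @export
selection_on_new_alleles <- function(population, mean_affinity, h, d,
                                     c_hom = 1, n_mei = 1, n_probes = 10) {
  haps <- population$haplotypes
  n_ind <- length(haps) %/% 2L
  fit <- function(q) {
    w <- fertility(q, d)
    pmax(1 - (1 - w)^n_mei, 1e-300)
  }
  pop_lw <- mean(vapply(seq_len(n_ind), function(i) {
    q <- genotype_q_snapshot(population, haps[[2L * i - 1L]], haps[[2L * i]],
                             c_hom)
    log(fit(q))
  }, numeric(1)))

  probe_lw <- mean(vapply(seq_len(n_probes), function(p) {
    y <- raffinity(h, mean_affinity)
    x <- occupancy(y, 1)                     # probe always heterozygous
    s1 <- sum(x)
    s2 <- sum(x^2 * (2 - x))
    mean(vapply(seq_len(n_ind), function(i) {
      a <- haps[[2L * i - 1L]]
      b <- haps[[2L * i]]
      ib <- allele_index_of(population, b$allele)
      xr <- occupancy(population$alleles[[ib]]$affinities, 1)
      aa <- hap_active(population, a, ib)
      bb <- hap_active(population, b, ib)
      sym <- xr * (2 - xr)
      num <- 2 * s2 + 2 * sum(xr[aa & bb] * sym[aa & bb])
      den <- 2 * s1 + sum(xr[aa]) + sum(xr[bb])
      log(fit(if (den > 0) num / den else 0))
    }, numeric(1)))
  }, numeric(1)))

  probe_lw - pop_lw
}
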
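# Population snapshots are plain lists:
#   generation, N, L, prdm9_slot, next_id,
#   alleles:    list of (id, birth, loci [1-based slots], affinities)
#   haplotypes: 2N entries of (allele = allele id,
#                              inactive = list parallel to `alleles` of
#                                         1-based site indices)
# A site absent from `inactive` is active; a new allele therefore starts
# population-wide active. The same schema is produced by the C++ engine and
# serialised to JSON for checkpoint/restart.

#' Initial population
#'
#' Builds a population of `N` diploid individuals monomorphic for one fresh
#' PRDM9 allele (all target sites active). Uses R's RNG for the allele's
#' slots and affinities.
#'
#' @param N Number of diploid individuals.
#' @param h Targets per allele.
#' @param mean_affinity Mean of the affinity distribution.
#' @param L Total slot count.
#' @param prdm9_slot 1-based PRDM9 locus slot (default mid-chromosome).
#' @return A population snapshot.
#' @export
init_population <- function(N, h, mean_affinity, L = 200L * h,
                            prdm9_slot = as.integer(L %/% 2)) {
  pop <- list(generation = 0L, N = as.integer(N), L = as.integer(L),
              prdm9_slot = as.integer(prdm9_slot), next_id = 0L,
              alleles = list(), haplotypes = list())
  res <- create_allele(pop, mean_affinity = mean_affinity, h = h)
  pop <- res$population
  hap <- list(allele = res$allele$id, inactive = list(integer(0)))
  pop$haplotypes <- rep(list(hap), 2L * N)
  pop
}

occupied_slots <- function(population) {
  c(population$prdm9_slot,
    unlist(lapply(population$alleles, `[[`, "loci"), use.names = FALSE))
}

#' Create a new PRDM9 allele
#'
#' Registers a fresh allele: `h` distinct target slots drawn uniformly from
#' the free slots, affinities drawn from the exponential law. Every
#' haplotype is active at the new loci (target sites are monomorphic for the
#' active variant at allele birth). The new allele is registered but not yet
#' carried by any haplotype.
#'
#' @param population A population snapshot.
#' @param mean_affinity Mean of the affinity distribution.
#' @param h Targets per allele (defaults to the size of existing alleles).
#' @return List with the updated `population` and the new `allele`.
#' @export
create_allele <- function(population, mean_affinity, h = NULL) {
  if (is.null(h)) {
    if (length(population$alleles) == 0)
      stop("`h` must be given for the first allele")
    h <- length(population$alleles[[1]]$loci)
  }
  used <- occupied_slots(population)
  n_free <- population$L - length(used)
  if (n_free < h)
    stop("slot pool exhausted: ", n_free, " free slots < h = ", h,
         " (increase L)")
  free <- setdiff(seq_len(population$L), used)
  allele <- list(
    id = population$next_id,
    birth = population$generation,
    # sites are kept sorted by slot position; affinities are i.i.d., so
    # sorting the slots leaves the joint distribution unchanged
    loci = sort(sample(free, h)),
    affinities = raffinity(h, mean_affinity)
  )
  population$next_id <- population$next_id + 1L
  population$alleles <- c(population$alleles, list(allele))
  population$haplotypes <- lapply(population$haplotypes, function(hp) {
    hp$inactive <- c(hp$inactive, list(integer(0)))
    hp
  })
  list(population = population, allele = allele)
}

#' PRDM9-locus mutation
#'
#' Each of the 2N gene copies is independently replaced, with probability
#' `u`, by a newly created allele.
#'
#' @param population A population snapshot.
#' @param u Mutation probability per gene copy.
#' @param mean_affinity Mean affinity for new alleles.
#' @return The updated population.
#' @export
mutate_prdm9 <- function(population, u, mean_affinity) {
  stopifnot(u >= 0, u <= 1)
  if (u == 0) return(population)
  hit <- which(runif(length(population$haplotypes)) < u)
  for (i in hit) {
    res <- create_allele(population, mean_affinity = mean_affinity)
    population <- res$population
    population$haplotypes[[i]]$allele <- res$allele$id
  }
  population
}

#' Target-site mutation
#'
#' Every target site of every diploid individual mutates with probability
#' `v` per generation; the inactivating hit lands on one of the two
#' homologous copies at random (a hit on an already-inactive copy changes
#' nothing). Inactive sites never revert.
#'
#' @param population A population snapshot.
#' @param v Inactivation probability per site per individual.
#' @return The updated population.
#' @export
mutate_targets <- function(population, v) {
  stopifnot(v >= 0, v <= 1)
  if (v == 0) return(population)
  hs <- vapply(population$alleles, function(a) length(a$loci), integer(1))
  n_ind <- length(population$haplotypes) %/% 2L
  for (i in seq_len(n_ind)) {
    for (a in seq_along(hs)) {
      hits <- which(runif(hs[[a]]) < v)
      if (length(hits) == 0) next
      copy <- sample(c(2L * i - 1L, 2L * i), length(hits), replace = TRUE)
      for (k in seq_along(hits)) {
        hp <- population$haplotypes[[copy[[k]]]]
        population$haplotypes[[copy[[k]]]]$inactive[[a]] <-
          sort(unique(c(hp$inactive[[a]], hits[[k]])))
      }
    }
  }
  population
}

#' Allele frequencies
#'
#' Counts over the 2N haplotypes, divided by 2N.
#'
#' @param population A population snapshot.
#' @return Named numeric vector (names = allele ids); sums to 1.
#' @export
allele_frequencies <- function(population) {
  if (length(population$haplotypes) == 0) stop("empty population")
  ids <- vapply(population$haplotypes, `[[`, integer(1), "allele")
  tab <- table(factor(ids))
  setNames(as.numeric(tab) / length(ids), names(tab))
}

#' Drop extinct alleles
#'
#' Removes registry entries (and the matching per-haplotype state columns)
#' of alleles carried by no haplotype, reclaiming their slots.
#'
#' @param population A population snapshot.
#' @return The compacted population.
#' @export
gc_population <- function(population) {
  carried <- unique(vapply(population$haplotypes, `[[`, integer(1), "allele"))
  keep <- vapply(population$alleles, function(a) a$id %in% carried, logical(1))
  if (all(keep)) return(population)
  population$alleles <- population$alleles[keep]
  population$haplotypes <- lapply(population$haplotypes, function(hp) {
    hp$inactive <- hp$inactive[keep]
    hp
  })
  population
}

#' Write / read a population snapshot as JSON
#'
#' @param population A population snapshot.
#' @param path File path.
#' @return `read_population` returns the snapshot; `write_population`
#'   returns `path` invisibly.
#' @export
write_population <- function(population, path) {
  jsonlite::write_json(population, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pop <- list(
    generation = as.integer(raw$generation),
    N = as.integer(raw$N),
    L = as.integer(raw$L),
    prdm9_slot = as.integer(raw$prdm9_slot),
    next_id = as.integer(raw$next_id),
    alleles = lapply(raw$alleles, function(a) {
      list(id = as.integer(a$id), birth = as.integer(a$birth),
           loci = as.integer(unlist(a$loci)),
           affinities = as.numeric(unlist(a$affinities)))
    }),
    haplotypes = lapply(raw$haplotypes, function(hp) {
      list(allele = as.integer(hp$allele),
           inactive = lapply(hp$inactive, function(x)
             as.integer(unlist(x))))
    })
  )
  pop
}
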
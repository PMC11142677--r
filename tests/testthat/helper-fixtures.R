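# Fixture builders shared across the test files.

# a minimal one- or two-allele genotype spec for the meiosis kernel
make_genotype <- function(y_a, y_b = NULL,
                          active_a = NULL, active_b = NULL,
                          loci_a = NULL, loci_b = NULL,
                          prdm9_slot = NULL) {
  ha <- length(y_a)
  if (is.null(loci_a)) loci_a <- seq_len(ha)
  alleles <- list(list(loci = loci_a, affinities = y_a))
  n_al <- 1L
  if (!is.null(y_b)) {
    hb <- length(y_b)
    if (is.null(loci_b)) loci_b <- max(loci_a) + seq_len(hb)
    alleles <- c(alleles, list(list(loci = loci_b, affinities = y_b)))
    n_al <- 2L
  }
  blank <- lapply(alleles, function(a) rep(TRUE, length(a$loci)))
  if (is.null(active_a)) active_a <- blank
  if (is.null(active_b)) active_b <- blank
  list(
    alleles = alleles,
    hap_a = list(allele = 1L, active = active_a),
    hap_b = list(allele = n_al, active = active_b),
    prdm9_slot = if (is.null(prdm9_slot))
      max(vapply(alleles, function(a) max(a$loci), numeric(1))) + 10 else prdm9_slot
  )
}

# run n meiosis attempts on a fixture genotype
attempt_meiosis <- function(genotype, d, c_hom = 1, symmetry = TRUE,
                            n = 1, seed = 1, trace = 0) {
  redqueen:::rq_meiosis_cpp(genotype, d = d, c_hom = c_hom,
                            symmetry = symmetry, n = n, seed = seed,
                            trace = trace)
}

# small standard configuration for engine tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(N = 50, u = 1e-3, v = 1e-3, h = 40, d = 6, mean_affinity = 6,
         generations = 200, burn_in = 50, seed = 7, record_every = 1),
    list(...))
  do.call(sim_config, args)
}
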
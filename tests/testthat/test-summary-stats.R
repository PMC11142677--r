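# Closed-form statistics: diversity, occupancy moments, symmetric-binding
# rates, fertility, haplo-insufficiency, background averaging, s0.

test_that("diversity is the inverse homozygosity", {
  expect_equal(diversity(1), 1)
  expect_equal(diversity(rep(1 / 7, 7)), 7)
  expect_equal(diversity(c(0.5, 0.25, 0.25)), 1 / 0.375)
  expect_error(diversity(numeric(0)), "empty")
  expect_error(diversity(c(0.5, 0.2)), "sum to 1")
})

test_that("moment set is monotone and q_hom reduces correctly", {
  set.seed(21)
  m <- site_moments(rexp(1000, 1 / 0.5), c = 2)
  expect_true(m$m3 <= m$m2 && m$m2 <= m$m1 && m$m1 <= 1)
  # degenerate distribution: q = 2x - x^2 = 1 - (1-x)^2
  x <- 0.5
  y <- x / (1 - x)
  mm <- site_moments(rep(y, 10), c = 1)
  expect_equal(q_hom(mm), 0.75)
  expect_equal(q_hom(mm), 1 - (1 - x)^2)
  # fully eroded allele: sterile flag
  q0 <- q_hom(list(m1 = 0, m2 = 0, m3 = 0))
  expect_equal(as.numeric(q0), 0)
  expect_true(attr(q0, "sterile"))
})

test_that("q_hom matches a Monte-Carlo quadrature of the moments", {
  # independent oracle: estimate <x^k> by direct MC over the exponential
  # affinity law and compare the plug-in q
  set.seed(22)
  x <- occupancy(rexp(1e6, 1 / 0.2), c = 2)
  q_mc <- (2 * mean(x^2) - mean(x^3)) / mean(x)
  set.seed(23)
  q_pkg <- q_hom(site_moments(rexp(800, 1 / 0.2), c = 2))
  expect_lt(abs(q_pkg - q_mc), 0.02)
})

test_that("q_het symmetry, limits, and site-enumeration oracle", {
  set.seed(24)
  y1 <- rexp(300, 1 / 0.2)
  y2 <- rexp(300, 1 / 0.2)
  m1 <- site_moments(y1, 1)
  m2 <- site_moments(y2, 1)
  # identical moment sets reduce to q_hom at c = 1
  expect_equal(q_het(m1, m1), q_hom(m1))
  # fully eroded partner: only the live allele contributes
  m0 <- list(m1 = 0, m2 = 0, m3 = 0)
  expect_equal(q_het(m1, m0), (2 * m1$m2 - m1$m3) / m1$m1)
  expect_true(attr(q_het(m0, m0), "sterile"))
  # brute-force per-site average over both alleles' sites
  x1 <- occupancy(y1, 1)
  x2 <- occupancy(y2, 1)
  brute <- (sum(x1 * (2 * x1 - x1^2)) + sum(x2 * (2 * x2 - x2^2))) /
    (sum(x1) + sum(x2))
  expect_equal(q_het(m1, m2), brute)
})

test_that("fertility is the Poisson no-success complement", {
  expect_equal(fertility(0, 6), 0)
  expect_equal(fertility(1, 1e9), 1)
  expect_equal(fertility(0.75, 6), 1 - exp(-4.5))
  q <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(fertility(q, 6)) > 0))          # increasing in q
  expect_true(all(fertility(q, 12) > fertility(q, 6))) # increasing in d
})

test_that("haplo-insufficiency definition and degenerate cases", {
  expect_equal(haplo_insufficiency(0.9, 0.9), 0)
  expect_equal(haplo_insufficiency(0.99, 0.9), 0.1)
  expect_true(is.na(haplo_insufficiency(0.5, 0)))
  # c_hom = 1: hemizygote and homozygote have identical occupancies
  set.seed(25)
  expect_equal(sigma_fresh(rexp(500, 1), d = 8, c_hom = 1), 0)
  expect_equal(sigma0(0.2, h = 100, d = 8, c_hom = 1), 0)
})

test_that("sigma0 and dosage: q_hom increases with c, sigma0 positive", {
  set.seed(26)
  y <- rexp(800, 1 / 0.2)
  expect_gt(q_hom(site_moments(y, 2)), q_hom(site_moments(y, 1)))
  set.seed(27)
  s <- sigma0(0.2, h = 800, d = 8, c_hom = 2)
  expect_gt(s, 0)
})

test_that("background-averaged statistics use weight 2 for homozygotes", {
  set.seed(28)
  pop <- init_population(N = 3, h = 20, mean_affinity = 0.5, L = 5000)
  res <- create_allele(pop, mean_affinity = 0.5)
  pop <- res$population
  idA <- pop$alleles[[1]]$id
  idB <- res$allele$id
  # genotypes: AA, AB, BB
  pop$haplotypes[[3]]$allele <- idB
  pop$haplotypes[[5]]$allele <- idB
  pop$haplotypes[[6]]$allele <- idB
  # degrade A's copy in the heterozygote to make backgrounds differ
  pop$haplotypes[[4]]$inactive[[1]] <- 1:10

  # allele with a single homozygous carrier: the genotype's own value
  qAA <- genotype_q(list(pop$alleles[[1]]$affinities),
                    list(rep(TRUE, 20)), list(rep(TRUE, 20)), c_hom = 2)
  qBB <- genotype_q(list(res$allele$affinities),
                    list(rep(TRUE, 20)), list(rep(TRUE, 20)), c_hom = 2)
  qAB <- genotype_q(
    list(pop$alleles[[1]]$affinities, res$allele$affinities),
    list(rep(TRUE, 20), rep(TRUE, 20)),
    list(c(rep(FALSE, 10), rep(TRUE, 10)), rep(TRUE, 20)), c_hom = 2)

  expect_equal(allele_background_average(pop, idB, "q", d = 8, c_hom = 2),
               (qAB + 2 * qBB) / 3)
  expect_equal(allele_background_average(pop, idA, "q", d = 8, c_hom = 2),
               (2 * qAA + qAB) / 3)
  expect_equal(allele_background_average(pop, idA, "w", d = 8, c_hom = 2),
               (2 * fertility(qAA, 8) + fertility(qAB, 8)) / 3)
  expect_error(allele_background_average(pop, 999, "q", d = 8), "no carriers")
})

test_that("selection on new alleles: exchangeable, erosion-driven, eviction", {
  set.seed(29)
  h <- 200
  # population fixed for a fresh allele, no dosage: probes are exchangeable
  # with the resident, s0 ~ 0 (up to probe sampling noise)
  pop <- init_population(N = 30, h = h, mean_affinity = 0.2, L = 50000)
  s_null <- selection_on_new_alleles(pop, mean_affinity = 0.2, h = h, d = 8,
                                     c_hom = 1, n_probes = 40)
  expect_lt(abs(s_null), 0.02)

  # heavily eroded resident (its highest-affinity sites converted, as
  # erosion does): fresh probes are favoured, s0 > 0
  top <- order(pop$alleles[[1]]$affinities, decreasing = TRUE)[1:150]
  pop_eroded <- pop
  pop_eroded$haplotypes <- lapply(pop_eroded$haplotypes, function(hp) {
    hp$inactive[[1]] <- sort(top)
    hp
  })
  s_pos <- selection_on_new_alleles(pop_eroded, mean_affinity = 0.2, h = h,
                                    d = 8, c_hom = 1, n_probes = 20)
  expect_gt(s_pos, 0.01)

  # eviction fixture: un-eroded homozygous resident with full dosage; fresh
  # probes land in heterozygotes at c = 1 and are counter-selected, s0 < 0
  s_neg <- selection_on_new_alleles(pop, mean_affinity = 0.2, h = h, d = 8,
                                    c_hom = 2, n_probes = 20)
  expect_lt(s_neg, 0)
})

test_that("closed-form fertility matches the kernel on heterozygotes too", {
  set.seed(30)
  y1 <- rexp(300, 1 / 0.5)
  y2 <- rexp(300, 1 / 0.5)
  gt <- make_genotype(y1, y2)
  n <- 20000
  res <- attempt_meiosis(gt, d = 6, c_hom = 2, n = n, seed = 31)
  w <- fertility(q_het(site_moments(y1, 1), site_moments(y2, 1)), 6)
  se <- sqrt(w * (1 - w) / n)
  expect_lt(abs(res$successes / n - w), 3 * se + 1e-3)
})
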
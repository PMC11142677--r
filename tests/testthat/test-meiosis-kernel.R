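# The meiosis kernel: occupancy, binding, DSBs, the symmetry requirement,
# conversion repair, crossover accounting, and the control mode.

test_that("occupancy follows the chemical-equilibrium law", {
  expect_equal(occupancy(1, 1), 0.5)
  expect_equal(occupancy(0, 2), 0)
  expect_equal(occupancy(6, 2), 12 / 13)
  expect_error(occupancy(-1, 1), "non-negative")
  # strictly increasing in affinity and in dosage
  y <- seq(0.1, 5, length.out = 20)
  expect_true(all(diff(occupancy(y, 1)) > 0))
  expect_true(all(occupancy(y, 2) > occupancy(y, 1)))
  expect_true(all(occupancy(y, 2) < 1))
})

test_that("binding count matches the binomial mean 4h*x over replicates", {
  h <- 50
  y <- rep(2, h)                       # x = 2/3 at c = 1; x = 4/5 at c = 2
  gt <- make_genotype(y)
  res <- attempt_meiosis(gt, d = 1e9, c_hom = 1, n = 4000, seed = 42)
  expect_lt(abs(res$mean_bound - 4 * h * 2 / 3),
            4 * sqrt(4 * h * (2 / 3) * (1 / 3) / 4000))
  res2 <- attempt_meiosis(gt, d = 1e9, c_hom = 2, n = 4000, seed = 43)
  expect_lt(abs(res2$mean_bound - 4 * h * 0.8),
            4 * sqrt(4 * h * 0.8 * 0.2 / 4000))
})

test_that("meiosis fails with no_binding when nothing can bind", {
  gt <- make_genotype(rep(5, 10),
                      active_a = list(rep(FALSE, 10)),
                      active_b = list(rep(FALSE, 10)))
  res <- attempt_meiosis(gt, d = 6, n = 50, seed = 1, trace = 1)
  expect_equal(res$successes, 0)
  expect_equal(res$no_binding, 50)
  expect_equal(res$traces[[1]]$failure_reason, "no_binding")
  expect_equal(res$traces[[1]]$n_bound, 0)
})

test_that("all bound sites break when k <= d, and E[#DSB] = d when k > d", {
  # few sites of enormous affinity: k = 4h deterministic, all break (p = 1)
  gt <- make_genotype(rep(1e9, 3))
  res <- attempt_meiosis(gt, d = 100, n = 200, seed = 2)
  expect_equal(res$mean_dsb, 12)
  # abundant binding: mean DSB number is d
  gt2 <- make_genotype(rep(6, 300))
  res2 <- attempt_meiosis(gt2, d = 6, n = 5000, seed = 3)
  expect_lt(abs(res2$mean_dsb - 6), 4 * sqrt(6 / 5000))
})

test_that("a DSB is symmetric only via the other homolog, not the sister", {
  # locus 1 active on both homologs; locus 2 active only on hap_a
  act_a <- list(c(TRUE, TRUE))
  act_b <- list(c(TRUE, FALSE))
  gt <- make_genotype(c(1e9, 1e9), active_a = act_a, active_b = act_b)
  res <- attempt_meiosis(gt, d = 1e9, n = 400, seed = 4, trace = 400)
  expect_equal(res$successes, 400)     # locus 1 always symmetrically broken
  for (tr in res$traces) {
    # 6 instances bound (4 at locus 1, 2 at locus 2 on A chromatids), all break
    expect_equal(tr$n_bound, 6)
    expect_equal(tr$n_dsb, 6)
    # the locus-2 DSBs (bound on both A chromatids, i.e. sister-only) are
    # never symmetric: only the 4 locus-1 DSBs are
    expect_equal(tr$n_symmetric, 4)
    expect_equal(tr$co_site, 1)
  }
})

test_that("meiosis fails without a symmetric DSB, but control mode succeeds", {
  # hap_b inactive everywhere: binding only on A chromatids, never symmetric
  h <- 20
  gt <- make_genotype(rep(1e9, h),
                      active_b = list(rep(FALSE, h)))
  res <- attempt_meiosis(gt, d = 6, symmetry = TRUE, n = 300, seed = 5)
  expect_equal(res$successes, 0)
  expect_equal(res$no_symmetric_dsb, 300)
  res2 <- attempt_meiosis(gt, d = 6, symmetry = FALSE, n = 300, seed = 6)
  expect_equal(res2$successes, 300)
})

test_that("conversion copies the homolog state: inactive templates convert,
           and conversion never activates a site", {
  # single target, active on A, inactive on B; control mode so meiosis
  # succeeds despite asymmetry
  gt <- make_genotype(1e9, active_b = list(FALSE))
  res <- attempt_meiosis(gt, d = 2, symmetry = FALSE, n = 600, seed = 7,
                         trace = 600)
  got_a <- 0L
  for (tr in res$traces) {
    expect_true(tr$success)
    gam <- tr$gamete
    # a gamete from an A chromatid was broken at the locus (it is always
    # bound and always breaks) and repaired off B: it must now be inactive.
    # a gamete from a B chromatid stays inactive (inherited).
    expect_equal(gam$inactive[[1]], 1)
    got_a <- got_a + (tr$co_chromatid <= 2)
  }
  expect_gt(got_a, 0)
})

test_that("exactly one crossover per successful meiosis, at a symmetric DSB", {
  set.seed(8)
  gt <- make_genotype(rexp(80, 1 / 6))
  res <- attempt_meiosis(gt, d = 6, n = 200, seed = 8, trace = 200)
  for (tr in res$traces) {
    if (!tr$success) next
    expect_length(tr$co_site, 1L)
    expect_false(is.na(tr$co_site))
    expect_gte(tr$n_symmetric, 1)
    # CO partner lies on the other homolog
    own_side <- tr$co_chromatid <= 2
    partner_side <- tr$partner_chromatid <= 2
    expect_true(own_side != partner_side)
  }
})

test_that("homozygote with saturating affinities almost always succeeds", {
  # all 40 instances bound; the only failure mode is zero DSBs after
  # thinning, with probability (1 - d/k)^k ~ exp(-6)
  gt <- make_genotype(rep(1e9, 10))
  res <- attempt_meiosis(gt, d = 6, n = 2000, seed = 9)
  expect_equal(res$no_binding, 0)          # k = 40 always
  expect_gt(res$successes / 2000, 1 - 3 * (1 - 6 / 40)^40)
})

test_that("fixed seed reproduces meiosis outcomes bit for bit", {
  set.seed(10)
  gt <- make_genotype(rexp(60, 1 / 2), rexp(60, 1 / 2))
  r1 <- attempt_meiosis(gt, d = 6, n = 200, seed = 77, trace = 5)
  r2 <- attempt_meiosis(gt, d = 6, n = 200, seed = 77, trace = 5)
  expect_identical(r1, r2)
  r3 <- attempt_meiosis(gt, d = 6, n = 200, seed = 78)
  expect_false(identical(r1$successes, r3$successes) &&
               identical(r1$mean_bound, r3$mean_bound))
})

test_that("empirical success rate matches the closed-form 1 - exp(-d q)
           across affinity, DSB number and dosage", {
  set.seed(11)
  n <- 20000
  grid <- expand.grid(ybar = c(0.2, 1, 6), d = c(6, 24), c = c(1, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    y <- rexp(400, 1 / g$ybar)
    gt <- make_genotype(y)
    res <- attempt_meiosis(gt, d = g$d, c_hom = g$c, n = n, seed = 100 + i)
    q <- q_hom(site_moments(y, g$c))
    w <- fertility(q, g$d)
    se <- sqrt(w * (1 - w) / n)
    expect_lt(abs(res$successes / n - w), 3 * se + 1e-4)
  }
})

test_that("homozygote success rate is monotone non-decreasing in dosage", {
  set.seed(12)
  y <- rexp(400, 1 / 0.2)
  gt <- make_genotype(y)
  succ <- vapply(c(1, 1.5, 2), function(cc) {
    attempt_meiosis(gt, d = 8, c_hom = cc, n = 20000, seed = 55)$successes
  }, numeric(1))
  expect_true(all(diff(succ) > -3 * sqrt(20000 * 0.25)))
})
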
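# The generation loop: population size, reproducibility, neutrality of the
# control model, checkpoint/restart, and the livelock guard.

test_that("each generation has exactly N individuals and frequencies sum to 1", {
  cfg <- small_config()
  res <- run_redqueen(cfg, return_population = TRUE)
  expect_length(res$population$haplotypes, 2 * cfg$N)
  tr <- res$trajectory
  sums <- tapply(tr$f, tr$generation, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  cfg <- small_config(s0_every = 50)
  r1 <- run_redqueen(cfg)
  r2 <- run_redqueen(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$scalars, r2$scalars)
  expect_identical(r1$s0, r2$s0)
  cfg2 <- small_config(seed = 8, s0_every = 50)
  r3 <- run_redqueen(cfg2)
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("generations = 0 yields only the initial record", {
  cfg <- sim_config(N = 10, u = 0, v = 0, h = 5, generations = 0, burn_in = 0,
                    seed = 1)
  res <- run_redqueen(cfg)
  expect_equal(nrow(res$scalars), 1L)
  expect_equal(res$summary$n_generations, 0L)
})

test_that("neutral control drift: fixation probability matches initial frequency", {
  # u = v = 0, saturating affinities, control mode: no selective differences.
  # An allele starting at frequency 1/2 must fix with probability ~ 1/2.
  set.seed(42)
  pop <- init_population(N = 30, h = 4, mean_affinity = 1000, L = 500)
  res <- create_allele(pop, mean_affinity = 1000)
  pop <- res$population
  for (i in seq_len(30)) pop$haplotypes[[i]]$allele <- res$allele$id
  cfg <- sim_config(N = 30, u = 0, v = 0, h = 4, d = 6, mean_affinity = 1000,
                    mode = "control_no_symmetry", generations = 400,
                    burn_in = 0, seed = 1, record_every = 400)
  fixed <- vapply(1:120, function(r) {
    cfg$seed <- 1000 + r
    out <- run_redqueen(cfg, init = pop)
    tr <- out$trajectory
    last <- tr[tr$generation == max(tr$generation), ]
    any(last$allele_id == res$allele$id & last$f == 1)
  }, logical(1))
  p_hat <- mean(fixed)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 120))
})

test_that("a run can restart from its own snapshot", {
  cfg <- small_config(generations = 60, burn_in = 10)
  r1 <- run_redqueen(cfg, return_population = TRUE)
  snap <- r1$population
  cfg2 <- small_config(generations = 40, burn_in = 10, seed = 99)
  r2 <- run_redqueen(cfg2, init = snap)
  expect_equal(r2$scalars$generation[1], snap$generation)
  expect_equal(nrow(r2$scalars), 41L)
  # restart through the JSON serialisation gives the same continuation
  # (affinities may differ in the last ulp after the text round trip, so
  # derived occupancy statistics are compared numerically)
  path <- tempfile(fileext = ".json")
  write_population(snap, path)
  r3 <- run_redqueen(cfg2, init = read_population(path))
  expect_identical(r3$scalars$generation, r2$scalars$generation)
  expect_identical(r3$scalars$n_alleles, r2$scalars$n_alleles)
  expect_identical(r3$scalars$D, r2$scalars$D)
  expect_equal(r3$scalars$q_bar, r2$scalars$q_bar, tolerance = 1e-12)
  expect_equal(r3$scalars$w_bar, r2$scalars$w_bar, tolerance = 1e-12)
  unlink(path)
})

test_that("a sterile population aborts with the livelock diagnostic", {
  # every target inactive and v fixed: k = 0 in every meiosis
  set.seed(13)
  pop <- init_population(N = 5, h = 3, mean_affinity = 5, L = 500)
  pop$haplotypes <- lapply(pop$haplotypes, function(hp) {
    hp$inactive <- list(1:3)
    hp
  })
  cfg <- sim_config(N = 5, u = 0, v = 0, h = 3, mean_affinity = 5,
                    generations = 5, burn_in = 0, seed = 1)
  expect_error(run_redqueen(cfg, init = pop), "sterile")
})

test_that("per-attempt failures redraw the parent; n_mei retries multiply success", {
  # fertility w per attempt; per-parent-draw success 1 - (1-w)^n_mei shows up
  # as fewer attempts per gamete at n_mei = 5 for an intermediate-w genotype
  set.seed(14)
  y <- rexp(100, 1 / 0.1)   # low affinities: substantial failure rate
  pop <- init_population(N = 20, h = 100, mean_affinity = 0.1, L = 30000)
  pop$alleles[[1]]$affinities <- y
  run_att <- function(n_mei) {
    cfg <- sim_config(N = 20, u = 0, v = 0, h = 100, d = 6,
                      mean_affinity = 0.1, n_mei = n_mei, generations = 30,
                      burn_in = 0, seed = 3, record_every = 30, L = 30000)
    run_redqueen(cfg, init = pop)$counters
  }
  c1 <- run_att(1)
  w <- c1$successes / c1$attempts
  expect_gt(w, 0.2)
  expect_lt(w, 0.95)
  c5 <- run_att(5)
  w5 <- c5$successes / c5$attempts
  # per-attempt success probability is a property of the genotype, not n_mei
  expect_lt(abs(w5 - w), 4 * sqrt(w * (1 - w) / c5$attempts) + 0.02)
})

test_that("erosion of a pinned allele accelerates with frequency (rate ~ f)", {
  # two subpopulation runs cannot be compared directly; instead check the
  # mean-field proportionality d(theta)/dt ~ -rho*f*theta via f = 1 vs the
  # analytical ratio at doubled v
  cfg <- sim_config(N = 100, u = 0, v = 5e-4, h = 40, d = 6,
                    mean_affinity = 6, generations = 300, burn_in = 0,
                    seed = 5, record_every = 10)
  r1 <- run_redqueen(cfg)
  cfg$v <- 1e-3
  cfg$seed <- 6
  r2 <- run_redqueen(cfg)
  end1 <- 1 - tail(r1$scalars$theta_bar, 1)
  end2 <- 1 - tail(r2$scalars$theta_bar, 1)
  expect_gt(end2, end1)   # erosion increases with v
})
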
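test_that("mixture_freq is the ancestry-weighted lineage frequency", {
  panel <- make_panel(c(0.8, 0.9), c(0.2, 0.1), c(0.5, 0.5))
  expect_equal(mixture_freq(panel, c(1, 0, 0), 1), 0.8)
  expect_equal(mixture_freq(panel, c(0.5, 0.5, 0), 1), 0.5)
  expect_equal(mixture_freq(panel, c(0.6, 0.2, 0.2), 2), 0.66)
  # clamping keeps frequencies off 0/1
  fixed <- make_panel(1, 0, 0)
  expect_equal(mixture_freq(fixed, c(1, 0, 0), 1), 1 - 1e-6)
  expect_equal(mixture_freq(fixed, c(0, 1, 0), 1), 1e-6)
})

test_that("binomial log-probability matches the exact closed form", {
  expect_equal(binomial_log_prob(0, 40, 0.5), 40 * log(0.5))
  expect_equal(binomial_log_prob(40, 40, 0.5), 40 * log(0.5))
  # C(40, 20) = 137846528820 by independent big-integer computation
  expect_equal(binomial_log_prob(20, 40, 0.5),
               log(137846528820) + 40 * log(0.5), tolerance = 1e-12)
})

test_that("negative log-likelihood reduces correctly and matches the exact oracle", {
  # flat panel: likelihood identical for every admixture vector
  panel <- flat_panel(4)
  colony <- make_colony(c(10L, 20L, 30L, 5L), panel)
  vals <- sapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1) / 3),
                 function(a) neg_log_likelihood(colony, panel, a))
  expect_equal(max(vals) - min(vals), 0)

  # single diagnostic SNP reduces to one binomial term
  p1 <- make_panel(1, 0, 0)
  c1 <- make_colony(20L, p1)
  expect_equal(neg_log_likelihood(c1, p1, c(0.5, 0.25, 0.25)),
               -binomial_log_prob(20, 40, 0.5))

  # random instances vs exact term-by-term oracle
  set.seed(41)
  for (i in 1:20) {
    inst <- random_instance(5)
    amc <- random_simplex()
    expect_equal(neg_log_likelihood(inst$colony, inst$panel, amc),
                 oracle_nll(inst$colony, inst$panel, amc), tolerance = 1e-9)
  }

  # missing SNPs contribute zero
  panel2 <- make_panel(c(0.9, 0.2), c(0.1, 0.7), c(0.4, 0.4))
  full <- make_colony(c(30L, 10L), panel2)
  part <- make_colony(c(30L, NA), panel2)
  one <- make_panel(0.9, 0.1, 0.4)
  expect_equal(neg_log_likelihood(part, panel2, c(0.3, 0.3, 0.4)),
               neg_log_likelihood(make_colony(30L, one), one, c(0.3, 0.3, 0.4)))
  expect_gt(neg_log_likelihood(full, panel2, c(0.3, 0.3, 0.4)),
            neg_log_likelihood(part, panel2, c(0.3, 0.3, 0.4)))
})

test_that("the estimate lies on the simplex and recovers vertices", {
  cfg <- simulation_config(seed = 21)
  panel <- simulate_panel(cfg)
  sim <- simulate_colony(panel, c(1, 0, 0), cfg)
  est <- estimate_admixture(sim$observation, panel)
  expect_equal(est$A + est$M + est$C, 1, tolerance = 1e-6)
  expect_gte(est$A, 0.99)
  expect_true(est$converged)
  expect_false(est$flat_likelihood_flag)
  expect_true(is.finite(est$neg_log_likelihood))
})

test_that("optimizer dominates the 0.01 grid oracle", {
  cfg <- simulation_config(seed = 22)
  panel <- simulate_panel(cfg)
  for (i in 1:8) {
    set.seed(300 + i)
    truth <- random_simplex()
    sim <- simulate_colony(panel, truth, simulation_config(seed = 300 + i))
    est <- estimate_admixture(sim$observation, panel)
    g <- grid_oracle(sim$observation, panel, step = 0.01)
    expect_lte(est$neg_log_likelihood, g$value + 1e-6)
    expect_true(max(abs(c(est$A, est$M, est$C) - g$admixture)) <= 0.01 + 1e-9)
  }
})

test_that("grid oracle lattice and tie-breaking follow the stated rules", {
  panel <- flat_panel(3)
  colony <- make_colony(c(20L, 18L, 22L), panel)
  g <- grid_oracle(colony, panel, step = 0.5)
  expect_equal(g$n_points, 6L)
  # flat likelihood: lexicographically smallest (A, M) wins -> (0, 0, 1)
  expect_equal(unname(g$admixture), c(0, 0, 1))
  expect_error(grid_oracle(colony, panel, step = 0.7), "step")
})

test_that("non-identifiable panels raise the flat-likelihood flag", {
  panel <- flat_panel(10)
  set.seed(5)
  for (i in 1:5) {
    colony <- make_colony(sample(0:40, 10, replace = TRUE), panel)
    est <- estimate_admixture(colony, panel)
    expect_true(est$flat_likelihood_flag)
  }
  # informative panels must not be flagged
  cfg <- simulation_config(seed = 23)
  p <- simulate_panel(cfg)
  sim <- simulate_colony(p, c(0.6, 0.2, 0.2), cfg)
  expect_false(estimate_admixture(sim$observation, p)$flat_likelihood_flag)
})

test_that("estimates are equivariant under lineage relabeling", {
  cfg <- simulation_config(seed = 24, panel_mode = "beta", n_snps = 40)
  panel <- simulate_panel(cfg)
  sim <- simulate_colony(panel, c(0.5, 0.3, 0.2), cfg)
  est <- estimate_admixture(sim$observation, panel)
  perm <- c(3L, 1L, 2L)   # rows reordered: new A = old C etc.
  panel_p <- lineage_panel(panel$snp_ids, panel$freqs[perm, ],
                           lineages = c("A", "M", "C"))
  est_p <- estimate_admixture(sim$observation, panel_p)
  expect_equal(c(est_p$A, est_p$M, est_p$C), c(est$A, est$M, est$C)[perm],
               tolerance = 1e-4)
  expect_equal(est_p$neg_log_likelihood, est$neg_log_likelihood,
               tolerance = 1e-6)
})

test_that("more informative loci give better recovery (consistency in L)", {
  err_at_L <- function(L, seeds) {
    sapply(seeds, function(s) {
      cfg <- simulation_config(seed = s, n_snps = L)
      panel <- simulate_panel(cfg)
      sim <- simulate_colony(panel, c(0.6, 0.2, 0.2), cfg)
      est <- estimate_admixture(sim$observation, panel)
      abs(est$A - 0.6)
    })
  }
  seeds <- 400:429
  e10 <- stats::median(err_at_L(10L, seeds))
  e94 <- stats::median(err_at_L(94L, seeds))
  e500 <- stats::median(err_at_L(500L, seeds))
  expect_lte(e94, e10)
  expect_lte(e500, e94)
})

test_that("estimate_batch is per-colony fault-tolerant and consistent", {
  cfg <- simulation_config(seed = 25, n_colonies = 10, n_apiaries = 2)
  A <- seq(0.05, 0.95, length.out = 10)
  truths <- cbind(A, (1 - A) * 0.6, (1 - A) * 0.4)
  sim <- simulate_dataset(cfg, true_admixture = truths)
  est <- estimate_batch(sim$colonies, sim$panel)
  expect_equal(nrow(est), 10L)
  expect_true(all(est$converged))
  expect_true(all(is.na(est$error)))
  # batch mean equals the arithmetic mean of per-colony estimates
  expect_equal(mean(est$A), sum(est$A) / 10)
  # rank order of true A recovered
  expect_gt(stats::cor(est$A, truths[, 1], method = "spearman"), 0.9)

  # an all-missing colony cannot be built, but a failing one is recorded:
  flat <- flat_panel(3)
  cols <- list(make_colony(c(1L, 2L, 3L), flat, id = "ok"))
  est2 <- estimate_batch(cols, flat)
  expect_true(est2$flat_flag[1])
})
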
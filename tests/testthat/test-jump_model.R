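test_that("the closed-form block-length pmf is a proper distribution", {
  lams <- exp(seq(log(0.01), log(20), length.out = 25))
  for (lam in lams) {
    tab <- jump_model_table(lam)
    expect_equal(sum(tab$pmf), 1, tolerance = 1e-12)
    K <- nrow(tab)
    expect_gte(jump_cdf(K, lam), 1 - 1e-9)          # truncation criterion
    # untruncated mass: analytic normalization is exact
    expect_equal(sum(jump_pmf(1:(K + 50L), lam)), 1, tolerance = 1e-9)
    expect_true(all(diff(jump_cdf(1:20, lam)) >= 0)) # cdf monotone
  }
})

test_that("cdf and pmf telescope", {
  for (lam in c(0.1, 1, 5)) {
    k <- 2:40
    # absolute comparison: deep in the geometric tail both sides underflow
    expect_lt(max(abs(jump_cdf(k, lam) - jump_cdf(k - 1, lam) -
                        jump_pmf(k, lam))), 1e-12)
    expect_equal(jump_cdf(1, lam), jump_pmf(1, lam), tolerance = 1e-12)
  }
})

test_that("scrambling and sparse limits behave", {
  expect_gt(jump_pmf(1, 20), 0.999)    # near-complete scrambling
  expect_gt(jump_cdf(1, 20), 0.999)
  # lambda -> 0: one sparse jump cuts the genome into three blocks, one of
  # them the moved singleton, so a third of blocks have length one
  expect_equal(jump_pmf(1, 1e-6), 1 / 3, tolerance = 1e-4)
  # expected mean block length strictly decreasing in lambda
  m <- vapply(c(0.05, 0.1, 0.3, 1, 3), function(l) {
    tab <- jump_model_table(l)
    sum(tab$k * tab$pmf)
  }, 0)
  expect_true(all(diff(m) < 0))
})

test_that("domain errors are raised", {
  expect_error(jump_pmf(1, 0), "positive")
  expect_error(jump_pmf(1, -1), "positive")
  expect_error(jump_pmf(0, 0.5), "positive integer")
  expect_error(jump_cdf(1.5, 0.5), "positive integer")
})

test_that("the jump simulation honours its contract", {
  sim0 <- simulate_jumps(100, 0, seed = 1)
  expect_identical(genome_cogs(sim0$ancestral), genome_cogs(sim0$derived))
  sbl0 <- extract_synteny_blocks(sim0$ancestral, sim0$derived)
  expect_equal(sbl0$total_blocks, 1)

  # determinism
  s1 <- simulate_jumps(500, 200, seed = 7)
  s2 <- simulate_jumps(500, 200, seed = 7)
  expect_identical(genome_cogs(s1$derived), genome_cogs(s2$derived))
  # gene set unchanged
  expect_setequal(genome_cogs(s1$derived), genome_cogs(s1$ancestral))

  # a single jump creates at most four blocks (moved singleton, the two
  # flanks of the source gap, the split destination piece)
  for (s in 1:10) {
    sim <- simulate_jumps(1000, 1, seed = s)
    sbl <- extract_synteny_blocks(sim$ancestral, sim$derived)
    expect_lte(sbl$total_blocks, 4)
    expect_gte(mean_sbl(sbl), 250)
  }
})

test_that("closed form matches the simulation oracle", {
  # Pooled empirical pmf over several runs; guards the transcription of
  # the displayed equation. The closed form is the model's asymptotic
  # solution: residual systematic Wasserstein offset is ~0.05 at moderate
  # lambda, while any mis-grouping of the equation exceeds 0.3.
  for (lam in c(0.1, 1.0)) {
    p <- pooled_sim_pmf(20000L, lam, seeds = 1:5)
    tab <- jump_model_table(lam, kmax = length(p))
    m <- numeric(length(p))
    m[tab$k] <- tab$pmf
    expect_lt(wasserstein1(p, m / sum(m)), 0.08)
  }
})

test_that("lambda fitting recovers tabulated model distributions exactly", {
  for (lam0 in c(0.05, 0.2, 0.4, 1.0)) {
    tab <- jump_model_table(lam0)
    obs <- sbl_distribution(setNames(tab$pmf, tab$k), counted = TRUE)
    fit <- fit_lambda(obs)
    expect_equal(fit$lambda, lam0, tolerance = 1e-3)
    expect_equal(fit$flag, "interior")
  }
})

test_that("lambda fitting flags saturated and degenerate inputs", {
  scrambled <- sbl_distribution(rep(1L, 1000))
  expect_equal(fit_lambda(scrambled)$flag, "high_bound")

  one_block <- sbl_distribution(2000L)
  fit <- fit_lambda(one_block)
  expect_equal(fit$flag, "degenerate")
  expect_equal(fit$lambda, 0)
})

test_that("lambda fitting recovers the simulated translocation load", {
  lams <- vapply(1:10, function(s) {
    sim <- simulate_jumps(20000, 4000, seed = s)
    fit_lambda(extract_synteny_blocks(sim$ancestral, sim$derived))$lambda
  }, 0)
  expect_lt(abs(median(lams) - 0.2) / 0.2, 0.15)
})
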
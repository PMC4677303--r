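test_that("Fermi imitation probability behaves at its limits", {
  expect_equal(fermi_imitation_probability(3, 3, 5), 0.5)
  expect_equal(fermi_imitation_probability(1, 9, 0), 0.5)
  expect_equal(fermi_imitation_probability(1, 2, 100), 1, tolerance = 1e-10)
  expect_equal(fermi_imitation_probability(2, 1, 100), 0, tolerance = 1e-10)
  # numerically stable at large argument
  expect_equal(fermi_imitation_probability(0, 700, 1), 1)
  expect_equal(fermi_imitation_probability(700, 0, 1), 0)
  expect_error(fermi_imitation_probability(1, 2, -1), "beta")
})

test_that("transition probabilities are neutral-symmetric and satisfy detailed balance", {
  N <- 30
  tr <- transition_probabilities(7, 4, 2, N, 0)
  # at beta = 0 the Fermi factor is 1/2 and T+ and T- coincide
  expect_equal(tr$T_plus, 7 * (N - 7) / N^2 / 2)
  expect_equal(tr$T_minus, tr$T_plus)
  expect_error(transition_probabilities(0, 1, 2, N, 1), "absorbing")
  expect_error(transition_probabilities(N, 1, 2, N, 1), "absorbing")
  # T-/T+ = exp(-beta (f_A - f_B)) over random inputs
  set.seed(1)
  for (i in 1:50) {
    k <- sample(1:(N - 1), 1)
    fA <- runif(1, 0, 10); fB <- runif(1, 0, 10); b <- runif(1, 0, 5)
    tr <- transition_probabilities(k, fA, fB, N, b)
    expect_equal(tr$T_minus / tr$T_plus, exp(-b * (fA - fB)),
                 tolerance = 1e-12)
  }
})

test_that("closed-form fixation probability matches the product-formula oracle", {
  set.seed(42)
  for (i in 1:200) {
    N <- sample(2:50, 1)
    fA <- runif(1, 0, 10); fB <- runif(1, 0, 10); b <- runif(1, 0, 5)
    expect_equal(fixation_probability(fA, fB, N, b),
                 fixation_bruteforce(fA, fB, N, b), tolerance = 1e-12)
  }
})

test_that("fixation probability has the known analytic special cases", {
  expect_identical(fixation_probability(3, 7, 100, 0), 1 / 100)
  expect_identical(fixation_probability(5, 5, 100, 2), 1 / 100)
  # N = 2: fixation equals the single imitation probability
  for (b in c(0.1, 1, 5)) {
    expect_equal(fixation_probability(4, 2, 2, b),
                 fermi_imitation_probability(2, 4, b), tolerance = 1e-12)
  }
  # log-domain branch: strongly disfavoured mutants underflow gracefully
  expect_true(fixation_probability(1, 9, 100, 10) >= 0)
  expect_lt(fixation_probability(1, 9, 100, 1), 1e-100)
})

test_that("embedded chain has the product state space and stochastic rows", {
  cfg <- ag_restricted()
  sp <- population_spec(cfg, N = 100)
  ch <- build_embedded_chain(sp, cfg, beta = 0.05)
  expect_equal(nrow(ch$states), 50)
  expect_equal(rowSums(ch$M), rep(1, 50), tolerance = 1e-12)
  expect_true(all(ch$M - diag(diag(ch$M)) >= 0))
  dgc <- dg_config()
  chd <- build_embedded_chain(population_spec(dgc), dgc, beta = 0.05)
  expect_equal(nrow(chd$states), 10)
  expect_equal(rowSums(chd$M), rep(1, 10), tolerance = 1e-12)
})

test_that("uniform rescaling of mutant-allocation weights preserves the stationary distribution", {
  cfg <- ag_restricted()
  sp <- population_spec(cfg, N = 100)
  d_half <- stationary_distribution(build_embedded_chain(sp, cfg, 0.02))
  # a lazier chain: both weights scaled by the same factor
  d_lazy <- stationary_distribution(
    build_embedded_chain(sp, cfg, 0.02, w_dictator = 0.25,
                         w_receiver = 0.25))
  expect_equal(d_half$probs, d_lazy$probs, tolerance = 1e-9)
})

test_that("stationary distribution satisfies pi M = pi and is normalised", {
  cfg <- ag_restricted()
  sp <- population_spec(cfg, N = 100)
  for (b in c(1e-6, 0.01, 0.3, 10)) {
    ch <- build_embedded_chain(sp, cfg, b)
    d <- stationary_distribution(ch)
    expect_lt(max(abs(drop(d$probs %*% ch$M) - d$probs)), 1e-10)
    expect_equal(sum(d$probs), 1, tolerance = 1e-10)
    expect_true(all(d$probs >= 0))
    expect_equal(sum(d$dictator_marginal), 1, tolerance = 1e-10)
    expect_equal(sum(d$receiver_marginal), 1, tolerance = 1e-10)
  }
})

test_that("neutral drift yields the uniform distribution over states", {
  cfg <- ag_restricted()
  sp <- population_spec(cfg, N = 100)
  d <- stationary_distribution(build_embedded_chain(sp, cfg, 1e-6))
  expect_lt(total_variation(d$probs, rep(1 / 50, 50)), 1e-3)
})

test_that("strong selection drives every variant to its minimum viable donation", {
  # DG and AG: 1 ECU. Noisy AG: an uninformed receiver applies the baseline
  # expectation q0 = 2, so 1-ECU donations are rejected half the time and
  # the backward-induction donation is 2.
  cases <- list(list(cfg = dg_config(), p_star = "1"),
                list(cfg = ag_restricted(), p_star = "1"),
                list(cfg = game_config("NOISY_AG", q_max = 5), p_star = "2"))
  for (case in cases) {
    sp <- population_spec(case$cfg, N = 100)
    d <- stationary_distribution(build_embedded_chain(sp, case$cfg, 10))
    expect_gt(d$dictator_marginal[case$p_star], 0.99)
  }
})

test_that("mean donation and expectation decrease with selection intensity", {
  grid <- default_beta_grid(length.out = 25)
  cfg <- ag_restricted()
  tab <- beta_sweep(population_spec(cfg, N = 100), cfg, grid)
  expect_nonincreasing(tab$mean_p)
  expect_nonincreasing(tab$mean_q)
})

test_that("summary statistics of a distribution are the marginal means", {
  cfg <- ag_restricted()
  sp <- population_spec(cfg, N = 100)
  d <- stationary_distribution(build_embedded_chain(sp, cfg, 1e-6))
  s <- summary(d)
  # uniform-ish marginal over 1..10 has mean 5.5
  expect_equal(s$mean_p, 5.5, tolerance = 1e-3)
  expect_equal(s$mean_p, sum(1:10 * d$dictator_marginal))
  expect_equal(s$mean_q, sum(1:5 * d$receiver_marginal))
  # point mass: strong selection puts the mean at 1
  d10 <- stationary_distribution(build_embedded_chain(sp, cfg, 10))
  expect_equal(d10$mean_p, 1, tolerance = 1e-6)
})
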
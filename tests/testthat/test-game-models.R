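test_that("effective expectation is the stated convex combination", {
  expect_equal(effective_expectation(4, 1, 2), 4)
  expect_equal(effective_expectation(4, 0.5, 2), 3.0)
  expect_equal(effective_expectation(5, 0, 2), 2.0)
  expect_error(effective_expectation(4, 1.2, 2), "omega")
})

test_that("acceptance follows the at-least threshold rule", {
  cfg <- ag_restricted()
  # the most demanding receiver accepts donations of at least 5
  expect_equal(accept_probability(5, 5, cfg), 1)
  expect_equal(accept_probability(2, 5, cfg), 0)
  # full-endowment donation clears any threshold
  expect_true(all(accept_probability(rep(10, 5), 1:5, cfg) == 1))
  # DG: the receiver has no action
  expect_equal(accept_probability(1, 1, dg_config()), 1)
})

test_that("Bernoulli information mixing averages the two indicator branches", {
  cfg <- game_config("NOISY_AG", q_max = 5, omega = 0.5, q0 = 2,
                     acceptance_mode = "BERNOULLI_MIX")
  # informed branch rejects (3 < 5), uninformed accepts (3 >= 2)
  expect_equal(accept_probability(3, 5, cfg), 0.5)
})

test_that("acceptance is monotone in p and q in both modes", {
  for (mode in c("THRESHOLD_MIX", "BERNOULLI_MIX")) {
    for (om in c(0, 0.3, 0.7, 1)) {
      cfg <- game_config("NOISY_AG", q_max = 5, omega = om,
                         acceptance_mode = mode)
      for (q in 1:5) {
        a <- accept_probability(1:10, rep(q, 10), cfg)
        expect_true(all(diff(a) >= 0))
      }
      for (p in 1:10) {
        a <- accept_probability(rep(p, 5), 1:5, cfg)
        expect_true(all(diff(a) <= 0))
      }
    }
  }
})

test_that("the two acceptance modes coincide at omega 0 and 1", {
  grid <- expand.grid(p = 1:10, q = 1:5)
  for (om in c(0, 1)) {
    thr <- game_config("NOISY_AG", q_max = 5, omega = om)
    ber <- game_config("NOISY_AG", q_max = 5, omega = om,
                       acceptance_mode = "BERNOULLI_MIX")
    expect_equal(accept_probability(grid$p, grid$q, thr),
                 accept_probability(grid$p, grid$q, ber))
  }
})

test_that("stage payoffs split the endowment on acceptance, zero otherwise", {
  cfg <- game_config("AG")
  sp <- stage_payoffs(3, 2, cfg)
  expect_equal(sp$dictator, 7)
  expect_equal(sp$receiver, 3)
  expect_true(sp$accepted)
  rej <- stage_payoffs(1, 3, cfg)
  expect_equal(c(rej$dictator, rej$receiver), c(0, 0))
  expect_false(rej$accepted)
  # conservation: payoffs sum to X on acceptance, 0 on rejection
  grid <- expand.grid(p = 1:10, q = 1:10)
  out <- stage_payoffs(grid$p, grid$q, cfg)
  tot <- out$dictator + out$receiver
  expect_true(all(tot[out$accepted] == cfg$X))
  expect_true(all(tot[!out$accepted] == 0))
})

test_that("anticipatory fitness interpolates current and future payoff", {
  crv <- structure(list(p = 1:10, A = c(0, 0, 0, 0.8, rep(1, 6))),
                   class = "acceptance_curve")
  # delta = 0: the future is ignored, stage payoff recovered for all (p, q)
  cfg0 <- ag_restricted(delta = 0)
  grid <- expand.grid(p = 1:10, q = 1:5)
  expect_equal(anticipatory_dictator_fitness(grid$p, grid$q, crv, cfg0),
               stage_payoffs(grid$p, grid$q, cfg0)$dictator)
  # delta = 1: success depends solely on the anticipated future payoff
  cfg1 <- ag_restricted(delta = 1)
  expect_equal(anticipatory_dictator_fitness(4, 1, crv, cfg1),
               (10 - 4) * 0.8)
  # intermediate delta: plain arithmetic
  cfg5 <- ag_restricted(delta = 0.5)
  expect_equal(anticipatory_dictator_fitness(4, 1, crv, cfg5),
               0.5 * 6 + 0.5 * 6 * 0.8)
  # rejection now zeroes present and future
  expect_equal(anticipatory_dictator_fitness(2, 5, crv, cfg5), 0)
  # curve must cover the donation range
  short <- structure(list(p = 1:5, A = rep(1, 5)),
                     class = "acceptance_curve")
  expect_error(anticipatory_dictator_fitness(7, 1, short, cfg5), "cover")
})

test_that("game configuration validates its invariants", {
  expect_error(game_config("AG", p_min = 0), "p_min")
  expect_error(game_config("AG", p_max = 8), "endowment")
  expect_error(game_config("AG", q_max = 11), "q_max")
  expect_error(game_config("AG", delta = 1.5), "delta")
  cfg <- game_config("dg")
  expect_equal(cfg$variant, "DG")
  expect_equal(cfg$omega, 1)
})

test_that("game configurations round-trip through YAML", {
  cfg <- game_config("NOISY_AG", q_max = 5, omega = 0.5, q0 = 2.2,
                     delta = 0.75, acceptance_mode = "BERNOULLI_MIX")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_game_config(cfg, path)
  expect_equal(read_game_config(path), cfg)
})
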
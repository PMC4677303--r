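test_that("acceptance curve counts the satisfied thresholds", {
  cfg <- ag_restricted()
  u <- setNames(rep(0.2, 5), 1:5)
  crv <- acceptance_curve(u, cfg)
  expect_equal(crv$A[crv$p == 3], 0.6)
  expect_equal(crv$A[crv$p == 5], 1)
  # a point mass on the minimal demand accepts everything
  pm <- setNames(c(1, 0, 0, 0, 0), 1:5)
  expect_equal(acceptance_curve(pm, cfg)$A, rep(1, 10))
  expect_error(acceptance_curve(u * 2, cfg), "sum to 1")
})

test_that("acceptance curve is monotone and saturates above the receiver cap", {
  set.seed(7)
  for (mode in c("THRESHOLD_MIX", "BERNOULLI_MIX")) {
    for (om in c(0.3, 0.5, 1)) {
      cfg <- game_config("NOISY_AG", q_max = 5, omega = om,
                         acceptance_mode = mode)
      for (i in 1:20) {
        w <- runif(5); w <- w / sum(w)
        crv <- acceptance_curve(setNames(w, 1:5), cfg)
        expect_true(all(diff(crv$A) >= 0))
        expect_true(all(crv$A >= 0 & crv$A <= 1))
        if (om == 1) expect_equal(crv$A[crv$p >= 5], rep(1, 6))
      }
    }
  }
})

test_that("delta = 0 reduces the fixed point to the basic model bit-for-bit", {
  cfg <- ag_restricted(delta = 0)
  sp <- population_spec(cfg, N = 100)
  fp <- solve_self_consistent(sp, cfg, beta = 0.03)
  basic <- stationary_distribution(build_embedded_chain(sp, cfg, 0.03))
  expect_identical(fp$distribution$probs, basic$probs)
  expect_identical(fp$distribution$mean_p, basic$mean_p)
  expect_true(fp$converged)
})

test_that("the converged fixed point is invariant under one extra iteration", {
  cfg <- ag_restricted(delta = 0.6)
  sp <- population_spec(cfg, N = 100)
  fp <- solve_self_consistent(sp, cfg, beta = 0.05, tol = 1e-8)
  expect_true(fp$converged)
  expect_lt(fp$residual, 1e-8)
  again <- solve_self_consistent(sp, cfg, beta = 0.05, tol = 1e-8,
                                 init_curve = fp$curve)
  expect_lt(max(abs(again$curve$A - fp$curve$A)), 1e-7)
  expect_equal(again$distribution$mean_p, fp$distribution$mean_p,
               tolerance = 1e-8)
})

test_that("restricted-model acceptance saturates for p >= 5 at every beta and delta", {
  cfg0 <- ag_restricted()
  sp <- population_spec(cfg0, N = 100)
  for (b in c(0.01, 0.1, 1)) {
    for (d in c(0, 0.5, 1)) {
      cfg <- ag_restricted(delta = d)
      fp <- solve_self_consistent(sp, cfg, beta = b)
      expect_identical(fp$curve$A[fp$curve$p >= 5], rep(1, 6))
    }
  }
})

test_that("higher future importance raises the stationary mean donation", {
  sp <- population_spec(ag_restricted(), N = 100)
  for (b in c(0.02, 0.1)) {
    mp <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
      solve_self_consistent(sp, ag_restricted(delta = d), b)$distribution$mean_p
    }, numeric(1))
    expect_true(all(diff(mp) >= -1e-8))
  }
})

test_that("the fixed point is reproducible from random initial curves", {
  cfg <- ag_restricted(delta = 0.5)
  sp <- population_spec(cfg, N = 100)
  chk <- check_fixed_point_multistart(sp, cfg, beta = 0.05, n_starts = 5,
                                      seed = 3)
  expect_lt(chk$max_discrepancy, 1e-6)
})

test_that("the damped solver converges on every cell of the default scan", {
  cfg <- ag_restricted()
  sp <- population_spec(cfg, N = 100)
  tab <- beta_delta_scan(sp, cfg)
  expect_true(all(tab$converged))
  expect_true(all(tab$iterations <= 200, na.rm = TRUE))
})

test_that("the beta x delta scan reduces, sorts and flags as specified", {
  cfg <- ag_restricted()
  sp <- population_spec(cfg, N = 100)
  grid <- default_beta_grid(1e-3, 1, length.out = 8)
  tab <- beta_delta_scan(sp, cfg, grid, c(0, 0.5, 1), target_mean_p = 4.2)
  expect_equal(nrow(tab), 24)
  expect_true(!is.unsorted(tab$delta))
  expect_true(all(tab$converged))
  # the delta = 0 row reproduces the basic-model sweep exactly
  sweep0 <- beta_sweep(sp, cfg, grid)
  expect_identical(tab$mean_p[tab$delta == 0], sweep0$mean_p)
  # each delta < 1 row is nonincreasing in beta; at delta = 1 only the
  # future matters, strong selection maximises (X - p) A(p) at p = q_max
  # and the row turns back up, so monotonicity holds only up to the dip
  for (d in setdiff(unique(tab$delta), 1)) {
    expect_nonincreasing(tab$mean_p[tab$delta == d])
  }
  row1 <- tab$mean_p[tab$delta == 1]
  expect_nonincreasing(row1[seq_len(which.min(row1))])
  expect_equal(row1[length(row1)], 5, tolerance = 1e-6)
  expect_equal(sum(tab$best_fit), 3)
  # larger delta shifts the best-fit beta upward for a fixed target
  best <- vapply(c(0, 0.5, 1), function(d) {
    tab$beta[tab$delta == d & tab$best_fit]
  }, numeric(1))
  expect_true(all(diff(best) >= 0))
})
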
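#' Cross-population payoff matrices
#'
#' Tabulates the fitness of every dictator strategy against every receiver
#' strategy (and vice versa) under a game configuration, optionally with the
#' anticipatory dictator fitness for a fixed acceptance curve. These matrices
#' drive both the embedded chain and the Monte Carlo simulator, whose payoffs
#' are linear in the opposite population's composition.
#'
#' @param spec a [population_spec()].
#' @param config a [game_config()].
#' @param curve optional [acceptance_curve()].
#' @return list with `D` (`|S_D| x |S_R|` dictator payoffs) and `R`
#'   (`|S_R| x |S_D|` receiver payoffs).
#' @export
payoff_matrices <- function(spec, config, curve = NULL) {
  fit <- stage_fitness(config, curve)
  SD <- spec$dictator_strategies
  SR <- spec$receiver_strategies
  D <- outer(SD, SR, function(p, q) mapply(fit$dictator, p, q))
  R <- outer(SR, SD, function(q, p) mapply(fit$receiver, q, p))
  dimnames(D) <- list(SD, SR)
  dimnames(R) <- list(SR, SD)
  list(D = D, R = R)
}

#' Configure a Monte Carlo run
#'
#' Bundles everything a forward simulation needs. The seed is mandatory:
#' every stochastic operation in the package is reproducible by construction.
#'
#' @param spec a [population_spec()].
#' @param game a [game_config()].
#' @param beta selection intensity.
#' @param mu mutation probability per update, in `[0, 1]`. The embedded
#'   chain is the `mu -> 0` limit; comparisons use `mu <= 1e-4 << 1/N`.
#' @param steps total number of updates (may exceed `2^31`; stored as a
#'   double).
#' @param burn_in updates discarded before statistics accumulate
#'   (default `steps / 10`).
#' @param sample_every trajectory sampling interval in updates (default
#'   `steps / 1000`).
#' @param seed integer RNG seed.
#' @param curve optional [acceptance_curve()] for anticipatory payoffs.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(spec, game, beta, mu, steps,
                              burn_in = steps / 10,
                              sample_every = max(1, steps / 1000),
                              seed, curve = NULL) {
  stopifnot(inherits(spec, "population_spec"), inherits(game, "game_config"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  if (steps <= burn_in) stop("steps must exceed burn_in", call. = FALSE)
  structure(
    list(spec = spec, game = game, beta = beta, mu = mu, steps = steps,
         burn_in = burn_in, sample_every = sample_every,
         seed = as.integer(seed), curve = curve),
    class = "simulation_config")
}

#' Forward Monte Carlo simulation of the imitation dynamics
#'
#' Simulates the full stochastic process with explicit mutation: at each
#' update a population is chosen (probability 1/2 each in the bipartite
#' game), a learner is drawn uniformly, and with probability `mu` it adopts a
#' uniformly random strategy (mutation is strategy-uniform and may redraw the
#' current strategy, so `mu` is comparable across strategy-set sizes);
#' otherwise it imitates a random role model of its own population with the
#' Fermi probability, payoffs being averages against the current composition
#' of the opposite population. The initial populations are homogeneous at the
#' lowest strategy of each set.
#'
#' Returned statistics are time averages over the post-burn-in updates:
#' per-strategy frequencies for each population, and the occupancy
#' distribution over homogeneous states (the empirical counterpart of the
#' embedded chain's stationary distribution, accumulated while both
#' populations are homogeneous).
#'
#' @param config a [simulation_config()].
#' @param max_samples cap on stored trajectory points (default `1e5`).
#' @return an object of class `mc_result`: `freq_d`, `freq_r` (named
#'   strategy frequencies), `state_occupancy` (matrix over `(p, q)`),
#'   `homogeneous_fraction`, `trajectory` (data.frame of `step`, `mean_p`,
#'   `mean_q`), `n_mutations`, `n_active_updates`, plus the `config`.
#' @examples
#' cfg <- game_config("DG")
#' sp <- population_spec(cfg, N = 50)
#' sim <- simulation_config(sp, cfg, beta = 0.1, mu = 1e-3, steps = 1e6,
#'                          seed = 42)
#' res <- monte_carlo(sim)
#' res$freq_d
#' @export
monte_carlo <- function(config, max_samples = 1e5) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- config$spec
  pm <- payoff_matrices(spec, config$game, config$curve)
  nD <- length(spec$dictator_strategies)
  nR <- length(spec$receiver_strategies)
  init_d <- integer(nD); init_d[1] <- spec$N
  init_r <- integer(nR); init_r[1] <- spec$N
  res <- withr_seed(config$seed, {
    .mc_run(spec$N, as.numeric(spec$dictator_strategies),
            as.numeric(spec$receiver_strategies),
            pm$D, pm$R, config$beta, config$mu,
            config$steps, config$burn_in, config$sample_every,
            spec$bipartite, init_d, init_r, as.integer(max_samples))
  })
  res$freq_d <- setNames(res$freq_d, spec$dictator_strategies)
  res$freq_r <- setNames(res$freq_r, spec$receiver_strategies)
  dimnames(res$state_occupancy) <- list(spec$dictator_strategies,
                                        spec$receiver_strategies)
  res$config <- config
  class(res) <- "mc_result"
  res
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "<mc_result> %.3g updates (mu=%g, beta=%g), %.0f mutations, homogeneous %.1f%% of sampled time\n",
    x$config$steps, x$config$mu, x$config$beta, x$n_mutations,
    100 * x$homogeneous_fraction))
  cat("dictator strategy frequencies:\n")
  print(round(x$freq_d, 4))
  invisible(x)
}

#' Total variation distance between two distributions
#'
#' @param p,q probability vectors (or matrices) on the same support.
#' @return `0.5 * sum(|p - q|)`.
#' @export
total_variation <- function(p, q) 0.5 * sum(abs(as.numeric(p) - as.numeric(q)))
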
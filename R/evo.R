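#' Bipartite population specification
#'
#' The evolutionary model places `N` dictators and `N` receivers in two
#' separate finite populations; games are played across populations while
#' imitation happens within a population. Strategy sets default to the full
#' integer ranges of the game configuration: donations `p_min:p_max` for
#' dictators and thresholds `1:q_max` for receivers. In the Dictator Game the
#' receiver population is trivial (the single "play" strategy) and the model
#' reduces to a single evolving population.
#'
#' @param config a [game_config()].
#' @param N individuals per population (default 100).
#' @param dictator_strategies,receiver_strategies optional strictly increasing
#'   integer vectors overriding the default strategy sets.
#' @return an object of class `population_spec`.
#' @examples
#' population_spec(game_config("AG", q_max = 5))
#' @export
population_spec <- function(config, N = 100L,
                            dictator_strategies = NULL,
                            receiver_strategies = NULL) {
  stopifnot(inherits(config, "game_config"))
  N <- as.integer(N)
  if (N < 2L) stop("N must be at least 2", call. = FALSE)
  if (is.null(dictator_strategies)) {
    dictator_strategies <- config$p_min:config$p_max
  }
  if (is.null(receiver_strategies)) {
    receiver_strategies <- if (config$variant == "DG") 1L else 1:config$q_max
  }
  check_strategy_set <- function(s, label) {
    if (length(s) == 0L || any(diff(s) <= 0)) {
      stop(sprintf("%s strategies must be nonempty and strictly increasing",
                   label), call. = FALSE)
    }
  }
  check_strategy_set(dictator_strategies, "dictator")
  check_strategy_set(receiver_strategies, "receiver")
  structure(
    list(N = N,
         dictator_strategies = as.integer(dictator_strategies),
         receiver_strategies = as.integer(receiver_strategies),
         bipartite = config$variant != "DG"),
    class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> N=%d per population, %d dictator x %d receiver strategies%s\n",
              x$N, length(x$dictator_strategies), length(x$receiver_strategies),
              if (x$bipartite) "" else " (single population)"))
  invisible(x)
}

#' Fermi imitation probability
#'
#' Probability that an individual with payoff `f_self` imitates a randomly
#' met individual with payoff `f_other` under the pairwise comparison rule:
#' `[1 + exp(-beta (f_other - f_self))]^-1`. At `beta = 0` imitation is a
#' coin-flip (neutral drift); as `beta` grows imitation becomes the
#' deterministic copying of the higher payoff.
#'
#' @param f_self,f_other payoffs in ECU (vectorised).
#' @param beta selection intensity, `beta >= 0`.
#' @return imitation probability.
#' @examples
#' fermi_imitation_probability(2, 2, 5)   # 0.5
#' fermi_imitation_probability(1, 2, 100) # ~1
#' @export
fermi_imitation_probability <- function(f_self, f_other, beta) {
  if (any(beta < 0)) stop("beta must be nonnegative", call. = FALSE)
  plogis(beta * (f_other - f_self))
}

#' One-step transition probabilities of the imitation process
#'
#' With `k` individuals playing strategy A (payoff `f_A`) and `N - k` playing
#' B (payoff `f_B`), the probability that `k` increases or decreases by one
#' in a single update is
#' `T± = (k/N) ((N-k)/N) [1 + exp(∓ beta (f_A - f_B))]^-1`.
#' Because every game interaction is with the opposite population, payoffs
#' here do not depend on `k`; arbitrary per-`k` payoffs are nevertheless
#' accepted.
#'
#' @param k number of A-players, `1 <= k <= N - 1`.
#' @param f_A,f_B payoffs of A- and B-players.
#' @param N population size.
#' @param beta selection intensity.
#' @return a list with components `T_plus` and `T_minus`.
#' @export
transition_probabilities <- function(k, f_A, f_B, N, beta) {
  if (any(beta < 0)) stop("beta must be nonnegative", call. = FALSE)
  if (any(k < 1 | k > N - 1)) {
    stop("k must lie strictly between 0 and N (boundary states are absorbing)",
         call. = FALSE)
  }
  base <- (k / N) * ((N - k) / N)
  list(T_plus = base * plogis(beta * (f_A - f_B)),
       T_minus = base * plogis(-beta * (f_A - f_B)))
}

# log(exp(z) - 1), stable for z in (0, Inf)
log_expm1 <- function(z) ifelse(z > 709, z, log(expm1(z)))

#' Fixation probability of a single mutant
#'
#' Probability that a single A-mutant takes over a population of `N - 1`
#' B-residents under the pairwise comparison rule,
#' `rho = [1 + sum_{i=1}^{N-1} prod_{j=1}^{i} T-_j / T+_j]^-1`.
#' Since cross-population interactions make payoffs independent of the mutant
#' count, each ratio equals `gamma = exp(-beta (f_A - f_B))` and the sum
#' collapses to the geometric closed form `rho = (1 - gamma)/(1 - gamma^N)`,
#' evaluated in log domain for large `beta` and falling back to the neutral
#' value `1/N` when `gamma = 1`.
#'
#' @param f_A mutant payoff (vectorised).
#' @param f_B resident payoff (vectorised).
#' @param N population size, `N >= 2`.
#' @param beta selection intensity, `beta >= 0`.
#' @return fixation probability in `(0, 1)` (may underflow to 0 for strongly
#'   deleterious mutants at large `beta`).
#' @examples
#' fixation_probability(3, 3, 100, 5) # 1/100
#' @export
fixation_probability <- function(f_A, f_B, N, beta) {
  if (any(beta < 0)) stop("beta must be nonnegative", call. = FALSE)
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  x <- -beta * (f_A - f_B)          # log gamma
  n <- max(length(f_A), length(f_B))
  x <- rep_len(x, n)
  rho <- numeric(n)
  neutral <- x == 0
  rho[neutral] <- 1 / N
  neg <- x < 0
  rho[neg] <- expm1(x[neg]) / expm1(N * x[neg])
  pos <- x > 0
  # disfavoured mutant: work in logs to avoid overflow of exp(N x)
  rho[pos] <- exp(log_expm1(x[pos]) - log_expm1(N * x[pos]))
  rho
}

#' Build the small-mutation embedded Markov chain
#'
#' In the rare-mutation limit each population is homogeneous almost all the
#' time, and the dynamics reduce to a Markov chain over homogeneous states
#' `(p, q)` — one resident strategy per population. A transition changes the
#' resident of exactly one population: a mutant arises in the dictator
#' population with probability `w_dictator` (in the receiver population with
#' `w_receiver`), uniformly among that population's other strategies, and
#' either fixates (with its fixation probability against the resident, given
#' the opposite population's resident) or vanishes. Off-diagonal entries are
#'
#' `M[(p,q) -> (p',q)] = w_dictator * rho_D(p' vs p | q) / (|S_D| - 1)`
#'
#' and symmetrically for receiver transitions; the diagonal absorbs the
#' remainder. Rescaling both weights by a common factor (a lazier chain)
#' leaves the stationary distribution unchanged. For the Dictator Game there
#' is a single evolving population and `w_dictator` is forced to 1.
#'
#' @param spec a [population_spec()].
#' @param config a [game_config()].
#' @param beta selection intensity.
#' @param fitness optional list of payoff functions as returned by
#'   [stage_fitness()]; defaults to the basic stage payoffs (or the
#'   anticipatory fitness when a `curve` is supplied).
#' @param curve optional [acceptance_curve()] passed to [stage_fitness()].
#' @param w_dictator probability that a rare mutant arises among dictators.
#' @param w_receiver probability that it arises among receivers (default the
#'   complement of `w_dictator`); `w_dictator + w_receiver` must not exceed 1.
#' @return an object of class `embedded_chain` with elements `states`
#'   (data.frame of `p`, `q`), `M` (row-stochastic matrix), `spec`, `config`,
#'   `beta`.
#' @examples
#' cfg <- game_config("AG", q_max = 5)
#' ch <- build_embedded_chain(population_spec(cfg), cfg, beta = 0.1)
#' nrow(ch$states) # 50
#' @export
build_embedded_chain <- function(spec, config, beta, fitness = NULL,
                                 curve = NULL, w_dictator = 0.5,
                                 w_receiver = 1 - w_dictator) {
  stopifnot(inherits(spec, "population_spec"), inherits(config, "game_config"))
  if (beta < 0) stop("beta must be nonnegative", call. = FALSE)
  if (is.null(fitness)) fitness <- stage_fitness(config, curve)
  SD <- spec$dictator_strategies
  SR <- spec$receiver_strategies
  nD <- length(SD); nR <- length(SR)
  if (!spec$bipartite) { w_dictator <- 1; w_receiver <- 0 }
  if (w_dictator < 0 || w_receiver < 0 || w_dictator + w_receiver > 1 + 1e-12) {
    stop("mutant-allocation weights must be nonnegative with sum at most 1",
         call. = FALSE)
  }
  states <- expand.grid(p = SD, q = SR, KEEP.OUT.ATTRS = FALSE)
  ns <- nrow(states)
  M <- matrix(0, ns, ns)
  idx <- function(ip, iq) (iq - 1L) * nD + ip

  # fitness tables: fD[p, q] resident-receiver-conditioned dictator payoff
  fD <- outer(SD, SR, function(p, q) {
    mapply(function(pp, qq) fitness$dictator(pp, qq), p, q)
  })
  fR <- outer(SR, SD, function(q, p) {
    mapply(function(qq, pp) fitness$receiver(qq, pp), q, p)
  })

  for (iq in seq_len(nR)) {
    for (ip in seq_len(nD)) {
      i <- idx(ip, iq)
      if (nD > 1L) {
        mut <- setdiff(seq_len(nD), ip)
        rho <- fixation_probability(fD[mut, iq], fD[ip, iq], spec$N, beta)
        M[i, idx(mut, iq)] <- w_dictator * rho / (nD - 1L)
      }
      if (spec$bipartite && nR > 1L) {
        mut <- setdiff(seq_len(nR), iq)
        rho <- fixation_probability(fR[mut, ip], fR[iq, ip], spec$N, beta)
        M[i, idx(ip, mut)] <- w_receiver * rho / (nR - 1L)
      }
    }
  }
  diag(M) <- 1 - rowSums(M)
  if (any(diag(M) < 0)) {
    stop("internal consistency error: negative diagonal in transition matrix",
         call. = FALSE)
  }
  structure(
    list(states = states, M = M, spec = spec, config = config, beta = beta),
    class = "embedded_chain")
}

#' @export
print.embedded_chain <- function(x, ...) {
  cat(sprintf("<embedded_chain> %d homogeneous states, N=%d, beta=%g (%s)\n",
              nrow(x$states), x$spec$N, x$beta, x$config$variant))
  invisible(x)
}

#' Stationary distribution of the embedded chain
#'
#' The long-run fraction of time the rare-mutation process spends in each
#' homogeneous state: the normalised eigenvector of `t(M)` associated with
#' eigenvalue 1. If the eigen-decomposition finds more than one eigenvalue
#' within `1e-9` of 1 the solver fails loudly rather than picking one
#' arbitrarily; if the eigenvector's residual is poor a power-iteration
#' fallback is used, and failure is reported if the final residual
#' `max |pi M - pi|` exceeds `1e-8`.
#'
#' @param chain an [build_embedded_chain()] result.
#' @return an object of class `stationary_distribution` with the per-state
#'   probabilities (`probs`, aligned with `chain$states`), the dictator and
#'   receiver marginals, `mean_p`, `mean_q`, and the achieved `residual`.
#' @export
stationary_distribution <- function(chain) {
  stopifnot(inherits(chain, "embedded_chain"))
  M <- chain$M
  eig <- eigen(t(M))
  near_one <- which(abs(eig$values - 1) < 1e-9)
  if (length(near_one) > 1L) {
    stop("degenerate chain: multiple eigenvalues within 1e-9 of 1",
         call. = FALSE)
  }
  pi_hat <- NULL
  if (length(near_one) == 1L) {
    v <- Re(eig$vectors[, near_one])
    v[abs(v) < 1e-14] <- 0
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    pi_hat <- v / sum(v)
  }
  residual <- function(p) if (is.null(p)) Inf else max(abs(drop(p %*% M) - p))
  if (residual(pi_hat) > 1e-10) {
    # power iteration fallback
    p <- rep(1 / nrow(M), nrow(M))
    for (i in seq_len(100000L)) {
      p_new <- drop(p %*% M)
      if (max(abs(p_new - p)) < 1e-15) { p <- p_new; break }
      p <- p_new
    }
    if (residual(p) < residual(pi_hat)) pi_hat <- p / sum(p)
  }
  res <- residual(pi_hat)
  if (res > 1e-8) {
    stop(sprintf("stationary solve failed: residual %.3e exceeds 1e-8", res),
         call. = FALSE)
  }
  states <- chain$states
  SD <- chain$spec$dictator_strategies
  SR <- chain$spec$receiver_strategies
  dm <- tapply(pi_hat, factor(states$p, levels = SD), sum)
  rm_ <- tapply(pi_hat, factor(states$q, levels = SR), sum)
  structure(
    list(states = states, probs = pi_hat,
         dictator_marginal = setNames(as.numeric(dm), SD),
         receiver_marginal = setNames(as.numeric(rm_), SR),
         mean_p = sum(states$p * pi_hat),
         mean_q = sum(states$q * pi_hat),
         residual = res),
    class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat(sprintf("<stationary_distribution> %d states, mean p = %.4f, mean q = %.4f\n",
              length(x$probs), x$mean_p, x$mean_q))
  cat("dictator marginal:\n")
  print(round(x$dictator_marginal, 4))
  invisible(x)
}

#' Summarise a stationary distribution
#'
#' Computes the quantities plotted in model sweeps: the mean donation
#' `mean_p = sum p * marginal(p)`, the mean expectation `mean_q`, and the full
#' marginals for distribution plots.
#'
#' @param object a `stationary_distribution`.
#' @param ... unused.
#' @return a list with `mean_p`, `mean_q`, `dictator_marginal`,
#'   `receiver_marginal`.
#' @export
summary.stationary_distribution <- function(object, ...) {
  list(mean_p = object$mean_p, mean_q = object$mean_q,
       dictator_marginal = object$dictator_marginal,
       receiver_marginal = object$receiver_marginal)
}

#' Convert a stationary distribution to a data frame
#'
#' @param x a `stationary_distribution`.
#' @param row.names,optional,... passed conventions of [as.data.frame()];
#'   unused.
#' @return a data.frame with columns `p`, `q`, `probability`, ordered by
#'   `(q, p)`.
#' @export
as.data.frame.stationary_distribution <- function(x, row.names = NULL,
                                                  optional = FALSE, ...) {
  data.frame(p = x$states$p, q = x$states$q, probability = x$probs)
}

#' Default logarithmic grid of selection intensities
#'
#' @param from,to grid endpoints (default `1e-4` to `10`).
#' @param length.out number of points (default 60).
#' @return numeric vector, logarithmically spaced.
#' @export
default_beta_grid <- function(from = 1e-4, to = 10, length.out = 60L) {
  10^seq(log10(from), log10(to), length.out = length.out)
}

#' Sweep the stationary distribution over selection intensities
#'
#' For each `beta` on the grid, solves the model (directly through the
#' embedded chain when `config$delta == 0`, through the self-consistent
#' fixed point otherwise) and records the mean donation and mean expectation.
#'
#' @param spec a [population_spec()].
#' @param config a [game_config()].
#' @param beta_grid numeric vector of selection intensities.
#' @param ... passed on to [solve_self_consistent()] when `delta > 0`.
#' @return a data.frame with columns `beta`, `mean_p`, `mean_q`, ordered by
#'   `beta`.
#' @export
beta_sweep <- function(spec, config, beta_grid = default_beta_grid(), ...) {
  beta_grid <- sort(beta_grid)
  rows <- lapply(beta_grid, function(b) {
    d <- solve_model(spec, config, b, ...)
    data.frame(beta = b, mean_p = d$mean_p, mean_q = d$mean_q)
  })
  do.call(rbind, rows)
}

# single solve dispatching on delta
solve_model <- function(spec, config, beta, ...) {
  if (config$delta == 0) {
    stationary_distribution(build_embedded_chain(spec, config, beta))
  } else {
    solve_self_consistent(spec, config, beta, ...)$distribution
  }
}
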
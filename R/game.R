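#' Configure an Anticipation Game variant
#'
#' Builds the configuration object shared by every model routine in the
#' package. Three stage games are supported:
#'
#' * `"DG"` — the standard Dictator Game. The receiver has no action (her
#'   strategy set is the single "play" strategy), so every donation is
#'   accepted and `omega` is irrelevant.
#' * `"AG"` — the Anticipation Game: before the Dictator Game is played the
#'   receiver may reject the proposed dictator based on the dictator's
#'   (perfectly inferred) donation; rejection gives both players zero.
#'   Corresponds to `omega = 1` (the receiver always knows the donation).
#' * `"NOISY_AG"` — the AG where with probability `1 - omega` the receiver is
#'   uninformed and falls back on a baseline expectation `q0`; the headline
#'   noisy treatment uses `omega = 0.5`.
#'
#' Dictator strategies are integer donations `p` in `p_min:p_max` out of an
#' endowment `X`; receiver strategies are integer minimum expectations `q` in
#' `1:q_max`. The basic model uses `q_max = p_max`; the restricted model caps
#' receiver expectations at `q_max = 5`, reflecting that receivers do not
#' demand more than half the endowment.
#'
#' Two semantics are available for partial information (`omega < 1`):
#'
#' * `"THRESHOLD_MIX"` (default): the receiver's effective expectation is the
#'   convex combination `omega * q + (1 - omega) * q0` and acceptance is the
#'   deterministic threshold rule `p >= effective expectation`.
#' * `"BERNOULLI_MIX"`: a per-round information coin-flip; acceptance
#'   probability is `omega * [p >= q] + (1 - omega) * [p >= q0]`.
#'
#' The two modes coincide exactly at `omega` 0 or 1.
#'
#' @param variant one of `"DG"`, `"AG"`, `"NOISY_AG"` (case-insensitive).
#' @param X integer endowment in ECU (default 10).
#' @param p_min,p_max smallest and largest allowed donation; `p_max` must
#'   equal `X`.
#' @param q_max cap on receiver expectations (`p_max` for the basic model,
#'   5 for the restricted model).
#' @param omega probability that the receiver knows the dictator's action.
#'   Defaults to 1 for `"AG"`, 0.5 for `"NOISY_AG"`; forced to 1 for `"DG"`.
#' @param q0 baseline expectation (ECU) applied when uninformed. Default 2,
#'   the average Dictator Game donation rounded to the nearest feasible
#'   integer donation.
#' @param delta weight of the anticipated future payoff in the dictator
#'   fitness, in `[0, 1]`. `delta = 0` recovers the basic model.
#' @param acceptance_mode `"THRESHOLD_MIX"` or `"BERNOULLI_MIX"`.
#' @return an object of class `game_config`.
#' @examples
#' cfg <- game_config("AG", q_max = 5)
#' accept_probability(5, 5, cfg)
#' @export
game_config <- function(variant = c("AG", "DG", "NOISY_AG"),
                        X = 10L, p_min = 1L, p_max = X, q_max = p_max,
                        omega = NULL, q0 = 2, delta = 0,
                        acceptance_mode = c("THRESHOLD_MIX", "BERNOULLI_MIX")) {
  variant <- toupper(variant)
  variant <- match.arg(variant, c("AG", "DG", "NOISY_AG"))
  acceptance_mode <- match.arg(acceptance_mode)
  X <- as.integer(X); p_min <- as.integer(p_min)
  p_max <- as.integer(p_max); q_max <- as.integer(q_max)
  if (is.null(omega)) {
    omega <- switch(variant, DG = 1, AG = 1, NOISY_AG = 0.5)
  }
  if (variant == "DG") omega <- 1  # receiver always plays; omega irrelevant
  if (!(p_min >= 1L && p_min <= p_max)) {
    stop("need 1 <= p_min <= p_max", call. = FALSE)
  }
  if (p_max != X) stop("p_max must equal the endowment X", call. = FALSE)
  if (!(q_max >= 1L && q_max <= p_max)) {
    stop("need 1 <= q_max <= p_max", call. = FALSE)
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0 || omega > 1) {
    stop("omega must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1) {
    stop("delta must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(q0) || length(q0) != 1L || q0 < 0) {
    stop("q0 must be a nonnegative ECU amount", call. = FALSE)
  }
  structure(
    list(variant = variant, X = X, p_min = p_min, p_max = p_max,
         q_max = q_max, omega = omega, q0 = q0, delta = delta,
         acceptance_mode = acceptance_mode),
    class = "game_config")
}

#' @export
print.game_config <- function(x, ...) {
  cat(sprintf("<game_config> %s: X=%d ECU, p in %d..%d, q in 1..%d\n",
              x$variant, x$X, x$p_min, x$p_max, x$q_max))
  cat(sprintf("  omega=%g, q0=%g, delta=%g, acceptance=%s\n",
              x$omega, x$q0, x$delta, x$acceptance_mode))
  invisible(x)
}

#' Effective receiver expectation under partial information
#'
#' When the dictator's history is available (probability `omega`) the receiver
#' applies her own threshold `q`; otherwise she falls back on the baseline
#' expectation `q0`. The effective expectation is the convex combination
#' `omega * q + (1 - omega) * q0`.
#'
#' @param q receiver strategy (minimum expected donation, ECU).
#' @param omega probability in `[0, 1]` that the history is available.
#' @param q0 baseline expectation (ECU) when uninformed.
#' @return the effective expectation in ECU (vectorised over `q`).
#' @examples
#' effective_expectation(4, 0.5, 2) # 3
#' @export
effective_expectation <- function(q, omega, q0) {
  if (!is.numeric(omega) || any(omega < 0) || any(omega > 1)) {
    stop("omega must lie in [0, 1]", call. = FALSE)
  }
  omega * q + (1 - omega) * q0
}

#' Probability that a receiver accepts a donation
#'
#' In the Dictator Game the receiver has no action and every donation is
#' accepted. In the Anticipation Game a receiver with threshold `q` accepts a
#' dictator donating `p` when `p` is at least her (effective) expectation;
#' ties accept. Under `"THRESHOLD_MIX"` the expectation is
#' [effective_expectation()]; under `"BERNOULLI_MIX"` the receiver is informed
#' with probability `omega` (compares to `q`) and uninformed otherwise
#' (compares to `q0`), so the acceptance probability mixes the two indicator
#' outcomes.
#'
#' @param p donation in ECU (vectorised).
#' @param q receiver threshold in ECU (vectorised, recycled against `p`).
#' @param config a [game_config()].
#' @return acceptance probability in `[0, 1]`.
#' @examples
#' cfg <- game_config("AG", q_max = 5)
#' accept_probability(5, 5, cfg) # 1: "at least" semantics
#' accept_probability(2, 5, cfg) # 0
#' @export
accept_probability <- function(p, q, config) {
  stopifnot(inherits(config, "game_config"))
  check_strategies(p, q, config)
  if (config$variant == "DG") {
    return(rep(1, length.out = max(length(p), length(q))))
  }
  if (config$acceptance_mode == "THRESHOLD_MIX") {
    thr <- effective_expectation(q, config$omega, config$q0)
    as.numeric(p >= thr)
  } else {
    config$omega * as.numeric(p >= q) +
      (1 - config$omega) * as.numeric(p >= config$q0)
  }
}

check_strategies <- function(p, q, config) {
  if (any(p < config$p_min | p > config$p_max)) {
    stop(sprintf("donation p outside [%d, %d]", config$p_min, config$p_max),
         call. = FALSE)
  }
  if (config$variant != "DG" && any(q < 1 | q > config$q_max)) {
    stop(sprintf("receiver threshold q outside [1, %d]", config$q_max),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Expected stage-game payoffs
#'
#' On acceptance the dictator keeps `X - p` and the receiver gets `p`; on
#' rejection both get zero. With probabilistic acceptance (noisy information,
#' `"BERNOULLI_MIX"`) the payoffs are expectations over the information
#' coin-flip.
#'
#' @inheritParams accept_probability
#' @return a list of class `stage_payoffs` with fields `dictator`, `receiver`
#'   (expected ECU) and `accepted` (`TRUE` iff the acceptance probability is
#'   positive).
#' @examples
#' cfg <- game_config("AG")
#' stage_payoffs(3, 2, cfg) # dictator 7, receiver 3
#' @export
stage_payoffs <- function(p, q, config) {
  a <- accept_probability(p, q, config)
  structure(
    list(dictator = (config$X - p) * a, receiver = p * a, accepted = a > 0),
    class = "stage_payoffs")
}

#' Anticipatory dictator fitness
#'
#' The extension at the heart of the model: a dictator's success is a weighted
#' combination of the current payoff and the payoff potentially obtained in
#' the next round, the latter scaled by the probability `A(p)` that a randomly
#' drawn receiver accepts the current donation:
#'
#' \deqn{f_D(p) = (1-\delta)\,(X-p)\,a_{now} + \delta\,(X-p)\,A(p)}
#'
#' when the current interaction occurs, and 0 when the matched receiver
#' rejects (zero payoff for the present and the future). `delta = 0` ignores
#' the future entirely and recovers the basic stage payoff; `delta = 1` makes
#' success depend solely on the anticipated future payoff.
#'
#' @inheritParams accept_probability
#' @param curve an [acceptance_curve()] covering every donation in
#'   `config$p_min:config$p_max`.
#' @return expected dictator fitness in ECU (vectorised over `p`, `q`).
#' @examples
#' cfg <- game_config("AG", q_max = 5, delta = 0.5)
#' crv <- acceptance_curve(c(`1` = 0, `2` = 0, `3` = 0, `4` = 0.2, `5` = 0.8),
#'                         cfg)
#' anticipatory_dictator_fitness(4, 1, crv, cfg)
#' @export
anticipatory_dictator_fitness <- function(p, q, curve, config) {
  stopifnot(inherits(config, "game_config"))
  if (!inherits(curve, "acceptance_curve")) {
    stop("curve must be an acceptance_curve", call. = FALSE)
  }
  if (!all(config$p_min:config$p_max %in% curve$p)) {
    stop("acceptance curve does not cover the donation range", call. = FALSE)
  }
  a_now <- accept_probability(p, q, config)
  A_p <- curve$A[match(p, curve$p)]
  delta <- config$delta
  fit <- (1 - delta) * (config$X - p) * a_now +
    delta * (config$X - p) * A_p
  fit[a_now == 0] <- 0
  fit
}

#' Stage fitness functions for the embedded chain
#'
#' Returns the pair of payoff functions used to build the small-mutation
#' embedded chain: the fitness of a dictator strategy `p` against a resident
#' receiver strategy `q`, and vice versa. With `curve = NULL` (or
#' `config$delta == 0`) the dictator side is the basic stage payoff
#' `(X - p) * a`; with an acceptance curve it is
#' [anticipatory_dictator_fitness()]. The receiver side is always the stage
#' payoff `p * a`: anticipation is a dictator-side trait.
#'
#' @param config a [game_config()].
#' @param curve optional [acceptance_curve()] for the anticipatory model.
#' @return a list with functions `dictator(p, q)` and `receiver(q, p)`.
#' @export
stage_fitness <- function(config, curve = NULL) {
  dict <- if (is.null(curve) || config$delta == 0) {
    function(p, q) (config$X - p) * accept_probability(p, q, config)
  } else {
    function(p, q) anticipatory_dictator_fitness(p, q, curve, config)
  }
  list(
    dictator = dict,
    receiver = function(q, p) p * accept_probability(p, q, config))
}

#' Read and write game configurations
#'
#' A [game_config()] serialises to a flat YAML mapping with the field names
#' used by the constructor, so that model runs can be driven by config files.
#'
#' @param config a [game_config()].
#' @param path file path.
#' @return `read_game_config()` returns a [game_config()];
#'   `write_game_config()` returns `path` invisibly.
#' @export
write_game_config <- function(config, path) {
  stopifnot(inherits(config, "game_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_game_config
#' @export
read_game_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(game_config, raw)
}
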
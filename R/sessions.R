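#' Strategy sources for the session generator
#'
#' A strategy source is a function `f(n)` returning a data.frame with integer
#' columns `p` (dictator donation) and `q` (receiver threshold), one row per
#' dictator/receiver pair, optionally with a `p_dg` column (the amount the
#' dictator would give in a plain Dictator Game, used for the final round
#' when `endgame_dg = TRUE`).
#'
#' `fixed_strategy_source()` recycles fixed strategy values;
#' `strategy_source_from_distribution()` draws `(p, q)` pairs jointly from a
#' stationary distribution.
#'
#' @param p,q fixed strategy values (recycled to `n`).
#' @param p_dg optional fixed Dictator Game donation.
#' @return a function `f(n)` as described.
#' @export
fixed_strategy_source <- function(p, q, p_dg = NULL) {
  function(n) {
    out <- data.frame(p = rep_len(p, n), q = rep_len(q, n))
    if (!is.null(p_dg)) out$p_dg <- rep_len(p_dg, n)
    out
  }
}

#' @rdname fixed_strategy_source
#' @param dist a [stationary_distribution()].
#' @export
strategy_source_from_distribution <- function(dist) {
  stopifnot(inherits(dist, "stationary_distribution"))
  states <- dist$states
  probs <- dist$probs
  function(n) {
    i <- sample.int(nrow(states), n, replace = TRUE, prob = probs)
    data.frame(p = states$p[i], q = states$q[i])
  }
}

#' Generate synthetic experimental sessions
#'
#' Emulates the behavioural protocol for testing summary-statistics code: in
#' each session `n_pairs` dictators and `n_pairs` receivers play 30 rounds of
#' the game, re-matched uniformly at random every round. Rounds 1-3 are the
#' initiation phase (standard Dictator Game, forced play) that seeds each
#' dictator's 3-round reputation history. From round 4 on, the receiver is
#' informed with probability `omega` (independent per round); an informed
#' receiver accepts when her statistic of the dictator's history (the mean of
#' the last three accepted-round donations by default, or the last one)
#' reaches her threshold `q`, an uninformed receiver accepts when the
#' baseline expectation `q0` reaches `q`. On acceptance the dictator donates
#' her strategy amount, both payoffs are booked and the donation replaces the
#' oldest history entry; on rejection both payoffs are zero and the history
#' is unchanged. With `endgame_dg = TRUE` dictators donate their Dictator
#' Game amount in round 30 (strategic reputation concerns vanish in the last
#' round).
#'
#' @param n_sessions number of sessions.
#' @param n_pairs_per_session dictator/receiver pairs per session (default 9,
#'   i.e. 18 subjects).
#' @param strategy_source a function `f(n)`; see [fixed_strategy_source()].
#' @param game a [game_config()].
#' @param seed mandatory integer seed.
#' @param endgame_dg donate the Dictator Game amount in round 30.
#' @param informed_stat `"mean"` (default) or `"last"`: the history statistic
#'   an informed receiver compares to her threshold.
#' @param n_rounds rounds per session (default 30, the first 3 forced).
#' @return a data.frame of class `session_table` with columns `session`,
#'   `round`, `pair` (dictator index within session), `informed`, `donation`
#'   (NA on rejected rounds), `accepted`, `dictator_payoff`,
#'   `receiver_payoff`, `history` (pre-round snapshot, semicolon-separated,
#'   most recent last).
#' @examples
#' cfg <- game_config("AG", q_max = 5)
#' tab <- generate_sessions(2, 9, fixed_strategy_source(4, 3), cfg, seed = 1)
#' session_summaries(tab)$pooled
#' @export
generate_sessions <- function(n_sessions, n_pairs_per_session = 9L,
                              strategy_source, game, seed,
                              endgame_dg = FALSE,
                              informed_stat = c("mean", "last"),
                              n_rounds = 30L) {
  stopifnot(inherits(game, "game_config"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  informed_stat <- match.arg(informed_stat)
  n_init <- 3L
  withr_seed(seed, {
    rows <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      strat <- strategy_source(n_pairs_per_session)
      if (!all(c("p", "q") %in% names(strat))) {
        stop("strategy_source must yield columns p and q", call. = FALSE)
      }
      check_strategies(strat$p, strat$q, game)
      p_dg <- if (!is.null(strat$p_dg)) strat$p_dg else rep(1L, nrow(strat))
      hist <- vector("list", n_pairs_per_session)  # per-dictator history
      srows <- vector("list", n_rounds)
      for (r in seq_len(n_rounds)) {
        matched <- sample.int(n_pairs_per_session)  # receiver for dictator i
        donation <- informed <- dict_pay <- recv_pay <- numeric(n_pairs_per_session)
        accepted <- logical(n_pairs_per_session)
        snapshot <- character(n_pairs_per_session)
        for (i in seq_len(n_pairs_per_session)) {
          snapshot[i] <- paste(hist[[i]], collapse = ";")
          give <- if (endgame_dg && r == n_rounds) p_dg[i] else strat$p[i]
          if (r <= n_init || game$variant == "DG") {
            # initiation phase / trivial receiver: forced play
            informed[i] <- NA
            accepted[i] <- TRUE
          } else {
            informed[i] <- rbinom(1L, 1L, game$omega)
            qr <- strat$q[matched[i]]
            if (informed[i] == 1L) {
              stat <- if (informed_stat == "mean") {
                mean(hist[[i]])
              } else {
                hist[[i]][length(hist[[i]])]
              }
              accepted[i] <- stat >= qr
            } else {
              accepted[i] <- game$q0 >= qr
            }
          }
          if (accepted[i]) {
            donation[i] <- give
            dict_pay[i] <- game$X - give
            recv_pay[i] <- give
            hist[[i]] <- utils::tail(c(hist[[i]], give), n_init)
          } else {
            donation[i] <- NA
            dict_pay[i] <- 0
            recv_pay[i] <- 0
            # history unchanged on rejected rounds
          }
        }
        srows[[r]] <- data.frame(
          session = s, round = r, pair = seq_len(n_pairs_per_session),
          informed = as.logical(informed), donation = donation,
          accepted = accepted, dictator_payoff = dict_pay,
          receiver_payoff = recv_pay, history = snapshot)
      }
      rows[[s]] <- do.call(rbind, srows)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("session_table", "data.frame")
    out
  })
}

#' Summary statistics of a session table
#'
#' The per-treatment summaries reported for the behavioural data: mean
#' donation over accepted rounds, acceptance rate over post-initiation
#' rounds, the per-round mean-donation series, the donation histogram, and
#' the mean donation conditioned on whether the receiver was informed.
#'
#' @param table a [generate_sessions()] result (or a compatible data.frame).
#' @param n_init number of initiation rounds excluded from the acceptance
#'   rate (default 3).
#' @return a list with `per_session` (data.frame: `session`,
#'   `mean_donation`, `acceptance_rate`), `pooled` (same statistics pooled),
#'   `per_round` (data.frame: `round`, `mean_donation`), `histogram` (named
#'   accepted-donation counts), and `by_informed` (mean donation for
#'   informed/uninformed rounds).
#' @export
session_summaries <- function(table, n_init = 3L) {
  if (is.null(table) || nrow(table) == 0L) {
    stop("empty session table", call. = FALSE)
  }
  acc <- table$accepted
  post <- table$round > n_init
  per_session <- do.call(rbind, lapply(split(table, table$session), function(d) {
    data.frame(session = d$session[1],
               mean_donation = mean(d$donation[d$accepted], na.rm = TRUE),
               acceptance_rate = mean(d$accepted[d$round > n_init]))
  }))
  rownames(per_session) <- NULL
  rounds <- sort(unique(table$round))
  per_round <- data.frame(
    round = rounds,
    mean_donation = vapply(rounds, function(r) {
      mean(table$donation[table$round == r & acc], na.rm = TRUE)
    }, numeric(1)))
  don <- table$donation[acc & !is.na(table$donation)]
  histogram <- table(factor(don, levels = sort(unique(don))))
  by_informed <- c(
    informed = mean(table$donation[acc & !is.na(table$informed) &
                                     table$informed], na.rm = TRUE),
    uninformed = mean(table$donation[acc & !is.na(table$informed) &
                                       !table$informed], na.rm = TRUE))
  list(per_session = per_session,
       pooled = list(mean_donation = mean(don),
                     acceptance_rate = mean(acc[post])),
       per_round = per_round,
       histogram = setNames(as.integer(histogram), names(histogram)),
       by_informed = by_informed)
}

#' Read and write session tables
#'
#' Plain-CSV serialisation of a [generate_sessions()] table with its exact
#' column set.
#'
#' @param table a session table.
#' @param path file path.
#' @return `read_session_table()` returns the table; `write_session_table()`
#'   returns `path` invisibly.
#' @export
write_session_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_table
#' @export
read_session_table <- function(path) {
  out <- read.csv(path, colClasses = c(history = "character"))
  class(out) <- c("session_table", "data.frame")
  out
}
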
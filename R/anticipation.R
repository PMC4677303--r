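#' Acceptance-probability curve of a receiver population
#'
#' `A(p)` is the probability that a randomly drawn receiver accepts a
#' dictator donating `p`: the receiver-marginal average of the acceptance
#' rule, `A(p) = sum_q marginal(q) * accept_probability(p, q)`. It is
#' nondecreasing in `p`, and in the restricted model (`q_max = 5`,
#' `omega = 1`) it equals 1 exactly for every `p >= 5`.
#'
#' @param receiver_marginal named numeric vector of receiver-strategy
#'   probabilities (names are the `q` values; unnamed vectors are taken to be
#'   aligned with `1:q_max`). Must sum to 1 within `1e-8`.
#' @param config a [game_config()].
#' @param p donations at which to evaluate the curve (default the full
#'   donation range).
#' @return an object of class `acceptance_curve` with fields `p` and `A`.
#' @examples
#' cfg <- game_config("AG", q_max = 5)
#' acceptance_curve(rep(0.2, 5), cfg)
#' @export
acceptance_curve <- function(receiver_marginal, config,
                             p = config$p_min:config$p_max) {
  stopifnot(inherits(config, "game_config"))
  q <- if (!is.null(names(receiver_marginal))) {
    as.integer(names(receiver_marginal))
  } else {
    seq_along(receiver_marginal)
  }
  w <- as.numeric(receiver_marginal)
  if (abs(sum(w) - 1) > 1e-8) {
    stop("receiver marginal must sum to 1 (within 1e-8)", call. = FALSE)
  }
  # complement form: exact saturation at 1 when every receiver accepts
  A <- vapply(p, function(pp) {
    1 - sum(w * (1 - accept_probability(rep(pp, length(q)), q, config)))
  }, numeric(1))
  structure(list(p = p, A = A), class = "acceptance_curve")
}

#' @export
print.acceptance_curve <- function(x, ...) {
  cat("<acceptance_curve>\n")
  print(setNames(round(x$A, 4), x$p))
  invisible(x)
}

#' @export
as.data.frame.acceptance_curve <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(p = x$p, A = x$A)
}

uniform_receiver_curve <- function(spec, config) {
  q <- spec$receiver_strategies
  acceptance_curve(setNames(rep(1 / length(q), length(q)), q), config)
}

#' Self-consistent solution of the anticipatory model
#'
#' With `delta > 0` the dictator fitness depends on the acceptance curve
#' `A(p)`, which is itself generated by the evolving receiver population.
#' The coupled system is solved as a fixed point: starting from the curve of
#' a uniform receiver population, iterate (i) build the embedded chain with
#' the anticipatory fitness under the current curve, (ii) compute its
#' stationary distribution, (iii) recompute the curve from the stationary
#' receiver marginal, and update with damping
#' `A <- damping * A_new + (1 - damping) * A_old` until the sup-norm change
#' of the curve falls below `tol`.
#'
#' With `one_shot = TRUE` the solver instead stops after the first chain
#' build, i.e. the dictators anticipate the acceptance behaviour of a uniform
#' receiver population; this baseline is kept for comparison only.
#'
#' @param spec a [population_spec()].
#' @param config a [game_config()]; `config$delta` sets the future weight.
#' @param beta selection intensity.
#' @param tol sup-norm convergence tolerance on the curve (default `1e-8`).
#' @param max_iter iteration cap (default 200).
#' @param damping step size in `(0, 1]` (default 0.5).
#' @param init_curve optional starting [acceptance_curve()].
#' @param one_shot if `TRUE`, single pass with the uniform-receiver curve.
#' @return an object of class `fixed_point_result`: `distribution`
#'   (the [stationary_distribution()]), `curve` (the converged
#'   [acceptance_curve()]), `iterations`, `residual`, `converged`.
#' @examples
#' cfg <- game_config("AG", q_max = 5, delta = 0.5)
#' sp <- population_spec(cfg, N = 100)
#' fp <- solve_self_consistent(sp, cfg, beta = 0.1)
#' fp$distribution$mean_p
#' @export
solve_self_consistent <- function(spec, config, beta, tol = 1e-8,
                                  max_iter = 200L, damping = 0.5,
                                  init_curve = NULL, one_shot = FALSE) {
  stopifnot(inherits(spec, "population_spec"), inherits(config, "game_config"))
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (damping <= 0 || damping > 1) {
    stop("damping must lie in (0, 1]", call. = FALSE)
  }
  curve <- if (is.null(init_curve)) {
    uniform_receiver_curve(spec, config)
  } else {
    init_curve
  }
  dist <- NULL
  residual <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    chain <- build_embedded_chain(spec, config, beta, curve = curve)
    dist <- stationary_distribution(chain)
    if (one_shot) {
      residual <- 0
      break
    }
    A_new <- acceptance_curve(dist$receiver_marginal, config, p = curve$p)
    residual <- max(abs(A_new$A - curve$A))
    curve$A <- damping * A_new$A + (1 - damping) * curve$A
    if (residual < tol || iter >= max_iter) break
  }
  converged <- residual < tol
  if (!converged && !one_shot) {
    warning(sprintf(
      "fixed point not converged after %d iterations (residual %.3e)",
      iter, residual), call. = FALSE)
  }
  structure(
    list(distribution = dist, curve = curve, iterations = iter,
         residual = residual, converged = converged,
         beta = beta, config = config, spec = spec),
    class = "fixed_point_result")
}

#' @export
print.fixed_point_result <- function(x, ...) {
  cat(sprintf(
    "<fixed_point_result> beta=%g delta=%g: mean p = %.4f, mean q = %.4f (%d iterations, residual %.2e)\n",
    x$beta, x$config$delta, x$distribution$mean_p, x$distribution$mean_q,
    x$iterations, x$residual))
  invisible(x)
}

#' Multi-start diagnostic for the self-consistent solve
#'
#' Re-solves the fixed point from `n_starts` random initial acceptance curves
#' (monotone, drawn under a fixed seed) and reports the maximum pairwise
#' sup-norm discrepancy between the resulting curves, as a check that the
#' solver is not silently selecting among multiple fixed points.
#'
#' @inheritParams solve_self_consistent
#' @param n_starts number of random restarts (default 5).
#' @param seed RNG seed for the random initial curves.
#' @return a list with `max_discrepancy` (sup-norm across all pairs) and
#'   `results` (the individual `fixed_point_result` objects).
#' @export
check_fixed_point_multistart <- function(spec, config, beta, n_starts = 5L,
                                         seed = 1L, ...) {
  base <- uniform_receiver_curve(spec, config)
  results <- withr_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      crv <- base
      crv$A <- sort(runif(length(crv$A)))  # random monotone curve
      solve_self_consistent(spec, config, beta, init_curve = crv, ...)
    })
  })
  curves <- vapply(results, function(r) r$curve$A, numeric(length(base$A)))
  max_disc <- max(apply(curves, 1, function(v) diff(range(v))))
  list(max_discrepancy = max_disc, results = results)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

#' Scan the model over selection intensity and future importance
#'
#' One converged self-consistent solve per `(beta, delta)` grid cell,
#' tabulating the mean donation and mean expectation. Optionally flags, per
#' `delta` row, the `beta` whose mean donation comes closest to a target
#' donation (the best-fit cell).
#'
#' @param spec a [population_spec()].
#' @param config a [game_config()]; its `delta` field is overridden cell-wise.
#' @param beta_grid,delta_grid nonempty numeric grids.
#' @param target_mean_p optional target donation for best-fit flagging.
#' @param ... passed to [solve_self_consistent()].
#' @return a data.frame sorted by `(delta, beta)` with columns `beta`,
#'   `delta`, `mean_p`, `mean_q`, `converged`, `iterations`, and `best_fit`
#'   when a target is given. Non-convergence in a cell is recorded, not
#'   fatal.
#' @export
beta_delta_scan <- function(spec, config, beta_grid = default_beta_grid(),
                            delta_grid = c(0, 0.25, 0.5, 0.75, 1),
                            target_mean_p = NULL, ...) {
  if (length(beta_grid) == 0L || length(delta_grid) == 0L) {
    stop("beta_grid and delta_grid must be nonempty", call. = FALSE)
  }
  beta_grid <- sort(beta_grid); delta_grid <- sort(delta_grid)
  rows <- list()
  for (d in delta_grid) {
    cfg_d <- config
    cfg_d$delta <- d
    for (b in beta_grid) {
      row <- tryCatch({
        if (d == 0) {
          dist <- stationary_distribution(build_embedded_chain(spec, cfg_d, b))
          data.frame(beta = b, delta = d, mean_p = dist$mean_p,
                     mean_q = dist$mean_q, converged = TRUE, iterations = 1L)
        } else {
          fp <- suppressWarnings(solve_self_consistent(spec, cfg_d, b, ...))
          data.frame(beta = b, delta = d, mean_p = fp$distribution$mean_p,
                     mean_q = fp$distribution$mean_q,
                     converged = fp$converged, iterations = fp$iterations)
        }
      }, error = function(e) {
        data.frame(beta = b, delta = d, mean_p = NA_real_, mean_q = NA_real_,
                   converged = FALSE, iterations = NA_integer_)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(target_mean_p)) {
    out$best_fit <- FALSE
    for (d in delta_grid) {
      sel <- which(out$delta == d & !is.na(out$mean_p))
      if (length(sel)) {
        out$best_fit[sel[which.min(abs(out$mean_p[sel] - target_mean_p))]] <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  out
}
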
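# Shared fixtures: small model configurations built in code.

ag_restricted <- function(delta = 0, ...) {
  game_config("AG", q_max = 5, delta = delta, ...)
}

dg_config <- function(...) game_config("DG", ...)

# Brute-force fixation probability: the explicit sum-of-products formula
# rho = [1 + sum_{i=1}^{N-1} prod_{j=1}^{i} T-_j / T+_j]^-1, evaluated term
# by term. Independent of the closed-form implementation.
fixation_bruteforce <- function(f_A, f_B, N, beta) {
  ratio <- vapply(seq_len(N - 1), function(k) {
    tr <- transition_probabilities(k, f_A, f_B, N, beta)
    tr$T_minus / tr$T_plus
  }, numeric(1))
  1 / (1 + sum(cumprod(ratio)))
}

expect_nonincreasing <- function(x, tol = 1e-10) {
  expect_true(all(diff(x) <= tol),
              info = paste("first increase at index",
                           which(diff(x) > tol)[1]))
}
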
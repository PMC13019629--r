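#' Variational-quantum-deflation objective
#'
#' Energy expectation of the Hermitian Hamiltonian plus an overlap penalty
#' against previously converged states:
#' \deqn{\langle\psi(\theta)|H_H|\psi(\theta)\rangle +
#'   c \sum_{j<i} |\langle\psi(\theta)|\psi(\theta_j)\rangle|^2.}
#' The penalty lifts already-found eigenstates by `c`, so minimizing the
#' deflated objective targets the next eigenstate in energy order.
#'
#' @param ansatz An [ansatz_spec()].
#' @param theta Current parameters.
#' @param priors List of parameter vectors of the previously found states.
#' @param ms A [measurement_set()] (its `A` component is the Hermitian
#'   Hamiltonian).
#' @param backend A [backend_config()].
#' @param penalty Penalty weight `c`.
#' @return Real objective value.
#' @export
deflation_objective <- function(ansatz, theta, priors = list(), ms,
                                backend = backend_config(), penalty = 100) {
  e <- if (backend$mode == "exact") {
    quad_form(prepare_state(ansatz, theta), ms$A_mat)
  } else {
    expectation(ansatz, theta, ms$A, backend)
  }
  if (length(priors) == 0) return(e)
  pen <- sum(vapply(priors, function(pj)
    overlap_squared(ansatz, theta, pj, backend), numeric(1)))
  e + penalty * pen
}

#' Solve the Hermitian eigenstate chain by variational quantum deflation
#'
#' Finds `N` successive eigenstates of the Hermitian Hamiltonian: state `i`
#' minimizes the [deflation_objective()] against states `1..i-1`, starting
#' from pseudorandom angles in `[-pi, pi]`.
#'
#' @param N Number of states (`<= 2^q`).
#' @param ansatz An [ansatz_spec()].
#' @param ms A [measurement_set()].
#' @param cfg A [deflation_config()].
#' @param backend A [backend_config()].
#' @return List of per-state entries: `theta`, `energy` (Rayleigh quotient
#'   of `H_H`), `objective`, `status`.
#' @export
solve_hermitian_chain <- function(N, ansatz, ms, cfg = deflation_config(),
                                  backend = backend_config()) {
  stopifnot(N >= 1, N <= 2^ansatz$q)
  out <- vector("list", N)
  priors <- list()
  for (i in seq_len(N)) {
    st <- hermitian_chain_step(ansatz, priors, ms, cfg, backend)
    out[[i]] <- st
    priors <- c(priors, list(st$theta))
  }
  out
}

# One deflation step against a fixed prior list. Exact mode caches the
# prior statevectors, which dominate the penalty cost.
hermitian_chain_step <- function(ansatz, priors, ms, cfg, backend) {
  p0 <- random_parameters(ansatz)
  exact <- backend$mode == "exact"
  prior_states <- if (exact) lapply(priors, prepare_state, ansatz = ansatz)
  obj <- function(theta) {
    if (exact) {
      psi <- prepare_state(ansatz, theta)
      e <- quad_form(psi, ms$A_mat)
      if (length(prior_states))
        e <- e + cfg$penalty * sum(vapply(prior_states, function(pp)
          Mod(sum(Conj(pp) * psi))^2, numeric(1)))
      e
    } else {
      deflation_objective(ansatz, theta, priors, ms, backend,
                          penalty = cfg$penalty)
    }
  }
  res <- optimize_parameters(obj, p0, cfg)
  energy <- if (exact) quad_form(prepare_state(ansatz, res$par), ms$A_mat)
            else expectation(ansatz, res$par, ms$A, backend)
  list(theta = res$par, energy = energy, objective = res$value,
       evals = res$evals, status = res$status)
}
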
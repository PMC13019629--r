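#' Noise-factor sweep of solution quality
#'
#' Maps how the pseudovariance and the fidelity error of the three target
#' states respond to device quality, over a grid of gate-noise reduction
#' factors and qubit longevity factors. The target states are first
#' converged in exact (zero-noise) mode - deflation chain plus
#' pseudovariance refinement, matched to the labeled exact eigenvectors.
#' For each grid cell the device model is rescaled with [scale_device()]
#' and each converged circuit is executed under the resulting noise model:
#' the reported pseudovariance is the shot-sampled noisy estimate at the
#' final-comparison budget, and the fidelity error is
#' \eqn{1 - \langle\psi_{exact}| \rho |\psi_{exact}\rangle} for the noisily
#' prepared density matrix. Both shrink toward zero as the gate errors and
#' thermal relaxation are dialed away.
#'
#' @param q Qubit count (default 3).
#' @param gate_factors Gate-noise reduction factors (>= 1).
#' @param longevities Qubit longevity factors, microseconds.
#' @param spec A [model_spec()].
#' @param device Base [device_model()].
#' @param shots Shots per circuit; the pseudovariance estimate uses ten
#'   times this (the final-comparison convention).
#' @param seed Master seed.
#' @param labels Which states to track.
#' @return List with `grid` (data frame: `gate_factor`, `longevity`,
#'   `label`, `sigma2`, `fidelity_error`) and `zero_noise` (the exact-mode
#'   starting records).
#' @export
noise_sweep <- function(q = 3, gate_factors = c(1, 10, 100),
                        longevities = c(10, 100, 1000),
                        spec = model_spec(), device = device_model(),
                        shots = 5e3, seed = 1,
                        labels = c("bound", "r1", "r2")) {
  stopifnot(all(gate_factors >= 1), all(longevities > 0))
  ansatz <- ansatz_spec(q)
  exact <- backend_config("exact")
  # zero-noise starting points: deflation chain plus exact refinement,
  # matched to the labeled exact eigenvectors
  starts <- list()
  for (par in c("even", "odd")) {
    ref <- cap_reference(q, par, spec)
    want <- intersect(ref$table$label, labels)
    if (length(want) == 0) next
    ms <- measurement_set(ref$ops)
    set.seed(task_seed(seed, paste0("sweep.", par)))
    N <- if (par == "even") 4 else 2
    ch <- solve_hermitian_chain(N, ansatz, ms, deflation_config(), exact)
    refined <- lapply(ch, function(st)
      refine_resonance(st$theta, ansatz, ms, refinement_config(), exact))
    for (lb in want) {
      vec <- ref$pairs$vectors[, which(ref$labels == lb)]
      ovl <- vapply(refined, function(r)
        Mod(sum(Conj(prepare_state(ansatz, r$phi)) * vec))^2, numeric(1))
      k <- which.max(ovl)
      starts[[lb]] <- list(phi = refined[[k]]$phi, parity = par, ms = ms,
                           exact_vec = vec, overlap = ovl[k])
    }
  }
  rows <- list()
  for (g in gate_factors) for (L in longevities) {
    dev <- scale_device(device, gate_factor = g, longevity = L)
    noisy <- backend_config("noisy", shots = shots, device = dev)
    for (lb in names(starts)) {
      st <- starts[[lb]]
      set.seed(task_seed(seed, sprintf("cell.%g.%g.%s", g, L, lb)))
      s2 <- pseudovariance(ansatz, st$phi, st$ms, noisy,
                           shots = 10 * shots)
      rho <- evolve_noisy(ansatz, st$phi, dev)
      fid <- Re(Conj(st$exact_vec) %*% rho %*% st$exact_vec)[1]
      rows[[length(rows) + 1]] <- data.frame(
        gate_factor = g, longevity = L, label = lb,
        sigma2 = s2, fidelity_error = 1 - fid,
        stringsAsFactors = FALSE)
    }
  }
  list(grid = do.call(rbind, rows), zero_noise = starts)
}

#' Monotone-trend check on sweep marginals
#'
#' Averages a sweep quantity over one grid axis and checks that it
#' decreases along the other as noise shrinks, allowing a limited number of
#' inversions (the simulations are stochastic). The net change must be a
#' decrease.
#'
#' @param grid The `grid` data frame of [noise_sweep()].
#' @param quantity `"sigma2"` or `"fidelity_error"`.
#' @param along `"gate_factor"` or `"longevity"`.
#' @param label State label to test.
#' @param allow_inversions Number of tolerated upward steps.
#' @return `TRUE` when the averaged marginal trend decreases.
#' @export
sweep_trend_decreasing <- function(grid, quantity = "sigma2",
                                   along = "gate_factor", label = "bound",
                                   allow_inversions = 1) {
  d <- grid[grid$label == label, , drop = FALSE]
  marg <- tapply(d[[quantity]], d[[along]], mean)
  marg <- marg[order(as.numeric(names(marg)))]
  steps <- diff(marg)
  sum(steps > 0) <= allow_inversions && marg[length(marg)] < marg[1]
}
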
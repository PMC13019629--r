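#' Single-qubit readout confusion model
#'
#' `p_ij` is the probability that a qubit in true state `i` is measured in
#' state `j`; rows of the confusion matrix sum to one.
#'
#' @param p01 Probability of reading 1 when the true state is 0.
#' @param p10 Probability of reading 0 when the true state is 1.
#' @return Object of class `readout_model` with entries `p00, p01, p10, p11`.
#' @export
readout_model <- function(p01 = 0.02, p10 = 0.02) {
  stopifnot(p01 >= 0, p01 <= 1, p10 >= 0, p10 <= 1)
  rm <- list(p00 = 1 - p01, p01 = p01, p10 = p10, p11 = 1 - p10)
  if (rm$p00 <= rm$p10)
    stop("singular confusion model: p00 must exceed p10")
  structure(rm, class = "readout_model")
}

#' Invert readout confusion on a two-outcome distribution
#'
#' Recovers the true outcome probabilities `(T0, T1)` from noisy measured
#' probabilities `(N0, N1)` by solving the linear confusion relation under
#' the normalization `T0 + T1 = 1`:
#' \eqn{T_0 = (N_0 - p_{10})/(p_{00} - p_{10})}, \eqn{T_1 = 1 - T_0}.
#'
#' @param N0,N1 Measured probabilities of outcomes 0 and 1 (sum to 1).
#' @param rm A [readout_model()].
#' @return Numeric vector `c(T0, T1)`.
#' @export
invert_readout <- function(N0, N1, rm = readout_model()) {
  if (abs(N0 + N1 - 1) > 1e-9) stop("N0 + N1 must equal 1")
  if (abs(rm$p00 - rm$p10) < 1e-12) stop("singular confusion matrix")
  T0 <- (N0 - rm$p10) / (rm$p00 - rm$p10)
  c(T0 = T0, T1 = 1 - T0)
}

#' Unitary gate folding for noise amplification
#'
#' Replaces each gate `g` by \eqn{g (g^\dagger g)^{(\lambda-1)/2}} for an odd
#' scale factor \eqn{\lambda \in \{1, 3, 5\}}. The noiseless unitary action
#' is unchanged while hardware noise accumulates \eqn{\lambda}-fold,
#' providing the amplified-noise points for zero-noise extrapolation.
#'
#' @param gates Gate program (as in `ansatz_spec()$gates`).
#' @param scale Odd integer noise scale factor.
#' @return Expanded gate program; each element carries an `invert` flag.
#' @export
fold_circuit <- function(gates, scale = 1) {
  if (scale %% 2 != 1 || scale < 1) stop("fold scale must be odd and >= 1")
  folded_program(gates, scale)
}

#' Hybrid exponential/linear zero-noise extrapolation
#'
#' Given circuit results `x1, x3, x5` at noise scales 1, 3 and 5, fits the
#' exponential decay model \eqn{x_\lambda = A + B e^{C\lambda}} when the
#' triple is monotone, i.e. when \eqn{\beta = (x_3-x_5)/(x_1-x_3) > 0}
#' (then \eqn{\beta = e^{2C}}), and returns its exact zero-noise limit
#' \deqn{x_0 = x_1 + (x_1 - x_3)/(\sqrt{\beta} + \beta).}
#' When monotonicity is violated (or not resolvable within statistical
#' significance, i.e. the successive differences are smaller than twice
#' their combined standard error `se`), an ordinary least-squares line
#' through the three points is evaluated at scale zero instead, clipped to
#' the observable's physical `range`.
#'
#' @param x1,x3,x5 Results at noise scales 1, 3, 5.
#' @param se Standard error of each individual result (0 disables the
#'   significance gate).
#' @param range Physical range for clipping the linear fallback
#'   (`c(-1, 1)` for Pauli-word expectations).
#' @return Extrapolated zero-noise value.
#' @examples
#' zne_extrapolate(0.5, 0.125, 0.03125)  # exact limit 1 of A=0, e^C=0.5
#' @export
zne_extrapolate <- function(x1, x3, x5, se = 0, range = c(-1, 1)) {
  stopifnot(is.finite(x1), is.finite(x3), is.finite(x5))
  if (x1 == x3 && x3 == x5) return(x1)
  d13 <- x1 - x3
  d35 <- x3 - x5
  significant <- abs(d13) > 2 * sqrt(2) * se && abs(d35) > 2 * sqrt(2) * se
  if (d13 != 0) {
    beta <- d35 / d13
    if (beta > 0 && significant) {
      return(x1 + d13 / (sqrt(beta) + beta))
    }
  }
  fit <- stats::lm.fit(cbind(1, c(1, 3, 5)), c(x1, x3, x5))
  x0 <- fit$coefficients[[1]]
  min(max(x0, range[1]), range[2])
}
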
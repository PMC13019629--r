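#' Model specification for the predissociation benchmark potential
#'
#' Bundles every physical and numerical parameter of the one-dimensional
#' benchmark system: a Gaussian-damped harmonic well that relaxes to a
#' dissociation asymptote `J`, a quadratic complex absorbing potential (CAP)
#' switched on at `x0`, and a uniform position grid on `[-x_max, x_max]`.
#'
#' The potential is \eqn{V_0(x) = (x^2/2 - J) e^{-\lambda x^2} + J} and the
#' CAP is \eqn{V_{CAP}(x) = -(|x|-x_0)^2/2} for \eqn{|x| > x_0}, zero inside.
#' All quantities are in atomic units.
#'
#' @param lambda Gaussian decay constant of the well (dimensionless, >= 0).
#' @param J Dissociation asymptote energy (au).
#' @param x0 CAP onset position (au); must satisfy `0 < x0 < x_max`.
#' @param x_max Half-width of the simulation box (au).
#' @param n_grid Number of grid points (>= 8).
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec()
#' potential_energy(0, spec)   # bottom of the well, 0
#' cap_potential(9, spec)      # -0.5
#' @export
model_spec <- function(lambda = 0.1, J = 0.8, x0 = 8, x_max = 10,
                       n_grid = 2^12) {
  stopifnot(lambda >= 0, x0 > 0, x0 < x_max, n_grid >= 8)
  structure(list(lambda = lambda, J = J, x0 = x0, x_max = x_max,
                 n_grid = as.integer(n_grid), L = 2 * x_max),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "Predissociation model: lambda = %g, J = %g au, CAP onset x0 = %g au\n",
    x$lambda, x$J, x$x0))
  cat(sprintf("Grid: %d points on [%g, %g] au (L = %g)\n",
              x$n_grid, -x$x_max, x$x_max, x$L))
  invisible(x)
}

#' Benchmark potential energy
#'
#' @param x Position(s), au.
#' @param spec A [model_spec()].
#' @return \eqn{(x^2/2 - J) e^{-\lambda x^2} + J} (au), vectorized over `x`.
#' @export
potential_energy <- function(x, spec = model_spec()) {
  stopifnot(all(is.finite(x)))
  (x^2 / 2 - spec$J) * exp(-spec$lambda * x^2) + spec$J
}

#' Quadratic complex absorbing potential
#'
#' Real, nonpositive CAP profile; the full absorbing term in the Hamiltonian
#' is `1i` times this function.
#'
#' @inheritParams potential_energy
#' @return 0 for `|x| <= x0`, else \eqn{-(|x|-x_0)^2/2} (au).
#' @export
cap_potential <- function(x, spec = model_spec()) {
  stopifnot(all(is.finite(x)))
  ifelse(abs(x) <= spec$x0, 0, -(abs(x) - spec$x0)^2 / 2)
}

#' Uniform grid of a model specification
#'
#' Endpoint-inclusive grid `x_k = -x_max + k*dx`, `dx = 2 x_max/(n_grid-1)`.
#'
#' @param spec A [model_spec()].
#' @return Numeric vector of length `n_grid`.
#' @export
grid_points <- function(spec = model_spec()) {
  seq(-spec$x_max, spec$x_max, length.out = spec$n_grid)
}

#' Kinetic-energy operator on the grid
#'
#' Second-order central finite-difference Laplacian with Dirichlet (zero)
#' values beyond the grid ends: \eqn{T = -D_2/2}.
#'
#' @param spec A [model_spec()].
#' @return A sparse symmetric tridiagonal matrix (`n_grid x n_grid`, au).
#' @export
kinetic_matrix <- function(spec = model_spec()) {
  n <- spec$n_grid
  if (n < 3) stop("kinetic matrix needs n_grid >= 3")
  dx <- 2 * spec$x_max / (n - 1)
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(rep(-0.5 / dx^2, n - 1),
                                      rep(1 / dx^2, n),
                                      rep(-0.5 / dx^2, n - 1)))
}

# Apply T = -D2/2 to the columns of a dense matrix without forming T.
# Dirichlet boundary: values outside the grid are zero.
apply_kinetic <- function(B, dx) {
  n <- nrow(B)
  D2 <- rbind(B[2, , drop = FALSE] - 2 * B[1, , drop = FALSE],
              B[3:n, , drop = FALSE] - 2 * B[2:(n - 1), , drop = FALSE] +
                B[1:(n - 2), , drop = FALSE],
              B[n - 1, , drop = FALSE] - 2 * B[n, , drop = FALSE])
  -0.5 * D2 / dx^2
}

#' Parity-split sinusoidal basis specification
#'
#' Particle-in-a-box sine functions of length `L = 2 x_max` split by parity.
#' The mode number `w` enters as \eqn{\sin(w\pi/L (x - L/2))}; odd `w` give
#' even functions of `x` and even `w` give odd functions, so the even-parity
#' basis uses `w = 1, 3, 5, ...` and the odd-parity basis `w = 2, 4, 6, ...`.
#' Restricting to one parity halves the basis needed for states of that
#' symmetry, i.e. saves one qubit.
#'
#' @param parity `"even"` or `"odd"`.
#' @param q Qubit count; the basis holds `2^q` states.
#' @return An object of class `basis_spec` with fields `parity`, `q`,
#'   `n_states` and the mode numbers `w`.
#' @export
basis_spec <- function(parity = c("even", "odd"), q = 4) {
  parity <- match.arg(parity)
  q <- as.integer(q)
  stopifnot(q >= 1)
  n <- 2L^q
  w <- if (parity == "even") seq(1L, by = 2L, length.out = n)
       else seq(2L, by = 2L, length.out = n)
  structure(list(parity = parity, q = q, n_states = n, w = w),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("%s-parity sine basis: %d states (q = %d), w = %s...\n",
              x$parity, x$n_states, x$q,
              paste(utils::head(x$w, 4), collapse = ", ")))
  invisible(x)
}

#' Evaluate the sine basis on the grid
#'
#' @param spec A [model_spec()].
#' @param basis A [basis_spec()].
#' @return `n_grid x n_states` matrix; column `k` holds
#'   \eqn{\sqrt{2/L}\,\sin(w_k \pi/L (x - L/2))}.
#' @export
sine_basis <- function(spec = model_spec(), basis = basis_spec()) {
  x <- grid_points(spec)
  L <- spec$L
  B <- vapply(basis$w,
              function(w) sqrt(2 / L) * sin(w * pi / L * (x - L / 2)),
              numeric(spec$n_grid))
  # enforce the stated parity exactly (guards against index/parity mismatch)
  sgn <- if (basis$parity == "even") 1 else -1
  if (max(abs(B[spec$n_grid:1, ] - sgn * B)) > 1e-8)
    stop("basis parity/index mismatch")
  B
}

# Trapezoid quadrature weights on the uniform grid (endpoints halved).
quad_weights <- function(spec) {
  dx <- 2 * spec$x_max / (spec$n_grid - 1)
  w <- rep(dx, spec$n_grid)
  w[c(1, spec$n_grid)] <- dx / 2
  w
}

#' Project the Hamiltonian and CAP onto the sine basis
#'
#' Galerkin projection by grid quadrature of the Hermitian Hamiltonian
#' `H_H = T + V_0` and of the CAP profile `V_CAP` onto the parity-split sine
#' basis. Both projected matrices are real symmetric; the projected CAP is
#' negative semidefinite (the grid profile is nonpositive).
#'
#' @param spec A [model_spec()].
#' @param basis A [basis_spec()].
#' @return An object of class `operator_set` with fields `HH`, `VCAP`
#'   (dense `n_states x n_states` matrices, au), `spec` and `basis`.
#' @export
project_operators <- function(spec = model_spec(), basis = basis_spec()) {
  B <- sine_basis(spec, basis)
  x <- grid_points(spec)
  dx <- 2 * spec$x_max / (spec$n_grid - 1)
  wts <- quad_weights(spec)
  V0 <- potential_energy(x, spec)
  Vc <- cap_potential(x, spec)
  TB <- apply_kinetic(B, dx)
  Bw <- B * wts
  HH <- crossprod(Bw, TB + V0 * B)
  VCAP <- crossprod(Bw, Vc * B)
  if (max(abs(HH - t(HH))) > 1e-8 || max(abs(VCAP - t(VCAP))) > 1e-8)
    stop("quadrature failure: projected operators not symmetric")
  HH <- (HH + t(HH)) / 2
  VCAP <- (VCAP + t(VCAP)) / 2
  structure(list(HH = HH, VCAP = VCAP, spec = spec, basis = basis),
            class = "operator_set")
}

#' @export
print.operator_set <- function(x, ...) {
  cat(sprintf("Projected operators: %d x %d (%s parity)\n",
              nrow(x$HH), ncol(x$HH), x$basis$parity))
  invisible(x)
}

#' Assemble the non-Hermitian CAP Hamiltonian
#'
#' @param ops An [project_operators()] result.
#' @return Complex symmetric matrix \eqn{H_N = H_H + i V_{CAP}}.
#' @export
assemble_HN <- function(ops) {
  stopifnot(inherits(ops, "operator_set"))
  ops$HH + 1i * ops$VCAP
}
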
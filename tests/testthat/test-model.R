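test_that("potential evaluates to its closed form", {
  spec <- model_spec()
  expect_equal(potential_energy(0, spec), 0)
  expect_equal(potential_energy(50, spec), 0.8, tolerance = 1e-12)
  expect_equal(potential_energy(-50, spec), 0.8, tolerance = 1e-12)
  # direct scalar evaluation oracle at x = 1
  expect_equal(potential_energy(1, spec), (0.5 - 0.8) * exp(-0.1) + 0.8)
  # parameter variations propagate
  spec2 <- model_spec(lambda = 0.3, J = 1.1)
  expect_equal(potential_energy(2, spec2), (2 - 1.1) * exp(-1.2) + 1.1)
})

test_that("CAP is zero inside the onset and quadratic outside", {
  spec <- model_spec()
  expect_equal(cap_potential(5, spec), 0)
  expect_equal(cap_potential(-8, spec), 0)
  expect_equal(cap_potential(9, spec), -0.5)
  expect_equal(cap_potential(-10, spec), -2.0)
  x <- seq(-10, 10, length.out = 201)
  expect_true(all(cap_potential(x, spec) <= 0))
})

test_that("model_spec rejects invalid parameter combinations", {
  expect_error(model_spec(x0 = 12), "x0")
  expect_error(model_spec(n_grid = 4))
  expect_error(model_spec(lambda = -1))
})

test_that("kinetic stencil annihilates constants and is symmetric", {
  spec <- small_spec(64)
  T <- as.matrix(kinetic_matrix(spec))
  expect_equal(T, t(T))
  v <- rep(1, 64)
  expect_equal((T %*% v)[2:63], rep(0, 62), tolerance = 1e-12)
})

test_that("kinetic stencil has the closed-form plane-wave spectrum on a periodic ring", {
  # periodic test stencil: same -1/2 D2 coefficients with wraparound;
  # discrete plane waves are exact eigenvectors with eigenvalue
  # (1 - cos(k dx))/dx^2
  n <- 32
  dx <- 0.37
  ring <- matrix(0, n, n)
  for (j in seq_len(n)) {
    ring[j, j] <- 1 / dx^2
    ring[j, j %% n + 1] <- -0.5 / dx^2
    ring[j %% n + 1, j] <- -0.5 / dx^2
  }
  for (mode in c(1, 3, 7)) {
    k <- 2 * pi * mode / n
    wave <- exp(1i * k * seq_len(n))
    expect_equal(ring %*% wave, matrix((1 - cos(k)) / dx^2 * wave),
                 tolerance = 1e-10)
  }
})

test_that("sine basis is quadrature orthonormal with correct parity and nodes", {
  spec <- model_spec()              # full 2^12 grid for the 1e-3 contract
  for (par in c("even", "odd")) {
    basis <- basis_spec(par, 3)
    B <- sine_basis(spec, basis)
    gram <- crossprod(B * siegertq:::quad_weights(spec), B)
    expect_lt(max(abs(gram - diag(8))), 1e-3)
    # parity: phi(-x) = +phi(x) for even, -phi(x) for odd
    sgn <- if (par == "even") 1 else -1
    expect_equal(B[spec$n_grid:1, ], sgn * B, tolerance = 1e-10)
    # nodes at the box edges
    expect_equal(B[1, ], rep(0, 8), tolerance = 1e-12)
    expect_equal(B[spec$n_grid, ], rep(0, 8), tolerance = 1e-12)
  }
})

test_that("basis parity index sets follow the trigonometric identity", {
  expect_equal(basis_spec("even", 2)$w, c(1L, 3L, 5L, 7L))
  expect_equal(basis_spec("odd", 2)$w, c(2L, 4L, 6L, 8L))
})

test_that("projected operators are symmetric, CAP is negative semidefinite", {
  spec <- model_spec()
  ops <- project_operators(spec, basis_spec("even", 4))
  expect_lt(max(abs(ops$HH - t(ops$HH))), 1e-10)
  expect_lt(max(abs(ops$VCAP - t(ops$VCAP))), 1e-10)
  expect_lt(max(eigen(ops$VCAP, symmetric = TRUE)$values), 1e-8)
})

test_that("projected ground state converges to the full-grid value", {
  spec <- model_spec()
  ops <- project_operators(spec, basis_spec("even", 4))
  e_proj <- min(eigen(ops$HH, symmetric = TRUE)$values)
  # full-grid Hermitian ground state by sparse-free inverse-free route:
  # dense diagonalization on a reduced 2^10 grid is an adequate oracle
  spec_g <- model_spec(n_grid = 2^10)
  x <- grid_points(spec_g)
  dx <- x[2] - x[1]
  Tg <- as.matrix(kinetic_matrix(spec_g))
  Hg <- Tg + diag(potential_energy(x, spec_g))
  e_grid <- min(eigen(Hg, symmetric = TRUE)$values)
  expect_lt(abs(e_proj - e_grid) / abs(e_grid), 0.02)
})

test_that("projection accuracy improves monotonically from q = 2 to 4", {
  spec <- model_spec()
  ref <- cap_reference(4, "even", spec)   # best available within the family
  exact_b <- ref$table$Re[ref$table$label == "bound"]
  errs <- vapply(2:4, function(q) {
    e <- min(eigen(project_operators(spec, basis_spec("even", q))$HH,
                   symmetric = TRUE)$values)
    abs(e - 0.502)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("H_N assembly is complex symmetric and reduces to H_H without CAP", {
  spec <- model_spec()
  ops <- project_operators(spec, basis_spec("odd", 3))
  HN <- assemble_HN(ops)
  expect_equal(HN, t(HN))
  expect_equal(HN - ops$HH, 1i * ops$VCAP)
  ops0 <- fake_operator_set(ops$HH, ops$VCAP * 0)
  expect_equal(assemble_HN(ops0), ops$HH + 0i)
})

test_that("cross-parity projections are decoupled blocks of the full problem", {
  # projecting even and odd bases separately must give the same eigenvalues
  # as the union basis (parity closure)
  spec <- model_spec(n_grid = 2^10)
  q <- 2
  ev <- eigen(assemble_HN(project_operators(spec, basis_spec("even", q))))$values
  od <- eigen(assemble_HN(project_operators(spec, basis_spec("odd", q))))$values
  # union basis w = 1..8
  B_even <- sine_basis(spec, basis_spec("even", q))
  B_odd <- sine_basis(spec, basis_spec("odd", q))
  x <- grid_points(spec)
  wts <- siegertq:::quad_weights(spec)
  B <- cbind(B_even, B_odd)
  dx <- x[2] - x[1]
  TB <- siegertq:::apply_kinetic(B, dx)
  H <- crossprod(B * wts, TB + potential_energy(x, spec) * B) +
    1i * crossprod(B * wts, cap_potential(x, spec) * B)
  all_v <- eigen((H + t(H)) / 2)$values
  got <- sort(Re(c(ev, od)))
  expect_equal(sort(Re(all_v)), got, tolerance = 1e-8)
})
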
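test_that("ansatz bookkeeping and state preparation basics", {
  a <- ansatz_spec(3, layers = 3)
  expect_equal(a$m, 24)          # 2 q (layers + 1)
  psi0 <- prepare_state(a, rep(0, a$m))
  expect_equal(psi0, c(1 + 0i, rep(0 + 0i, 7)))
  set.seed(2)
  for (rep in 1:5) {
    psi <- prepare_state(a, random_parameters(a))
    expect_equal(sum(Mod(psi)^2), 1, tolerance = 1e-12)
  }
  expect_error(prepare_state(a, rep(0, 5)), "length")
  # deterministic in the parameters
  th <- random_parameters(a)
  expect_identical(prepare_state(a, th), prepare_state(a, th))
})

test_that("exact expectation matches the dense quadratic form", {
  set.seed(7)
  a <- ansatz_spec(2)
  b <- backend_config("exact")
  for (rep in 1:5) {
    th <- random_parameters(a)
    M <- random_hermitian(4)
    d <- pauli_decompose(M)
    psi <- prepare_state(a, th)
    expect_equal(expectation(a, th, d, b),
                 Re(Conj(psi) %*% M %*% psi)[1], tolerance = 1e-10)
  }
  expect_error(expectation(a, random_parameters(a),
                           pauli_decompose(matrix(c(0, 1i, 2, 0), 2, 2)),
                           b), "Hermitian")
})

test_that("the all-identity word contributes its coefficient exactly in every mode", {
  a <- ansatz_spec(2)
  d <- pauli_decompose(diag(4) * 0.7)
  th <- rep(0.3, a$m)
  for (mode in c("exact", "sampled")) {
    b <- backend_config(mode, shots = 10)
    expect_identical(expectation(a, th, d, b), 0.7)
  }
  b <- backend_config("noisy", shots = 10, device = device_model())
  expect_identical(expectation(a, th, d, b), 0.7)
})

test_that("sampled expectations are unbiased with shot-limited error", {
  set.seed(31)
  a <- ansatz_spec(2)
  spec <- small_spec()
  ms <- measurement_set(project_operators(spec, basis_spec("even", 2)))
  th <- random_parameters(a)
  exact <- expectation(a, th, ms$A, backend_config("exact"))
  n <- 1e5
  b <- backend_config("sampled", shots = n)
  draws <- replicate(50, expectation(a, th, ms$A, b))
  # the total standard error is bounded by the sum of per-word coefficient
  # magnitudes over sqrt(n); the mean of 50 draws must sit within 4 of its
  # (conservatively bounded) standard errors
  se_bound <- sum(Mod(ms$A$coefficient)) / sqrt(n)
  expect_lt(abs(mean(draws) - exact), 4 * se_bound / sqrt(50))
})

test_that("sampled estimator variance scales as 1/shots", {
  set.seed(5)
  a <- ansatz_spec(1)
  d <- pauli_decompose(matrix(c(0, 1, 1, 0), 2, 2))  # X
  th <- random_parameters(a)
  ns <- c(1e2, 1e4, 1e6)
  vars <- vapply(ns, function(n) {
    b <- backend_config("sampled", shots = n)
    stats::var(replicate(40, expectation(a, th, d, b)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(vars) ~ log(ns)))[2]
  expect_lt(slope, -0.8)
  expect_gt(slope, -1.2)
})

test_that("squared overlaps behave across modes", {
  set.seed(13)
  a <- ansatz_spec(2)
  th1 <- random_parameters(a)
  th2 <- random_parameters(a)
  b <- backend_config("exact")
  expect_equal(overlap_squared(a, th1, th1, b), 1, tolerance = 1e-12)
  # computational-basis flip: Ry(pi) on one qubit of the zero state
  flip <- rep(0, a$m); flip[1] <- pi
  expect_equal(overlap_squared(a, rep(0, a$m), flip, b), 0,
               tolerance = 1e-12)
  # exact mode agrees with the statevector inner-product oracle
  p1 <- prepare_state(a, th1); p2 <- prepare_state(a, th2)
  expect_equal(overlap_squared(a, th1, th2, b),
               Mod(sum(Conj(p1) * p2))^2, tolerance = 1e-10)
  # sampled mode estimates the same quantity
  bs <- backend_config("sampled", shots = 1e5)
  est <- mean(replicate(20, overlap_squared(a, th1, th2, bs)))
  expect_lt(abs(est - Mod(sum(Conj(p1) * p2))^2), 0.01)
  expect_error(overlap_squared(a, th1, c(th2, 1), b), "match")
})

test_that("Kraus channel sets are complete and vanish at t = 0", {
  for (t_ns in c(0, 35, 300)) {
    Kad <- siegertq:::kraus_amplitude_damping(t_ns, 70, p_excited = 0.1)
    S <- Reduce(`+`, lapply(Kad, function(K) Conj(t(K)) %*% K))
    expect_lt(max(Mod(S - diag(2))), 1e-12)
    Kpd <- siegertq:::kraus_phase_damping(t_ns, 50)
    S <- Reduce(`+`, lapply(Kpd, function(K) Conj(t(K)) %*% K))
    expect_lt(max(Mod(S - diag(2))), 1e-12)
  }
  # t = 0: both channels are the identity
  K0 <- siegertq:::kraus_amplitude_damping(0, 70)
  rho <- random_hermitian(2)
  expect_equal(siegertq:::apply_kraus(rho, K0), rho, tolerance = 1e-12)
})

test_that("noisy evolution preserves trace and reduces purity", {
  set.seed(3)
  a <- ansatz_spec(2)
  th <- random_parameters(a)
  dev <- device_model()
  rho <- evolve_noisy(a, th, dev)
  expect_lt(abs(sum(diag(rho)) - 1), 1e-10)
  expect_lt(max(Mod(rho - Conj(t(rho)))), 1e-10)
  expect_lt(Re(sum(diag(rho %*% rho))), 1)
  # noiseless device reproduces the pure state exactly
  dev0 <- device_model(T1 = Inf, T2 = Inf, p1 = 0, p2 = 0,
                       p01 = 0, p10 = 0)
  psi <- prepare_state(a, th)
  expect_lt(max(Mod(evolve_noisy(a, th, dev0) - psi %*% t(Conj(psi)))),
            1e-10)
  expect_error(device_model(T1 = 10, T2 = 30), "unphysical")
})

test_that("full depolarizing noise yields the maximally mixed marginal", {
  set.seed(8)
  a <- ansatz_spec(1)
  psi <- prepare_state(a, random_parameters(a))
  rho <- psi %*% t(Conj(psi))
  out <- siegertq:::apply_depolarizing(rho, 1, 1, 1)
  expect_lt(max(Mod(out - diag(2) / 2)), 1e-12)
})

test_that("device scaling follows the longevity and gate-factor rules", {
  dev <- device_model(T1 = 70, T2 = 50)
  d2 <- scale_device(dev, gate_factor = 1, longevity = 100)
  expect_equal(d2$T1, 700)
  expect_equal(d2$T2, 500)
  # g = 1 at the base order leaves the device unchanged
  d3 <- scale_device(dev, gate_factor = 1, longevity = 10)
  expect_equal(d3$T1, 70)
  expect_equal(d3$T2, 50)
  d4 <- scale_device(dev, gate_factor = 100)
  expect_equal(d4$p1, dev$p1 / 100)
  expect_equal(d4$p2, dev$p2 / 100)
  # infinite longevity removes thermal relaxation entirely
  d5 <- scale_device(dev, longevity = Inf)
  K <- siegertq:::kraus_amplitude_damping(1e6, d5$T1)
  expect_equal(K[[2]], matrix(0, 2, 2))
  expect_error(scale_device(dev, gate_factor = 0.5), ">= 1")
})

test_that("readout confusion and its inversion are inverse maps on distributions", {
  set.seed(21)
  dev <- device_model(p01 = 0.04, p10 = 0.07)
  for (q in 1:3) {
    p <- stats::runif(2^q); p <- p / sum(p)
    noisy <- siegertq:::apply_confusion(p, dev, q)
    expect_equal(sum(noisy), 1, tolerance = 1e-12)
    expect_equal(siegertq:::unconfuse(noisy, dev, q), p, tolerance = 1e-10)
  }
})

test_that("a bundled device file loads and matches its stated values", {
  f <- system.file("extdata", "device_synthetic_nisq.txt",
                   package = "siegertq")
  dev <- read_device_model(f)
  expect_s3_class(dev, "device_model")
  expect_equal(dev$T1, 70)
  expect_equal(dev$T2, 50)
  expect_equal(dev$p00, 0.98)
})
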
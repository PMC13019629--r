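# Shared small fixtures. Tiny grids keep unit tests fast; the physical
# 2^12-point grid is exercised where the assertion needs it.

small_spec <- function(n_grid = 2^9) model_spec(n_grid = n_grid)

# Random Hermitian matrix of dimension d.
random_hermitian <- function(d) {
  M <- matrix(stats::rnorm(d^2), d, d) +
    1i * matrix(stats::rnorm(d^2), d, d)
  (M + Conj(t(M))) / 2
}

# Random real symmetric matrix of dimension d.
random_symmetric <- function(d) {
  M <- matrix(stats::rnorm(d^2), d, d)
  (M + t(M)) / 2
}

# An operator_set with prescribed matrices (for oracle tests).
fake_operator_set <- function(HH, VCAP) {
  structure(list(HH = HH, VCAP = VCAP,
                 spec = model_spec(), basis = NULL),
            class = "operator_set")
}
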
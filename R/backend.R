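#' Hardware-efficient SU(2) ansatz specification
#'
#' Rotation layers of single-qubit `Ry` then `Rz` gates on every qubit,
#' alternated with entangling layers of CNOTs on a linear chain, with
#' `layers` entangling repetitions and a final rotation layer. The parameter
#' count is `m = 2 q (layers + 1)` angles in radians.
#'
#' @param q Number of qubits.
#' @param layers Number of entangling repetitions (default 3).
#' @return Object of class `ansatz_spec` with the gate program and
#'   precomputed amplitude index tables.
#' @examples
#' a <- ansatz_spec(3)
#' a$m   # 24
#' @export
ansatz_spec <- function(q, layers = 3) {
  q <- as.integer(q); layers <- as.integer(layers)
  stopifnot(q >= 1, layers >= 0)
  dim <- 2L^q
  # index tables: for qubit j, positions with bit j clear/set (1-based),
  # paired so idx1[k] flips bit j of idx0[k]
  bits <- 0:(dim - 1)
  idx <- lapply(seq_len(q), function(j) {
    mask <- bitwAnd(bits, 2L^(j - 1L))
    i0 <- which(mask == 0L)
    list(i0 = i0, i1 = i0 + 2L^(j - 1L))
  })
  gates <- list()
  p <- 0L
  add_rot <- function(gates) {
    for (j in seq_len(q)) {
      p <<- p + 1L
      gates[[length(gates) + 1L]] <- list(type = "ry", qubit = j, pidx = p)
      p <<- p + 1L
      gates[[length(gates) + 1L]] <- list(type = "rz", qubit = j, pidx = p)
    }
    gates
  }
  for (l in seq_len(layers)) {
    gates <- add_rot(gates)
    if (q > 1)
      for (j in seq_len(q - 1))
        gates[[length(gates) + 1L]] <-
          list(type = "cx", control = j, target = j + 1L, pidx = NA_integer_)
  }
  gates <- add_rot(gates)
  structure(list(q = q, layers = layers, m = p, dim = dim,
                 gates = gates, idx = idx),
            class = "ansatz_spec")
}

#' @export
print.ansatz_spec <- function(x, ...) {
  cat(sprintf("Efficient-SU(2) ansatz: q = %d, %d entangling layers, m = %d angles\n",
              x$q, x$layers, x$m))
  invisible(x)
}

#' Draw random initial ansatz angles
#'
#' Uniform on `[-pi, pi]`, the initialization domain of the method.
#'
#' @param ansatz An [ansatz_spec()].
#' @return Numeric vector of length `ansatz$m`.
#' @export
random_parameters <- function(ansatz) {
  stats::runif(ansatz$m, -pi, pi)
}

# Apply one gate (optionally inverted) to a statevector.
apply_gate_sv <- function(psi, g, theta, idx, invert = FALSE) {
  if (g$type == "cx") {
    t_idx <- idx[[g$target]]
    ctrl_set <- bitwAnd(t_idx$i0 - 1L, 2L^(g$control - 1L)) != 0L
    a <- t_idx$i0[ctrl_set]; b <- t_idx$i1[ctrl_set]
    tmp <- psi[a]; psi[a] <- psi[b]; psi[b] <- tmp
    return(psi)
  }
  th <- theta[g$pidx]
  if (invert) th <- -th
  i <- idx[[g$qubit]]
  if (g$type == "ry") {
    c2 <- cos(th / 2); s2 <- sin(th / 2)
    a0 <- psi[i$i0]; a1 <- psi[i$i1]
    psi[i$i0] <- c2 * a0 - s2 * a1
    psi[i$i1] <- s2 * a0 + c2 * a1
  } else {  # rz
    ph <- exp(1i * th / 2)
    psi[i$i0] <- psi[i$i0] / ph
    psi[i$i1] <- psi[i$i1] * ph
  }
  psi
}

#' Prepare the ansatz statevector
#'
#' Applies the gate program to the all-zeros computational state. With all
#' angles zero the circuit is the identity and the all-zeros state returns.
#'
#' @param ansatz An [ansatz_spec()].
#' @param theta Numeric vector of `ansatz$m` angles (radians).
#' @return Complex unit vector of length `2^q`.
#' @export
prepare_state <- function(ansatz, theta) {
  if (length(theta) != ansatz$m)
    stop("parameter vector has length ", length(theta),
         ", ansatz needs ", ansatz$m)
  psi <- complex(ansatz$dim)
  psi[1] <- 1 + 0i
  for (g in ansatz$gates) psi <- apply_gate_sv(psi, g, theta, ansatz$idx)
  psi
}

# Statevector of the inverse circuit applied to psi (for compute-uncompute).
apply_inverse_sv <- function(psi, ansatz, theta) {
  for (g in rev(ansatz$gates))
    psi <- apply_gate_sv(psi, g, theta, ansatz$idx, invert = TRUE)
  psi
}

#' Backend configuration
#'
#' @param mode `"exact"` (statevector expectation values), `"sampled"`
#'   (finite shots per circuit), or `"noisy"` (density-matrix simulation
#'   with a device noise model, finite shots and readout confusion).
#' @param shots Shots per circuit in sampled/noisy mode (default `1e5`).
#' @param final_shots Shots used for final cross-batch comparison
#'   (default `1e6`, one order of magnitude more).
#' @param device A [device_model()], required for `"noisy"`.
#' @param readout_mitigation Apply per-qubit confusion-matrix inversion to
#'   measured statistics (noisy mode).
#' @param zne Apply hybrid exponential/linear zero-noise extrapolation with
#'   gate folding at scales 1, 3, 5 (noisy mode).
#' @return Object of class `backend_config`.
#' @export
backend_config <- function(mode = c("exact", "sampled", "noisy"),
                           shots = 1e5, final_shots = 1e6, device = NULL,
                           readout_mitigation = FALSE, zne = FALSE) {
  mode <- match.arg(mode)
  if (mode %in% c("sampled", "noisy") && shots < 1)
    stop("sampled/noisy mode needs shots >= 1")
  if (mode == "noisy" && is.null(device))
    stop("noisy mode needs a device model")
  structure(list(mode = mode, shots = shots, final_shots = final_shots,
                 device = device,
                 readout_mitigation = isTRUE(readout_mitigation),
                 zne = isTRUE(zne)),
            class = "backend_config")
}

# ---- device noise model -----------------------------------------------------

#' Device noise model
#'
#' Thermal relaxation (generalized amplitude damping with time `T1`,
#' phase damping with time `T2 <= 2 T1`), depolarizing one- and two-qubit
#' gate errors, readout confusion and gate durations. Scalars are recycled
#' across qubits.
#'
#' @param T1,T2 Relaxation times, microseconds.
#' @param p_excited Equilibrium excited-state population (default 0: cold
#'   bath).
#' @param p1,p2 One-/two-qubit depolarizing error probabilities.
#' @param p01,p10 Readout confusion probabilities (`p_ij`: true state `i`
#'   read as `j`); the diagonal entries are their complements.
#' @param t_1q,t_2q Gate durations, nanoseconds.
#' @return Object of class `device_model`.
#' @export
device_model <- function(T1 = 70, T2 = 50, p_excited = 0,
                         p1 = 3e-4, p2 = 3e-3,
                         p01 = 0.02, p10 = 0.02,
                         t_1q = 50, t_2q = 300) {
  if (any(T2 > 2 * T1 + 1e-12)) stop("unphysical model: T2 > 2*T1")
  probs <- c(p_excited, p1, p2, p01, p10)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  structure(list(T1 = T1, T2 = T2, p_excited = p_excited,
                 p1 = p1, p2 = p2,
                 p00 = 1 - p01, p01 = p01, p10 = p10, p11 = 1 - p10,
                 t_1q = t_1q, t_2q = t_2q),
            class = "device_model")
}

#' Read a device model from a key = value text file
#'
#' @param file Path to a plain-text file with `key = value` lines matching
#'   the arguments of [device_model()]. A synthetic NISQ-grade default ships
#'   with the package (`system.file("extdata", "device_synthetic_nisq.txt",
#'   package = "siegertq")`).
#' @return A [device_model()].
#' @export
read_device_model <- function(file) {
  kv <- read_key_values(file)
  do.call(device_model, kv[intersect(names(kv), names(formals(device_model)))])
}

#' Rescale a device model toward lower noise
#'
#' Divides the depolarizing gate-error probabilities by the gate-noise
#' reduction factor. The qubit longevity factor sets the order of magnitude
#' of `T1` while preserving its leading digit (e.g. base `T1 = 70` with
#' longevity 100 microseconds gives `T1 = 700`); `T2` is rescaled to keep
#' the `T1/T2` ratio fixed. An infinite longevity removes thermal relaxation
#' entirely.
#'
#' @param dev A [device_model()].
#' @param gate_factor Gate-noise reduction factor `g >= 1`.
#' @param longevity Qubit longevity factor in microseconds, or `Inf`.
#' @return A rescaled [device_model()].
#' @export
scale_device <- function(dev, gate_factor = 1, longevity = NULL) {
  stopifnot(inherits(dev, "device_model"))
  if (gate_factor < 1) stop("gate-noise reduction factor must be >= 1")
  out <- dev
  out$p1 <- dev$p1 / gate_factor
  out$p2 <- dev$p2 / gate_factor
  if (!is.null(longevity)) {
    if (is.infinite(longevity)) {
      out$T1 <- Inf; out$T2 <- Inf
    } else {
      lead <- dev$T1 / 10^floor(log10(dev$T1))
      T1new <- lead * longevity
      out$T2 <- T1new * dev$T2 / dev$T1
      out$T1 <- T1new
    }
  }
  out
}

# ---- Kraus channels ---------------------------------------------------------

# Generalized amplitude damping Kraus set for duration t (ns), T1 (us).
kraus_amplitude_damping <- function(t_ns, T1_us, p_excited = 0) {
  if (is.infinite(T1_us)) g1 <- 0 else g1 <- 1 - exp(-(t_ns * 1e-3) / T1_us)
  p <- p_excited
  list(
    sqrt(1 - p) * matrix(c(1, 0, 0, sqrt(1 - g1)), 2, 2),
    sqrt(1 - p) * matrix(c(0, 0, sqrt(g1), 0), 2, 2),
    sqrt(p) * matrix(c(sqrt(1 - g1), 0, 0, 1), 2, 2),
    sqrt(p) * matrix(c(0, sqrt(g1), 0, 0), 2, 2)
  )
}

# Phase damping Kraus set for duration t (ns), T2 (us).
kraus_phase_damping <- function(t_ns, T2_us) {
  if (is.infinite(T2_us)) g2 <- 0 else g2 <- 1 - exp(-(t_ns * 1e-3) / T2_us)
  list(
    matrix(c(1, 0, 0, sqrt(1 - g2)), 2, 2),
    matrix(c(0, 0, 0, sqrt(g2)), 2, 2)
  )
}

# Embed a single-qubit operator on qubit j of q qubits (qubit 1 = least
# significant bit, consistent with the statevector index tables).
embed_1q <- function(op, j, q) {
  M <- op
  if (j < q) M <- kronecker(diag(2^(q - j)), M)
  if (j > 1) M <- kronecker(M, diag(2^(j - 1)))
  M
}

apply_kraus <- function(rho, kraus_full) {
  out <- matrix(0 + 0i, nrow(rho), ncol(rho))
  for (K in kraus_full) out <- out + K %*% rho %*% Conj(t(K))
  out
}

# d-qubit depolarizing channel on the subset `qs` of qubits: with
# probability p the state of those qubits is replaced by I/2^d.
apply_depolarizing <- function(rho, p, qs, q) {
  if (p <= 0) return(rho)
  d <- length(qs)
  dim <- 2^q
  bits <- 0:(dim - 1)
  keep <- setdiff(seq_len(q), qs)
  idx_of <- function(set) {
    v <- integer(dim)
    for (k in seq_along(set))
      v <- v + (bitwAnd(bits, 2L^(set[k] - 1L)) %/% 2L^(set[k] - 1L)) *
        2L^(k - 1L)
    v
  }
  keep_idx <- idx_of(keep)
  qs_idx <- idx_of(qs)
  nk <- 2^length(keep)
  tr_part <- matrix(0 + 0i, nk, nk)
  for (a in seq_len(dim)) for (b in seq_len(dim))
    if (qs_idx[a] == qs_idx[b])
      tr_part[keep_idx[a] + 1, keep_idx[b] + 1] <-
        tr_part[keep_idx[a] + 1, keep_idx[b] + 1] + rho[a, b]
  mixed <- matrix(0 + 0i, dim, dim)
  for (a in seq_len(dim)) for (b in seq_len(dim))
    if (qs_idx[a] == qs_idx[b])
      mixed[a, b] <- tr_part[keep_idx[a] + 1, keep_idx[b] + 1] / 2^d
  (1 - p) * rho + p * mixed
}

# Full-dimension unitary of one gate.
gate_unitary <- function(g, theta, q, invert = FALSE) {
  if (g$type == "cx") {
    dim <- 2^q
    U <- matrix(0, dim, dim)
    bits <- 0:(dim - 1)
    tgt <- vapply(bits, function(b) {
      if (bitwAnd(b, 2L^(g$control - 1L)) != 0L)
        bitwXor(b, 2L^(g$target - 1L)) else b
    }, integer(1))
    U[cbind(tgt + 1, bits + 1)] <- 1
    return(U)
  }
  th <- theta[g$pidx]
  if (invert) th <- -th
  op <- if (g$type == "ry") {
    matrix(c(cos(th / 2), sin(th / 2), -sin(th / 2), cos(th / 2)), 2, 2)
  } else {
    diag(c(exp(-1i * th / 2), exp(1i * th / 2)))
  }
  embed_1q(op, g$qubit, q)
}

# Gate program with optional unitary folding g (g^-1 g)^((scale-1)/2).
folded_program <- function(gates, scale = 1) {
  if (scale == 1) return(lapply(gates, function(g) c(g, invert = FALSE)))
  if (scale %% 2 != 1) stop("folding scale must be odd")
  out <- list()
  reps <- (scale - 1) / 2
  for (g in gates) {
    out[[length(out) + 1]] <- c(g, invert = FALSE)
    for (r in seq_len(reps)) {
      out[[length(out) + 1]] <- c(g, invert = TRUE)
      out[[length(out) + 1]] <- c(g, invert = FALSE)
    }
  }
  out
}

#' Evolve the ansatz under a device noise model
#'
#' Density-matrix simulation: after each gate the per-qubit thermal
#' relaxation channels (generalized amplitude damping and phase damping for
#' the gate's duration) act on every qubit the gate touches, followed by the
#' d-qubit depolarizing channel with the device's gate-error probability.
#'
#' @param ansatz An [ansatz_spec()].
#' @param theta Angles, length `ansatz$m`.
#' @param dev A [device_model()].
#' @param program Optional explicit gate program (e.g. a folded one);
#'   defaults to the ansatz program.
#' @return Complex `2^q x 2^q` density matrix with unit trace.
#' @export
evolve_noisy <- function(ansatz, theta, dev, program = NULL) {
  stopifnot(inherits(dev, "device_model"))
  q <- ansatz$q
  dim <- ansatz$dim
  rho <- matrix(0 + 0i, dim, dim)
  rho[1, 1] <- 1
  if (is.null(program)) program <- folded_program(ansatz$gates, 1)
  for (g in program) {
    U <- gate_unitary(g, theta, q, invert = isTRUE(g$invert))
    rho <- U %*% rho %*% Conj(t(U))
    qs <- if (g$type == "cx") c(g$control, g$target) else g$qubit
    t_ns <- if (g$type == "cx") dev$t_2q else dev$t_1q
    for (j in qs) {
      Kad <- lapply(kraus_amplitude_damping(t_ns, dev$T1, dev$p_excited),
                    embed_1q, j = j, q = q)
      rho <- apply_kraus(rho, Kad)
      Kpd <- lapply(kraus_phase_damping(t_ns, dev$T2), embed_1q, j = j, q = q)
      rho <- apply_kraus(rho, Kpd)
    }
    pd <- if (g$type == "cx") dev$p2 else dev$p1
    rho <- apply_depolarizing(rho, pd, qs, q)
  }
  if (abs(sum(diag(rho)) - 1) > 1e-8) stop("trace not preserved")
  rho
}

# ---- measurement ------------------------------------------------------------

# Single-qubit basis-change unitaries mapping the Pauli eigenbasis to Z.
basis_change_1q <- list(
  I = diag(2),
  Z = diag(2),
  X = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),                 # H
  Y = matrix(c(1, 1, -1i, 1i), 2, 2) / sqrt(2)                # H S^dagger
)

# Parity (+1/-1) of each computational outcome for a Pauli word.
word_parity <- function(word, q) {
  letters_ <- rev(strsplit(word, "")[[1]])  # letters_[j] acts on qubit j
  bits <- 0:(2^q - 1)
  par <- rep(1, 2^q)
  for (j in seq_len(q)) {
    if (letters_[j] != "I") {
      bit <- bitwAnd(bits, 2L^(j - 1L)) %/% 2L^(j - 1L)
      par <- par * (1 - 2 * bit)
    }
  }
  par
}

# Full basis-change unitary for a word (letter k acts on qubit q-k+1).
word_rotation <- function(word, q) {
  letters_ <- strsplit(word, "")[[1]]
  U <- basis_change_1q[[letters_[1]]]
  for (s in letters_[-1]) U <- kronecker(U, basis_change_1q[[s]])
  U
}

# Apply per-qubit readout confusion to a probability vector over outcomes.
apply_confusion <- function(probs, dev, q) {
  C <- matrix(c(dev$p00, dev$p01, dev$p10, dev$p11), 2, 2, byrow = TRUE)
  out <- probs
  for (j in seq_len(q)) {
    dim(out) <- c(2^(j - 1), 2, 2^(q - j))
    new <- out
    new[, 1, ] <- C[1, 1] * out[, 1, ] + C[2, 1] * out[, 2, ]
    new[, 2, ] <- C[1, 2] * out[, 1, ] + C[2, 2] * out[, 2, ]
    out <- new
  }
  dim(out) <- NULL
  out
}

# Invert per-qubit readout confusion on a probability vector: the
# single-qubit two-outcome inversion applied tensorially per qubit axis.
unconfuse <- function(probs, dev, q) {
  C <- matrix(c(dev$p00, dev$p01, dev$p10, dev$p11), 2, 2, byrow = TRUE)
  Ci <- solve(C)
  out <- probs
  for (j in seq_len(q)) {
    dim(out) <- c(2^(j - 1), 2, 2^(q - j))
    new <- out
    new[, 1, ] <- Ci[1, 1] * out[, 1, ] + Ci[2, 1] * out[, 2, ]
    new[, 2, ] <- Ci[1, 2] * out[, 1, ] + Ci[2, 2] * out[, 2, ]
    out <- new
  }
  dim(out) <- NULL
  out
}

# Sampled parity estimate from an outcome distribution.
sample_parity <- function(probs, parity, shots) {
  probs <- pmax(probs, 0)
  probs <- probs / sum(probs)
  counts <- stats::rmultinom(1, shots, probs)[, 1]
  sum(counts * parity) / shots
}

#' Expectation value of a Hermitian Pauli decomposition
#'
#' Evaluates \eqn{\langle\psi(\theta)| M |\psi(\theta)\rangle} for a
#' Hermitian operator given as a Pauli decomposition. The all-identity word
#' is analytically `<psi|psi> = 1`, so its coefficient is added exactly in
#' every mode and bypasses shot noise, readout confusion and extrapolation.
#'
#' In `"sampled"` mode each remaining word is measured by rotating to its
#' eigenbasis and drawing `shots` outcomes; in `"noisy"` mode the state is a
#' density matrix evolved under the device model and readout confusion acts
#' on the outcome distribution, optionally followed by confusion inversion
#' and zero-noise extrapolation over folded circuits.
#'
#' @param ansatz An [ansatz_spec()].
#' @param theta Angles, length `ansatz$m`.
#' @param d A Hermitian [pauli_decompose()] result.
#' @param backend A [backend_config()].
#' @param shots Optional shot override (e.g. the final-comparison budget).
#' @return Real scalar.
#' @export
expectation <- function(ansatz, theta, d, backend = backend_config(),
                        shots = NULL) {
  if (!isTRUE(attr(d, "is_hermitian")))
    stop("expectation requires a Hermitian decomposition")
  q <- ansatz$q
  if (is.null(shots)) shots <- backend$shots
  coefs <- Re(d$coefficient)
  id_word <- strrep("I", q)
  is_id <- d$word == id_word
  val <- sum(coefs[is_id])              # analytically exact identity term
  rest <- which(!is_id)
  if (length(rest) == 0) return(val)
  if (backend$mode == "exact") {
    M <- pauli_reconstruct(d[rest, , drop = FALSE] |>
                             structure(q = q, class = class(d)))
    psi <- prepare_state(ansatz, theta)
    return(val + Re(sum(Conj(psi) * (M %*% psi))))
  }
  if (backend$mode == "sampled") {
    psi <- prepare_state(ansatz, theta)
    for (k in rest) {
      U <- word_rotation(d$word[k], q)
      probs <- Mod(U %*% psi)^2
      val <- val + coefs[k] * sample_parity(probs, word_parity(d$word[k], q),
                                            shots)
    }
    return(val)
  }
  # noisy mode
  dev <- backend$device
  scales <- if (backend$zne) c(1, 3, 5) else 1
  rhos <- lapply(scales, function(s)
    evolve_noisy(ansatz, theta, dev, folded_program(ansatz$gates, s)))
  for (k in rest) {
    w <- d$word[k]
    U <- word_rotation(w, q)
    par <- word_parity(w, q)
    xs <- vapply(rhos, function(rho) {
      probs <- Re(diag(U %*% rho %*% Conj(t(U))))
      probs <- apply_confusion(probs, dev, q)
      probs <- pmax(probs, 0); probs <- probs / sum(probs)
      counts <- stats::rmultinom(1, shots, probs)[, 1]
      emp <- counts / shots
      if (backend$readout_mitigation) emp <- unconfuse(emp, dev, q)
      sum(emp * par)
    }, numeric(1))
    x0 <- if (backend$zne) {
      zne_extrapolate(xs[1], xs[2], xs[3],
                      se = sqrt(1 / shots))
    } else xs[1]
    val <- val + coefs[k] * x0
  }
  val
}

#' Squared overlap of two ansatz states
#'
#' \eqn{|\langle\psi(\theta_1)|\psi(\theta_2)\rangle|^2} via the
#' compute-uncompute construction: the all-zeros outcome probability of
#' \eqn{U^\dagger(\theta_1) U(\theta_2) |0\rangle}.
#'
#' @param ansatz An [ansatz_spec()].
#' @param theta1,theta2 Angle vectors of length `ansatz$m`.
#' @param backend A [backend_config()].
#' @param shots Optional shot override.
#' @return Value in `[0, 1]`.
#' @export
overlap_squared <- function(ansatz, theta1, theta2,
                            backend = backend_config(), shots = NULL) {
  if (length(theta1) != ansatz$m || length(theta2) != ansatz$m)
    stop("parameter vectors must match the ansatz")
  if (is.null(shots)) shots <- backend$shots
  if (backend$mode == "exact") {
    p1 <- prepare_state(ansatz, theta1)
    p2 <- prepare_state(ansatz, theta2)
    return(Mod(sum(Conj(p1) * p2))^2)
  }
  if (backend$mode == "sampled") {
    psi <- prepare_state(ansatz, theta2)
    psi <- apply_inverse_sv(psi, ansatz, theta1)
    p0 <- Mod(psi[1])^2
    return(stats::rbinom(1, shots, min(max(p0, 0), 1)) / shots)
  }
  # noisy: run the compute-uncompute circuit as one noisy program; the
  # compute half uses theta2 and the uncompute half theta1
  dev <- backend$device
  q <- ansatz$q
  rho <- matrix(0 + 0i, ansatz$dim, ansatz$dim); rho[1, 1] <- 1
  run_half <- function(rho, gates, th, invert) {
    ordered <- if (invert) rev(gates) else gates
    for (g in ordered) {
      U <- gate_unitary(g, th, q, invert = invert)
      rho <- U %*% rho %*% Conj(t(U))
      qs <- if (g$type == "cx") c(g$control, g$target) else g$qubit
      t_ns <- if (g$type == "cx") dev$t_2q else dev$t_1q
      for (j in qs) {
        rho <- apply_kraus(rho, lapply(
          kraus_amplitude_damping(t_ns, dev$T1, dev$p_excited),
          embed_1q, j = j, q = q))
        rho <- apply_kraus(rho, lapply(kraus_phase_damping(t_ns, dev$T2),
                                       embed_1q, j = j, q = q))
      }
      rho <- apply_depolarizing(rho, if (g$type == "cx") dev$p2 else dev$p1,
                                qs, q)
    }
    rho
  }
  rho <- run_half(rho, ansatz$gates, theta2, invert = FALSE)
  rho <- run_half(rho, ansatz$gates, theta1, invert = TRUE)
  probs <- apply_confusion(Re(diag(rho)), dev, q)
  probs <- pmax(probs, 0); probs <- probs / sum(probs)
  counts <- stats::rmultinom(1, shots, probs)[, 1]
  emp <- counts / shots
  if (backend$readout_mitigation) emp <- unconfuse(emp, dev, q)
  emp[1]
}

# Fast exact quadratic form <psi|M|psi> used in optimizer hot loops.
quad_form <- function(psi, M) Re(sum(Conj(psi) * (M %*% psi)))
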
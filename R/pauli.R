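#' @keywords internal
pauli_1q <- list(
  I = matrix(c(1, 0, 0, 1), 2, 2),
  X = matrix(c(0, 1, 1, 0), 2, 2),
  Y = matrix(c(0, 1i, -1i, 0), 2, 2),
  Z = matrix(c(1, 0, 0, -1), 2, 2)
)

#' Matrix of a Pauli word
#'
#' Tensor product of single-qubit Pauli operators. The first letter of the
#' word acts on the most significant qubit (leftmost Kronecker factor).
#'
#' @param word Character string over `{I, X, Y, Z}`.
#' @return Complex `2^q x 2^q` matrix for a word of length `q`.
#' @export
pauli_matrix <- function(word) {
  letters_ <- strsplit(word, "")[[1]]
  if (!all(letters_ %in% names(pauli_1q))) stop("invalid Pauli word: ", word)
  M <- pauli_1q[[letters_[1]]]
  for (s in letters_[-1]) M <- kronecker(M, pauli_1q[[s]])
  M
}

all_pauli_words <- function(q) {
  grids <- rep(list(c("I", "X", "Y", "Z")), q)
  g <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  apply(g[, rev(seq_len(q)), drop = FALSE], 1, paste0, collapse = "")
}

#' Decompose an operator into weighted Pauli words
#'
#' Expands a `2^q x 2^q` matrix `M` as \eqn{M = \sum_P c_P P} over all Pauli
#' words `P`, with \eqn{c_P = \mathrm{Tr}(M P)/2^q} (the normalization that
#' makes the expansion exact, since \eqn{\mathrm{Tr}(P^2) = 2^q}). Words with
#' `|c| < prune` are dropped to bound downstream measurement counts.
#'
#' @param M Square complex matrix; dimension must be a power of two.
#' @param prune Magnitude threshold below which coefficients are dropped.
#' @return Object of class `pauli_decomposition`: data frame with columns
#'   `word` and `coefficient` (complex), plus attributes `q` and
#'   `is_hermitian` (TRUE when all coefficients are numerically real).
#' @examples
#' d <- pauli_decompose(diag(c(1, -1)))   # the Z operator
#' @export
pauli_decompose <- function(M, prune = 1e-12) {
  n <- nrow(M)
  if (n != ncol(M)) stop("matrix must be square")
  q <- as.integer(round(log2(n)))
  if (2^q != n) stop("dimension must be a power of two")
  words <- all_pauli_words(q)
  coef <- vapply(words, function(w) sum(diag(M %*% pauli_matrix(w))) / n,
                 complex(1))
  keep <- Mod(coef) >= prune
  herm <- max(abs(Im(coef[keep])), 0) < 1e-10
  d <- data.frame(word = words[keep], stringsAsFactors = FALSE)
  d$coefficient <- coef[keep]
  structure(d, q = q, is_hermitian = herm,
            class = c("pauli_decomposition", "data.frame"))
}

#' Reconstruct the operator of a Pauli decomposition
#'
#' @param d A [pauli_decompose()] result (or a data frame with `word` and
#'   `coefficient` columns plus a `q` attribute).
#' @return Complex `2^q x 2^q` matrix \eqn{\sum c_P P}.
#' @export
pauli_reconstruct <- function(d) {
  q <- attr(d, "q")
  M <- matrix(0 + 0i, 2^q, 2^q)
  for (k in seq_len(nrow(d)))
    M <- M + d$coefficient[k] * pauli_matrix(d$word[k])
  M
}

#' @export
print.pauli_decomposition <- function(x, ...) {
  cat(sprintf("Pauli decomposition: %d words on %d qubit(s)%s\n",
              nrow(x), attr(x, "q"),
              if (isTRUE(attr(x, "is_hermitian"))) " (Hermitian)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Write a decomposition as two-column text
#'
#' @param d A [pauli_decompose()] result.
#' @param file Path of the output file.
#' @export
write_pauli <- function(d, file) {
  utils::write.table(
    data.frame(word = d$word, coefficient = Re(d$coefficient)),
    file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

#' Hermitian measurement operators for the pseudovariance
#'
#' The pseudovariance of \eqn{H_N = H_H + i V_{CAP}} requires only standard
#' expectation values of three Hermitian operators: `A` \eqn{= H_H},
#' `W` \eqn{= V_{CAP}}, and `G` \eqn{= H_N^\dagger H_N =
#' H_H^2 + V_{CAP}^2 + i[H_H, V_{CAP}]}. The commutator term times `i` is
#' Hermitian because `H_H` and `V_CAP` are.
#'
#' @param ops An [project_operators()] result.
#' @param prune Coefficient pruning threshold, see [pauli_decompose()].
#' @return Object of class `measurement_set` with Pauli decompositions `A`,
#'   `W`, `G` and the dense matrices retained for exact evaluation.
#' @export
measurement_set <- function(ops, prune = 1e-12) {
  stopifnot(inherits(ops, "operator_set"))
  HH <- ops$HH; VC <- ops$VCAP
  G <- HH %*% HH + VC %*% VC + 1i * (HH %*% VC - VC %*% HH)
  if (max(abs(G - Conj(t(G)))) > 1e-10) stop("G not Hermitian")
  structure(list(A = pauli_decompose(HH, prune),
                 W = pauli_decompose(VC, prune),
                 G = pauli_decompose(G, prune),
                 A_mat = HH, W_mat = VC, G_mat = G,
                 ops = ops),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("Measurement set (q = %d): |A| = %d, |W| = %d, |G| = %d words\n",
              attr(x$A, "q"), nrow(x$A), nrow(x$W), nrow(x$G)))
  invisible(x)
}
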
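# Independent oracles, deliberately coded differently from the package paths.

# Brute-force SOS right moment: explicit loops over alpha, beta, n with the
# fluctuation-dipole subtraction written out longhand.
oracle_sos_right <- function(energies, dipoles, f) {
  n_states <- length(energies)
  omega <- energies[f + 1] / 2
  mu00 <- dipoles[1, 1, ]
  S <- matrix(0, 3, 3)
  for (a in 1:3) {
    for (b in 1:3) {
      acc <- 0
      for (k in seq_len(n_states)) {
        mfk_a <- dipoles[f + 1, k, a] - if (k == f + 1) mu00[a] else 0
        mfk_b <- dipoles[f + 1, k, b] - if (k == f + 1) mu00[b] else 0
        mk0_a <- dipoles[k, 1, a] - if (k == 1) mu00[a] else 0
        mk0_b <- dipoles[k, 1, b] - if (k == 1) mu00[b] else 0
        acc <- acc + (mfk_a * mk0_b + mfk_b * mk0_a) / (energies[k] - omega)
      }
      S[a, b] <- acc
    }
  }
  S
}

# random symmetric 3x3 tensor
random_symmetric_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3)
  (A + t(A)) / 2
}

# random manifold with arbitrary symmetric dipole matrix, guaranteed to be
# clear of the resonance guard for state f = 1
random_test_manifold <- function(n_states = 4) {
  w1 <- stats::runif(1, 0.08, 0.12)
  energies <- c(0, w1)
  if (n_states > 2) {
    energies <- c(energies, w1 * (1 + cumsum(stats::runif(n_states - 2, 0.5, 1))))
  }
  dip <- array(0, c(n_states, n_states, 3))
  for (i in seq_len(n_states)) {
    for (j in i:n_states) {
      v <- stats::rnorm(3)
      dip[i, j, ] <- v
      dip[j, i, ] <- v
    }
  }
  manifold(energies, dip)
}

table1_path <- function() {
  system.file("extdata", "table1_rpsb5.csv", package = "rpsb2pa")
}
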
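#' Electronic-state manifold
#'
#' A few-state model of a chromophore: excitation energies (atomic units,
#' ground state at 0) and the full dipole matrix, where entry `(n, m)` is the
#' Cartesian vector `<n|mu|m>` in au — permanent dipoles on the diagonal,
#' transition dipoles off it. Real wavefunctions are assumed, so the dipole
#' matrix must be entrywise symmetric.
#'
#' @param energies_au Numeric vector of excitation energies, strictly
#'   increasing from 0 (first element must be 0).
#' @param dipoles_au Numeric array `[n_states, n_states, 3]` of dipole
#'   vectors, symmetric in its first two indices.
#' @param labels Optional state labels.
#' @return A `tpa_manifold` object.
#' @examples
#' m <- two_state_manifold(omega_f = 0.1, mu01 = c(4, 0, 0),
#'                         mu00 = c(3, 0, 0), mu11 = c(1, 0, 0))
#' sos_delta(m, f = 1)
#' @export
manifold <- function(energies_au, dipoles_au, labels = NULL) {
  n <- length(energies_au)
  stopifnot(n >= 2, is.numeric(energies_au))
  if (energies_au[1] != 0) {
    stop("first excitation energy must be 0 (the ground state)", call. = FALSE)
  }
  if (any(diff(energies_au) <= 0)) {
    stop("excitation energies must be strictly increasing", call. = FALSE)
  }
  dipoles_au <- as.array(dipoles_au)
  if (!all(dim(dipoles_au) == c(n, n, 3))) {
    stop("dipoles_au must be an [n, n, 3] array matching energies_au",
      call. = FALSE
    )
  }
  for (a in 1:3) {
    if (max(abs(dipoles_au[, , a] - t(dipoles_au[, , a]))) > 1e-10) {
      stop("dipole matrix must be symmetric (real wavefunctions)",
        call. = FALSE
      )
    }
  }
  structure(
    list(energies = as.numeric(energies_au), dipoles = dipoles_au,
         labels = labels),
    class = "tpa_manifold"
  )
}

#' @rdname manifold
#' @param omega_f Excitation energy of the final state, au.
#' @param mu01,mu00,mu11 Transition, ground- and excited-state dipole
#'   vectors, au.
#' @export
two_state_manifold <- function(omega_f, mu01, mu00 = c(0, 0, 0),
                               mu11 = c(0, 0, 0)) {
  d <- array(0, c(2, 2, 3))
  d[1, 1, ] <- unclass(mu00)
  d[2, 2, ] <- unclass(mu11)
  d[1, 2, ] <- d[2, 1, ] <- unclass(mu01)
  manifold(c(0, omega_f), d)
}

#' @export
print.tpa_manifold <- function(x, ...) {
  cat("<tpa_manifold> ", length(x$energies), " states; excitation energies (au): ",
    paste(signif(x$energies, 4), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Manifold JSON I/O
#'
#' Schema: `{"energies_au": [0, ...ascending...], "dipoles_au": [n][n][3],
#' "labels": optional}`.
#'
#' @param m A [manifold()].
#' @param path File path.
#' @return `read_manifold()`: a `tpa_manifold`; `write_manifold()`: `m`,
#'   invisibly.
#' @export
write_manifold <- function(m, path) {
  stopifnot(inherits(m, "tpa_manifold"))
  obj <- list(
    energies_au = m$energies,
    dipoles_au = purrr::map(seq_along(m$energies), function(i) {
      purrr::map(seq_along(m$energies), function(j) m$dipoles[i, j, ])
    })
  )
  if (!is.null(m$labels)) obj$labels <- m$labels
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(m)
}

#' @rdname write_manifold
#' @export
read_manifold <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  n <- length(obj$energies_au)
  d <- array(aperm(obj$dipoles_au, c(1, 2, 3)), c(n, n, 3))
  manifold(obj$energies_au, d, labels = obj$labels)
}

#' Resonance diagnostics for the sum-over-states expansion
#'
#' The SOS denominators `omega_n - omega_f/2` diverge when an intermediate
#' state sits near half the final-state energy (one-photon resonance with the
#' intermediate). This lists every intermediate within `guard` of that
#' condition; an empty result means the expansion is well-conditioned.
#'
#' @param m A [manifold()].
#' @param f Final-state index (1-based among excited states: `f = 1` is S1).
#' @param guard Detuning threshold in au (> 0). Default 0.0095 au
#'   (~0.26 eV).
#' @return A tibble with columns `state` and `detuning_au` (signed
#'   `omega_n - omega_f/2`), one row per flagged intermediate.
#' @examples
#' m <- two_state_manifold(0.1, mu01 = c(1, 0, 0))
#' resonance_check(m, 1, guard = 0.01)  # empty: detunings are 0.05 au
#' @export
resonance_check <- function(m, f, guard = 0.0095) {
  stopifnot(inherits(m, "tpa_manifold"), guard > 0)
  n_exc <- length(m$energies) - 1
  if (f < 1 || f > n_exc) {
    stop("final state index out of range [1, ", n_exc, "]", call. = FALSE)
  }
  omega <- m$energies[f + 1] / 2
  det <- m$energies - omega
  hit <- which(abs(det) < guard)
  tibble::tibble(state = hit - 1L, detuning_au = det[hit])
}

#' Few-state sum-over-states two-photon transition moment
#'
#' Builds the left (`0 <- f`) and right (`f <- 0`) second-order transition
#' moments for the degenerate two-photon `0 -> f` transition at photon
#' energy `omega_f/2`, by direct summation over all states of the manifold:
#'
#' `S_ab = sum_n [ mu_a(0,n) mu_b(n,f) + mu_b(0,n) mu_a(n,f) ] / (omega_n - omega_f/2)`
#'
#' Dipole operators enter in fluctuation form — the ground-state permanent
#' dipole is subtracted from every diagonal element — which makes the `n = 0`
#' term vanish, renders the result independent of the coordinate origin, and
#' yields the familiar two-state limit. Because the dipole matrix is
#' symmetric (real wavefunctions), the left and right moments satisfy
#' `left = t(right)`.
#'
#' `sos_delta()` is the composition with [average_hermitian()]; it returns
#' the rotationally averaged strength plus resonance diagnostics.
#'
#' @inheritParams resonance_check
#' @return `sos_moment()`: a [tpa_tensor()]. `sos_delta()`: a list with
#'   `delta2pa` (au), `tensor`, and `resonance_flags`.
#' @examples
#' m <- two_state_manifold(0.1, mu01 = c(4, 0, 0), mu11 = c(2, 0, 0))
#' sos_delta(m, 1)$delta2pa
#' @export
sos_moment <- function(m, f, guard = 0.0095) {
  flags <- resonance_check(m, f, guard)
  if (nrow(flags) > 0) {
    msg <- paste(
      sprintf("state %d (detuning %.4g au)", flags$state, flags$detuning_au),
      collapse = ", "
    )
    cond <- simpleError(paste0(
      "intermediate state(s) within the resonance guard of omega_f/2: ", msg
    ))
    cond$resonance_flags <- flags
    stop(cond)
  }
  n <- length(m$energies)
  omega <- m$energies[f + 1] / 2
  # fluctuation dipoles: subtract mu00 from every diagonal element
  dip <- m$dipoles
  mu00 <- dip[1, 1, ]
  for (i in seq_len(n)) dip[i, i, ] <- dip[i, i, ] - mu00
  fi <- f + 1
  right <- matrix(0, 3, 3)
  for (k in seq_len(n)) {
    denom <- m$energies[k] - omega
    mf_k <- dip[fi, k, ] # <f|mu|k>
    k_0 <- dip[k, 1, ] # <k|mu|0>
    right <- right + (outer(mf_k, k_0) + outer(k_0, mf_k)) / denom
  }
  tpa_tensor(left = t(right), right = right)
}

#' @rdname sos_moment
#' @export
sos_delta <- function(m, f, guard = 0.0095) {
  S <- sos_moment(m, f, guard)
  list(
    delta2pa = average_hermitian(S),
    tensor = S,
    resonance_flags = resonance_check(m, f, guard)
  )
}

#' Two-state closed form of the two-photon transition strength
#'
#' Truncating the sum-over-states to the ground and final states gives the
#' generalised two-state model: for parallel linearly polarised degenerate
#' photons,
#'
#' `delta = 16 |mu01|^2 |dmu|^2 (1 + 2 cos^2 theta) / (15 omega_f^2)`
#'
#' where `theta` is the angle between the transition dipole and the
#' permanent-dipole change. This is derived by specialising the rotational
#' average of [average_hermitian()] to the rank-one-pair tensor
#' `S_ab = 2 (dmu_a mu01_b + dmu_b mu01_a) / omega_f` and is exactly equal
#' to `sos_delta()` on any two-state manifold. For collinear dipoles
#' (`theta = 0`, the quasi-linear charge-transfer limit) the bracket is 3 and
#' `delta = 16 |mu01|^2 |dmu|^2 / (5 omega_f^2)`.
#'
#' @param mu01 Transition dipole vector, au.
#' @param dmu Permanent-dipole-change vector, au.
#' @param omega_f Final-state excitation energy, au, > 0.
#' @return The averaged strength in au.
#' @examples
#' two_state_delta(c(4, 0, 0), c(2, 0, 0), 0.1)
#' @export
two_state_delta <- function(mu01, dmu, omega_f) {
  if (!is.numeric(omega_f) || omega_f <= 0) {
    stop("omega_f must be > 0", call. = FALSE)
  }
  a <- unclass(dmu); b <- unclass(mu01)
  stopifnot(length(a) == 3, length(b) == 3)
  16 * (sum(a^2) * sum(b^2) + 2 * sum(a * b)^2) / (15 * omega_f^2)
}
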
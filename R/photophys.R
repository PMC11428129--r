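#' Tagged dipole vector
#'
#' A length-3 Cartesian electric dipole vector carrying its unit (`"au"` or
#' `"D"`). Most workflows never build these by hand; they come out of
#' [generate_manifold()] or go into [delta_mu()] / [two_state_delta()].
#'
#' @param x,y,z Cartesian components.
#' @param unit `"au"` (atomic units) or `"D"` (Debye).
#' @param v A dipole vector (or bare numeric of length 3).
#' @return `dipole()`: a `tpa_dipole` numeric vector; `dipole_norm()`: its
#'   Euclidean magnitude.
#' @examples
#' dipole_norm(dipole(3, 4, 0))  # 5
#' @export
dipole <- function(x, y = NULL, z = NULL, unit = c("au", "D")) {
  unit <- match.arg(unit)
  v <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  stopifnot(length(v) == 3, is.numeric(v))
  structure(as.numeric(v), unit = unit, class = "tpa_dipole")
}

#' @rdname dipole
#' @export
dipole_norm <- function(v) sqrt(sum(unclass(v)^2))

dipole_unit <- function(v) attr(v, "unit") %||% "au"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Magnitude of the permanent-dipole change
#'
#' The change in permanent dipole moment upon excitation is the *vector*
#' difference of the excited- and ground-state permanent dipoles: per-axis
#' differences squared, summed, square-rooted. It therefore need not equal
#' the difference of the two magnitudes (and for charge-transfer states it
#' usually does not).
#'
#' @param mu00,mu11 Ground- and excited-state permanent dipole vectors
#'   ([dipole()] or bare length-3 numerics, same unit).
#' @return Magnitude of `mu11 - mu00` in the shared unit.
#' @examples
#' delta_mu(dipole(3, 4, 0), dipole(0, 0, 0))  # 5
#' @export
delta_mu <- function(mu00, mu11) {
  u0 <- if (inherits(mu00, "tpa_dipole")) dipole_unit(mu00) else NULL
  u1 <- if (inherits(mu11, "tpa_dipole")) dipole_unit(mu11) else NULL
  if (!is.null(u0) && !is.null(u1) && !identical(u0, u1)) {
    stop("unit mismatch: mu00 in ", u0, ", mu11 in ", u1, call. = FALSE)
  }
  stopifnot(length(mu00) == 3, length(mu11) == 3)
  sqrt(sum((unclass(mu11) - unclass(mu00))^2))
}

#' Two-photon transition moment tensor
#'
#' Holds the left (`0 <- f`) and right (`f <- 0`) second-order transition
#' moments as 3x3 real matrices, in atomic units. Hermitian response theories
#' (TD-DFT) have `left = t(right)`; coupled-cluster response does not.
#'
#' @param left,right 3x3 numeric matrices. If `right` is omitted it defaults
#'   to `t(left)` (the Hermitian case).
#' @return A `tpa_tensor` object.
#' @examples
#' S <- tpa_tensor(diag(3))
#' average_hermitian(S)
#' @export
tpa_tensor <- function(left, right = t(left)) {
  left <- as.matrix(left); right <- as.matrix(right)
  stopifnot(
    is.numeric(left), is.numeric(right),
    all(dim(left) == c(3, 3)), all(dim(right) == c(3, 3))
  )
  structure(list(left = left, right = right), class = "tpa_tensor")
}

# relative Frobenius asymmetry between left and t(right)
tensor_asymmetry <- function(S) {
  num <- norm(S$left - t(S$right), "F")
  den <- max(norm(S$left, "F"), norm(S$right, "F"))
  if (den == 0) 0 else num / den
}

# 1/15-weighted contraction for parallel linearly polarised degenerate
# photons: <(e.SL.e)(e.SR.e)> over orientations
contract_parallel <- function(left, right) {
  (sum(diag(left)) * sum(diag(right)) +
    sum(left * right) +
    sum(left * t(right))) / 15
}

#' Rotationally averaged two-photon transition strength
#'
#' Orientation average of the two-photon transition probability for two
#' identical photons with parallel linear polarisation, from the second-order
#' transition moment tensor. `average_hermitian()` takes a symmetric tensor
#' (Hermitian response, e.g. TD-DFT); `average_nonhermitian()` takes distinct
#' left/right moments (e.g. CC2 response) and reduces exactly to the
#' Hermitian form when `left = t(right)`. `average_numerical()` is a
#' Monte-Carlo estimate over uniformly random rigid rotations, kept as an
#' independent check of the closed forms.
#'
#' The closed form is the isotropic fourth-rank average
#' `delta = (Tr(SL) Tr(SR) + sum(SL * SR) + sum(SL * t(SR))) / 15`.
#'
#' @param S A [tpa_tensor()].
#' @param tol Relative Frobenius asymmetry tolerated by the Hermitian route.
#' @param n_orientations Number of Monte-Carlo orientations (>= 1000).
#' @param seed Integer seed for the Monte-Carlo orientations.
#' @return The averaged strength `delta` in atomic units. For
#'   `average_numerical()`, the estimate carries the attribute `"se"` (its
#'   Monte-Carlo standard error). Non-Hermitian averages can be negative for
#'   pathological left/right pairs; they are returned as-is with a warning.
#' @examples
#' S <- tpa_tensor(diag(3))
#' average_hermitian(S)                 # (9 + 3 + 3)/15 = 1 for the identity
#' average_nonhermitian(S)              # identical
#' @export
average_hermitian <- function(S, tol = 1e-8) {
  stopifnot(inherits(S, "tpa_tensor"))
  if (tensor_asymmetry(S) > tol) {
    stop(
      "tensor is not Hermitian (left != t(right) beyond tolerance ", tol,
      "); use average_nonhermitian()",
      call. = FALSE
    )
  }
  contract_parallel(S$left, S$right)
}

#' @rdname average_hermitian
#' @export
average_nonhermitian <- function(S) {
  stopifnot(inherits(S, "tpa_tensor"))
  out <- contract_parallel(S$left, S$right)
  if (out < 0) {
    warning(
      "negative rotationally averaged strength (", format(out),
      " au): pathological left/right pair, returned unclipped",
      call. = FALSE
    )
  }
  out
}

#' @rdname average_hermitian
#' @export
average_numerical <- function(S, n_orientations = 20000, seed = 1) {
  stopifnot(inherits(S, "tpa_tensor"), n_orientations >= 1000)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  e <- c(0, 0, 1)
  samples <- vapply(seq_len(n_orientations), function(i) {
    R <- random_rotation_matrix()
    sl <- R %*% S$left %*% t(R)
    sr <- R %*% S$right %*% t(R)
    drop(crossprod(e, sl %*% e)) * drop(crossprod(e, sr %*% e))
  }, numeric(1))
  est <- mean(samples)
  attr(est, "se") <- stats::sd(samples) / sqrt(n_orientations)
  est
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# uniform rotation from SO(3) via quaternion of 4 standard normals
random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Lorentzian lineshape parameters
#'
#' Bundles the phenomenological lifetime broadening `Gamma` (eV, half-width
#' at half-maximum of the area-normalised Lorentzian) and the integer
#' degeneracy/convention factor `N` used by [cross_section()]. The defaults
#' (`Gamma = 0.1` eV, `N = 4`) are the values used for the packaged RPSB5
#' table.
#'
#' @param gamma_eV Broadening, > 0.
#' @param n_factor Integer multiplier, >= 1.
#' @return A named list with class `tpa_lineshape`.
#' @examples
#' lineshape_params()
#' @export
lineshape_params <- function(gamma_eV = 0.1, n_factor = 4L) {
  if (!is.numeric(gamma_eV) || gamma_eV <= 0) {
    stop("gamma_eV must be > 0", call. = FALSE)
  }
  if (n_factor < 1) stop("n_factor must be >= 1", call. = FALSE)
  structure(
    list(gamma_eV = gamma_eV, n_factor = as.integer(n_factor),
         shape = "lorentzian"),
    class = "tpa_lineshape"
  )
}

#' Microscopic-to-macroscopic 2PA conversion
#'
#' Converts a rotationally averaged two-photon transition strength `delta`
#' (atomic units) and an excitation energy `dE` (eV) into the peak 2PA cross
#' section in GM (1 GM = 1e-50 cm^4 s/photon), for two degenerate photons of
#' energy `dE/2` and a Lorentzian band of half-width `Gamma`:
#'
#' `sigma = N pi^3 alpha^2 omega^2 g_peak delta * (a0^4 t_au / 1e-50)`
#'
#' with `omega = dE/2` and `g_peak = 1/(pi Gamma)` (all in atomic units).
#' The reported number is the peak of the Lorentzian, not a band integral,
#' so `sigma` scales linearly in `delta`, quadratically in the photon
#' energy, and inversely in `Gamma`.
#'
#' @param delta2pa Two-photon transition strength(s), au. Negative values
#'   (possible from non-Hermitian response) produce a warning and a signed
#'   result.
#' @param dE_eV Excitation energy(ies), eV, > 0.
#' @param params A [lineshape_params()] bundle.
#' @return Cross section(s) in GM.
#' @examples
#' cross_section(21307, 2.720)  # ~58 GM
#' @export
cross_section <- function(delta2pa, dE_eV, params = lineshape_params()) {
  stopifnot(is.numeric(delta2pa), is.numeric(dE_eV))
  if (any(dE_eV <= 0)) stop("dE_eV must be > 0", call. = FALSE)
  if (params$gamma_eV <= 0) stop("gamma_eV must be > 0", call. = FALSE)
  if (any(delta2pa < 0)) {
    warning("negative delta2pa: returning signed cross section",
      call. = FALSE
    )
  }
  k <- tpa_constants()
  omega <- convert_units(dE_eV, "eV", "hartree") / 2
  gamma <- convert_units(params$gamma_eV, "eV", "hartree")
  g_peak <- 1 / (pi * gamma)
  sigma_au <- params$n_factor * pi^3 * k$alpha^2 * omega^2 * g_peak * delta2pa
  sigma_au * au_cross_section_gm()
}
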
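#' Parameters for the synthetic-manifold generator
#'
#' Defaults emulate quasi-linear charge-transfer chromophores of the RPSB5
#' type: S1 excitation energies of 2.5-3.1 eV, strong transition dipoles of
#' 10-12.5 D, ground-state permanent dipoles of 5.5-8.5 D shrinking to
#' 1-6 D on excitation, and a permanent-dipole change nearly collinear with
#' the transition dipole (within 15 degrees). Method biases mimic the
#' TD-DFT-vs-coupled-cluster pattern: excitation energies shifted up,
#' dipole changes shrunk.
#'
#' @param n_states Number of states (ground + excited), >= 2.
#' @param dE_range S1 excitation energy range, eV.
#' @param mu01_range Transition dipole magnitude range, D.
#' @param mu00_range Ground-state permanent dipole magnitude range, D.
#' @param mu11_range Excited-state permanent dipole magnitude range, D.
#' @param collinearity_deg Maximum angle between the transition dipole and
#'   the permanent-dipole change, degrees.
#' @param n_structures Number of synthetic structures per record set.
#' @param method_bias Named list: for each method, a list with `dE_shift`
#'   (eV), `dipole_scale` (multiplies the permanent-dipole change) and
#'   `noise_sd` (relative, applied to dipole magnitudes). Must contain a
#'   zero-bias reference.
#' @param seed Integer seed; fixed seed gives fully reproducible output.
#' @return A `tpa_genparams` list.
#' @examples
#' generator_params(seed = 7)$dE_range
#' @export
generator_params <- function(n_states = 4,
                             dE_range = c(2.5, 3.1),
                             mu01_range = c(10, 12.5),
                             mu00_range = c(5.5, 8.5),
                             mu11_range = c(1, 6),
                             collinearity_deg = 15,
                             n_structures = 7,
                             method_bias = default_method_bias(),
                             seed = 1L) {
  stopifnot(
    n_states >= 2,
    length(dE_range) == 2, all(dE_range > 0), diff(dE_range) >= 0,
    all(mu01_range > 0), all(mu00_range > 0), all(mu11_range > 0),
    collinearity_deg >= 0, n_structures >= 1
  )
  structure(
    list(
      n_states = as.integer(n_states), dE_range = dE_range,
      mu01_range = mu01_range, mu00_range = mu00_range,
      mu11_range = mu11_range, collinearity_deg = collinearity_deg,
      n_structures = as.integer(n_structures),
      method_bias = method_bias, seed = as.integer(seed)
    ),
    class = "tpa_genparams"
  )
}

#' @rdname generator_params
#' @export
default_method_bias <- function() {
  list(
    "reference" = list(dE_shift = 0, dipole_scale = 1, noise_sd = 0),
    "biased-mild" = list(dE_shift = 0.15, dipole_scale = 0.8, noise_sd = 0),
    "biased-strong" = list(dE_shift = 0.25, dipole_scale = 0.55, noise_sd = 0)
  )
}

# unit vector uniform on the sphere
random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# unit vector at most `max_deg` away from axis u, uniform on the cap
random_cone_vector <- function(u, max_deg) {
  cmin <- cos(max_deg * pi / 180)
  cosang <- stats::runif(1, cmin, 1)
  sinang <- sqrt(1 - cosang^2)
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal frame around u
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2],
    u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  cosang * u + sinang * (cos(phi) * e1 + sin(phi) * e2)
}

#' Generate a synthetic electronic manifold
#'
#' Draws a charge-transfer-like few-state manifold: the S1 energy from
#' `dE_range`, permanent and transition dipoles from their magnitude ranges
#' with the S1 permanent-dipole change constrained to lie within
#' `collinearity_deg` of the transition dipole, and geometrically decaying
#' couplings (factor 0.3 per state) to the higher states so the
#' sum-over-states stays dominated by the two-state term. Higher-state
#' energies are placed above S1 and outside the default resonance guard of
#' the S1 two-photon transition.
#'
#' @param p A [generator_params()] bundle.
#' @return A [manifold()] (all quantities in atomic units).
#' @examples
#' m <- generate_manifold(generator_params(seed = 3))
#' sos_delta(m, 1)$delta2pa > 0
#' @export
generate_manifold <- function(p = generator_params()) {
  stopifnot(inherits(p, "tpa_genparams"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(p$seed)
  generate_manifold_impl(p)
}

# internal: assumes RNG state already set
generate_manifold_impl <- function(p) {
  n <- p$n_states
  w1 <- convert_units(stats::runif(1, p$dE_range[1], p$dE_range[2]),
    "eV", "hartree"
  )
  # higher states well above w1 (and hence outside the guard around w1/2)
  energies <- c(0, w1)
  if (n > 2) {
    gaps <- stats::runif(n - 2, 0.3, 0.6) * w1
    energies <- c(energies, w1 + cumsum(gaps))
  }

  mu01_mag <- convert_units(
    stats::runif(1, p$mu01_range[1], p$mu01_range[2]), "D", "au"
  )
  mu00_mag <- convert_units(
    stats::runif(1, p$mu00_range[1], p$mu00_range[2]), "D", "au"
  )
  mu11_mag <- convert_units(
    stats::runif(1, p$mu11_range[1], p$mu11_range[2]), "D", "au"
  )

  u01 <- random_unit_vector()
  mu01 <- mu01_mag * u01
  # dmu = mu11 - mu00 near-collinear with mu01
  dmu_dir <- random_cone_vector(u01, p$collinearity_deg)
  # choose mu00 along a loosely related direction, then set mu11 = mu00 + dmu
  dmu_mag <- sqrt(max(
    mu00_mag^2 + mu11_mag^2 -
      2 * mu00_mag * mu11_mag * stats::runif(1, 0.2, 0.95),
    1e-6
  ))
  dmu <- dmu_mag * dmu_dir
  # place mu00 so that |mu00| matches and mu11 = mu00 + dmu is consistent
  mu00 <- mu00_mag * random_cone_vector(-dmu_dir, 60)
  mu11 <- mu00 + dmu

  dip <- array(0, c(n, n, 3))
  dip[1, 1, ] <- mu00
  dip[2, 2, ] <- mu11
  dip[1, 2, ] <- dip[2, 1, ] <- mu01
  if (n > 2) {
    for (k in 3:n) {
      decay <- 0.3^(k - 2)
      v1 <- decay * mu01_mag * random_unit_vector()
      v2 <- decay * mu01_mag * random_unit_vector()
      dip[1, k, ] <- dip[k, 1, ] <- v1
      dip[2, k, ] <- dip[k, 2, ] <- v2
      dip[k, k, ] <- decay * mu00_mag * random_unit_vector()
      if (k < n) {
        for (j in (k + 1):n) {
          vkj <- 0.3^(j - 2) * decay * mu01_mag * random_unit_vector()
          dip[k, j, ] <- dip[j, k, ] <- vkj
        }
      }
    }
  }
  manifold(energies, dip)
}

#' Generate a synthetic multi-method record set with known ground truth
#'
#' Emulates the structure of a method-benchmark table: for each synthetic
#' structure a reference manifold is drawn, each method's bias (excitation
#' energy shift, shrink of the permanent-dipole change, optional relative
#' noise) is applied, and the two-photon strength and cross section are
#' computed through the few-state and conversion pipeline. The injected
#' biases are stored in the `"bias_truth"` attribute so recovery tests can
#' compare them with what [build_report()] measures.
#'
#' @param p A [generator_params()] bundle.
#' @param lineshape A [lineshape_params()] bundle for the cross sections.
#' @return A `tpa_records` tibble with attribute `bias_truth`.
#' @examples
#' rs <- generate_recordset(generator_params(seed = 5))
#' nrow(validate_records(rs)) == 0
#' @export
generate_recordset <- function(p = generator_params(),
                               lineshape = lineshape_params()) {
  stopifnot(inherits(p, "tpa_genparams"))
  if (!any(vapply(
    p$method_bias,
    function(b) b$dE_shift == 0 && b$dipole_scale == 1 && b$noise_sd == 0,
    logical(1)
  ))) {
    stop("method_bias must include a zero-bias reference method",
      call. = FALSE
    )
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(p$seed)

  rows <- list()
  for (s in seq_len(p$n_structures)) {
    base <- generate_manifold_impl(p)
    sname <- sprintf("synthetic-%02d", s)
    for (mname in names(p$method_bias)) {
      b <- p$method_bias[[mname]]
      m <- apply_method_bias(base, b)
      res <- sos_delta(m, 1)
      dE_eV <- convert_units(m$energies[2], "hartree", "eV")
      mu00 <- m$dipoles[1, 1, ]
      mu11 <- m$dipoles[2, 2, ]
      mu01 <- m$dipoles[1, 2, ]
      rows[[length(rows) + 1]] <- tibble::tibble(
        method = mname, structure = sname,
        dE_eV = dE_eV,
        delta2pa_au = res$delta2pa,
        sigma2pa_GM = cross_section(res$delta2pa, dE_eV, lineshape),
        mu01_D = convert_units(sqrt(sum(mu01^2)), "au", "D"),
        dmu_D = convert_units(delta_mu(mu00, mu11), "au", "D"),
        mu00_D = convert_units(sqrt(sum(mu00^2)), "au", "D"),
        mu11_D = convert_units(sqrt(sum(mu11^2)), "au", "D")
      )
    }
  }
  out <- new_recordset(
    dplyr::bind_rows(rows),
    provenance = sprintf("synthetic record set (seed %d)", p$seed)
  )
  attr(out, "bias_truth") <- p$method_bias
  out
}

# shift S1 (and higher states) up in energy; scale dmu about mu00; add
# relative noise to dipole magnitudes
apply_method_bias <- function(m, b) {
  energies <- m$energies
  shift <- convert_units(b$dE_shift, "eV", "hartree")
  energies[-1] <- energies[-1] + shift
  dip <- m$dipoles
  mu00 <- dip[1, 1, ]
  dmu <- dip[2, 2, ] - mu00
  dip[2, 2, ] <- mu00 + b$dipole_scale * dmu
  if (b$noise_sd > 0) {
    n <- dim(dip)[1]
    for (i in seq_len(n)) {
      for (j in i:n) {
        f <- 1 + stats::rnorm(1, 0, b$noise_sd)
        dip[i, j, ] <- dip[i, j, ] * f
        dip[j, i, ] <- dip[i, j, ]
      }
    }
  }
  manifold(energies, dip, labels = m$labels)
}

#' Rigidly rotate a manifold
#'
#' Rotates every dipole vector by a proper rotation matrix; energies are
#' untouched. Rotationally averaged strengths are invariant under this.
#'
#' @param m A [manifold()].
#' @param rotation 3x3 proper orthogonal matrix (checked).
#' @return The rotated manifold.
#' @examples
#' m <- generate_manifold(generator_params(seed = 2))
#' r <- rotate_manifold(m, diag(3))
#' @export
rotate_manifold <- function(m, rotation) {
  stopifnot(inherits(m, "tpa_manifold"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
    max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
    abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be a proper orthogonal 3x3 matrix", call. = FALSE)
  }
  n <- length(m$energies)
  dip <- m$dipoles
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dip[i, j, ] <- drop(rotation %*% dip[i, j, ])
    }
  }
  manifold(m$energies, dip, labels = m$labels)
}

#' Draw a uniformly random rotation matrix
#'
#' Uniform on the rotation group (via normalised quaternions), reproducible
#' for a fixed seed.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A 3x3 proper orthogonal matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  random_rotation_matrix()
}
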
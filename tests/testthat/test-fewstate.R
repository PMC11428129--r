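test_that("sos_moment matches an independently coded direct summation", {
  set.seed(11)
  for (i in 1:8) {
    m <- random_test_manifold(n_states = 4)
    S <- sos_moment(m, 1)
    expect_equal(S$right, oracle_sos_right(m$energies, m$dipoles, 1),
      tolerance = 1e-12
    )
    expect_equal(S$left, t(S$right), tolerance = 1e-12)
  }
})

test_that("sos on a two-state manifold equals the two-state closed form", {
  set.seed(12)
  for (i in 1:20) {
    omega_f <- stats::runif(1, 0.05, 0.15)
    mu01 <- stats::rnorm(3)
    mu00 <- stats::rnorm(3)
    mu11 <- stats::rnorm(3)
    m <- two_state_manifold(omega_f, mu01, mu00, mu11)
    expect_equal(
      sos_delta(m, 1)$delta2pa,
      two_state_delta(mu01, mu11 - mu00, omega_f),
      tolerance = 1e-12
    )
  }
})

test_that("two-state closed form has the stated structure", {
  expect_equal(two_state_delta(c(3, 1, 0), c(0, 0, 0), 0.1), 0)
  # quadratic in |mu01|
  expect_equal(
    two_state_delta(c(6, 0, 0), c(2, 1, 0), 0.1),
    4 * two_state_delta(c(3, 0, 0), c(2, 1, 0), 0.1)
  )
  # 1/omega^2 scaling
  expect_equal(
    two_state_delta(c(3, 0, 0), c(2, 0, 0), 0.05),
    4 * two_state_delta(c(3, 0, 0), c(2, 0, 0), 0.1)
  )
  # angle factor: collinear/perpendicular = 3
  expect_equal(
    two_state_delta(c(1, 0, 0), c(2, 0, 0), 0.1) /
      two_state_delta(c(1, 0, 0), c(0, 2, 0), 0.1),
    3
  )
  expect_error(two_state_delta(c(1, 0, 0), c(1, 0, 0), -0.1), "omega_f")
})

test_that("sos result is origin-independent (fluctuation-dipole contract)", {
  set.seed(13)
  for (i in 1:5) {
    m <- random_test_manifold(4)
    shift <- stats::rnorm(3, sd = 5)
    dip <- m$dipoles
    for (k in seq_along(m$energies)) dip[k, k, ] <- dip[k, k, ] + shift
    m2 <- manifold(m$energies, dip)
    expect_equal(sos_moment(m2, 1)$right, sos_moment(m, 1)$right,
      tolerance = 1e-10
    )
  }
})

test_that("sos transforms covariantly under rotation; delta is invariant", {
  set.seed(14)
  for (i in 1:5) {
    m <- random_test_manifold(4)
    R <- random_rotation(seed = 400 + i)
    m2 <- rotate_manifold(m, R)
    S <- sos_moment(m, 1)
    S2 <- sos_moment(m2, 1)
    expect_equal(S2$right, R %*% S$right %*% t(R), tolerance = 1e-10)
    expect_equal(
      average_hermitian(S2), average_hermitian(S),
      tolerance = 1e-10
    )
  }
})

test_that("manifolds with no transition pathway give a zero tensor", {
  d <- array(0, c(3, 3, 3))
  d[1, 1, ] <- c(1, 0, 0); d[2, 2, ] <- c(2, 0, 0); d[3, 3, ] <- c(1, 1, 0)
  m <- manifold(c(0, 0.1, 0.25), d)
  expect_equal(sos_moment(m, 1)$right, matrix(0, 3, 3))
})

test_that("resonance_check flags intermediates near half the final energy", {
  m <- two_state_manifold(0.1, mu01 = c(1, 0, 0))
  expect_equal(nrow(resonance_check(m, 1, guard = 0.01)), 0)
  # both states flagged when the guard exceeds omega_f/2
  expect_equal(nrow(resonance_check(m, 1, guard = 0.06)), 2)

  d <- array(0, c(3, 3, 3))
  d[1, 2, ] <- d[2, 1, ] <- c(1, 0, 0)
  d[2, 3, ] <- d[3, 2, ] <- c(1, 0, 0)
  m3 <- manifold(c(0, 0.051, 0.100), d)
  flags <- resonance_check(m3, 2, guard = 0.01)
  expect_equal(flags$state, 1L)
  expect_equal(flags$detuning_au, 0.001, tolerance = 1e-12)

  # exact resonance: detuning 0
  m0 <- manifold(c(0, 0.05, 0.100), d)
  f0 <- resonance_check(m0, 2, guard = 0.01)
  expect_true(0 %in% round(f0$detuning_au, 12))
  expect_error(resonance_check(m, 3), "out of range")
})

test_that("sos errors inside the resonance guard, carrying the flags", {
  d <- array(0, c(3, 3, 3))
  d[1, 2, ] <- d[2, 1, ] <- c(1, 0, 0)
  d[2, 3, ] <- d[3, 2, ] <- c(1, 0, 0)
  m <- manifold(c(0, 0.0502, 0.100), d)
  err <- tryCatch(sos_moment(m, 2, guard = 0.01), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "resonance guard")
  expect_equal(err$resonance_flags$state, 1L)
})

test_that("|delta| grows monotonically as an intermediate approaches the
           resonance", {
  deltas_for <- function(w1) {
    d <- array(0, c(3, 3, 3))
    d[1, 2, ] <- d[2, 1, ] <- c(1, 0.2, 0)
    d[2, 3, ] <- d[3, 2, ] <- c(0.8, 0, 0.1)
    d[1, 3, ] <- d[3, 1, ] <- c(0.5, 0.1, 0)
    m <- manifold(c(0, w1, 0.100), d)
    abs(sos_delta(m, 2, guard = 1e-6)$delta2pa)
  }
  from_above <- vapply(c(0.080, 0.070, 0.060, 0.055), deltas_for, numeric(1))
  expect_true(all(diff(from_above) > 0))
  from_below <- vapply(c(0.020, 0.030, 0.040, 0.045), deltas_for, numeric(1))
  expect_true(all(diff(from_below) > 0))
})

test_that("manifold JSON round-trips", {
  set.seed(15)
  m <- random_test_manifold(3)
  f <- tempfile(fileext = ".json")
  write_manifold(m, f)
  back <- read_manifold(f)
  expect_equal(back$energies, m$energies)
  expect_equal(back$dipoles, m$dipoles)
})

test_that("manifold constructor enforces its invariants", {
  expect_error(manifold(c(0.1, 0.2), array(0, c(2, 2, 3))), "ground state")
  expect_error(manifold(c(0, 0.2, 0.1), array(0, c(3, 3, 3))), "increasing")
  d <- array(0, c(2, 2, 3))
  d[1, 2, 1] <- 1 # asymmetric
  expect_error(manifold(c(0, 0.1), d), "symmetric")
})
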
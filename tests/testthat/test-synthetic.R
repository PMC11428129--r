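test_that("generators are fully reproducible under a fixed seed", {
  p <- generator_params(seed = 21)
  m1 <- generate_manifold(p)
  m2 <- generate_manifold(p)
  expect_identical(m1$energies, m2$energies)
  expect_identical(m1$dipoles, m2$dipoles)
  rs1 <- generate_recordset(p)
  rs2 <- generate_recordset(p)
  expect_identical(as.data.frame(rs1), as.data.frame(rs2))
  expect_false(identical(
    generate_manifold(generator_params(seed = 22))$dipoles, m1$dipoles
  ))
})

test_that("generated manifolds have the advertised structure", {
  for (s in 1:20) {
    p <- generator_params(seed = s)
    m <- generate_manifold(p)
    expect_equal(m$energies[1], 0)
    expect_true(all(diff(m$energies) > 0))
    dE <- convert_units(m$energies[2], "hartree", "eV")
    expect_true(dE >= p$dE_range[1] && dE <= p$dE_range[2])
    # S1 two-photon transition clear of the default resonance guard
    expect_equal(nrow(resonance_check(m, 1)), 0)
    # near-collinearity of mu01 and dmu
    mu01 <- m$dipoles[1, 2, ]
    dmu <- m$dipoles[2, 2, ] - m$dipoles[1, 1, ]
    cosang <- sum(mu01 * dmu) / sqrt(sum(mu01^2) * sum(dmu^2))
    expect_gte(cosang, cos(p$collinearity_deg * pi / 180) - 1e-9)
  }
})

test_that("sampled transition dipoles track the configured range", {
  mags <- vapply(1:200, function(s) {
    m <- generate_manifold(generator_params(seed = 1000 + s, n_states = 2))
    convert_units(sqrt(sum(m$dipoles[1, 2, ]^2)), "au", "D")
  }, numeric(1))
  p <- generator_params()
  expect_true(all(mags >= p$mu01_range[1] & mags <= p$mu01_range[2]))
  expect_gt(mean(mags), p$mu01_range[1])
  expect_lt(mean(mags), p$mu01_range[2])
})

test_that("two-state synthetic manifolds obey the closed-form contract", {
  for (s in 1:10) {
    m <- generate_manifold(generator_params(seed = 30 + s, n_states = 2))
    mu01 <- m$dipoles[1, 2, ]
    dmu <- m$dipoles[2, 2, ] - m$dipoles[1, 1, ]
    expect_equal(
      sos_delta(m, 1)$delta2pa,
      two_state_delta(mu01, dmu, m$energies[2]),
      tolerance = 1e-12
    )
  }
})

test_that("generated record sets pass validation and include the reference", {
  rs <- generate_recordset(generator_params(seed = 41))
  expect_equal(nrow(rs), 7 * 3)
  expect_equal(nrow(validate_records(rs)), 0)
  expect_true("reference" %in% rs$method)
  expect_error(
    generate_recordset(generator_params(
      seed = 1,
      method_bias = list(m = list(dE_shift = 0.1, dipole_scale = 1,
        noise_sd = 0
      ))
    )),
    "zero-bias reference"
  )
})

test_that("injected method biases are recovered exactly at zero noise", {
  bias <- list(
    "reference" = list(dE_shift = 0, dipole_scale = 1, noise_sd = 0),
    "shifted" = list(dE_shift = 0.2, dipole_scale = 1, noise_sd = 0),
    "shrunk" = list(dE_shift = 0, dipole_scale = 0.6, noise_sd = 0)
  )
  rs <- generate_recordset(generator_params(seed = 51, method_bias = bias))
  # energy shift recovered through the benchmark MAE
  expect_equal(mae(rs, "shifted", "reference", "dE_eV"), 0.2,
    tolerance = 1e-10
  )
  expect_equal(mae(rs, "shifted", "reference", "dmu_D"), 0,
    tolerance = 1e-10
  )
  # dipole scaling recovered row-by-row from the dmu column
  p <- rs[rs$method == "shrunk", ]
  q <- rs[rs$method == "reference", ]
  q <- q[match(p$structure, q$structure), ]
  expect_equal(p$dmu_D / q$dmu_D, rep(0.6, 7), tolerance = 1e-10)
})

test_that("a pure dmu shrink scales two-state strengths by the inverse
           square", {
  bias <- list(
    "reference" = list(dE_shift = 0, dipole_scale = 1, noise_sd = 0),
    "shrunk" = list(dE_shift = 0, dipole_scale = 0.6, noise_sd = 0)
  )
  rs <- generate_recordset(generator_params(
    seed = 61, n_states = 2, method_bias = bias
  ))
  r <- ratio_range(rs, "shrunk", "reference", "delta2pa_au")
  expect_equal(unname(r), c(1, 1) / 0.6^2, tolerance = 1e-10)
  # with weakly coupled higher states the ratio stays near 1/0.6^2
  rs4 <- generate_recordset(generator_params(
    seed = 61, n_states = 4, method_bias = bias
  ))
  r4 <- ratio_range(rs4, "shrunk", "reference", "delta2pa_au")
  expect_true(all(abs(unname(r4) - 1 / 0.6^2) < 0.6))
})

test_that("rotate_manifold preserves energies and averaged strengths", {
  m <- generate_manifold(generator_params(seed = 71))
  expect_identical(rotate_manifold(m, diag(3))$dipoles, m$dipoles)
  R1 <- random_rotation(seed = 81)
  R2 <- random_rotation(seed = 82)
  # composition of rotations equals rotation by the product
  expect_equal(
    rotate_manifold(rotate_manifold(m, R1), R2)$dipoles,
    rotate_manifold(m, R2 %*% R1)$dipoles,
    tolerance = 1e-12
  )
  d0 <- sos_delta(m, 1)$delta2pa
  d1 <- sos_delta(rotate_manifold(m, R1), 1)$delta2pa
  expect_equal(d1, d0, tolerance = 1e-10)
  expect_error(rotate_manifold(m, matrix(1:9, 3)), "orthogonal")
  expect_error(rotate_manifold(m, -diag(3)), "orthogonal") # improper
})
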
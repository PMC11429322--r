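test_that("micro constants match the two-compartment algebra", {
  mc <- micro_constants(typical_params())
  expect_equal(mc$k10, 12.4 / 8.26, tolerance = 1e-12)
  expect_equal(mc$lambda1, 2.705, tolerance = 5e-4)
  expect_equal(mc$lambda2, 0.7135, tolerance = 5e-4)
  # Vieta identities for random parameter sets
  for (p in random_params(50)) {
    mc <- micro_constants(p)
    expect_equal(mc$lambda1 * mc$lambda2, (p$CL / p$V1) * (p$Q / p$V2),
                 tolerance = 1e-10)
    expect_equal(mc$lambda1 + mc$lambda2, mc$k10 + mc$k12 + mc$k21,
                 tolerance = 1e-10)
    expect_true(mc$lambda1 > mc$lambda2, info = "lambda1 > lambda2")
    expect_true(mc$lambda2 > 0)
  }
})

test_that("Q = 0 degenerates to the one-compartment limit", {
  p <- pk_params(CL = 12, V1 = 10, Q = 0, V2 = 5)
  mc <- micro_constants(p)
  expect_equal(mc$lambda1, 12 / 10)
  expect_equal(mc$lambda2, 0)
  hl <- half_lives(p)
  expect_equal(hl$t_half_alpha, log(2) * 10 / 12)
  expect_identical(hl$t_half_beta, Inf)
  # one-compartment infusion kinetics still evaluate correctly
  r <- regimen(500, 0.5, 8)
  tt <- c(0.25, 0.5, 1, 3)
  expect_equal(conc_profile(p, r, tt), ode_oracle(p, r, tt), tolerance = 1e-7)
})

test_that("half-lives are scale invariant and match the typical subject", {
  hl <- half_lives(typical_params())
  expect_equal(hl$t_half_alpha, 0.256, tolerance = 2e-3)
  expect_equal(hl$t_half_beta, 0.971, tolerance = 2e-3)
  # scaling CL, Q by c and V1, V2 by c leaves rates (hence half-lives) unchanged
  for (c_ in c(0.5, 2, 7)) {
    p2 <- pk_params(12.4 * c_, 8.26 * c_, 5.22 * c_, 4.06 * c_)
    hl2 <- half_lives(p2)
    expect_equal(hl2$t_half_alpha, hl$t_half_alpha, tolerance = 1e-12)
    expect_equal(hl2$t_half_beta, hl$t_half_beta, tolerance = 1e-12)
  }
})

test_that("invalid parameters and times are rejected", {
  expect_error(pk_params(-1, 8, 5, 4), "CL")
  expect_error(pk_params(12, 0, 5, 4), "V1")
  expect_error(regimen(500, 3, 2), "tinf")
  expect_error(regimen(-1, 0.5, 8), "dose")
  expect_error(conc_profile(typical_params(), regimen(500, 0.5, 8), c(-1, 2)),
               "non-negative")
})

test_that("closed form matches the numeric ODE oracle across random subjects", {
  tt <- seq(0, 24, by = 0.5)
  worst <- 0
  for (p in random_params(100, seed = 7)) {
    r <- regimen(1000, 0.5, 8)
    cf <- conc_profile(p, r, tt, n_doses = 3)
    od <- ode_oracle(p, r, tt, n_doses = 3)
    keep <- cf > 1e-9
    worst <- max(worst, max(abs(cf[keep] - od[keep]) / cf[keep]))
  }
  expect_lt(worst, 1e-6)
})

test_that("single-dose area under the oracle curve equals dose/CL", {
  p <- typical_params()
  r <- regimen(500, 0.5, 8)
  od <- ode_oracle(p, r, c(0, 40), auc = TRUE)
  expect_equal(attr(od, "auc")[2], 500 / 12.4, tolerance = 1e-6)
})

test_that("zero input gives identically zero concentrations", {
  p <- typical_params()
  tt <- c(0, 0.5, 2, 8)
  expect_equal(conc_profile(p, regimen(0, 0.5, 8), tt), rep(0, 4))
  expect_equal(ode_oracle(p, regimen(0, 0.5, 8), tt), rep(0, 4))
})

test_that("analytic steady state agrees with 50-dose superposition", {
  tt <- seq(0, 8, by = 0.25)
  checked <- 0
  for (p in random_params(120, seed = 11)) {
    if (half_lives(p)$t_half_beta > 1.5) next
    r <- regimen(1000, 0.5, 8)
    ss <- conc_profile(p, r, tt, steady_state = TRUE)
    sup <- conc_profile(p, r, tt + 49 * 8, n_doses = 50)
    expect_lt(max(abs(ss - sup) / pmax(ss, 1e-12)), 1e-8)
    checked <- checked + 1
  }
  expect_gte(checked, 20)
})

test_that("steady-state profile is periodic in the dosing interval", {
  p <- typical_params()
  r <- regimen(1000, 0.5, 8)
  tt <- seq(0, 8, by = 0.1)
  ss <- conc_profile(p, r, tt, steady_state = TRUE)
  wrapped <- conc_profile(p, r, tt + 16, steady_state = TRUE)
  expect_equal(ss, wrapped, tolerance = 1e-12)
})

test_that("time-averaged steady-state concentration equals dose/(CL tau)", {
  r <- regimen(1000, 0.5, 8)
  for (p in c(list(typical_params()), random_params(5, seed = 3))) {
    avg <- stats::integrate(function(t) conc_profile(p, r, t, steady_state = TRUE),
                            0, 8, rel.tol = 1e-9, subdivisions = 500L)$value / 8
    expect_equal(avg, 1000 / (p$CL * 8), tolerance = 1e-6)
  }
})

test_that("concentration is exactly linear in dose", {
  p <- typical_params()
  tt <- seq(0, 24, by = 0.25)
  base <- conc_profile(p, regimen(500, 0.5, 8), tt, n_doses = 3)
  quad <- conc_profile(p, regimen(2000, 0.5, 8), tt, n_doses = 3)
  expect_identical(quad, 4 * base)
  ss1 <- conc_profile(p, regimen(500, 0.5, 8), tt, steady_state = TRUE)
  ss4 <- conc_profile(p, regimen(2000, 0.5, 8), tt, steady_state = TRUE)
  expect_identical(ss4, 4 * ss1)
})

test_that("continuous infusion reaches the analytic plateau rate/CL", {
  p <- typical_params()
  r <- regimen(2000, mode = "continuous")
  expect_equal(conc_profile(p, r, 0, steady_state = TRUE),
               (2000 / 24) / 12.4)
  # after >= 10 terminal half-lives the transient sits on the plateau
  t10 <- 10 * half_lives(p)$t_half_beta
  expect_equal(conc_profile(p, r, t10), 2000 / 24 / 12.4, tolerance = 1e-3)
  expect_equal(conc_profile(p, r, c(1, 5, 12)), ode_oracle(p, r, c(1, 5, 12)),
               tolerance = 1e-7)
})
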
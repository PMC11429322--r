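test_that("continuous-infusion attainment is the exact plateau comparison", {
  p <- typical_params()
  r <- regimen(2000, mode = "continuous")
  # f * Css = 0.98 * 6.72 = 6.59 > 4
  expect_identical(ft_above_mic(p, r, mic = 4, pd_target(0.4, 1)), 1)
  expect_identical(ft_above_mic(p, r, mic = 8, pd_target(0.4, 1)), 0)
})

test_that("extreme MICs give full or zero time above threshold", {
  p <- typical_params()
  r <- regimen(1000, 0.5, 8)
  expect_equal(ft_above_mic(p, r, mic = 1e-9, pd_target(0.4, 1)), 1)
  expect_equal(ft_above_mic(p, r, mic = 1e6, pd_target(0.4, 1)), 0)
  expect_error(ft_above_mic(p, r, mic = 0, pd_target(0.4, 1)), "mic")
})

test_that("time above MIC matches a brute-force fine-grid measure", {
  p <- typical_params()
  r <- regimen(1000, 0.5, 8)
  for (mic in c(0.5, 2, 8)) {
    ft <- ft_above_mic(p, r, mic, pd_target(0.4, 1))
    tt <- seq(0, 8, length.out = 80001)
    cc <- conc_profile(p, r, tt, steady_state = TRUE)
    brute <- mean(0.98 * cc > mic)
    expect_equal(ft, brute, tolerance = 5e-4)
  }
})

test_that("halving the grid step barely moves the fraction", {
  p <- typical_params()
  r <- regimen(1000, 3, 12)
  for (mic in c(0.5, 1, 4)) {
    f1 <- ft_above_mic(p, r, mic, pd_target(0.4, 1), grid_step = 0.005)
    f2 <- ft_above_mic(p, r, mic, pd_target(0.4, 1), grid_step = 0.0025)
    expect_lt(abs(f1 - f2), 0.005)
  }
})

test_that("PTA is monotone in MIC and dose", {
  pop <- sample_population(400, seed = 8)
  curve <- pta_curve(pop, regimen(1000, 0.5, 8), target = pd_target(0.4, 1))
  expect_true(all(diff(curve$pta) <= 0))
  # non-decreasing in dose at fixed MIC
  p_lo <- pta(pop, regimen(500, 0.5, 8), 2, pd_target(0.4, 1))
  p_hi <- pta(pop, regimen(2000, 0.5, 8), 2, pd_target(0.4, 1))
  expect_gte(p_hi, p_lo)
})

test_that("quadrupling the dose is bit-identical to quartering the threshold", {
  pop <- sample_population(500, seed = 77)
  mics <- mic_distribution()$mic
  hi <- pta_curve(pop, regimen(2000, 0.5, 8), mics, pd_target(0.4, 4))
  lo <- pta_curve(pop, regimen(500, 0.5, 8), mics, pd_target(0.4, 1))
  expect_identical(hi$pta, lo$pta)
})

test_that("a point-mass MIC distribution reduces weighting to plain PTA", {
  pop <- sample_population(300, seed = 21)
  reg <- regimen(1000, 0.5, 8)
  tg <- pd_target(0.4, 1)
  dist1 <- mic_distribution(mic = 2, prob = 1)
  expect_equal(weighted_attainment(pop, reg, tg, dist1, "expectation"),
               pta(pop, reg, 2, tg))
  expect_equal(weighted_attainment(pop, reg, tg, dist1, "random_assignment",
                                   seed = 1),
               pta(pop, reg, 2, tg))
})

test_that("random MIC assignment agrees with the expectation estimator", {
  pop <- sample_population(2000, seed = 13)
  reg <- regimen(1000, 0.5, 8)
  tg <- pd_target(0.4, 1)
  expectation <- weighted_attainment(pop, reg, tg, mode = "expectation")
  diffs <- vapply(1:10, function(s) {
    abs(weighted_attainment(pop, reg, tg, mode = "random_assignment",
                            seed = s) - expectation)
  }, numeric(1))
  expect_lt(mean(diffs), 0.015)
})

test_that("the EUCAST ladder is renormalised and validated", {
  d <- mic_distribution()
  expect_equal(sum(d$prob), 1)
  # printed percentages cover 94.95% of isolates; weights keep their ratios
  expect_equal(d$prob[1] * 0.9495, 0.0443, tolerance = 1e-10)
  expect_equal(d$prob[1] / d$prob[4], 0.0443 / 0.2015, tolerance = 1e-12)
  expect_error(mic_distribution(mic = c(1, 2), prob = c(0.6, 0.6)), "sum")
})

test_that("continuous PTA equals the closed-form clearance-threshold share", {
  pop <- sample_population(5000, seed = 3001)
  tg <- pd_target(1, 4)
  r2 <- regimen(2000, mode = "continuous")
  sim <- pta(pop, r2, 1, tg)
  closed <- mean(pop$CL < 0.98 * (2000 / 24) / 4)
  expect_equal(sim, closed)
  # three settings that reduce to the same clearance threshold are identical
  a <- pta(pop, r2, 1, pd_target(1, 4))
  b <- pta(pop, r2, 4, pd_target(1, 1))
  c_ <- pta(pop, regimen(8000, mode = "continuous"), 4, pd_target(1, 4))
  expect_identical(a, b)
  expect_identical(a, c_)
})

test_that("degenerate inputs are rejected", {
  p <- typical_params()
  expect_error(ft_above_mic(p, regimen(1000, 0.5, 8), 1, pd_target(0.4, 1),
                            grid_step = 10), "grid_step")
  expect_error(pta(data.frame(), regimen(1000, 0.5, 8), 1, pd_target(0.4, 1)))
  expect_error(pd_target(0, 1))
  expect_error(pd_target(0.4, 3))
})

test_that("the campaign table covers the full grid and reuses one population", {
  pop <- sample_population(100, seed = 4)
  tab <- pta_campaign(pop, intermittent_regimens(c(500, 1000), 0.5, c(8, 12)),
                      standard_targets(), mics = c(0.5, 2), grid_step = 0.02)
  expect_equal(nrow(tab), 2 * 1 * 2 * 4 * 2)
  expect_true(all(tab$pta >= 0 & tab$pta <= 1))
  expect_true(all(tab$n == 100))
  # rows where the MIC multiplier is 4 at dose 2000 match multiplier 1 at 500
  tab2 <- pta_campaign(pop, intermittent_regimens(2000, 0.5, 8),
                       standard_targets(), mics = c(0.5, 2), grid_step = 0.02)
  tab1 <- pta_campaign(pop, intermittent_regimens(500, 0.5, 8),
                       standard_targets(), mics = c(0.5, 2), grid_step = 0.02)
  expect_identical(tab2$pta[tab2$target == "40%fT>4MIC"],
                   tab1$pta[tab1$target == "40%fT>MIC"])
})
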
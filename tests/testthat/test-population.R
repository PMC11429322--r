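test_that("the creatinine covariate law reproduces the published clearances", {
  expect_equal(signif(typical_cl(0.6), 3), 14.3)
  expect_equal(signif(typical_cl(1.0), 3), 11.7)
  expect_identical(typical_cl(0.86), 12.4) # reference creatinine, exact
  m <- population_model()
  expect_equal(m$tv_V1 + m$tv_V2, 12.32, tolerance = 1e-12) # typical Vss
  # strictly decreasing in creatinine
  cr <- seq(0.3, 3, by = 0.05)
  expect_true(all(diff(typical_cl(cr)) < 0))
  expect_error(typical_cl(0), "positive")
  expect_error(typical_cl(-1), "positive")
})

test_that("sampled clearances have the log-normal moments the omegas imply", {
  # fix creatinine at the reference so only eta_CL drives the spread
  covs <- covariate_distribution(cr_mean = 0.86, cr_cv = 0)
  pop <- sample_population(1e5, covs = covs, seed = 101)
  cv_cl <- stats::sd(pop$CL) / mean(pop$CL)
  expect_equal(cv_cl, sqrt(exp(0.262^2) - 1), tolerance = 0.02)
  expect_equal(stats::median(pop$CL), 12.4, tolerance = 0.01)
})

test_that("creatinine draws match the arithmetic mean and CV of the cohort", {
  pop <- sample_population(1e5, seed = 202)
  expect_equal(mean(pop$CR), 0.863, tolerance = 0.01)
  expect_equal(stats::sd(pop$CR) / mean(pop$CR), 0.190, tolerance = 0.02)
})

test_that("V1 shares the clearance eta with a 1.53 multiplier", {
  pop <- sample_population(5000, seed = 33)
  m <- population_model()
  cl_dev <- log(pop$CL) - log(typical_cl(pop$CR, m))
  v1_dev <- log(pop$V1) - log(m$tv_V1)
  expect_equal(stats::cor(cl_dev, v1_dev), 1, tolerance = 1e-12)
  slope <- stats::coef(stats::lm(v1_dev ~ cl_dev))[2]
  expect_equal(unname(slope), 1.53, tolerance = 1e-10)
})

test_that("fixed-omega variability on Q and V2 can be switched off", {
  pop <- sample_population(200, seed = 5, include_fixed_iiv = FALSE)
  expect_true(all(pop$Q == 5.22))
  expect_true(all(pop$V2 == 4.06))
  pop2 <- sample_population(2000, seed = 5, include_fixed_iiv = TRUE)
  expect_equal(stats::sd(log(pop2$Q)), 0.144, tolerance = 0.06)
  expect_equal(stats::sd(log(pop2$V2)), 0.179, tolerance = 0.06)
})

test_that("population sampling is reproducible under a seed", {
  a <- sample_population(50, seed = 99, demographics = TRUE)
  b <- sample_population(50, seed = 99, demographics = TRUE)
  expect_identical(a, b)
})

test_that("Cockcroft-Gault clearance matches hand arithmetic and is monotone", {
  expect_equal(clcr_cg(age = 40, weight = 72, cr = 1.0, female = FALSE), 100)
  expect_equal(clcr_cg(age = 40, weight = 72, cr = 1.0, female = TRUE), 85)
  # strictly decreasing in creatinine and age
  expect_true(all(diff(clcr_cg(40, 72, seq(0.5, 2, 0.1), FALSE)) < 0))
  expect_true(all(diff(clcr_cg(seq(20, 80, 5), 72, 1, FALSE)) < 0))
  norm <- clcr_cg(40, 72, 1, FALSE, normalized = TRUE, height = 175)
  expect_equal(norm, 100 / bsa_dubois(175, 72) * 1.73)
})

test_that("Du Bois BSA reproduces the cohort mean at mean demographics", {
  expect_equal(bsa_dubois(170, 65.7), 0.007185 * 170^0.725 * 65.7^0.425)
  # Table-level sanity: mean height/weight give roughly the cohort mean BSA
  expect_equal(bsa_dubois(168, 65.7), 1.74, tolerance = 0.02)
})

test_that("CKD-EPI kernels hit their knot points and MDRD follows its form", {
  # at the male creatinine knot (0.9) the min kernel is exactly 1
  age <- 40
  expect_equal(egfr_ckdepi(age, cr = 0.9, female = FALSE, type = "cr"),
               142 * 0.9938^age)
  expect_equal(egfr_ckdepi(age, cr = 0.7, female = TRUE, type = "cr"),
               142 * 0.9938^age * 1.012)
  expect_equal(egfr_mdrd(50, 1.2, FALSE), 175 * 1.2^(-1.154) * 50^(-0.203))
  expect_equal(egfr_mdrd(50, 1.2, TRUE), 175 * 1.2^(-1.154) * 50^(-0.203) * 0.742)
})

test_that("the renal panel returns every measure and flags missing cystatin C", {
  panel <- renal_panel(age = 40, weight = 72, height = 175, cr = 1.0,
                       female = FALSE)
  expect_true(is.na(panel$egfr_ckdepi_cc))
  expect_true(is.na(panel$egfr_ckdepi_cr_cc))
  expect_true(all(vapply(panel[c("bsa", "clcr_cg", "clcr_cg_norm", "egfr_mdrd",
                                 "egfr_ckdepi_cr", "egfr_mdrd_adj")],
                         function(x) is.finite(x) && x > 0, logical(1))))
  full <- renal_panel(40, 72, 175, 1.0, FALSE, cc = 0.8)
  expect_true(is.finite(full$egfr_ckdepi_cc) && full$egfr_ckdepi_cc > 0)
  expect_true(is.finite(full$egfr_ckdepi_cr_cc) && full$egfr_ckdepi_cr_cc > 0)
  expect_equal(full$egfr_ckdepi_cr_adj,
               full$egfr_ckdepi_cr / 1.73 * full$bsa)
})
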
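#' Final population pharmacokinetic model for meropenem in healthy adults
#'
#' Typical values, the serum-creatinine covariate law on clearance, the
#' shared-eta interindividual variability (IIV) structure and the proportional
#' residual-error magnitude of the final two-compartment model:
#' \deqn{CL = \theta_1 (CR/0.86)^{\theta_2} e^{\eta_{CL}},\quad
#'       V1 = TVV1\, e^{1.53\,\eta_{CL}},\quad
#'       Q = TVQ\, e^{\eta_Q},\quad V2 = TVV2\, e^{\eta_{V2}}}
#' with \eqn{\eta_{CL} \sim N(0, \omega_{CL}^2)} and independent
#' \eqn{\eta_Q, \eta_{V2}}. Because CL and V1 share a single eta (their
#' log-scale deviations were almost perfectly correlated), the V1 deviation is
#' `shared_exponent` times the CL deviation.
#'
#' @param theta1 Typical clearance at the reference creatinine, L/h.
#' @param theta2 Creatinine covariate exponent (negative: CL falls as CR rises).
#' @param tv_V1,tv_Q,tv_V2 Typical central volume (L), intercompartmental
#'   clearance (L/h) and peripheral volume (L).
#' @param omega_CL SD of the log-scale eta on CL.
#' @param shared_exponent Multiplier mapping the CL eta onto V1's log deviation.
#' @param omega_Q,omega_V2 SDs of the log-scale etas on Q and V2 (fixed in the
#'   original fit).
#' @param sigma_prop Proportional residual-error SD.
#' @param cr_ref Reference serum creatinine, mg/dL.
#' @return An object of class `population_model`.
#' @examples
#' mod <- population_model()
#' typical_cl(0.6, mod)
#' @export
population_model <- function(theta1 = 12.4, theta2 = -0.392,
                             tv_V1 = 8.26, tv_Q = 5.22, tv_V2 = 4.06,
                             omega_CL = 0.262, shared_exponent = 1.53,
                             omega_Q = 0.144, omega_V2 = 0.179,
                             sigma_prop = 0.109, cr_ref = 0.86) {
  assert_positive(theta1, "theta1")
  assert_positive(tv_V1, "tv_V1")
  assert_positive(tv_Q, "tv_Q")
  assert_positive(tv_V2, "tv_V2")
  assert_positive(cr_ref, "cr_ref")
  for (nm in c("omega_CL", "omega_Q", "omega_V2", "sigma_prop")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    }
  }
  structure(list(theta1 = theta1, theta2 = theta2, tv_V1 = tv_V1, tv_Q = tv_Q,
                 tv_V2 = tv_V2, omega_CL = omega_CL,
                 shared_exponent = shared_exponent, omega_Q = omega_Q,
                 omega_V2 = omega_V2, sigma_prop = sigma_prop, cr_ref = cr_ref),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (two-compartment, creatinine covariate on CL)\n")
  cat(sprintf("  CL = %.3g * (CR/%.2f)^%.3g L/h; V1 = %.3g L; Q = %.3g L/h; V2 = %.3g L\n",
              x$theta1, x$cr_ref, x$theta2, x$tv_V1, x$tv_Q, x$tv_V2))
  cat(sprintf("  IIV: omega_CL %.3g (V1 shares eta x %.3g), omega_Q %.3g, omega_V2 %.3g\n",
              x$omega_CL, x$shared_exponent, x$omega_Q, x$omega_V2))
  cat(sprintf("  Proportional residual SD %.3g\n", x$sigma_prop))
  invisible(x)
}

#' Covariate distribution for virtual patients
#'
#' Arithmetic means and CVs of the study covariates; virtual patients draw
#' each covariate log-normal with these moments. Only serum creatinine enters
#' the kinetics (through the clearance covariate law); the demographics are
#' carried for record completeness and per-kg reporting.
#'
#' @param cr_mean,cr_cv Serum creatinine mean (mg/dL) and CV.
#' @param weight_mean,weight_cv Body weight mean (kg) and CV.
#' @param age_mean,age_cv Age mean (years) and CV.
#' @param height_mean,height_cv Height mean (cm) and CV.
#' @param prop_female Probability a virtual subject is female.
#' @return An object of class `covariate_distribution`.
#' @export
covariate_distribution <- function(cr_mean = 0.863, cr_cv = 0.190,
                                   weight_mean = 65.7, weight_cv = 0.208,
                                   age_mean = 36.8, age_cv = 0.199,
                                   height_mean = 168, height_cv = 0.0429,
                                   prop_female = 4 / 12) {
  stopifnot(cr_mean > 0, cr_cv >= 0, weight_mean > 0, age_mean > 0,
            height_mean > 0, prop_female >= 0, prop_female <= 1)
  structure(list(cr_mean = cr_mean, cr_cv = cr_cv,
                 weight_mean = weight_mean, weight_cv = weight_cv,
                 age_mean = age_mean, age_cv = age_cv,
                 height_mean = height_mean, height_cv = height_cv,
                 prop_female = prop_female),
            class = "covariate_distribution")
}

#' Typical clearance at a given serum creatinine
#'
#' The final model's covariate law
#' `CL = theta1 * (CR/cr_ref)^theta2`, strictly decreasing in creatinine for
#' `theta2 < 0`. At the reference creatinine it returns exactly `theta1`.
#'
#' @param cr Serum creatinine, mg/dL (vectorised; strictly positive).
#' @param model A [population_model()].
#' @return Typical clearance, L/h.
#' @examples
#' typical_cl(c(0.6, 0.86, 1.0))
#' @export
typical_cl <- function(cr, model = population_model()) {
  stopifnot(inherits(model, "population_model"))
  if (!is.numeric(cr) || any(!is.finite(cr)) || any(cr <= 0)) {
    stop("`cr` must be finite and strictly positive", call. = FALSE)
  }
  model$theta1 * (cr / model$cr_ref)^model$theta2
}

#' Sample a virtual patient population
#'
#' Draws `n` virtual subjects: serum creatinine log-normal with the given
#' arithmetic mean/CV, `eta_CL ~ N(0, omega_CL^2)`, and
#' `CL = typical_cl(CR) exp(eta_CL)`, `V1 = tv_V1 exp(shared_exponent *
#' eta_CL)`, `Q = tv_Q exp(eta_Q)`, `V2 = tv_V2 exp(eta_V2)` with independent
#' etas on Q and V2 (their omegas were fixed, not estimated, in the original
#' fit; set `include_fixed_iiv = FALSE` to zero them).
#'
#' @param n Number of subjects (>= 1).
#' @param model A [population_model()].
#' @param covs A [covariate_distribution()].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param demographics If `TRUE`, also sample age, weight, height and sex.
#' @param include_fixed_iiv Sample the fixed-omega etas on Q and V2?
#' @return A `data.frame` of class `mp_population` with columns `id`, `CR`,
#'   `eta_CL`, `CL`, `V1`, `Q`, `V2` (and demographics when requested).
#' @examples
#' pop <- sample_population(5, seed = 1)
#' @export
sample_population <- function(n, model = population_model(),
                              covs = covariate_distribution(), seed = NULL,
                              demographics = FALSE, include_fixed_iiv = TRUE) {
  stopifnot(inherits(model, "population_model"),
            inherits(covs, "covariate_distribution"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    lp <- lnorm_pars(covs$cr_mean, covs$cr_cv)
    CR <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
    eta_cl <- stats::rnorm(n, 0, model$omega_CL)
    eta_q <- if (include_fixed_iiv) stats::rnorm(n, 0, model$omega_Q) else numeric(n)
    eta_v2 <- if (include_fixed_iiv) stats::rnorm(n, 0, model$omega_V2) else numeric(n)
    out <- data.frame(
      id = seq_len(n),
      CR = CR,
      eta_CL = eta_cl,
      CL = typical_cl(CR, model) * exp(eta_cl),
      V1 = model$tv_V1 * exp(model$shared_exponent * eta_cl),
      Q = model$tv_Q * exp(eta_q),
      V2 = model$tv_V2 * exp(eta_v2)
    )
    if (demographics) {
      la <- lnorm_pars(covs$age_mean, covs$age_cv)
      lw <- lnorm_pars(covs$weight_mean, covs$weight_cv)
      lh <- lnorm_pars(covs$height_mean, covs$height_cv)
      out$AGE <- stats::rlnorm(n, la$meanlog, la$sdlog)
      out$WT <- stats::rlnorm(n, lw$meanlog, lw$sdlog)
      out$HT <- stats::rlnorm(n, lh$meanlog, lh$sdlog)
      out$SEX <- stats::rbinom(n, 1, covs$prop_female) # 1 = female
    }
    class(out) <- c("mp_population", "data.frame")
    out
  })
}

#' @export
print.mp_population <- function(x, ...) {
  cat(sprintf("Virtual population: %d subjects\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more\n", nrow(x) - 6))
  invisible(x)
}

# coerce one row of an mp_population to pk_params
params_from_row <- function(pop, i) {
  pk_params(CL = pop$CL[i], V1 = pop$V1[i], Q = pop$Q[i], V2 = pop$V2[i])
}
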
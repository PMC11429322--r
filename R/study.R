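#' Design of the single-dose pharmacokinetic study
#'
#' The sampling design the generator replicates: healthy adults receiving a
#' single 500 mg meropenem dose infused over 0.5 h, with plasma samples just
#' before the infusion (0 h), at its end (0.5 h) and at 0.75, 1, 2, 3 and 6 h
#' after the infusion commenced, observed with proportional residual error.
#'
#' @param n_subjects Number of subjects.
#' @param dose Dose, mg.
#' @param tinf Infusion duration, h.
#' @param times Sampling times, h (must include the end of infusion).
#' @param error_on Apply proportional residual error to observations?
#' @param seed Optional seed used by [generate_study()].
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_subjects = 12, dose = 500, tinf = 0.5,
                         times = c(0, 0.5, 0.75, 1, 2, 3, 6),
                         error_on = TRUE, seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be >= 1", call. = FALSE)
  }
  assert_positive(dose, "dose")
  assert_positive(tinf, "tinf")
  stopifnot(all(times >= 0), !anyDuplicated(times))
  if (!any(times == tinf)) {
    stop("`times` must include the end-of-infusion sample", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), dose = dose, tinf = tinf,
                 times = sort(times), error_on = isTRUE(error_on), seed = seed),
            class = "study_design")
}

#' Generate a virtual replicate of the single-dose study
#'
#' Samples virtual subjects (kinetic parameters and demographic covariates)
#' from the population model, computes true concentrations with the
#' closed-form two-compartment solution, and observes them with proportional
#' residual error `DV = C * (1 + eps)`, `eps ~ N(0, sigma_prop^2)`, truncated
#' at zero (negative draws are floored; at `sigma = 0.109` this is a
#' measure-negligible guard). The result is a NONMEM-style rectangular dataset
#' with one dosing record (`EVID = 1`, `MDV = 1`, `AMT`/`RATE` set) and one
#' observation record per sample (`EVID = 0`, `MDV = 0`, `DV` set) per
#' subject, plus covariate columns `CR`, `AGE`, `WT`, `HT`, `SEX`
#' (1 = female).
#'
#' @param design A [study_design()].
#' @param model A [population_model()].
#' @param covs A [covariate_distribution()].
#' @param seed Optional seed (overrides `design$seed`).
#' @return `data.frame` with columns `ID`, `TIME`, `AMT`, `RATE`, `DV`,
#'   `EVID`, `MDV`, `CR`, `AGE`, `WT`, `HT`, `SEX`. The simulated ground
#'   truth (one row per subject: `id`, `CL`, `V1`, `Q`, `V2`) is attached as
#'   attribute `"true_params"` so recovery studies can compare estimates to
#'   the parameters that actually generated the data.
#' @examples
#' d <- generate_study(study_design(n_subjects = 3, seed = 7))
#' @export
generate_study <- function(design = study_design(),
                           model = population_model(),
                           covs = covariate_distribution(), seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  seed <- if (!is.null(seed)) seed else design$seed
  with_seed(seed, {
    pop <- sample_population(design$n_subjects, model, covs,
                             demographics = TRUE)
    reg <- regimen(design$dose, design$tinf,
                   tau = max(design$times) + design$tinf)
    cmat <- conc_multi_matrix(pop$CL, pop$V1, pop$Q, pop$V2, reg,
                              design$times, n_doses = 1L)
    n <- design$n_subjects
    nt <- length(design$times)
    dv <- as.vector(t(cmat)) # subject-major: times within subject
    if (design$error_on) {
      eps <- stats::rnorm(n * nt, 0, model$sigma_prop)
      dv <- pmax(dv * (1 + eps), 0)
    }
    obs <- data.frame(
      ID = rep(pop$id, each = nt),
      TIME = rep(design$times, times = n),
      AMT = NA_real_, RATE = NA_real_,
      DV = dv, EVID = 0L, MDV = 0L
    )
    dosing <- data.frame(
      ID = pop$id, TIME = 0, AMT = design$dose,
      RATE = design$dose / design$tinf,
      DV = NA_real_, EVID = 1L, MDV = 1L
    )
    out <- rbind(dosing, obs)
    out <- out[order(out$ID, out$TIME, -out$EVID), ]
    cov_cols <- pop[, c("id", "CR", "AGE", "WT", "HT", "SEX")]
    out <- merge(out, cov_cols, by.x = "ID", by.y = "id", sort = FALSE)
    out <- out[order(out$ID, out$TIME, -out$EVID), ]
    rownames(out) <- NULL
    attr(out, "true_params") <- pop[, c("id", "CL", "V1", "Q", "V2")]
    out
  })
}
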
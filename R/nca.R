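# Noncompartmental analysis of concentration-time profiles.

#' Subject concentration-time profile
#'
#' @param times Sampling times, h (unique, non-negative, sorted internally).
#' @param conc Concentrations, mg/L (non-negative).
#' @param dose Administered dose, mg.
#' @param tinf Infusion duration, h.
#' @param id Optional subject identifier.
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(times, conc, dose, tinf, id = NA) {
  stopifnot(length(times) == length(conc), all(is.finite(times)),
            all(times >= 0), !anyDuplicated(times), all(conc >= 0))
  assert_positive(dose, "dose")
  assert_positive(tinf, "tinf")
  ord <- order(times)
  structure(list(id = id, dose = dose, tinf = tinf,
                 times = times[ord], conc = conc[ord]),
            class = "subject_profile")
}

#' Terminal elimination rate constant
#'
#' Log-linear regression of the terminal-phase concentrations. Usable points
#' are the strictly positive concentrations strictly after the observed Cmax.
#' The default `"best_adjr2"` rule examines every contiguous terminal window of
#' at least 3 points (all ending at the last observation) and keeps the window
#' with the highest adjusted R-squared, breaking near-ties (within 1e-4) in
#' favour of more points; `"last3"` always fits the final three points.
#'
#' @param profile A [subject_profile()].
#' @param rule Terminal point-selection rule.
#' @return List of class `lambda_z_fit`: `lambda_z` (1/h), `n_points`,
#'   `adj_r2`, `intercept` (log scale), `ok` (logical). Fewer than 3 usable
#'   points, or a non-positive slope estimate, set `ok = FALSE` and
#'   `lambda_z = NA`; downstream extrapolations are then withheld.
#' @export
lambda_z <- function(profile, rule = c("best_adjr2", "last3")) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "subject_profile"))
  pos <- profile$conc > 0
  t_cmax <- profile$times[which.max(profile$conc)]
  use <- which(pos & profile$times > t_cmax)
  fail <- list(lambda_z = NA_real_, n_points = length(use),
               adj_r2 = NA_real_, intercept = NA_real_, ok = FALSE)
  class(fail) <- "lambda_z_fit"
  if (length(use) < 3L) return(fail)
  tt <- profile$times[use]
  lc <- log(profile$conc[use])
  n_use <- length(use)
  fit_window <- function(k) { # last k points
    sel <- (n_use - k + 1L):n_use
    f <- stats::lm.fit(cbind(1, tt[sel]), lc[sel])
    ss_res <- sum(f$residuals^2)
    ss_tot <- sum((lc[sel] - mean(lc[sel]))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    list(slope = unname(f$coefficients[2]),
         intercept = unname(f$coefficients[1]),
         adj_r2 = 1 - (1 - r2) * (k - 1) / (k - 2), k = k)
  }
  cand <- if (rule == "last3") list(fit_window(3L)) else {
    lapply(3:n_use, fit_window)
  }
  adj <- vapply(cand, `[[`, numeric(1), "adj_r2")
  best <- max(adj)
  # near-ties resolved towards the longer window
  pick <- cand[[max(which(adj >= best - 1e-4))]]
  if (!is.finite(pick$slope) || pick$slope >= 0) return(fail)
  structure(list(lambda_z = -pick$slope, n_points = pick$k,
                 adj_r2 = pick$adj_r2, intercept = pick$intercept, ok = TRUE),
            class = "lambda_z_fit")
}

#' @export
print.lambda_z_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("lambda_z = %.5g 1/h (%d points, adj R2 = %.5f)\n",
                x$lambda_z, x$n_points, x$adj_r2))
  } else {
    cat("terminal slope estimation failed\n")
  }
  invisible(x)
}

#' AUC and AUMC by the linear-up/log-down trapezoidal method
#'
#' Rising or flat segments (and any segment touching a zero concentration) use
#' the linear trapezoid; strictly falling segments with positive endpoints use
#' the log trapezoid `(C1 - C2)/k * ...` with `k = log(C1/C2)/dt`, which is
#' exact for mono-exponential decline. The first-moment areas use the matching
#' formulas (`AUMC_seg = (t1 C1 - t2 C2)/k + (C1 - C2)/k^2` on log segments).
#'
#' @param times Sorted sampling times, h.
#' @param conc Concentrations, mg/L.
#' @return List with `auc_last` (mg.h/L) and `aumc_last` (mg.h^2/L) from the
#'   first to the last observation.
#' @examples
#' auc_aumc(c(1, 2), c(10, 5))$auc_last   # 5/log(2)
#' @export
auc_aumc <- function(times, conc) {
  stopifnot(length(times) == length(conc), !is.unsorted(times))
  auc <- 0
  aumc <- 0
  for (i in seq_len(length(times) - 1L)) {
    t1 <- times[i]; t2 <- times[i + 1L]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    dt <- t2 - t1
    if (c2 < c1 && c1 > 0 && c2 > 0) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + dt * (c1 + c2) / 2
      aumc <- aumc + dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  list(auc_last = auc, aumc_last = aumc)
}

#' Noncompartmental analysis of one profile
#'
#' Computes the standard NCA parameter set: Cmax, Tlast and Clast read
#' directly off the observations; AUClast/AUMClast by [auc_aumc()];
#' `AUCinf = AUClast + Clast/lambda_z`;
#' `AUMCinf = AUMClast + Tlast*Clast/lambda_z + Clast/lambda_z^2`;
#' `MRTinf = AUMCinf/AUCinf - tinf/2` (the half-infusion correction removes
#' the mean input time of a zero-order infusion); `CL = dose/AUCinf`;
#' `Vz = CL/lambda_z`; `Vss = MRT * CL`; `t_half = log(2)/lambda_z`.
#' If the last observed concentration is zero, the terminal-fit prediction at
#' `Tlast` is substituted for the extrapolation terms.
#'
#' @param profile A [subject_profile()].
#' @param rule Terminal point-selection rule, see [lambda_z()].
#' @return A one-row `data.frame` of class `nca_result` with columns `id`,
#'   `cmax`, `tlast`, `clast`, `auc_last`, `auc_inf`, `aumc_last`, `aumc_inf`,
#'   `mrt_inf`, `lambda_z`, `lambda_z_n`, `lambda_z_adj_r2`, `cl`, `vz`, `vss`,
#'   `t_half`, `ok`. When the terminal fit fails, the extrapolated quantities
#'   are `NA` and `ok` is `FALSE`.
#' @export
nca <- function(profile, rule = c("best_adjr2", "last3")) {
  stopifnot(inherits(profile, "subject_profile"))
  lz <- lambda_z(profile, rule)
  area <- auc_aumc(profile$times, profile$conc)
  obs_pos <- profile$conc > 0
  cmax <- max(profile$conc)
  tlast <- max(profile$times[obs_pos])
  clast <- profile$conc[profile$times == tlast]
  out <- data.frame(
    id = profile$id, cmax = cmax, tlast = tlast, clast = clast,
    auc_last = area$auc_last, auc_inf = NA_real_,
    aumc_last = area$aumc_last, aumc_inf = NA_real_, mrt_inf = NA_real_,
    lambda_z = lz$lambda_z, lambda_z_n = lz$n_points,
    lambda_z_adj_r2 = lz$adj_r2,
    cl = NA_real_, vz = NA_real_, vss = NA_real_, t_half = NA_real_,
    ok = lz$ok
  )
  if (lz$ok) {
    cl_ext <- if (clast > 0) clast else exp(lz$intercept - lz$lambda_z * tlast)
    out$auc_inf <- area$auc_last + cl_ext / lz$lambda_z
    out$aumc_inf <- area$aumc_last + tlast * cl_ext / lz$lambda_z +
      cl_ext / lz$lambda_z^2
    out$mrt_inf <- out$aumc_inf / out$auc_inf - profile$tinf / 2
    out$cl <- profile$dose / out$auc_inf
    out$vz <- out$cl / lz$lambda_z
    out$vss <- out$mrt_inf * out$cl
    out$t_half <- log(2) / lz$lambda_z
  }
  class(out) <- c("nca_result", "data.frame")
  out
}

#' NCA over a NONMEM-style dataset
#'
#' Splits a study dataset (as produced by [generate_study()] or read with
#' [read_nonmem_csv()]) into per-subject profiles, runs [nca()] on each, and
#' optionally divides clearance/volume terms by body weight to report the
#' weight-normalised convention (L/h/kg, L/kg).
#'
#' @param data Data frame with columns `ID`, `TIME`, `DV`, `EVID`, `AMT`,
#'   `RATE` (and `WT` when `per_kg = TRUE`).
#' @param rule Terminal point-selection rule.
#' @param per_kg Normalise `cl`, `vz`, `vss` by subject weight?
#' @return `data.frame` with one [nca()] row per subject.
#' @export
nca_dataset <- function(data, rule = c("best_adjr2", "last3"), per_kg = FALSE) {
  stopifnot(all(c("ID", "TIME", "DV", "EVID", "AMT", "RATE") %in% names(data)))
  res <- lapply(split(data, data$ID), function(d) {
    dose_row <- d[d$EVID == 1, ][1, ]
    obs <- d[d$EVID == 0, ]
    pr <- subject_profile(obs$TIME, obs$DV, dose = dose_row$AMT,
                          tinf = dose_row$AMT / dose_row$RATE,
                          id = dose_row$ID)
    row <- nca(pr, rule)
    if (per_kg) {
      wt <- d$WT[1]
      row$cl <- row$cl / wt
      row$vz <- row$vz / wt
      row$vss <- row$vss / wt
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summary table of NCA results
#'
#' Mean, CV%, median and IQR for every numeric NCA parameter across subjects,
#' mirroring the usual descriptive-statistics layout of PK study reports.
#'
#' @param results Output of [nca_dataset()].
#' @return `data.frame` with columns `parameter`, `mean`, `cv_pct`, `median`,
#'   `q1`, `q3`, computed over converged subjects.
#' @export
nca_summary <- function(results) {
  ok <- results[results$ok, ]
  params <- c("cmax", "tlast", "clast", "auc_last", "auc_inf", "aumc_last",
              "aumc_inf", "mrt_inf", "lambda_z", "cl", "vz", "vss", "t_half")
  rows <- lapply(params, function(p) {
    x <- ok[[p]]
    data.frame(parameter = p, mean = mean(x),
               cv_pct = 100 * stats::sd(x) / mean(x),
               median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)),
               q3 = unname(stats::quantile(x, 0.75)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
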
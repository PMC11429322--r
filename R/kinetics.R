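# Closed-form two-compartment zero-order-infusion kinetics.
#
# Unit-impulse (bolus) response of the central compartment is
#   C(t) = (D/V1) [ c1 e^(-lambda1 t) + c2 e^(-lambda2 t) ],
#   c1 = (lambda1 - k21)/(lambda1 - lambda2), c2 = (k21 - lambda2)/(lambda1 - lambda2).
# Convolving with a zero-order input of rate R0 over (0, T] gives, per
# exponential term with amplitude a = (R0/V1) c/lambda,
#   g(t) = 1 - e^(-lambda t)                       t <= T
#        = e^(-lambda t) (e^(lambda T) - 1)        t >  T
# and the steady-state profile under interval tau adds, for every t in [0, tau],
#   e^(-lambda t) (e^(lambda T) - 1) * e^(-lambda tau)/(1 - e^(-lambda tau)).

# Per-(subject, regimen) constants for fast repeated evaluation. CL..V2 may be
# vectors (a whole virtual population). Terms with lambda == 0 (one-compartment
# limit) carry zero amplitude.
ss_constants <- function(CL, V1, Q, V2, reg) {
  mc <- micro_vec(CL, V1, Q, V2)
  dl <- mc$lambda1 - mc$lambda2
  c1 <- (mc$lambda1 - mc$k21) / dl
  c2 <- (mc$k21 - mc$lambda2) / dl
  l1 <- mc$lambda1
  l2 <- mc$lambda2
  a1 <- ifelse(l1 > 0, (reg$rate / V1) * (c1 / ifelse(l1 > 0, l1, 1)), 0)
  a2 <- ifelse(l2 > 0, (reg$rate / V1) * (c2 / ifelse(l2 > 0, l2, 1)), 0)
  l1s <- ifelse(l1 > 0, l1, 1)
  l2s <- ifelse(l2 > 0, l2, 1)
  out <- list(a1 = a1, a2 = a2, l1 = l1s, l2 = l2s,
              T = reg$tinf, tau = reg$tau, mode = reg$mode,
              rate = reg$rate, CL = CL)
  if (reg$mode == "intermittent") {
    out$eT1 <- expm1(l1s * reg$tinf)
    out$eT2 <- expm1(l2s * reg$tinf)
    out$r1 <- exp(-l1s * reg$tau) / (-expm1(-l1s * reg$tau))
    out$r2 <- exp(-l2s * reg$tau) / (-expm1(-l2s * reg$tau))
  }
  out
}

# single-term unit response at times t (vector), scalar lambda/T
g_term <- function(lambda, tinf, t) {
  ifelse(t <= tinf,
         -expm1(-lambda * pmax(t, 0)) * (t >= 0),
         exp(-lambda * t) * expm1(lambda * tinf))
}

# steady-state concentration for subjects idx of `sc` at per-subject times t
# (t and idx same length, t within [0, tau]); vectorised over crossings
conc_ss_at <- function(sc, t, idx) {
  E1 <- exp(-sc$l1[idx] * t)
  E2 <- exp(-sc$l2[idx] * t)
  g1 <- ifelse(t <= sc$T, 1 - E1, E1 * sc$eT1[idx])
  g2 <- ifelse(t <= sc$T, 1 - E2, E2 * sc$eT2[idx])
  sc$a1[idx] * (g1 + E1 * sc$eT1[idx] * sc$r1[idx]) +
    sc$a2[idx] * (g2 + E2 * sc$eT2[idx] * sc$r2[idx])
}

# full steady-state profile matrix (subjects x times); times within [0, tau]
conc_ss_matrix <- function(sc, times) {
  n <- length(sc$a1)
  E1 <- exp(outer(-sc$l1, times))
  E2 <- exp(outer(-sc$l2, times))
  during <- times <= sc$T
  G1 <- sweep(E1, 1, sc$eT1, "*")
  G2 <- sweep(E2, 1, sc$eT2, "*")
  g1 <- G1
  g2 <- G2
  if (any(during)) {
    g1[, during] <- 1 - E1[, during, drop = FALSE]
    g2[, during] <- 1 - E2[, during, drop = FALSE]
  }
  sc$a1 * (g1 + G1 * sc$r1) + sc$a2 * (g2 + G2 * sc$r2)
}

# finite-dose superposition matrix (subjects x times); times from first dose.
# CL..V2 vectors over a population, `reg` intermittent.
conc_multi_matrix <- function(CL, V1, Q, V2, reg, times, n_doses = 1L) {
  sc <- ss_constants(CL, V1, Q, V2, reg)
  n <- length(sc$a1)
  out <- matrix(0, n, length(times))
  for (k in seq_len(n_doses) - 1L) {
    tk <- times - k * reg$tau
    live <- which(tk > 0)
    if (!length(live)) next
    tl <- tk[live]
    E1 <- exp(outer(-sc$l1, tl))
    E2 <- exp(outer(-sc$l2, tl))
    during <- tl <= reg$tinf
    g1 <- sweep(E1, 1, sc$eT1, "*")
    g2 <- sweep(E2, 1, sc$eT2, "*")
    if (any(during)) {
      g1[, during] <- 1 - E1[, during, drop = FALSE]
      g2[, during] <- 1 - E2[, during, drop = FALSE]
    }
    out[, live] <- out[, live, drop = FALSE] + sc$a1 * g1 + sc$a2 * g2
  }
  out
}

#' Central-compartment concentration under a dosing regimen
#'
#' Closed-form two-compartment concentration (mg/L) in the central compartment
#' for intravenous zero-order infusions: single or multiple doses by
#' superposition, analytic steady state via per-exponential accumulation
#' factors `1/(1 - exp(-lambda tau))`, and continuous infusion (ongoing
#' zero-order input from time 0; at steady state the plateau is
#' `Css = rate/CL`).
#'
#' @param params A [pk_params()] object.
#' @param reg A [regimen()].
#' @param times Numeric vector of non-negative times (h). For finite-dose
#'   intermittent dosing, time since the start of the first infusion; for
#'   `steady_state = TRUE`, time within a steady-state dosing interval (values
#'   beyond `tau` are wrapped modulo `tau`).
#' @param n_doses Number of doses administered (intermittent, finite series).
#' @param steady_state If `TRUE`, return the steady-state profile (analytic
#'   accumulation; for continuous mode the constant plateau `rate/CL`).
#' @return Numeric vector of concentrations, mg/L.
#' @examples
#' p <- pk_params(12.4, 8.26, 5.22, 4.06)
#' conc_profile(p, regimen(500, 0.5, 8), times = c(0.5, 1, 2, 6))
#' conc_profile(p, regimen(2000, mode = "continuous"), 0, steady_state = TRUE)
#' @export
conc_profile <- function(params, reg, times, n_doses = 1L, steady_state = FALSE) {
  stopifnot(inherits(params, "pk_params"), inherits(reg, "regimen"))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and non-negative", call. = FALSE)
  }
  sc <- ss_constants(params$CL, params$V1, params$Q, params$V2, reg)
  if (reg$mode == "continuous") {
    if (steady_state) return(rep(reg$rate / params$CL, length(times)))
    # ongoing infusion from t = 0 (tinf = Inf): g reduces to 1 - e^(-lambda t)
    return(sc$a1 * (-expm1(-sc$l1 * times)) + sc$a2 * (-expm1(-sc$l2 * times)))
  }
  if (steady_state) {
    tw <- times %% reg$tau
    tw[times > 0 & tw == 0] <- reg$tau
    return(drop(conc_ss_matrix(sc, tw)))
  }
  stopifnot(n_doses >= 1)
  out <- numeric(length(times))
  for (k in seq_len(n_doses) - 1L) {
    tk <- times - k * reg$tau
    live <- tk > 0
    if (!any(live)) next
    out[live] <- out[live] +
      sc$a1 * g_term(sc$l1, reg$tinf, tk[live]) +
      sc$a2 * g_term(sc$l2, reg$tinf, tk[live])
  }
  out
}
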
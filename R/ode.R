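#' Numeric ODE oracle for two-compartment infusion kinetics
#'
#' Independent check on the closed-form solutions: integrates the amount
#' equations
#' \deqn{dA1/dt = R(t) - (k10 + k12) A1 + k21 A2,\quad dA2/dt = k12 A1 - k21 A2}
#' with `C = A1/V1`, using `deSolve::lsoda` piecewise between infusion on/off
#' boundaries so the discontinuous input never degrades the integrator's
#' accuracy. Intended for testing; the simulation code paths use the closed
#' form.
#'
#' @param params A [pk_params()] object.
#' @param reg A [regimen()].
#' @param times Non-negative times (h) from the start of the first dose.
#' @param n_doses Number of doses (intermittent mode).
#' @param rtol,atol Integrator tolerances.
#' @param auc If `TRUE`, also integrate the cumulative central-compartment
#'   AUC and return it as attribute `"auc"` (value at each requested time).
#' @return Concentrations (mg/L) at `times`; integration failures raise an
#'   error rather than returning truncated output.
#' @export
ode_oracle <- function(params, reg, times, n_doses = 1L,
                       rtol = 1e-10, atol = 1e-12, auc = FALSE) {
  stopifnot(inherits(params, "pk_params"), inherits(reg, "regimen"))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be finite and non-negative", call. = FALSE)
  }
  mc <- micro_vec(params$CL, params$V1, params$Q, params$V2)
  t_end <- max(times)
  # infusion on/off boundaries within [0, t_end]
  if (reg$mode == "continuous") {
    bounds <- numeric(0)
    rate_at <- function(t) reg$rate
  } else {
    starts <- (seq_len(n_doses) - 1L) * reg$tau
    stops <- starts + reg$tinf
    bounds <- sort(unique(c(starts, stops)))
    bounds <- bounds[bounds > 0 & bounds < t_end]
    rate_at <- function(t) {
      k <- floor(t / reg$tau)
      if (k < n_doses && (t - k * reg$tau) < reg$tinf) reg$rate else 0
    }
  }
  deriv <- function(t, y, p) {
    dA1 <- p$rate - (mc$k10 + mc$k12) * y[1] + mc$k21 * y[2]
    dA2 <- mc$k12 * y[1] - mc$k21 * y[2]
    if (length(y) == 3L) list(c(dA1, dA2, y[1] / params$V1))
    else list(c(dA1, dA2))
  }
  y <- if (auc) c(0, 0, 0) else c(0, 0)
  grid <- sort(unique(c(0, bounds, t_end, times)))
  sol_c <- numeric(length(grid))   # concentration at each grid time
  sol_a <- numeric(length(grid))   # cumulative AUC at each grid time
  seg_edges <- sort(unique(c(0, bounds, t_end)))
  for (i in seq_len(length(seg_edges) - 1L)) {
    lo <- seg_edges[i]; hi <- seg_edges[i + 1L]
    tt <- grid[grid >= lo & grid <= hi]
    if (length(tt) < 2L) tt <- c(lo, hi)
    rate <- rate_at((lo + hi) / 2)
    sol <- deSolve::lsoda(y, tt, deriv, parms = list(rate = rate),
                          rtol = rtol, atol = atol)
    if (nrow(sol) < length(tt)) stop("ODE integration failed", call. = FALSE)
    keep <- match(grid[grid >= lo & grid <= hi], sol[, 1])
    sol_c[grid >= lo & grid <= hi] <- sol[keep, 2] / params$V1
    if (auc) sol_a[grid >= lo & grid <= hi] <- sol[keep, 4]
    y <- as.numeric(sol[nrow(sol), -1])
  }
  pos <- match(times, grid)
  conc <- sol_c[pos]
  conc[times == 0] <- 0
  if (auc) {
    aucv <- sol_a[pos]
    aucv[times == 0] <- 0
    attr(conc, "auc") <- aucv
  }
  conc
}
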
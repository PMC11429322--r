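#' Two-compartment pharmacokinetic parameters
#'
#' Container for an individual's disposition parameters in the mammillary
#' two-compartment model: total clearance `CL` (L/h), central volume `V1` (L),
#' intercompartmental clearance `Q` (L/h) and peripheral volume `V2` (L).
#' The steady-state volume of distribution is `Vss = V1 + V2`.
#'
#' @param CL Total clearance, L/h. Strictly positive.
#' @param V1 Central volume of distribution, L. Strictly positive.
#' @param Q Intercompartmental clearance, L/h. Strictly positive (`Q = 0` is
#'   tolerated as the one-compartment limit).
#' @param V2 Peripheral volume of distribution, L. Strictly positive.
#' @return An object of class `pk_params`.
#' @examples
#' p <- pk_params(CL = 12.4, V1 = 8.26, Q = 5.22, V2 = 4.06)
#' vss(p)
#' @export
pk_params <- function(CL, V1, Q, V2) {
  assert_positive(CL, "CL")
  assert_positive(V1, "V1")
  assert_positive(V2, "V2")
  if (!is.numeric(Q) || !is.finite(Q) || Q < 0) {
    stop("`Q` must be a finite non-negative number", call. = FALSE)
  }
  structure(list(CL = CL, V1 = V1, Q = Q, V2 = V2), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment PK parameters\n")
  cat(sprintf("  CL = %.4g L/h, V1 = %.4g L, Q = %.4g L/h, V2 = %.4g L (Vss = %.4g L)\n",
              x$CL, x$V1, x$Q, x$V2, x$V1 + x$V2))
  invisible(x)
}

#' Steady-state volume of distribution
#'
#' @param params A [pk_params()] object.
#' @return `V1 + V2` in litres.
#' @export
vss <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  params$V1 + params$V2
}

#' Micro rate constants and hybrid disposition rates
#'
#' Converts clearances/volumes to the micro constants `k10 = CL/V1`,
#' `k12 = Q/V1`, `k21 = Q/V2` and the hybrid (macro) disposition rate
#' constants `lambda1 > lambda2`, the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21 = 0`. `lambda1` governs the fast
#' distribution phase (alpha), `lambda2` the terminal elimination phase (beta).
#'
#' @param params A [pk_params()] object.
#' @return A list of class `micro_constants` with elements `k10`, `k12`,
#'   `k21`, `lambda1`, `lambda2` (all 1/h).
#' @examples
#' micro_constants(pk_params(12.4, 8.26, 5.22, 4.06))
#' @export
micro_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  mc <- micro_vec(params$CL, params$V1, params$Q, params$V2)
  structure(
    list(k10 = mc$k10, k12 = mc$k12, k21 = mc$k21,
         lambda1 = mc$lambda1, lambda2 = mc$lambda2),
    class = "micro_constants"
  )
}

# vectorised micro-constant algebra (used for whole virtual populations)
micro_vec <- function(CL, V1, Q, V2) {
  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(pmax(s^2 - 4 * p, 0))
  lambda1 <- (s + disc) / 2
  lambda2 <- (s - disc) / 2
  # repeated-root guard: physiologically unreachable, but a coincidental
  # lambda1 == lambda2 would zero the bi-exponential denominators; nudge k10.
  deg <- which(lambda1 - lambda2 < 1e-9 * lambda1 & k21 > 0)
  if (length(deg)) {
    k10d <- k10[deg] * (1 + 1e-9)
    sd_ <- k10d + k12[deg] + k21[deg]
    dd <- sqrt(pmax(sd_^2 - 4 * k10d * k21[deg], 0))
    lambda1[deg] <- (sd_ + dd) / 2
    lambda2[deg] <- (sd_ - dd) / 2
  }
  list(k10 = k10, k12 = k12, k21 = k21, lambda1 = lambda1, lambda2 = lambda2)
}

#' @export
print.micro_constants <- function(x, ...) {
  cat(sprintf("k10 = %.5g, k12 = %.5g, k21 = %.5g (1/h)\n", x$k10, x$k12, x$k21))
  cat(sprintf("lambda1 (alpha) = %.5g, lambda2 (beta) = %.5g (1/h)\n",
              x$lambda1, x$lambda2))
  invisible(x)
}

#' Distribution and elimination half-lives
#'
#' `t_half_alpha = ln(2)/lambda1` (distribution phase) and
#' `t_half_beta = ln(2)/lambda2` (terminal elimination phase). In the
#' one-compartment limit (`Q = 0`) `lambda2 = 0` and `t_half_beta` is `Inf`;
#' the single meaningful half-life is then `t_half_alpha = ln(2) V1/CL`.
#'
#' @param params A [pk_params()] object.
#' @return Named list with `t_half_alpha` and `t_half_beta`, hours.
#' @export
half_lives <- function(params) {
  mc <- micro_constants(params)
  list(t_half_alpha = log(2) / mc$lambda1,
       t_half_beta = if (mc$lambda2 > 0) log(2) / mc$lambda2 else Inf)
}

#' Dosing regimen
#'
#' Describes an intravenous meropenem regimen. Intermittent regimens give
#' `dose` mg as a zero-order infusion of `tinf` hours every `tau` hours.
#' Continuous regimens interpret `dose` as the total daily amount, infused at
#' a constant rate of `dose/24` mg/h.
#'
#' @param dose Amount per administration (mg); for continuous mode, the daily
#'   amount (mg). A zero dose is legal and yields identically zero
#'   concentrations.
#' @param tinf Infusion duration, h. Required for intermittent mode, must
#'   satisfy `0 < tinf <= tau`. Ignored for continuous mode.
#' @param tau Dosing interval, h. Required for intermittent mode.
#' @param mode `"intermittent"` or `"continuous"`.
#' @return An object of class `regimen`.
#' @examples
#' regimen(1000, tinf = 0.5, tau = 8)           # 1 g q8h over 30 min
#' regimen(2000, mode = "continuous")           # 2 g/day continuous infusion
#' @export
regimen <- function(dose, tinf = NULL, tau = NULL,
                    mode = c("intermittent", "continuous")) {
  mode <- match.arg(mode)
  if (!is.numeric(dose) || !is.finite(dose) || dose < 0) {
    stop("`dose` must be a finite non-negative number", call. = FALSE)
  }
  if (mode == "intermittent") {
    assert_positive(tinf, "tinf")
    assert_positive(tau, "tau")
    if (tinf > tau) stop("`tinf` must not exceed the dosing interval `tau`", call. = FALSE)
    structure(list(dose = dose, tinf = tinf, tau = tau, mode = mode,
                   rate = dose / tinf), class = "regimen")
  } else {
    structure(list(dose = dose, tinf = Inf, tau = Inf, mode = mode,
                   rate = dose / 24), class = "regimen")
  }
}

#' @export
print.regimen <- function(x, ...) {
  if (x$mode == "intermittent") {
    cat(sprintf("%g mg infused over %g h every %g h (rate %g mg/h)\n",
                x$dose, x$tinf, x$tau, x$rate))
  } else {
    cat(sprintf("continuous infusion, %g mg/day (rate %.4g mg/h)\n",
                x$dose, x$rate))
  }
  invisible(x)
}
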
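#' Pharmacodynamic target for time-dependent killing
#'
#' Beta-lactam efficacy tracks the fraction of the steady-state 24-h window
#' during which the unbound (free) concentration exceeds the MIC. A target is
#' the pair (required fraction, MIC multiplier): e.g. 40%fT>MIC is
#' `pd_target(0.40, 1)`, 100%fT>4MIC is `pd_target(1.00, 4)`.
#'
#' @param fraction_threshold Required fraction of the dosing window with
#'   `f * C > mic_multiplier * MIC`; in (0, 1].
#' @param mic_multiplier 1 (fT>MIC) or 4 (fT>4MIC).
#' @param unbound_fraction Free fraction `f` of meropenem in plasma.
#' @return Object of class `pd_target`.
#' @examples
#' pd_target(0.4, 1)   # 40% fT>MIC
#' pd_target(1, 4)     # 100% fT>4MIC
#' @export
pd_target <- function(fraction_threshold, mic_multiplier = 1,
                      unbound_fraction = 0.98) {
  stopifnot(fraction_threshold > 0, fraction_threshold <= 1,
            mic_multiplier %in% c(1, 4),
            unbound_fraction > 0, unbound_fraction <= 1)
  structure(list(fraction_threshold = fraction_threshold,
                 mic_multiplier = mic_multiplier,
                 unbound_fraction = unbound_fraction),
            class = "pd_target")
}

#' @export
print.pd_target <- function(x, ...) {
  cat(sprintf("%g%% fT>%sMIC (f = %g)\n", 100 * x$fraction_threshold,
              if (x$mic_multiplier == 1) "" else x$mic_multiplier,
              x$unbound_fraction))
  invisible(x)
}

# label used in tidy outputs
target_label <- function(target) {
  sprintf("%g%%fT>%sMIC", 100 * target$fraction_threshold,
          if (target$mic_multiplier == 1) "" else target$mic_multiplier)
}

#' The four simulated efficacy targets
#'
#' 40%fT>MIC, 40%fT>4MIC, 100%fT>MIC and 100%fT>4MIC with the unbound
#' fraction fixed at 0.98.
#'
#' @param unbound_fraction Free fraction of meropenem.
#' @return Named list of [pd_target()]s.
#' @export
standard_targets <- function(unbound_fraction = 0.98) {
  list(
    `40%fT>MIC` = pd_target(0.40, 1, unbound_fraction),
    `40%fT>4MIC` = pd_target(0.40, 4, unbound_fraction),
    `100%fT>MIC` = pd_target(1.00, 1, unbound_fraction),
    `100%fT>4MIC` = pd_target(1.00, 4, unbound_fraction)
  )
}

#' MIC distribution
#'
#' A ladder of (MIC, probability) pairs. The default is the EUCAST 2024
#' wild-type-plus-resistant MIC distribution of meropenem for *Pseudomonas
#' aeruginosa* (59,460 isolates). The published per-MIC percentages cover the
#' 0.06-16 mg/L ladder only and sum to 0.9495 (the remaining isolates fall
#' outside the ladder); probabilities are renormalised internally so the
#' ladder is a proper distribution.
#'
#' @param mic MIC values, mg/L (doubling ladder).
#' @param prob Probabilities (renormalised to sum to 1; must sum to 1 within
#'   0.1 before renormalisation).
#' @return A `data.frame` of class `mic_distribution` with columns `mic`,
#'   `prob`.
#' @examples
#' mic_distribution()  # EUCAST P. aeruginosa ladder
#' @export
mic_distribution <- function(mic = c(0.06, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16),
                             prob = c(0.0443, 0.1014, 0.1829, 0.2015, 0.1481,
                                      0.0868, 0.0635, 0.0546, 0.0664)) {
  stopifnot(length(mic) == length(prob), all(mic > 0), all(prob >= 0))
  if (abs(sum(prob) - 1) > 0.1) {
    stop("`prob` must sum to 1 within 0.1", call. = FALSE)
  }
  structure(data.frame(mic = mic, prob = prob / sum(prob)),
            class = c("mic_distribution", "data.frame"))
}
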
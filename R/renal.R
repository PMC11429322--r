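#' Body surface area (Du Bois)
#'
#' `BSA = 0.007185 * height^0.725 * weight^0.425` (m^2).
#'
#' @param height Height, cm.
#' @param weight Weight, kg.
#' @return BSA in m^2 (vectorised).
#' @export
bsa_dubois <- function(height, weight) {
  assert_positive(height, "height")
  assert_positive(weight, "weight")
  0.007185 * height^0.725 * weight^0.425
}

#' Cockcroft-Gault creatinine clearance
#'
#' `CLcr = (140 - age) * weight / (72 * CR)`, multiplied by 0.85 for females;
#' mL/min. `normalized = TRUE` rescales to a 1.73 m^2 body surface area
#' (`CLcr / BSA * 1.73`, requiring `height`).
#'
#' @param age Age, years.
#' @param weight Weight, kg.
#' @param cr Serum creatinine, mg/dL.
#' @param female Logical; `TRUE` for female subjects.
#' @param normalized Normalise to 1.73 m^2 BSA?
#' @param height Height in cm (needed when `normalized = TRUE`).
#' @return Creatinine clearance, mL/min (or mL/min/1.73 m^2).
#' @examples
#' clcr_cg(age = 40, weight = 72, cr = 1.0, female = FALSE) # 100 mL/min
#' @export
clcr_cg <- function(age, weight, cr, female, normalized = FALSE, height = NULL) {
  assert_positive(age, "age")
  assert_positive(weight, "weight")
  assert_positive(cr, "cr")
  stopifnot(is.logical(female))
  out <- (140 - age) * weight / (72 * cr)
  out <- out * ifelse(female, 0.85, 1)
  if (normalized) {
    if (is.null(height)) stop("`height` required for BSA normalisation", call. = FALSE)
    out <- out / bsa_dubois(height, weight) * 1.73
  }
  out
}

#' MDRD estimated glomerular filtration rate
#'
#' `eGFR = 175 * CR^-1.154 * age^-0.203` (x 0.742 if female), mL/min/1.73 m^2.
#'
#' @inheritParams clcr_cg
#' @return eGFR, mL/min/1.73 m^2.
#' @export
egfr_mdrd <- function(age, cr, female) {
  assert_positive(age, "age")
  assert_positive(cr, "cr")
  175 * cr^(-1.154) * age^(-0.203) * ifelse(female, 0.742, 1)
}

#' CKD-EPI estimated glomerular filtration rate
#'
#' The creatinine, cystatin-C and combined creatinine/cystatin-C CKD-EPI
#' equations with their sex-specific knots and min/max kernels, all in
#' mL/min/1.73 m^2:
#' * creatinine: `142 * min(CR/k,1)^a * max(CR/k,1)^-1.200 * 0.9938^age`
#'   with `k = 0.7, a = -0.241` (female, x 1.012) or `k = 0.9, a = -0.302`
#'   (male);
#' * cystatin C: `133 * min(CC/0.7,1)^-0.499 * max(CC/0.7,1)^-1.328 *
#'   0.9962^age` (x 0.932 if female);
#' * combined: `135 * min(CR/k,1)^a * max(CR/k,1)^-0.544 * min(CC/0.8,1)^0.323
#'   * max(CC/0.8,1)^-0.778 * 0.9961^age` with `k = 0.7, a = -0.219` (female,
#'   x 0.963) or `k = 0.9, a = -0.144` (male).
#'
#' @inheritParams clcr_cg
#' @param cc Serum cystatin C, mg/dL (`NA` allowed; cystatin-dependent results
#'   come back `NA`).
#' @param type Which equation: `"cr"`, `"cc"` or `"cr_cc"`.
#' @return eGFR, mL/min/1.73 m^2.
#' @export
egfr_ckdepi <- function(age, cr, female, cc = NA_real_,
                        type = c("cr", "cc", "cr_cc")) {
  type <- match.arg(type)
  assert_positive(age, "age")
  stopifnot(is.logical(female))
  if (type == "cr") {
    assert_positive(cr, "cr")
    k <- ifelse(female, 0.7, 0.9)
    a <- ifelse(female, -0.241, -0.302)
    return(142 * pmin(cr / k, 1)^a * pmax(cr / k, 1)^(-1.200) *
             0.9938^age * ifelse(female, 1.012, 1))
  }
  if (type == "cc") {
    return(ifelse(is.na(cc), NA_real_,
                  133 * pmin(cc / 0.7, 1)^(-0.499) * pmax(cc / 0.7, 1)^(-1.328) *
                    0.9962^age * ifelse(female, 0.932, 1)))
  }
  assert_positive(cr, "cr")
  k <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.219, -0.144)
  ifelse(is.na(cc), NA_real_,
         135 * pmin(cr / k, 1)^a * pmax(cr / k, 1)^(-0.544) *
           pmin(cc / 0.8, 1)^(0.323) * pmax(cc / 0.8, 1)^(-0.778) *
           0.9961^age * ifelse(female, 0.963, 1))
}

#' Renal-function panel for a subject
#'
#' Computes the full suite of renal-function measures used to characterise the
#' study cohort: Cockcroft-Gault creatinine clearance (raw and BSA-normalised),
#' MDRD, the three CKD-EPI equations, and the BSA-adjusted ("de-normalised",
#' `eGFR / 1.73 * BSA`) variants. Cystatin-dependent outputs are `NA` when
#' `cc` is missing; everything else is still returned.
#'
#' @inheritParams egfr_ckdepi
#' @param weight Weight, kg.
#' @param height Height, cm.
#' @return Named list: `bsa`, `clcr_cg`, `clcr_cg_norm`, `egfr_mdrd`,
#'   `egfr_ckdepi_cr`, `egfr_ckdepi_cc`, `egfr_ckdepi_cr_cc`, and `_adj`
#'   BSA-adjusted versions of the four eGFRs.
#' @examples
#' renal_panel(age = 40, weight = 72, height = 175, cr = 1.0, female = FALSE)
#' @export
renal_panel <- function(age, weight, height, cr, female, cc = NA_real_) {
  bsa <- bsa_dubois(height, weight)
  mdrd <- egfr_mdrd(age, cr, female)
  cr_eq <- egfr_ckdepi(age, cr, female, type = "cr")
  cc_eq <- egfr_ckdepi(age, cr, female, cc, type = "cc")
  crcc <- egfr_ckdepi(age, cr, female, cc, type = "cr_cc")
  adj <- function(x) x / 1.73 * bsa
  list(
    bsa = bsa,
    clcr_cg = clcr_cg(age, weight, cr, female),
    clcr_cg_norm = clcr_cg(age, weight, cr, female, normalized = TRUE, height = height),
    egfr_mdrd = mdrd,
    egfr_ckdepi_cr = cr_eq,
    egfr_ckdepi_cc = cc_eq,
    egfr_ckdepi_cr_cc = crcc,
    egfr_mdrd_adj = adj(mdrd),
    egfr_ckdepi_cr_adj = adj(cr_eq),
    egfr_ckdepi_cc_adj = adj(cc_eq),
    egfr_ckdepi_cr_cc_adj = adj(crcc)
  )
}
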
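# Deterministic dietary risk chain:
#   EDI = MC * IR * EF * ED / (BW * AT) * ADAF * ARm        (daily intake)
#   EWI = 7 * EDI                                           (weekly intake)
#   THQ = EF * ED * FIR * C * 1e-3 / (RfD * BW * AT)        (hazard quotient)
#   HI  = sum(THQ)                                          (hazard index)
#   CR  = EF * ED * CSF * EDI / AT * 1e-3                   (cancer risk)
#   TCR = sum(CR)                                           (total risk)
# The 1e-3 in THQ is the g -> kg conversion of FIR. The 1e-3 in CR is kept
# as printed in the source methodology ("as_printed"); an "unscaled" mode
# omits it because the factor is dimensionally unexplained.

#' Exposure parameters for fish consumption
#'
#' Bundles the constants of the intake equations with validation. Defaults
#' describe an adult consumer in the study area: ingestion rate `IR`
#' 0.34 kg/person/day (equivalently `FIR` 340 g/day), daily exposure all
#' year (`EF` 365 days/year) over an average lifetime (`ED` 74.8 years),
#' body weight `BW` 60 kg, averaging time `AT = EF * ED` days, adult
#' age-dependent adjustment factor `ADAF` 1, and per-element
#' gastrointestinal absorption efficiencies `ARm` (Pb 0.33, As 0.75, 1
#' otherwise).
#'
#' @param IR Ingestion rate, kg/person/day.
#' @param EF Exposure frequency, days/year.
#' @param ED Exposure duration, years.
#' @param BW Body weight, kg.
#' @param AT Averaging time, days; defaults to `EF * ED`.
#' @param ADAF Age-dependent adjustment factor (adult: 1).
#' @param FIR Fish ingestion rate, g/day (used by the hazard quotient).
#' @param ARm Named vector of absorption efficiencies in (0, 1]; defaults
#'   come from the element registry.
#' @return An object of class `"exposure_params"`.
#' @examples
#' exposure_params()
#' @export
exposure_params <- function(IR = 0.34, EF = 365, ED = 74.8, BW = 60,
                            AT = EF * ED, ADAF = 1, FIR = 340,
                            ARm = NULL) {
  if (is.null(ARm)) {
    tab <- .elements_table()
    ARm <- stats::setNames(tab$arm, tab$symbol)
  }
  for (nm in c("IR", "EF", "ED", "BW", "AT", "ADAF", "FIR")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(ARm) || is.null(names(ARm)) ||
      any(!is.finite(ARm) | ARm <= 0 | ARm > 1))
    stop("`ARm` must be a named vector of fractions in (0, 1]",
         call. = FALSE)
  structure(list(IR = IR, EF = EF, ED = ED, BW = BW, AT = AT, ADAF = ADAF,
                 FIR = FIR, ARm = ARm),
            class = "exposure_params")
}

#' @export
print.exposure_params <- function(x, ...) {
  cat("Exposure parameters:\n",
      sprintf("  IR %.3g kg/day, FIR %.4g g/day, EF %.4g d/yr, ED %.4g yr,\n",
              x$IR, x$FIR, x$EF, x$ED),
      sprintf("  BW %.4g kg, AT %.6g d, ADAF %.3g\n", x$BW, x$AT, x$ADAF),
      "  ARm:", paste(names(x$ARm), format(x$ARm), collapse = ", "), "\n")
  invisible(x)
}

#' Toxicity parameters
#'
#' Oral reference doses (`RfD`, mg/kg-bw/day), cancer slope factors (`CSF`,
#' (mg/kg-day)^-1) and the set of carcinogens. Defaults come from the
#' element registry: USEPA IRIS oral RfDs (As 3e-4, Cu 4e-2, Pb 3.5e-3,
#' Zn 3e-1) and CSFs for the two carcinogens (As 1.5, Pb 0.0085).
#'
#' @param RfD Named vector of positive oral reference doses.
#' @param CSF Named vector of positive cancer slope factors.
#' @param carcinogens Character vector of carcinogenic element symbols;
#'   every carcinogen must have a CSF.
#' @return An object of class `"toxicity_params"`.
#' @export
toxicity_params <- function(RfD = NULL, CSF = NULL, carcinogens = NULL) {
  tab <- .elements_table()
  if (is.null(RfD)) RfD <- stats::setNames(tab$rfd, tab$symbol)
  if (is.null(CSF)) {
    CSF <- stats::setNames(tab$csf, tab$symbol)
    CSF <- CSF[!is.na(CSF)]
  }
  if (is.null(carcinogens)) carcinogens <- tab$symbol[tab$carcinogen]
  if (!is.numeric(RfD) || is.null(names(RfD)) ||
      any(!is.finite(RfD) | RfD <= 0))
    stop("`RfD` must be a named vector of positive values", call. = FALSE)
  missing_csf <- setdiff(carcinogens, names(CSF))
  if (length(missing_csf))
    stop("carcinogen(s) without a CSF: ",
         paste(missing_csf, collapse = ", "), call. = FALSE)
  if (any(!is.finite(CSF) | CSF <= 0))
    stop("`CSF` values must be positive", call. = FALSE)
  structure(list(RfD = RfD, CSF = CSF, carcinogens = carcinogens),
            class = "toxicity_params")
}

#' @export
print.toxicity_params <- function(x, ...) {
  cat("Toxicity parameters:\n  RfD:",
      paste(names(x$RfD), format(x$RfD), collapse = ", "),
      "\n  CSF:", paste(names(x$CSF), format(x$CSF), collapse = ", "),
      "\n  carcinogens:", paste(x$carcinogens, collapse = ", "), "\n")
  invisible(x)
}

# Chain operations -----------------------------------------------------------

#' Estimated daily and weekly intake
#'
#' `edi()` converts a mean muscle concentration (mg/kg) into the estimated
#' daily intake per kg body weight, applying the element's gastrointestinal
#' absorption efficiency; with the default averaging time `AT = EF * ED` it
#' reduces to `conc * IR / BW * ADAF * ARm`. `ewi()` is the corresponding
#' weekly intake, `7 * EDI`.
#'
#' @param conc Mean concentration(s), mg/kg (>= 0).
#' @param element Element symbol(s), recycled against `conc`.
#' @param exposure An [exposure_params()] object.
#' @return Intake in mg/kg body weight per day (`edi`) or per week (`ewi`).
#' @examples
#' edi(0.24, "Pb")  # 4.488e-4
#' @export
edi <- function(conc, element, exposure = exposure_params()) {
  stopifnot(inherits(exposure, "exposure_params"))
  if (any(!is.finite(conc) | conc < 0))
    stop("`conc` must be finite and >= 0", call. = FALSE)
  arm <- exposure$ARm[element]
  if (anyNA(arm))
    stop("no absorption efficiency (ARm) for element(s): ",
         paste(unique(element[is.na(arm)]), collapse = ", "), call. = FALSE)
  conc * exposure$IR * exposure$EF * exposure$ED /
    (exposure$BW * exposure$AT) * exposure$ADAF * unname(arm)
}

#' @rdname edi
#' @param edi_value Estimated daily intake value(s) (>= 0).
#' @export
ewi <- function(edi_value) {
  if (any(!is.finite(edi_value) | edi_value < 0))
    stop("`edi_value` must be finite and >= 0", call. = FALSE)
  7 * edi_value
}

#' Target hazard quotient
#'
#' Ratio of chronic intake to the oral reference dose:
#' `EF * ED * FIR * conc * 1e-3 / (RfD * BW * AT)`, where the `1e-3`
#' converts the fish ingestion rate from g/day to kg/day. Values above 1
#' flag potential non-carcinogenic effects. The absorption efficiency ARm
#' does not enter the hazard quotient; it applies to the intake path only.
#'
#' @inheritParams edi
#' @param toxicity A [toxicity_params()] object supplying the RfD.
#' @return Dimensionless hazard quotient(s).
#' @examples
#' thq(2.51, "Zn")  # 0.04741
#' @export
thq <- function(conc, element, exposure = exposure_params(),
                toxicity = toxicity_params()) {
  stopifnot(inherits(exposure, "exposure_params"),
            inherits(toxicity, "toxicity_params"))
  if (any(!is.finite(conc) | conc < 0))
    stop("`conc` must be finite and >= 0", call. = FALSE)
  rfd <- toxicity$RfD[element]
  if (anyNA(rfd))
    stop("no oral reference dose (RfD) configured for element(s): ",
         paste(unique(element[is.na(rfd)]), collapse = ", "), call. = FALSE)
  exposure$EF * exposure$ED * exposure$FIR * conc * 1e-3 /
    (unname(rfd) * exposure$BW * exposure$AT)
}

#' Hazard index
#'
#' Exact sum of the per-element target hazard quotients; values above 1
#' indicate a risk of non-carcinogenic effects over a lifetime. The
#' exceedance flag is attached as attribute `"exceeds"`.
#'
#' @param thq_values Numeric vector of hazard quotients (>= 0, non-empty).
#' @return The hazard index with attribute `exceeds` (`HI > 1`).
#' @export
hazard_index <- function(thq_values) {
  if (length(thq_values) == 0L)
    stop("`thq_values` must contain at least one hazard quotient",
         call. = FALSE)
  if (any(!is.finite(thq_values) | thq_values < 0))
    stop("hazard quotients must be finite and >= 0", call. = FALSE)
  hi <- sum(thq_values)
  structure(hi, exceeds = hi > 1)
}

#' Carcinogenic risk
#'
#' Lifetime cancer risk from the estimated daily intake of a carcinogen:
#' `EF * ED * CSF * EDI / AT * 1e-3` in the default `"as_printed"` mode
#' (which reduces to `CSF * EDI * 1e-3` at the default averaging time); the
#' `"unscaled"` mode omits the trailing `1e-3`, whose dimensional role is
#' not established, and is provided for sensitivity analysis. The mode used
#' is recorded as attribute `"mode"`.
#'
#' @param edi_value Estimated daily intake(s), mg/kg-bw/day (>= 0).
#' @param csf Cancer slope factor, (mg/kg-day)^-1 (> 0).
#' @param exposure An [exposure_params()] object (EF, ED, AT enter the
#'   printed formula; they cancel at the default averaging time).
#' @param mode `"as_printed"` or `"unscaled"`.
#' @return Dimensionless risk value(s) with attribute `mode`.
#' @examples
#' cancer_risk(4.675e-4, 1.5)  # 7.0125e-7
#' @export
cancer_risk <- function(edi_value, csf, exposure = exposure_params(),
                        mode = c("as_printed", "unscaled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(exposure, "exposure_params"))
  if (!is.numeric(csf) || any(!is.finite(csf) | csf <= 0))
    stop("`csf` must be positive", call. = FALSE)
  if (any(!is.finite(edi_value) | edi_value < 0))
    stop("`edi_value` must be finite and >= 0", call. = FALSE)
  scale <- if (mode == "as_printed") 1e-3 else 1
  cr <- exposure$EF * exposure$ED * csf * edi_value / exposure$AT * scale
  structure(cr, mode = mode)
}

#' Total cancer risk and its classification
#'
#' `total_cancer_risk()` sums the per-carcinogen risks exactly and
#' classifies the sum against the conventional acceptability band
#' `[1e-6, 1e-4]` (closed at both ends): `"below 1e-6"`, `"within band"`,
#' or `"above 1e-4"`.
#'
#' @param cr_values Numeric vector of per-carcinogen risks (>= 0,
#'   non-empty).
#' @return The total risk with attribute `classification`.
#' @export
total_cancer_risk <- function(cr_values) {
  if (length(cr_values) == 0L)
    stop("`cr_values` must contain at least one cancer risk", call. = FALSE)
  if (any(!is.finite(cr_values) | cr_values < 0))
    stop("cancer risks must be finite and >= 0", call. = FALSE)
  tcr <- sum(cr_values)
  structure(tcr, classification = classify_tcr(tcr))
}

#' @rdname total_cancer_risk
#' @param x Total cancer risk value(s).
#' @export
classify_tcr <- function(x) {
  ifelse(x < 1e-6, "below 1e-6",
         ifelse(x <= 1e-4, "within band", "above 1e-4"))
}
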
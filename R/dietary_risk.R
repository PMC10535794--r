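# The user-facing "model" object: per-sector deterministic risk assessment
# fitted from a concentration table, with simulate() as the Monte Carlo
# companion.

#' Dietary risk assessment from a concentration table
#'
#' Runs the full deterministic chain on the fish-muscle records of a
#' concentration table: per (sector, element) the mean concentration is
#' mapped to estimated daily and weekly intake (EDI, EWI) and target hazard
#' quotient (THQ); per sector the hazard index (HI, exact sum of THQs), the
#' per-carcinogen cancer risk (CR) and the total cancer risk (TCR) with its
#' acceptability classification.
#'
#' @param data A concentration table containing muscle records (other
#'   matrices are ignored by the risk chain but may be present).
#' @param exposure An [exposure_params()] object.
#' @param toxicity A [toxicity_params()] object.
#' @param cr_mode Cancer-risk scale mode, `"as_printed"` (default) or
#'   `"unscaled"`; see [cancer_risk()].
#' @param center Summary used as the "mean metal concentration" entering
#'   the chain: `"mean"` (default, as the intake equations are written) or
#'   `"median"` (the robust summary the monitoring tables print).
#' @return An object of class `"dietary_risk"`: a list with elements
#'   `concentrations` (per sector x element: n, mean, sd, center value
#'   used), `intake` (per sector x element: EDI, EWI, THQ), `hazard` (per
#'   sector: HI and HI > 1 flag), `cancer` (per sector x carcinogen: EDI,
#'   CR), `tcr` (per sector: TCR and classification), plus the parameter
#'   objects, `cr_mode`, `center` and the matched call.
#' @examples
#' x <- generate_concentrations(seed = 1)
#' fit <- dietary_risk(x)
#' fit
#' summary(fit)
#' @seealso [simulate.dietary_risk()] for Monte Carlo propagation.
#' @export
dietary_risk <- function(data, exposure = exposure_params(),
                         toxicity = toxicity_params(),
                         cr_mode = c("as_printed", "unscaled"),
                         center = c("mean", "median")) {
  cr_mode <- match.arg(cr_mode)
  center <- match.arg(center)
  stopifnot(inherits(exposure, "exposure_params"),
            inherits(toxicity, "toxicity_params"))
  data <- validate_concentrations(data)
  muscle <- data[data$matrix == "muscle", ]
  if (nrow(muscle) == 0L)
    stop("no muscle records: the dietary risk chain needs fish-muscle ",
         "concentrations", call. = FALSE)

  conc <- summarize_concentrations(muscle)
  conc$center <- if (center == "mean") conc$mean else conc$median
  conc <- conc[, c("sector", "element", "n", "mean", "sd", "median",
                   "center")]

  intake <- conc[, c("sector", "element")]
  intake$EDI <- edi(conc$center, conc$element, exposure)
  intake$EWI <- ewi(intake$EDI)
  intake$THQ <- thq(conc$center, conc$element, exposure, toxicity)

  sectors <- unique(conc$sector)
  sectors <- sectors[order(match(sectors, .SECTORS))]

  hazard <- do.call(rbind, lapply(sectors, function(s) {
    hi <- hazard_index(intake$THQ[intake$sector == s])
    data.frame(sector = s, HI = as.numeric(hi),
               exceeds = attr(hi, "exceeds"), stringsAsFactors = FALSE)
  }))

  carcs <- intersect(toxicity$carcinogens, unique(conc$element))
  if (length(carcs) == 0L)
    stop("no carcinogenic elements present in the data", call. = FALSE)
  cancer <- do.call(rbind, lapply(sectors, function(s) {
    rows <- intake[intake$sector == s & intake$element %in% carcs, ]
    cr <- cancer_risk(rows$EDI, toxicity$CSF[rows$element],
                      exposure, cr_mode)
    data.frame(sector = s, element = rows$element, EDI = rows$EDI,
               CR = as.numeric(cr), stringsAsFactors = FALSE)
  }))
  tcr <- do.call(rbind, lapply(sectors, function(s) {
    t <- total_cancer_risk(cancer$CR[cancer$sector == s])
    data.frame(sector = s, TCR = as.numeric(t),
               classification = attr(t, "classification"),
               stringsAsFactors = FALSE)
  }))

  structure(list(concentrations = conc, intake = intake, hazard = hazard,
                 cancer = cancer, tcr = tcr, exposure = exposure,
                 toxicity = toxicity, cr_mode = cr_mode, center = center,
                 sectors = sectors, call = match.call()),
            class = "dietary_risk")
}

#' @export
print.dietary_risk <- function(x, digits = 4, ...) {
  cat("Dietary heavy-metal risk assessment (", x$center,
      " concentration, CR mode: ", x$cr_mode, ")\n\n", sep = "")
  tab <- merge(x$hazard, x$tcr, by = "sector", sort = FALSE)
  tab <- tab[match(x$sectors, tab$sector), ]
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Summary tables for a dietary risk assessment
#'
#' Produces the wide per-sector hazard table (one THQ column per element
#' plus HI) and the cancer-risk table (per-carcinogen CR, TCR,
#' classification).
#'
#' @param object A `"dietary_risk"` object.
#' @param ... Unused.
#' @return An object of class `"summary.dietary_risk"` with components
#'   `hazard_table` and `cancer_table`.
#' @export
summary.dietary_risk <- function(object, ...) {
  elems <- unique(object$intake$element)
  wide <- data.frame(sector = object$sectors, stringsAsFactors = FALSE)
  for (e in elems) {
    v <- object$intake[object$intake$element == e, ]
    wide[[paste0("THQ_", e)]] <- v$THQ[match(object$sectors, v$sector)]
  }
  wide$HI <- object$hazard$HI[match(object$sectors, object$hazard$sector)]

  cwide <- data.frame(sector = object$sectors, stringsAsFactors = FALSE)
  for (e in unique(object$cancer$element)) {
    v <- object$cancer[object$cancer$element == e, ]
    cwide[[paste0("CR_", e)]] <- v$CR[match(object$sectors, v$sector)]
  }
  cwide$TCR <- object$tcr$TCR[match(object$sectors, object$tcr$sector)]
  cwide$classification <-
    object$tcr$classification[match(object$sectors, object$tcr$sector)]

  structure(list(hazard_table = wide, cancer_table = cwide,
                 cr_mode = object$cr_mode, center = object$center),
            class = "summary.dietary_risk")
}

#' @export
print.summary.dietary_risk <- function(x, digits = 4, ...) {
  cat("Target hazard quotients and hazard index by sector:\n")
  print(format(x$hazard_table, digits = digits), row.names = FALSE)
  cat("\nCarcinogenic risk by sector (mode: ", x$cr_mode, "):\n", sep = "")
  print(format(x$cancer_table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.dietary_risk <- function(object, ...) {
  stats::setNames(object$hazard$HI, object$hazard$sector)
}
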
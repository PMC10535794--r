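#' Reported hazard-quotient reference table for the study area
#'
#' The metal-exposure assessment published for rainbow trout consumption on
#' the Tishgo River reports, per sector, the target hazard quotients of Cu,
#' Pb, Zn and As (rounded to 4 decimals) and the hazard index. The table is
#' provided as a reference surface for internal-consistency checks (the
#' hazard index is defined as the exact sum of the quotients) and for
#' side-by-side reporting; it is not used by the risk chain itself.
#'
#' @return Data frame with columns `sector`, `THQ_Cu`, `THQ_Pb`, `THQ_Zn`,
#'   `THQ_As`, `HI`.
#' @examples
#' ref <- reference_hazard_table()
#' rowSums(ref[, c("THQ_Cu", "THQ_Pb", "THQ_Zn", "THQ_As")]) - ref$HI
#' @export
reference_hazard_table <- function() {
  data.frame(
    sector = c("lower", "middle", "upper"),
    THQ_Cu = c(0.0004, 0.0004, 0.0003),
    THQ_Pb = c(0.1954, 0.1547, 0.1384),
    THQ_Zn = c(0.0007, 0.0007, 0.0007),
    THQ_As = c(0.0299, 0.0054, 0.0027),
    HI     = c(0.2264, 0.1613, 0.1421),
    stringsAsFactors = FALSE
  )
}
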
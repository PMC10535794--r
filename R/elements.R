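# Element registry: toxicological constants per element symbol.
# ARm values follow the study design (Pb 33%, As 75%, others complete
# absorption); RfD defaults are the USEPA IRIS oral reference doses; CSF is
# defined for the two carcinogens considered (As, Pb).

.registry <- new.env(parent = emptyenv())

.builtin_elements <- function() {
  data.frame(
    symbol     = c("As", "Cu", "Pb", "Zn"),
    arm        = c(0.75, 1.00, 0.33, 1.00),
    rfd        = c(3e-04, 4e-02, 3.5e-03, 3e-01),
    csf        = c(1.5, NA, 0.0085, NA),
    carcinogen = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

.elements_table <- function() {
  if (is.null(.registry$elements)) .registry$elements <- .builtin_elements()
  .registry$elements
}

#' Element registry
#'
#' The package keeps a registry of element symbols together with the
#' toxicological constants the risk chain needs: the gastrointestinal
#' absorption efficiency `arm` (fraction in (0, 1]), the oral reference dose
#' `rfd` (mg/kg body weight/day), the cancer slope factor `csf`
#' ((mg/kg-day)^-1, `NA` for non-carcinogens) and a carcinogen flag.
#' The built-in registry covers As, Cu, Pb and Zn; further elements can be
#' registered but only with a full set of toxicity parameters.
#'
#' @return `elements()` returns the registry as a data frame with columns
#'   `symbol`, `arm`, `rfd`, `csf`, `carcinogen`.
#' @examples
#' elements()
#' element_params("Pb")$arm  # 0.33
#' @export
elements <- function() .elements_table()

#' @rdname elements
#' @param symbol Element symbol, e.g. `"As"`.
#' @param rfd Oral reference dose, mg/kg body weight/day (> 0).
#' @param arm Gastrointestinal absorption efficiency, fraction in (0, 1].
#' @param csf Cancer slope factor, (mg/kg-day)^-1; `NA` for non-carcinogens.
#' @param carcinogen Logical; defaults to `TRUE` when a `csf` is supplied.
#' @export
register_element <- function(symbol, rfd, arm = 1,
                             csf = NA_real_, carcinogen = !is.na(csf)) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nzchar(symbol))
  tab <- .elements_table()
  if (symbol %in% tab$symbol)
    stop("element '", symbol, "' is already registered", call. = FALSE)
  if (!is.numeric(rfd) || length(rfd) != 1L || !is.finite(rfd) || rfd <= 0)
    stop("`rfd` must be a single positive number", call. = FALSE)
  if (!is.numeric(arm) || length(arm) != 1L || !is.finite(arm) ||
      arm <= 0 || arm > 1)
    stop("`arm` must be a fraction in (0, 1]", call. = FALSE)
  if (isTRUE(carcinogen) && (!is.numeric(csf) || is.na(csf) || csf <= 0))
    stop("a carcinogenic element needs a positive `csf`", call. = FALSE)
  .registry$elements <- rbind(tab, data.frame(
    symbol = symbol, arm = arm, rfd = rfd, csf = as.numeric(csf),
    carcinogen = isTRUE(carcinogen), stringsAsFactors = FALSE))
  invisible(.registry$elements)
}

#' @rdname elements
#' @export
reset_elements <- function() {
  .registry$elements <- .builtin_elements()
  invisible(.registry$elements)
}

#' @rdname elements
#' @export
element_params <- function(symbol) {
  tab <- .elements_table()
  i <- match(symbol, tab$symbol)
  if (anyNA(i))
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(i)], collapse = ", "),
         " (register with register_element())", call. = FALSE)
  tab[i, , drop = FALSE]
}

# Sampling design vocabulary ------------------------------------------------

.SECTORS  <- c("upper", "middle", "lower")
.MATRICES <- c("muscle", "water", "sediment")

#' Measurement units per sample matrix
#'
#' Units are fixed by the matrix kind: wet-weight mg/kg for fish muscle,
#' mg/L for water, and mg/kg as reported for sediment (the monitoring data
#' do not state a dry/wet basis, so sediment values are carried unchanged).
#'
#' @param kind Character vector of matrix kinds
#'   (`"muscle"`, `"water"`, `"sediment"`).
#' @return Character vector of unit labels.
#' @examples
#' matrix_units("water")
#' @export
matrix_units <- function(kind) {
  u <- c(muscle = "mg/kg w/w", water = "mg/L",
         sediment = "mg/kg (as reported)")
  bad <- setdiff(unique(kind), names(u))
  if (length(bad))
    stop("unknown matrix kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(u[kind])
}
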
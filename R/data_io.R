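# Concentration-table IO and validation.
#
# Canonical long format: one row per (sector, matrix, element, replicate_id)
# with a non-negative concentration in the units fixed by the matrix kind.
# CSV dialect: comma separator, decimal point, UTF-8, header row required.

.CONC_COLUMNS <- c("sector", "matrix", "element", "replicate_id",
                   "concentration")

#' Validate a concentration table
#'
#' Checks the canonical long-format invariants: known sector, matrix and
#' element labels, integer replicate ids >= 1, non-negative finite
#' concentrations, and uniqueness of the (sector, matrix, element,
#' replicate_id) key. Violations raise an error naming the offending row(s);
#' missing values are rejected (the supported data contain no non-detects).
#'
#' @param x A data frame with columns `sector`, `matrix`, `element`,
#'   `replicate_id`, `concentration`.
#' @return The validated data frame (invisibly usable), with a `units`
#'   column attached from the matrix kind.
#' @export
validate_concentrations <- function(x) {
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.CONC_COLUMNS, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  fail <- function(what, rows) {
    stop(what, " in row(s): ",
         paste(utils::head(rows, 10L), collapse = ", "),
         if (length(rows) > 10L) " ..." else "", call. = FALSE)
  }
  rows <- seq_len(nrow(x))

  bad <- rows[!(x$sector %in% .SECTORS)]
  if (length(bad)) fail("unknown sector", bad)
  bad <- rows[!(x$matrix %in% .MATRICES)]
  if (length(bad)) fail("unknown matrix", bad)
  known <- .elements_table()$symbol
  bad <- rows[!(x$element %in% known)]
  if (length(bad)) fail("unknown element", bad)

  rid <- suppressWarnings(as.numeric(x$replicate_id))
  bad <- rows[is.na(rid) | rid < 1 | rid != round(rid)]
  if (length(bad)) fail("invalid replicate_id (integer >= 1 required)", bad)

  conc <- suppressWarnings(as.numeric(x$concentration))
  bad <- rows[is.na(conc) | !is.finite(conc)]
  if (length(bad)) fail("missing or non-numeric concentration", bad)
  bad <- rows[conc < 0]
  if (length(bad)) fail("negative concentration", bad)

  key <- paste(x$sector, x$matrix, x$element, rid, sep = "\r")
  bad <- rows[duplicated(key) | duplicated(key, fromLast = TRUE)]
  if (length(bad)) fail("duplicate (sector, matrix, element, replicate) key",
                        unique(bad))

  out <- data.frame(
    sector = as.character(x$sector),
    matrix = as.character(x$matrix),
    element = as.character(x$element),
    replicate_id = as.integer(rid),
    concentration = conc,
    stringsAsFactors = FALSE
  )
  out$units <- matrix_units(out$matrix)
  out
}

#' Read and write concentration tables
#'
#' `read_concentrations()` reads a CSV in the canonical long format and
#' validates every row; `write_concentrations()` writes one back so that a
#' read/write round trip reproduces the records exactly.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(concentration = "value_mgkg")`.
#' @return `read_concentrations()` returns a validated data frame with
#'   columns `sector`, `matrix`, `element`, `replicate_id`, `concentration`,
#'   `units`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' x <- generate_concentrations(n_replicates = 2, seed = 1)
#' write_concentrations(x, tf)
#' y <- read_concentrations(tf)
#' all.equal(x$concentration, y$concentration)
#' @export
read_concentrations <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), .CONC_COLUMNS)
    if (length(bad))
      stop("schema maps unknown column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw))
        stop("schema column '", src, "' not present in file", call. = FALSE)
      names(raw)[names(raw) == src] <- canonical
    }
  }
  validate_concentrations(raw)
}

#' @rdname read_concentrations
#' @param x A validated concentration table.
#' @export
write_concentrations <- function(x, path) {
  x <- validate_concentrations(x)
  utils::write.csv(x[, .CONC_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize concentrations per sampling cell
#'
#' Groups a concentration table by (sector, matrix, element) and reports the
#' replicate count, mean, standard deviation and median. The median uses the
#' midpoint of the two central order statistics for even n.
#'
#' @param x A concentration table (validated on entry).
#' @param by Grouping columns; the default is the full sampling cell.
#' @return Data frame with one row per group: grouping columns plus `units`,
#'   `n`, `mean`, `sd`, `median`.
#' @export
summarize_concentrations <- function(x,
                                     by = c("sector", "matrix", "element")) {
  x <- validate_concentrations(x)
  if (nrow(x) == 0L)
    stop("empty group: no records to summarize", call. = FALSE)
  key <- interaction(x[by], drop = TRUE, lex.order = TRUE)
  split_conc <- split(x$concentration, key)
  split_rows <- split(seq_len(nrow(x)), key)
  out <- do.call(rbind, lapply(names(split_conc), function(k) {
    v <- split_conc[[k]]
    first <- split_rows[[k]][1L]
    cbind(x[first, by, drop = FALSE],
          data.frame(units = x$units[first], n = length(v), mean = mean(v),
                     sd = stats::sd(v), median = stats::median(v),
                     stringsAsFactors = FALSE))
  }))
  out <- out[order(match(out$matrix, .MATRICES),
                   match(out$sector, .SECTORS),
                   out$element), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Guideline limits -----------------------------------------------------------

#' Regulatory maximum limits (ML)
#'
#' The built-in guideline registry holds one maximum limit per (matrix,
#' element): food-safety limits for fish muscle (FAO/WHO Codex; FSANZ for
#' As), USEPA water-quality criteria for water, and the Canadian interim
#' sediment quality guidelines (CEQG-ISQG) for sediment.
#'
#' @return `builtin_guidelines()` returns a 12-row data frame with columns
#'   `matrix`, `element`, `value`, `units`, `source`.
#' @examples
#' guideline_limit("muscle", "Pb")  # 0.3 mg/kg w/w
#' @export
builtin_guidelines <- function() {
  g <- data.frame(
    matrix  = rep(.MATRICES, each = 4L),
    element = rep(c("As", "Cu", "Pb", "Zn"), times = 3L),
    value   = c(2, 30, 0.3, 30,        # muscle, mg/kg w/w
                0.01, 1.3, 0.015, 5,   # water, mg/L
                5.9, 35.7, 35.0, 123), # sediment ISQG, mg/kg
    source  = c("FSANZ", "FAO/WHO", "FAO/WHO", "FAO/WHO",
                rep("USEPA", 4L), rep("CEQG-ISQG", 4L)),
    stringsAsFactors = FALSE
  )
  g$units <- matrix_units(g$matrix)
  g[, c("matrix", "element", "value", "units", "source")]
}

#' @rdname builtin_guidelines
#' @param matrix,element Vectors identifying the cell(s) to look up
#'   (recycled to a common length).
#' @param guidelines Guideline table; defaults to the built-in registry.
#' @export
guideline_limit <- function(matrix, element, guidelines = builtin_guidelines()) {
  n <- max(length(matrix), length(element))
  matrix <- rep_len(matrix, n)
  element <- rep_len(element, n)
  i <- match(paste(matrix, element), paste(guidelines$matrix, guidelines$element))
  if (anyNA(i))
    stop("no guideline limit for: ",
         paste(unique(paste0(matrix[is.na(i)], "/", element[is.na(i)])),
               collapse = ", "), call. = FALSE)
  guidelines$value[i]
}

#' @rdname builtin_guidelines
#' @param path Output CSV path.
#' @export
write_guidelines <- function(path, guidelines = builtin_guidelines()) {
  utils::write.csv(guidelines, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
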
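# Bioaccumulation factors: BCF (muscle vs water) and BSAF (muscle vs
# sediment), per replicate pair and summarized per (sector, element).

#' Bioconcentration and biosediment accumulation factors
#'
#' `bcf()` is the ratio of the contaminant concentration in the organism
#' (mg/kg) to that in water (mg/L); it quantifies uptake from the dissolved
#' phase. `bsaf()` is the ratio of the organism concentration to the
#' sediment concentration (both mg/kg) and quantifies accumulation from
#' sediment. Both are reported as plain quotients; BCF mixes mg/kg over
#' mg/L, so its "dimensionless" value follows the usual L/kg convention.
#'
#' @param c_organism Concentration(s) in the organism, mg/kg (>= 0).
#' @param c_water,c_sediment Concentration(s) in the reference matrix
#'   (strictly positive; a zero denominator is a domain error, never a
#'   silent infinity).
#' @return Numeric vector of ratios.
#' @examples
#' bcf(2.51, 0.05)    # 50.2
#' bsaf(0.20, 15.22)  # ~0.01314
#' @export
bcf <- function(c_organism, c_water) {
  .check_ratio_args(c_organism, c_water, "c_water")
  c_organism / c_water
}

#' @rdname bcf
#' @export
bsaf <- function(c_organism, c_sediment) {
  .check_ratio_args(c_organism, c_sediment, "c_sediment")
  c_organism / c_sediment
}

.check_ratio_args <- function(num, den, den_name) {
  if (!is.numeric(num) || !is.numeric(den))
    stop("concentrations must be numeric", call. = FALSE)
  if (any(!is.finite(num)) || any(num < 0))
    stop("`c_organism` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(den)) || any(den <= 0))
    stop("`", den_name, "` must be strictly positive (ratio undefined at ",
         "zero denominator)", call. = FALSE)
  invisible(TRUE)
}

#' Per-pair accumulation-factor profile
#'
#' Forms one factor per replicate pair — muscle vs water for BCF, muscle vs
#' sediment for BSAF — pairing samples by replicate id within each sector,
#' and summarizes the pairs per (sector, element). Because the median of
#' per-pair ratios generally differs from the ratio of cell medians, both
#' are reported (`median` and `ratio_of_medians`).
#'
#' @param x A concentration table (validated on entry).
#' @param kind `"BCF"` or `"BSAF"`.
#' @return An object of class `"factor_profile"`: a list with `pairs` (one
#'   row per replicate pair: sector, element, replicate_id, organism,
#'   reference, value) and `summary` (per sector x element: `n_pairs`,
#'   `median`, `min`, `max`, `ratio_of_medians`).
#' @examples
#' x <- generate_concentrations(seed = 1)
#' fp <- factor_profile(x, "BCF")
#' head(fp$summary)
#' @export
factor_profile <- function(x, kind = c("BCF", "BSAF")) {
  kind <- match.arg(kind)
  x <- validate_concentrations(x)
  ref_matrix <- if (kind == "BCF") "water" else "sediment"
  org <- x[x$matrix == "muscle", ]
  ref <- x[x$matrix == ref_matrix, ]
  if (nrow(org) == 0L || nrow(ref) == 0L)
    stop("need both muscle and ", ref_matrix, " records", call. = FALSE)

  key <- function(d) paste(d$sector, d$element, d$replicate_id, sep = "\r")
  i <- match(key(org), key(ref))
  if (anyNA(i)) {
    orphan <- org[is.na(i), ][1L, ]
    stop("unpaired replicate: no ", ref_matrix, " sample for (",
         orphan$sector, ", ", orphan$element, ", replicate ",
         orphan$replicate_id, ")", call. = FALSE)
  }
  if (length(setdiff(key(ref), key(org)))) {
    orphan <- ref[!key(ref) %in% key(org), ][1L, ]
    stop("unpaired replicate: no muscle sample for (", orphan$sector, ", ",
         orphan$element, ", replicate ", orphan$replicate_id, ")",
         call. = FALSE)
  }

  ratio_fun <- if (kind == "BCF") bcf else bsaf
  pairs <- data.frame(
    sector = org$sector, element = org$element,
    replicate_id = org$replicate_id,
    organism = org$concentration, reference = ref$concentration[i],
    stringsAsFactors = FALSE
  )
  pairs$value <- ratio_fun(pairs$organism, pairs$reference)

  grp <- interaction(pairs$sector, pairs$element, drop = TRUE)
  summary <- do.call(rbind, lapply(split(pairs, grp), function(d) {
    data.frame(
      sector = d$sector[1L], element = d$element[1L], kind = kind,
      n_pairs = nrow(d), median = stats::median(d$value),
      min = min(d$value), max = max(d$value),
      ratio_of_medians = ratio_fun(stats::median(d$organism),
                                   stats::median(d$reference)),
      stringsAsFactors = FALSE
    )
  }))
  summary <- summary[order(match(summary$sector, .SECTORS),
                           summary$element), ]
  rownames(summary) <- NULL
  structure(list(kind = kind, pairs = pairs, summary = summary),
            class = "factor_profile")
}

#' @export
print.factor_profile <- function(x, digits = 4, ...) {
  cat(x$kind, "profile (", nrow(x$pairs), "replicate pairs )\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.factor_profile <- function(x, ...) x$summary
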
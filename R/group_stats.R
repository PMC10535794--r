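# Nonparametric battery: Kruskal-Wallis across sectors, one-sample Wilcoxon
# signed-rank versus maximum limits, Spearman correlation across
# matrix-element pairs. The tests themselves are delegated to stats::.

.test_result <- function(test, statistic, p_value, n, grouping,
                         alpha = 0.05, extra = list()) {
  structure(c(list(test = test, statistic = statistic, p_value = p_value,
                   n = n, grouping = grouping,
                   significant = is.finite(p_value) && p_value < alpha,
                   alpha = alpha), extra),
            class = "risk_test_result")
}

#' @export
print.risk_test_result <- function(x, digits = 4, ...) {
  cat(x$test, "(", x$grouping, ")\n")
  cat("  statistic =", format(x$statistic, digits = digits),
      ", p =", format(x$p_value, digits = digits),
      if (x$significant) paste0(" (significant at alpha = ", x$alpha, ")")
      else "", "\n")
  invisible(x)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based comparison of two or more groups (e.g. river sectors) with
#' the usual tie correction; the H statistic is referred to a chi-squared
#' distribution with k - 1 degrees of freedom.
#'
#' @param groups A list of two or more numeric vectors.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A `"risk_test_result"` with the H `statistic`, `df`, `p_value`,
#'   per-group `n` and a significance flag.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("`groups` must be a list of at least two numeric vectors",
         call. = FALSE)
  n <- lengths(groups)
  if (any(n < 1L) || sum(n) < 3L)
    stop("each group needs >= 1 value and >= 3 values in total",
         call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  kt <- stats::kruskal.test(x, g)
  .test_result("Kruskal-Wallis rank sum test",
               unname(kt$statistic), unname(kt$p.value), n,
               paste(length(groups), "groups"), alpha,
               extra = list(df = unname(kt$parameter)))
}

#' One-sample Wilcoxon signed-rank test against a maximum limit
#'
#' Tests whether sample concentrations exceed (or differ from) a regulatory
#' maximum limit. Values exactly equal to the limit are dropped before
#' ranking; the exact signed-rank distribution is used for n <= 25 when
#' there are no ties in the absolute differences, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param values Numeric sample.
#' @param ml The maximum limit to compare against (> 0).
#' @param alternative `"greater"` (significant exceedance, the flag
#'   convention of monitoring tables) or `"two.sided"`.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A `"risk_test_result"` with the signed-rank `statistic` (the
#'   positive-rank sum), `p_value`, effective `n` and significance flag.
#' @examples
#' wilcoxon_vs_limit(c(1, 2, 3), 2)  # symmetric: p = 1
#' @export
wilcoxon_vs_limit <- function(values, ml,
                              alternative = c("greater", "two.sided"),
                              alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (!is.numeric(ml) || length(ml) != 1L || !is.finite(ml) || ml <= 0)
    stop("`ml` must be a single positive limit", call. = FALSE)
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values)))
    stop("`values` must be a non-empty finite numeric vector",
         call. = FALSE)
  kept <- values[values != ml]
  if (length(kept) == 0L)
    stop("degenerate input: all values equal the maximum limit; the ",
         "signed-rank test is undefined", call. = FALSE)
  exact <- length(kept) <= 25L
  wt <- suppressWarnings(
    stats::wilcox.test(kept, mu = ml, alternative = alternative,
                       exact = exact, correct = TRUE)
  )
  .test_result(paste0("Wilcoxon signed-rank vs limit (", alternative, ")"),
               unname(wt$statistic), unname(wt$p.value), length(kept),
               paste0("ml = ", format(ml)), alpha,
               extra = list(ml = ml, alternative = alternative,
                            dropped_zeros = length(values) - length(kept)))
}

#' Exceedance screening of every sampling cell against its limit
#'
#' Applies [wilcoxon_vs_limit()] to each (sector, matrix, element) cell of
#' a concentration table using the registered guideline limits, mirroring
#' the asterisk convention of monitoring summary tables (significant
#' exceedance of the maximum limit).
#'
#' @param x A concentration table.
#' @param guidelines Guideline table (default [builtin_guidelines()]).
#' @param alternative,alpha Passed to [wilcoxon_vs_limit()].
#' @return Data frame per cell: `sector`, `matrix`, `element`, `n`,
#'   `median`, `ml`, `source`, `p_value`, `exceeds` (the flag).
#' @export
compare_with_limits <- function(x, guidelines = builtin_guidelines(),
                                alternative = "greater", alpha = 0.05) {
  x <- validate_concentrations(x)
  grp <- interaction(x$sector, x$matrix, x$element, drop = TRUE)
  out <- do.call(rbind, lapply(split(x, grp), function(d) {
    ml <- guideline_limit(d$matrix[1L], d$element[1L], guidelines)
    src <- guidelines$source[guidelines$matrix == d$matrix[1L] &
                               guidelines$element == d$element[1L]]
    res <- tryCatch(
      wilcoxon_vs_limit(d$concentration, ml, alternative, alpha),
      error = function(e) NULL)
    data.frame(
      sector = d$sector[1L], matrix = d$matrix[1L], element = d$element[1L],
      n = nrow(d), median = stats::median(d$concentration), ml = ml,
      source = src,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      exceeds = if (is.null(res)) FALSE else res$significant,
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(match(out$matrix, .MATRICES),
                   match(out$sector, .SECTORS), out$element), ]
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix across matrix-element pairs
#'
#' Aligns records by (sector, replicate_id) and correlates every
#' matrix-element pair (labels like `"As-m"`, `"Pb-w"`, `"Zn-s"` for
#' muscle/water/sediment) using Spearman's rank correlation with average
#' ranks for ties. Sectors are pooled by default (n = sectors x
#' replicates), matching a single whole-river correlation panel; set
#' `per_sector = TRUE` for one matrix per sector.
#'
#' @param x A concentration table.
#' @param per_sector Return a named list of per-sector matrices instead of
#'   the pooled matrix.
#' @return An object of class `"correlation_matrix"`: list with `rho`
#'   (symmetric, unit diagonal), `p` (per-cell p-values, asymptotic t
#'   approximation), `n` and `labels`. Convert to long format with
#'   [as.data.frame()].
#' @export
spearman_matrix <- function(x, per_sector = FALSE) {
  x <- validate_concentrations(x)
  if (per_sector) {
    out <- lapply(split(x, x$sector), spearman_matrix, per_sector = FALSE)
    return(out[order(match(names(out), .SECTORS))])
  }
  x$label <- paste0(x$element, "-", substr(x$matrix, 1L, 1L))
  labels <- unique(x$label[order(match(x$matrix, .MATRICES), x$element)])
  rows <- unique(x[, c("sector", "replicate_id")])
  rows <- rows[order(match(rows$sector, .SECTORS), rows$replicate_id), ]
  rowkey <- paste(rows$sector, rows$replicate_id)
  wide <- matrix(NA_real_, nrow(rows), length(labels),
                 dimnames = list(rowkey, labels))
  idx <- cbind(match(paste(x$sector, x$replicate_id), rowkey),
               match(x$label, labels))
  wide[idx] <- x$concentration
  if (anyNA(wide)) {
    bad <- which(is.na(wide), arr.ind = TRUE)[1L, ]
    stop("pairing error: no record for (", rowkey[bad[1L]], ") x ",
         labels[bad[2L]], call. = FALSE)
  }
  if (nrow(wide) < 3L)
    stop("need at least 3 aligned replicates per cell", call. = FALSE)

  rho <- stats::cor(wide, method = "spearman")
  k <- length(labels)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ct <- suppressWarnings(
      stats::cor.test(wide[, i], wide[, j], method = "spearman",
                      exact = FALSE))
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(rho = rho, p = p, n = nrow(wide), labels = labels),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix (n =", x$n, "aligned replicates)\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' @export
as.data.frame.correlation_matrix <- function(x, ...) {
  k <- length(x$labels)
  ij <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- data.frame(var1 = x$labels[ij[, 1L]], var2 = x$labels[ij[, 2L]],
                    rho = x$rho[ij], p = x$p[ij],
                    stringsAsFactors = FALSE)
  out$bh_adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out[order(out$var1, out$var2), ]
}
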
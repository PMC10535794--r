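# Monte Carlo propagation of concentration uncertainty through the cancer
# risk chain. Concentration distributions are parameterized by (mean, sd):
# lognormal via moment matching, or a normal truncated at zero whose
# pre-truncation parameters are the stated mean/sd (the truncation biases
# the realized mean upward; documented, not corrected).

#' Concentration distribution from a (mean, sd) summary
#'
#' Builds a non-negative sampling distribution for a concentration from its
#' reported mean and standard deviation. `"lognormal"` matches the first
#' two moments exactly (`sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2 / 2`). `"normal_truncated"` draws from a
#' normal with the given pre-truncation mean and sd, conditioned on being
#' >= 0. A zero sd gives a point mass at the mean.
#'
#' @param mean Target mean (> 0, or >= 0 when `sd = 0`).
#' @param sd Target standard deviation (>= 0).
#' @param family `"lognormal"` or `"normal_truncated"`.
#' @return An object of class `"distribution_spec"`.
#' @examples
#' spec <- fit_distribution(0.24, 0.05)
#' mean(rdist(spec, 1e5))  # close to 0.24
#' @export
fit_distribution <- function(mean, sd,
                             family = c("lognormal", "normal_truncated")) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean < 0)
    stop("`mean` must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("`sd` must be a single finite non-negative number", call. = FALSE)
  if (sd == 0) {
    return(structure(list(family = "point", mean = mean, sd = 0,
                          params = list(value = mean)),
                     class = "distribution_spec"))
  }
  if (mean <= 0)
    stop("`mean` must be > 0 for a non-degenerate distribution",
         call. = FALSE)
  params <- switch(family,
    lognormal = {
      sdlog <- sqrt(log(1 + (sd / mean)^2))
      list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    },
    normal_truncated = list(mu = mean, sigma = sd)
  )
  structure(list(family = family, mean = mean, sd = sd, params = params),
            class = "distribution_spec")
}

#' @rdname fit_distribution
#' @param spec A `"distribution_spec"` object.
#' @param n Number of draws.
#' @export
rdist <- function(spec, n) {
  stopifnot(inherits(spec, "distribution_spec"))
  qdist(spec, stats::runif(n))
}

#' @rdname fit_distribution
#' @param p Probabilities.
#' @export
qdist <- function(spec, p) {
  stopifnot(inherits(spec, "distribution_spec"))
  switch(spec$family,
    point = rep(spec$params$value, length(p)),
    lognormal = stats::qlnorm(p, spec$params$meanlog, spec$params$sdlog),
    normal_truncated = {
      p0 <- stats::pnorm(0, spec$params$mu, spec$params$sigma)
      stats::qnorm(p0 + p * (1 - p0), spec$params$mu, spec$params$sigma)
    }
  )
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat("distribution_spec:", x$family,
      sprintf("(mean %.4g, sd %.4g)\n", x$mean, x$sd))
  invisible(x)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's stream
# (the simulate.lm idiom).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Monte Carlo simulation of total cancer risk
#'
#' Draws `n_draws` independent concentration vectors for the carcinogens,
#' maps each through the deterministic chain (EDI, CR, TCR), and estimates
#' the probability that TCR exceeds an acceptability threshold, with its
#' binomial Monte Carlo standard error `sqrt(p(1-p)/n)` and percentile
#' summaries at the requested confidence level. Draws are generated
#' element-major (all draws for the first carcinogen, then the next) from a
#' single seeded stream, so results are bit-reproducible. An optional rank
#' correlation between element concentrations is available through a
#' Gaussian copula.
#'
#' @param specs Named list of [fit_distribution()] specs, one per
#'   carcinogen (must cover every element in `toxicity$carcinogens`).
#' @param exposure An [exposure_params()] object.
#' @param toxicity A [toxicity_params()] object.
#' @param n_draws Number of simulations (default 10000).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param threshold TCR acceptability cutoff (default 1e-4, the upper bound
#'   of the conventional band).
#' @param confidence Level for the percentile summary (default 0.95).
#' @param cr_mode Cancer-risk scale mode; see [cancer_risk()].
#' @param rank_correlation Pairwise correlation of the underlying Gaussian
#'   copula (default 0: independent elements).
#' @return An object of class `"mc_risk"`: TCR draws, the per-element CR
#'   matrix, `exceedance_probability`, `mc_se`, `percentiles`, and a config
#'   echo (threshold, n_draws, seed, family, mode).
#' @examples
#' specs <- list(As = fit_distribution(0.11, 0.03),
#'               Pb = fit_distribution(0.24, 0.05))
#' sim <- simulate_tcr(specs, n_draws = 1000, seed = 1)
#' sim$exceedance_probability
#' @export
simulate_tcr <- function(specs, exposure = exposure_params(),
                         toxicity = toxicity_params(), n_draws = 10000,
                         seed = NULL, threshold = 1e-4, confidence = 0.95,
                         cr_mode = c("as_printed", "unscaled"),
                         rank_correlation = 0) {
  cr_mode <- match.arg(cr_mode)
  stopifnot(inherits(exposure, "exposure_params"),
            inherits(toxicity, "toxicity_params"))
  if (!is.numeric(n_draws) || n_draws < 1)
    stop("`n_draws` must be >= 1", call. = FALSE)
  n_draws <- as.integer(n_draws)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` must be > 0", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  if (abs(rank_correlation) >= 1)
    stop("`rank_correlation` must be in (-1, 1)", call. = FALSE)
  carcs <- toxicity$carcinogens
  missing_spec <- setdiff(carcs, names(specs))
  if (length(missing_spec))
    stop("missing distribution spec for carcinogen(s): ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  ok <- vapply(specs[carcs], inherits, logical(1), "distribution_spec")
  if (!all(ok))
    stop("all specs must be distribution_spec objects", call. = FALSE)

  conc <- .with_seed(seed, {
    if (rank_correlation == 0) {
      # element-major: one full column of draws per carcinogen, in order
      vapply(carcs, function(e) rdist(specs[[e]], n_draws),
             numeric(n_draws))
    } else {
      k <- length(carcs)
      z <- matrix(stats::rnorm(n_draws * k), n_draws, k)
      r <- matrix(rank_correlation, k, k); diag(r) <- 1
      z <- z %*% chol(r)
      u <- stats::pnorm(z)
      m <- vapply(seq_along(carcs),
                  function(j) qdist(specs[[carcs[j]]], u[, j]),
                  numeric(n_draws))
      colnames(m) <- carcs
      m
    }
  })
  conc <- matrix(conc, nrow = n_draws,
                 dimnames = list(NULL, carcs))

  cr <- vapply(carcs, function(e) {
    as.numeric(cancer_risk(edi(conc[, e], e, exposure),
                           toxicity$CSF[[e]], exposure, cr_mode))
  }, numeric(n_draws))
  cr <- matrix(cr, nrow = n_draws, dimnames = list(NULL, carcs))
  tcr <- rowSums(cr)

  p <- mean(tcr > threshold)
  alpha <- (1 - confidence) / 2
  pct <- stats::quantile(tcr, c(alpha, 0.5, 1 - alpha), names = TRUE)
  structure(list(
    draws = tcr, cr = cr,
    exceedance_probability = p,
    mc_se = sqrt(p * (1 - p) / n_draws),
    percentiles = pct,
    config = list(n_draws = n_draws, seed = seed, threshold = threshold,
                  confidence = confidence, cr_mode = cr_mode,
                  rank_correlation = rank_correlation,
                  families = vapply(specs[carcs], `[[`, "", "family"))
  ), class = "mc_risk")
}

#' @export
print.mc_risk <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat("Monte Carlo total cancer risk (", cfg$n_draws, " draws, mode ",
      cfg$cr_mode, ")\n", sep = "")
  cat(sprintf("  P(TCR > %.3g) = %.4g (MC se %.3g)\n", cfg$threshold,
              x$exceedance_probability, x$mc_se))
  cat("  percentiles:",
      paste(names(x$percentiles), format(x$percentiles, digits = digits),
            collapse = ", "), "\n")
  invisible(x)
}

#' Exceedance curve over a grid of thresholds
#'
#' Re-evaluates the exceedance probability of a set of TCR draws over a
#' sorted grid of thresholds; the curve is non-increasing by construction.
#'
#' @param x An `"mc_risk"` object or a numeric vector of TCR draws.
#' @param thresholds Strictly positive, sorted increasing thresholds.
#' @return Data frame with columns `threshold`, `exceedance_probability`,
#'   `mc_se`.
#' @export
threshold_sweep <- function(x, thresholds) {
  draws <- if (inherits(x, "mc_risk")) x$draws else x
  if (!is.numeric(draws) || length(draws) == 0L)
    stop("`x` must be an mc_risk object or a numeric vector of draws",
         call. = FALSE)
  if (any(thresholds <= 0))
    stop("thresholds must be positive", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be sorted in strictly increasing order",
         call. = FALSE)
  p <- vapply(thresholds, function(t) mean(draws > t), numeric(1))
  data.frame(threshold = thresholds, exceedance_probability = p,
             mc_se = sqrt(p * (1 - p) / length(draws)))
}

#' Monte Carlo simulation method for dietary risk assessments
#'
#' Propagates the per-sector concentration uncertainty of a fitted
#' [dietary_risk()] object through the cancer-risk chain: for each sector a
#' distribution is fitted to the muscle mean/sd of every carcinogen and
#' [simulate_tcr()] is run.
#'
#' @param object A `"dietary_risk"` object.
#' @param nsim Number of draws per sector (default 10000).
#' @param seed Integer seed; sector streams are derived as `seed + 0, 1,
#'   ...` in sector order so sectors are independent but reproducible.
#' @param family Distribution family for [fit_distribution()].
#' @param threshold,confidence,rank_correlation Passed to [simulate_tcr()].
#' @param ... Unused.
#' @return A named list of `"mc_risk"` objects, one per sector, with class
#'   `"mc_risk_by_sector"`.
#' @export
simulate.dietary_risk <- function(object, nsim = 10000, seed = NULL,
                                  family = c("lognormal",
                                             "normal_truncated"),
                                  threshold = 1e-4, confidence = 0.95,
                                  rank_correlation = 0, ...) {
  family <- match.arg(family)
  carcs <- object$toxicity$carcinogens
  out <- lapply(seq_along(object$sectors), function(i) {
    s <- object$sectors[i]
    cc <- object$concentrations
    specs <- lapply(carcs, function(e) {
      row <- cc[cc$sector == s & cc$element == e, ]
      if (nrow(row) == 0L)
        stop("sector '", s, "' has no muscle data for carcinogen '", e,
             "'", call. = FALSE)
      sdv <- row$sd
      if (is.na(sdv)) sdv <- 0   # single replicate: degenerate spread
      fit_distribution(row$mean, sdv, family)
    })
    names(specs) <- carcs
    simulate_tcr(specs, object$exposure, object$toxicity, n_draws = nsim,
                 seed = if (is.null(seed)) NULL else seed + i - 1L,
                 threshold = threshold, confidence = confidence,
                 cr_mode = object$cr_mode,
                 rank_correlation = rank_correlation)
  })
  names(out) <- object$sectors
  structure(out, class = "mc_risk_by_sector")
}

#' @export
print.mc_risk_by_sector <- function(x, ...) {
  for (s in names(x)) {
    cat("--", s, "course --\n")
    print(x[[s]], ...)
  }
  invisible(x)
}

#' @export
as.data.frame.mc_risk_by_sector <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(s) {
    r <- x[[s]]; cfg <- r$config
    data.frame(sector = s, threshold = cfg$threshold,
               n_draws = cfg$n_draws,
               seed = if (is.null(cfg$seed)) NA_integer_ else cfg$seed,
               exceedance_probability = r$exceedance_probability,
               mc_se = r$mc_se,
               p2.5 = unname(r$percentiles[1L]),
               p50 = unname(r$percentiles[2L]),
               p97.5 = unname(r$percentiles[3L]),
               stringsAsFactors = FALSE)
  }))
}
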
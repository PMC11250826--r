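## Non-coding element burden testing. Passenger mutations calibrate
## per-trinucleotide-context mutation rates; an element's expected burden is
## the sum over its context composition and per-sample exposure factors; the
## observed count is tested against a negative-binomial background whose
## dispersion is fitted on passenger elements. P-values from multiple
## methods are combined with Empirical Brown's method, and
## Benjamini-Hochberg controls the FDR across elements.

#' Per-context mutation rates from passenger mutations
#'
#' Rate of each of the 96 single-base-substitution channels
#' (pyrimidine-centred trinucleotide x alternative base) estimated as
#' passenger count / mutational opportunity. Satisfies
#' \eqn{\sum_c rate_c \times opportunity_c = total count} by construction.
#'
#' @param muts passenger mutation data.frame (must exclude tested elements)
#'   with trinucleotide and alt columns
#' @param opportunity data.frame with context
#'   (\code{"<tri>:<alt>"}) and opportunity (site count x samples) columns
#' @return opportunity with added count and rate columns
#' @export
contextRates <- function(muts, opportunity) {
  key <- paste0(muts$trinucleotide, ":", muts$alt)
  counts <- table(factor(key, levels = opportunity$context))
  opportunity$count <- as.integer(counts)
  zero <- opportunity$opportunity == 0
  if (any(zero)) warning(sum(zero), " context(s) with zero opportunity; rate set to 0")
  opportunity$rate <- ifelse(zero, 0, opportunity$count / opportunity$opportunity)
  opportunity
}

#' Per-sample exposure factors
#'
#' @param muts passenger mutations with sample_id
#' @return named vector: per-sample burden divided by the cohort mean burden
#' @export
sampleFactors <- function(muts) {
  tab <- table(muts$sample_id)
  f <- as.numeric(tab) / mean(tab)
  stats::setNames(f, names(tab))
}

#' Expected element burden under the context model
#'
#' @param element_opp data.frame with element_id, context, opportunity
#'   (context site counts inside each element, one genome copy)
#' @param rates from \code{\link{contextRates}}
#' @param factors per-sample factors from \code{\link{sampleFactors}}
#' @return named vector of expected counts per element
#' @export
expectedElementBurden <- function(element_opp, rates, factors) {
  r <- stats::setNames(rates$rate, rates$context)
  element_opp$exp1 <- element_opp$opportunity * r[element_opp$context]
  per_elem <- tapply(element_opp$exp1, element_opp$element_id, sum)
  stats::setNames(as.vector(per_elem) * sum(factors), names(per_elem))
}

#' Negative-binomial burden test per element
#'
#' Upper-tail probability of seeing at least the observed count under a
#' negative-binomial background with the model-expected mean. Dispersion is
#' estimated by method of moments on passenger elements (observed vs
#' expected pairs); if no overdispersion is detectable the test collapses
#' to Poisson.
#'
#' @param observed named vector of observed element counts
#' @param expected matching expected counts (> 0)
#' @param passenger_obs,passenger_exp optional passenger-element counts for
#'   the dispersion fit; defaults to the tested elements themselves
#' @param theta NB size parameter; overrides the fit if given
#' @return data.frame with element_id, observed, expected, p
#' @export
elementBurdenTest <- function(observed, expected, passenger_obs = observed,
                              passenger_exp = expected, theta = NULL) {
  if (any(expected <= 0)) stop("element with zero opportunity/expected count",
                               call. = FALSE)
  if (is.null(theta)) {
    ## moments: Var = mu + mu^2/theta  =>  1/theta = mean[((x-mu)^2 - mu)/mu^2]
    inv <- mean(((passenger_obs - passenger_exp)^2 - passenger_exp) /
                passenger_exp^2)
    theta <- if (inv <= 1e-8) Inf else 1 / inv
  }
  p <- if (is.infinite(theta)) {
    stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  } else {
    stats::pnbinom(observed - 1, size = theta, mu = expected,
                   lower.tail = FALSE)
  }
  data.frame(element_id = names(observed), observed = as.numeric(observed),
             expected = as.numeric(expected), p = pmin(p, 1),
             theta = theta, row.names = NULL, stringsAsFactors = FALSE)
}

#' Empirical Brown's method for combining dependent p-values
#'
#' Per element, the Fisher statistic \eqn{S = \sum_m -2 \ln p_m} is
#' referred to a scaled chi-square whose scale and degrees of freedom are
#' set from the empirical covariance of \eqn{-2 \ln p} across elements:
#' E = 2k, Var = 4k + 2 sum of pairwise covariances, scale c = Var/(2E),
#' df f = 2E^2/Var. With independent methods this reduces to Fisher's
#' method; with perfectly duplicated methods it returns the single-method
#' p-value. Requires enough elements to estimate the covariance.
#'
#' @param pmat numeric matrix, elements x methods; zeros are clamped to the
#'   smallest positive double with a warning
#' @param min_elements minimum rows for the covariance estimate (default 20)
#' @param cov_matrix optional covariance matrix of -2 log p to use in place
#'   of the empirical one (a diagonal matrix forces Fisher's method)
#' @return numeric vector of combined p-values
#' @export
combineEmpiricalBrown <- function(pmat, min_elements = 20,
                                  cov_matrix = NULL) {
  pmat <- as.matrix(pmat)
  k <- ncol(pmat)
  if (any(pmat == 0)) {
    warning("zero p-value(s) clamped to machine minimum")
    pmat[pmat == 0] <- .Machine$double.xmin
  }
  x <- -2 * log(pmat)
  S <- rowSums(x)
  if (k == 1) return(pmat[, 1])
  if (is.null(cov_matrix) && nrow(pmat) < min_elements) {
    stop("need >= ", min_elements, " elements to estimate the covariance",
         call. = FALSE)
  }
  cv <- if (is.null(cov_matrix)) stats::cov(x) else cov_matrix
  E <- 2 * k
  Var <- 4 * k + 2 * sum(cv[upper.tri(cv)])
  Var <- max(Var, E * 1e-6)
  cc <- Var / (2 * E)
  f <- 2 * E^2 / Var
  stats::pchisq(S / cc, df = f, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to \code{p.adjust}); monotonicity in
#' the sorted p-values is guaranteed by the procedure.
#'
#' @param p numeric vector of p-values in [0,1]
#' @return Q-values
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
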
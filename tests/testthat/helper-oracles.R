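## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## two-sided Fisher exact p by exhaustive hypergeometric enumeration over
## all tables with the observed margins
enumFisherP <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## brute-force maximum-likelihood estimate of gain time by grid search over
## the two-category multinomial P(multiplicity 2) implied by the state
gridPiML <- function(n1, n2, state, grid = seq(0, 1, by = 5e-4)) {
  p2 <- switch(state,
    "2+1" = grid / (3 - grid),
    "2+0" = grid / (2 - grid),
    "2+2" = 2 * grid / (4 - 2 * grid))
  ll <- ifelse(p2 > 0, n2 * log(p2), ifelse(n2 == 0, 0, -Inf)) +
    ifelse(p2 < 1, n1 * log(1 - p2), ifelse(n1 == 0, 0, -Inf))
  grid[which.max(ll)]
}

## Fisher's method for combining independent p-values
fisherCombine <- function(pmat) {
  S <- rowSums(-2 * log(pmat))
  pchisq(S, df = 2 * ncol(pmat), lower.tail = FALSE)
}

## small cohort for fast structural tests (cached per session)
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generateCohort(simulationConfig(n_tumours = 40), seed = 42)
    }
    cache
  }
})
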
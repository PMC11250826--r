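## Cohort-level relative ordering of driver events. Per-tumour timing calls
## (early-clonal / late-clonal / subclonal for mutations, molecular time pi
## for copy-number gains) define pairwise "matches"; a Bradley-Terry league
## fitted by minorisation-maximisation turns match results into event
## strengths, and the average finishing position with a tumour-level
## bootstrap CI summarises the cohort ordering.

.classRank <- c("early-clonal" = 1, "late-clonal" = 2, "subclonal" = 3,
                "clonal-NA" = NA)

## outcome of one match: 1 = a beats b (a earlier), 0 = b beats a, 0.5 = tie
.matchOutcome <- function(class_a, class_b, pi_a, pi_b, pi_margin = 0.05) {
  if (!is.na(pi_a) && !is.na(pi_b)) {           # CNA vs CNA: earlier pi wins
    d <- pi_b - pi_a
    return(if (d > pi_margin) 1 else if (d < -pi_margin) 0 else 0.5)
  }
  if (!is.na(pi_a) || !is.na(pi_b)) return(0.5) # mixed CNA/mutation: tie
  if (class_a == "clonal-NA" || class_b == "clonal-NA") {
    ## clonal with no within-clonal resolution: beats subclonal, else tie
    if (class_a == "clonal-NA" && class_b == "subclonal") return(1)
    if (class_b == "clonal-NA" && class_a == "subclonal") return(0)
    return(0.5)
  }
  ra <- .classRank[[class_a]]; rb <- .classRank[[class_b]]
  if (ra < rb) 1 else if (ra > rb) 0 else 0.5
}

#' Pairwise precedence matrix from per-tumour event calls
#'
#' For every pair of events co-called in a tumour, records a win for the
#' earlier event, a loss for the later, or a tie. Mutation timing classes
#' order early-clonal < late-clonal < subclonal; clonal-NA ties with the
#' early/late classes and beats subclonal. Copy-number events are compared
#' on molecular time pi with a tie margin.
#'
#' @param calls data.frame with columns sample_id, event, and either
#'   \code{timing} (a class from \code{\link{assignMutationTiming}}; NA for
#'   CNAs) or \code{pi} (numeric molecular time; NA for mutations)
#' @param pi_margin minimum pi difference counted as a win (default 0.05)
#' @return list with matrices \code{wins} and \code{ties} (events x events)
#'   and the de-duplicated calls
#' @export
pairwisePrecedence <- function(calls, pi_margin = 0.05) {
  if (is.null(calls$pi)) calls$pi <- NA_real_
  if (is.null(calls$timing)) calls$timing <- NA_character_
  ## one call per (sample, event)
  calls <- calls[!duplicated(calls[c("sample_id", "event")]), , drop = FALSE]
  events <- sort(unique(calls$event))
  k <- length(events)
  W <- matrix(0, k, k, dimnames = list(events, events))
  Tt <- matrix(0, k, k, dimnames = list(events, events))
  for (df in split(calls, calls$sample_id)) {
    if (nrow(df) < 2) next
    for (a in seq_len(nrow(df) - 1)) for (b in (a + 1):nrow(df)) {
      o <- .matchOutcome(df$timing[a], df$timing[b], df$pi[a], df$pi[b],
                         pi_margin)
      i <- df$event[a]; j <- df$event[b]
      if (o == 1) W[i, j] <- W[i, j] + 1
      else if (o == 0) W[j, i] <- W[j, i] + 1
      else { Tt[i, j] <- Tt[i, j] + 1; Tt[j, i] <- Tt[j, i] + 1 }
    }
  }
  list(wins = W, ties = Tt, calls = calls)
}

## Bradley-Terry strengths by MM iteration on win counts (ties already
## folded in as half-wins); small pseudo-win keeps the MLE finite under
## one-sided records without disturbing the ordering.
.btFit <- function(W, eps = 0.1, max_iter = 500, tol = 1e-8) {
  k <- nrow(W)
  played <- (W + t(W)) > 0
  Wp <- W
  Wp[played] <- Wp[played] + eps
  p <- rep(1, k)
  wi <- rowSums(Wp)
  for (it in seq_len(max_iter)) {
    denom <- vapply(seq_len(k), function(i) {
      j <- which(played[i, ])
      if (!length(j)) return(NA_real_)
      sum((Wp[i, j] + Wp[j, i]) / (p[i] + p[j]))
    }, numeric(1))
    pnew <- ifelse(is.na(denom) | wi == 0, p, wi / denom)
    pnew[is.na(denom)] <- NA
    pnew <- pnew / exp(mean(log(pnew), na.rm = TRUE))
    if (max(abs(pnew - p), na.rm = TRUE) < tol) { p <- pnew; break }
    p <- pnew
  }
  stats::setNames(p, rownames(W))
}

#' Fit the league model and rank events
#'
#' Bradley-Terry strengths are fitted on the precedence matrix (ties split
#' half-half); an event's finishing position is the rank of its strength
#' (1 = earliest). The CI comes from a bootstrap that resamples tumours,
#' recomputes the matrix and re-ranks.
#'
#' @param calls per-tumour event calls as in \code{\link{pairwisePrecedence}}
#' @param n_boot bootstrap replicates (default 500; 0 skips the bootstrap
#'   and reports the full-data positions only)
#' @param seed RNG seed
#' @param pi_margin tie margin for CNA comparisons
#' @return data.frame with event, position (full-data rank),
#'   mean_finishing_position, ci_low, ci_high, n_tumours
#' @export
runLeague <- function(calls, n_boot = 500, seed = 1L, pi_margin = 0.05) {
  pp <- pairwisePrecedence(calls, pi_margin)
  calls <- pp$calls
  rankOf <- function(W, Tt) {
    p <- .btFit(W + Tt / 2)
    r <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    r[ok] <- rank(-p[ok], ties.method = "average")
    stats::setNames(r, names(p))
  }
  events <- rownames(pp$wins)
  pos0 <- rankOf(pp$wins, pp$ties)
  ntum0 <- vapply(events, function(e)
    length(unique(calls$sample_id[calls$event == e])), integer(1))
  if (n_boot == 0) {
    return(data.frame(event = events, position = pos0[events],
                      mean_finishing_position = pos0[events],
                      ci_low = NA_real_, ci_high = NA_real_,
                      n_tumours = ntum0, row.names = NULL,
                      stringsAsFactors = FALSE))
  }
  sids <- unique(calls$sample_id)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample(sids, length(sids), replace = TRUE)
      res <- lapply(seq_along(pick), function(i) {
        df <- calls[calls$sample_id == pick[i], , drop = FALSE]
        df$sample_id <- paste0("b", i)
        df
      })
      ppb <- pairwisePrecedence(do.call(rbind, res), pi_margin)
      rb <- rankOf(ppb$wins, ppb$ties)
      out <- stats::setNames(rep(NA_real_, length(events)), events)
      out[names(rb)] <- rb
      out
    }, numeric(length(events)))
  })
  boot <- matrix(boot, nrow = length(events),
                 dimnames = list(events, NULL))
  ntum <- vapply(events, function(e)
    length(unique(calls$sample_id[calls$event == e])), integer(1))
  data.frame(
    event = events,
    position = pos0[events],
    mean_finishing_position = apply(boot, 1, mean, na.rm = TRUE),
    ci_low = apply(boot, 1, stats::quantile, 0.025, na.rm = TRUE),
    ci_high = apply(boot, 1, stats::quantile, 0.975, na.rm = TRUE),
    n_tumours = ntum, row.names = NULL, stringsAsFactors = FALSE)
}

#' Odds that a gene's driver mutations are clonal
#'
#' For each gene, forms the 2x2 table of clonal/subclonal mutation counts
#' in the gene versus all other driver genes, applies the Haldane-Anscombe
#' 0.5 correction when any cell is zero, and returns the odds ratio with a
#' Wald CI on the log scale. OR > 1 means mutations in the gene are more
#' likely clonal than driver mutations generally.
#'
#' @param counts data.frame with columns gene, clonal, subclonal (cohort
#'   mutation counts)
#' @return data.frame with gene, odds_ratio, ci_low, ci_high, p and the
#'   four table cells
#' @export
clonalityOdds <- function(counts) {
  totC <- sum(counts$clonal); totS <- sum(counts$subclonal)
  out <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$clonal[i]; b <- counts$subclonal[i]
    c_ <- totC - a; d <- totS - b
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- sqrt(sum(1 / cells))
    z <- stats::qnorm(0.975)
    data.frame(gene = counts$gene[i], odds_ratio = or,
               ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
               p = 2 * stats::pnorm(-abs(log(or) / se)),
               clonal = a, subclonal = b, rest_clonal = c_, rest_subclonal = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
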
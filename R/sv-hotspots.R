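## Detection of structural-variant breakpoint hotspots against a
## covariate-adjusted background. Simple-SV breakends are binned genome-wide;
## a negative-binomial regression on local genomic covariates (GC,
## replication timing, gene density, chromatin accessibility, repeats,
## expression) gives the expected density; piecewise-constant fitting on
## variance-stabilised counts proposes candidate segments; and a permutation
## test that redistributes breakends proportionally to the fitted background
## assigns each candidate an empirical p-value, BH-adjusted across
## candidates. Hotspots overlapping large late-replicating genes are flagged
## as likely fragile sites and excluded from the retained list.

#' Tile a genome into fixed-width bins
#'
#' @param genome data.frame with columns chrom, length (bp)
#' @param bin_size bin width in bp (default 100 kb)
#' @return data.frame with chrom, start, end (0-based half-open)
#' @export
makeBins <- function(genome, bin_size = 1e5) {
  stopifnot(bin_size > 0)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + bin_size, genome$length[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bin simple-SV breakends across the cohort
#'
#' Each structural variant labelled \code{simple} contributes both of its
#' breakends (the midpoints of the two BEDPE intervals); complex-event
#' breakends are excluded, as clustered rearrangements would swamp the
#' background model. Counts are summed over tumours.
#'
#' @param svs SV data.frame (BEDPE-convention columns, with complexity)
#' @param bins bin data.frame from \code{\link{makeBins}}, optionally with
#'   covariate columns
#' @return \code{bins} with an added \code{count} column
#' @export
collectBreakpoints <- function(svs, bins) {
  stopifnot(all(bins$end > bins$start))
  bins$count <- 0L
  if (!nrow(svs)) return(bins)
  simple <- svs[svs$complexity == "simple", , drop = FALSE]
  if (!nrow(simple)) return(bins)
  ends <- rbind(
    data.frame(chrom = simple$chrom1,
               pos = floor((simple$start1 + simple$end1) / 2)),
    data.frame(chrom = simple$chrom2,
               pos = floor((simple$start2 + simple$end2) / 2)))
  for (ch in unique(ends$chrom)) {
    bi <- which(bins$chrom == ch)
    if (!length(bi)) next
    p <- ends$pos[ends$chrom == ch]
    p <- p[p >= bins$start[bi[1]] & p < bins$end[bi[length(bi)]]]
    if (!length(p)) next
    idx <- findInterval(p, bins$start[bi])
    tab <- tabulate(idx, nbins = length(bi))
    bins$count[bi] <- bins$count[bi] + tab
  }
  bins
}

#' Fit the covariate-adjusted breakpoint background
#'
#' Negative-binomial regression (log link) of per-bin breakend counts on
#' the supplied covariate columns, with a log bin-width offset. Falls back
#' to Poisson with a warning if the NB fit does not converge (which also
#' happens, benignly, when the data are genuinely Poisson and the
#' dispersion is unbounded).
#'
#' @param track binned counts from \code{\link{collectBreakpoints}}
#' @param covariates character vector of covariate column names in
#'   \code{track}; may be empty for an intercept-only background
#' @return list with \code{mu} (fitted mean per bin), \code{theta} (NB
#'   size; Inf for Poisson), \code{family}, \code{coefficients}
#' @export
fitBackground <- function(track, covariates = NULL) {
  if (all(track$count == 0)) stop("all-zero counts: background not estimable",
                                  call. = FALSE)
  if (is.null(covariates)) {
    covariates <- setdiff(names(track), c("chrom", "start", "end", "count"))
  }
  rhs <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("count ~", rhs,
                                 "+ offset(log(end - start))"))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = track)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    if (is.null(fit)) warning("NB background did not converge; using Poisson")
    fit <- stats::glm(fml, data = track, family = stats::poisson())
    theta <- Inf
  } else theta <- fit$theta
  list(mu = as.numeric(stats::fitted(fit)), theta = theta,
       family = if (is.infinite(theta)) "poisson" else "negative-binomial",
       coefficients = stats::coef(fit))
}

## O(n^2) dynamic program for penalised least-squares segmentation
.pcf1d <- function(y, gamma) {
  n <- length(y)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {            # cost of segment y[i..j]
    s <- cs[j + 1] - cs[i]; s2 <- cs2[j + 1] - cs2[i]
    s2 - s^2 / (j - i + 1)
  }
  F <- c(-gamma, rep(Inf, n))        # F[t+1] = best cost of y[1..t]
  back <- integer(n)
  for (t in seq_len(n)) {
    costs <- vapply(seq_len(t), function(s) F[s] + gamma + sse(s, t),
                    numeric(1))
    back[t] <- which.min(costs)
    F[t + 1] <- costs[back[t]]
  }
  bounds <- integer(0); t <- n
  while (t > 0) { s <- back[t]; bounds <- c(s, bounds); t <- s - 1 }
  bounds                              # segment start indices
}

#' Piecewise-constant segmentation of the breakpoint profile
#'
#' Applies the Anscombe variance-stabilising transform to per-bin counts
#' and fits a penalised least-squares piecewise-constant signal per
#' chromosome (exact dynamic programming). Segments whose mean count
#' exceeds the local background mean are returned as hotspot candidates.
#'
#' @param track binned counts
#' @param background optional fit from \code{\link{fitBackground}}; if
#'   absent the chromosome mean is the background
#' @param gamma penalty per change-point on the VST scale; default
#'   \code{3 * log(n bins on the chromosome)}
#' @param min_fold minimum observed/expected ratio for a candidate
#'   (default 1.5)
#' @return data.frame of candidates: chrom, start, end, first_bin,
#'   n_bins, observed, expected
#' @export
segmentDensity <- function(track, background = NULL, gamma = NULL,
                           min_fold = 1.5) {
  mu <- if (is.null(background)) NULL else background$mu
  out <- list()
  for (ch in unique(track$chrom)) {
    bi <- which(track$chrom == ch)
    y <- 2 * sqrt(track$count[bi] + 3 / 8)     # Anscombe VST
    g <- if (is.null(gamma)) max(3 * log(length(bi)), 10) else gamma
    starts <- .pcf1d(y, g)
    ends <- c(starts[-1] - 1L, length(bi))
    muc <- if (is.null(mu)) rep(mean(track$count[bi]), length(bi)) else mu[bi]
    for (s in seq_along(starts)) {
      idx <- starts[s]:ends[s]
      obs <- sum(track$count[bi[idx]])
      exp_ <- sum(muc[idx])
      if (exp_ > 0 && obs / exp_ >= min_fold) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = track$start[bi[idx[1]]],
          end = track$end[bi[idx[length(idx)]]],
          first_bin = starts[s], n_bins = length(idx),
          observed = obs, expected = exp_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    first_bin = integer(0), n_bins = integer(0), observed = integer(0),
    expected = numeric(0)))
  do.call(rbind, out)
}

#' Permutation test for candidate hotspots
#'
#' Under the null, each chromosome's breakends are redistributed across its
#' bins with probability proportional to the fitted background mean,
#' preserving the per-chromosome total. A candidate's p-value is the
#' fraction of permutations in which the maximal window count of the same
#' bin-length anywhere on the chromosome reaches the observed count
#' (add-one corrected); BH adjustment across candidates gives Q, and
#' candidates with Q below the cutoff are flagged significant.
#'
#' @param candidates from \code{\link{segmentDensity}}
#' @param track binned counts
#' @param background from \code{\link{fitBackground}}
#' @param n_perm permutations (>= 100; default 1000)
#' @param seed RNG seed
#' @param q_cut FDR cutoff (default 0.05)
#' @return candidates with p_value, q_value, fold, significant columns
#' @export
callHotspots <- function(candidates, track, background, n_perm = 1000,
                         seed = 1L, q_cut = 0.05) {
  if (n_perm < 100) stop("n_perm < 100 gives too coarse a p-value resolution",
                         call. = FALSE)
  if (!nrow(candidates)) return(cbind(candidates, p_value = numeric(0),
                                      q_value = numeric(0), fold = numeric(0),
                                      significant = logical(0)))
  candidates$p_value <- NA_real_
  withr::with_seed(seed, {
    for (ch in unique(candidates$chrom)) {
      bi <- which(track$chrom == ch)
      Nc <- sum(track$count[bi])
      ci <- which(candidates$chrom == ch)
      if (Nc == 0) { candidates$p_value[ci] <- 1; next }
      prob <- background$mu[bi]
      prob <- prob / sum(prob)
      perm <- stats::rmultinom(n_perm, Nc, prob)   # bins x n_perm
      csum <- apply(perm, 2, cumsum)
      csum <- rbind(0, csum)
      for (i in ci) {
        L <- candidates$n_bins[i]
        nb <- length(bi)
        if (L >= nb) {
          mx <- rep(Nc, n_perm)
        } else {
          ws <- csum[(L + 1):(nb + 1), , drop = FALSE] -
            csum[1:(nb - L + 1), , drop = FALSE]
          mx <- apply(ws, 2, max)
        }
        candidates$p_value[i] <- (1 + sum(mx >= candidates$observed[i])) /
          (1 + n_perm)
      }
    }
  })
  candidates$q_value <- stats::p.adjust(candidates$p_value, method = "BH")
  candidates$fold <- candidates$observed / candidates$expected
  candidates$significant <- candidates$q_value < q_cut
  candidates
}

#' Flag hotspots at putative fragile sites
#'
#' A hotspot is flagged fragile when it overlaps a gene at least
#' \code{min_length} bp long in the latest-replicating quartile; such loci
#' rearrange for mechanistic rather than selective reasons and are removed
#' from the retained list.
#'
#' @param hotspots hotspot data.frame with chrom/start/end
#' @param genes gene annotation (chrom, start, end, gene, rt_quartile;
#'   quartile 4 = latest)
#' @param min_length minimum gene length in bp (default 600 kb)
#' @return hotspots with \code{fragile_flag}; the retained (non-fragile)
#'   subset is in attribute \code{"retained"}
#' @export
filterFragile <- function(hotspots, genes, min_length = 6e5) {
  flag <- rep(FALSE, nrow(hotspots))
  if (nrow(genes)) {
    frg <- genes[(genes$end - genes$start) >= min_length &
                 genes$rt_quartile == 4, , drop = FALSE]
    for (i in seq_len(nrow(hotspots))) {
      gi <- frg[frg$chrom == hotspots$chrom[i], , drop = FALSE]
      if (!nrow(gi)) next
      flag[i] <- any(gi$start < hotspots$end[i] & gi$end > hotspots$start[i])
    }
  }
  hotspots$fragile_flag <- flag
  attr(hotspots, "retained") <- hotspots[!flag, , drop = FALSE]
  hotspots
}

#' Full hotspot pipeline
#'
#' Bin simple-SV breakends, fit the covariate background, segment the
#' profile, permutation-test the candidates and (optionally) flag fragile
#' sites.
#'
#' @param svs SV data.frame
#' @param bins bins with covariate columns
#' @param covariates covariate column names (NULL = all non-coordinate)
#' @param n_perm,seed,q_cut permutation controls
#' @param genes optional gene annotation for fragile filtering
#' @param gamma optional segmentation penalty
#' @return significant hotspots (after fragile exclusion when genes given);
#'   full candidate table in attribute \code{"candidates"}
#' @export
svHotspots <- function(svs, bins, covariates = NULL, n_perm = 1000,
                       seed = 1L, q_cut = 0.05, genes = NULL, gamma = NULL) {
  track <- collectBreakpoints(svs, bins)
  bg <- fitBackground(track, covariates)
  cand <- segmentDensity(track, bg, gamma = gamma)
  called <- callHotspots(cand, track, bg, n_perm = n_perm, seed = seed,
                         q_cut = q_cut)
  hs <- called[called$significant, , drop = FALSE]
  if (!is.null(genes) && nrow(hs)) {
    hs <- filterFragile(hs, genes)
    out <- attr(hs, "retained")
    attr(out, "flagged") <- hs
  } else out <- hs
  attr(out, "candidates") <- called
  out
}
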
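## Mutation multiplicity, cancer cell fraction, clonality classification,
## molecular-time estimation of copy-number gains / WGD, and conversion of
## molecular time to years before sampling.
##
## A copy-number gain duplicates every mutation already present on the gained
## allele: those mutations sit at multiplicity 2 afterwards, while mutations
## acquired later sit at multiplicity 1. The ratio of multiplicity-2 to
## multiplicity-1 clonal mutations in the gained region therefore dates the
## gain on the mutational clock. With pi the fraction of clonal mutation
## accumulation elapsed at the gain, the expected per-unit-time allele counts
## give closed-form maximum-likelihood estimators:
##   2+1 (single-allele gain):  pi = 3 n2 / (n1 + 2 n2)
##   2+0 (gain with LOH) and 2+2 (WGD):  pi = 2 n2 / (n1 + 2 n2)

.GAIN_STATES <- c("2+1", "2+0", "2+2")

#' Estimate mutation multiplicity from read counts
#'
#' Standard VAF decomposition: the expected variant allele fraction of a
#' clonal mutation at multiplicity m in a tumour of purity rho with local
#' total copy number CNt is \eqn{m \rho / (\rho CNt + 2(1-\rho))}. Inverting
#' and rounding (half-up) gives the integer copy count bearing the mutation,
#' clamped to [1, major_cn].
#'
#' @param alt_count,total_depth variant and total read counts (vectorised)
#' @param purity tumour purity rho in (0,1]
#' @param major_cn,minor_cn allele-specific copy numbers of the segment
#' @return integer multiplicities
#' @export
#' @examples
#' estimateMultiplicity(50, 100, 1, 1, 1)          # 1
#' estimateMultiplicity(50, 100, 0.5, 2, 1)        # 2
estimateMultiplicity <- function(alt_count, total_depth, purity, major_cn,
                                 minor_cn) {
  .assertThat(
    "purity must be in (0,1]" = purity > 0 & purity <= 1,
    "total_depth must be > 0" = total_depth > 0,
    "CNt must be >= 1" = major_cn + minor_cn >= 1)
  cnt <- major_cn + minor_cn
  vaf <- alt_count / total_depth
  m_raw <- (vaf / purity) * (purity * cnt + 2 * (1 - purity))
  m <- roundHalfUp(m_raw)
  as.integer(pmin(pmax(m, 1), major_cn))
}

#' Cancer cell fraction with binomial confidence interval
#'
#' \eqn{CCF = VAF (\rho CNt + 2(1-\rho)) / (\rho m)}, capped at 1.5. The CI
#' transforms a Clopper-Pearson interval on alt/depth through the same
#' linear map, so coverage is inherited from the exact binomial interval.
#'
#' @param alt_count,total_depth read counts (vectorised)
#' @param purity tumour purity
#' @param cnt total copy number of the segment
#' @param m multiplicity (>= 1)
#' @param conf confidence level (default 0.95)
#' @return data.frame with columns ccf, ci_low, ci_high, multiplicity
#' @export
computeCcf <- function(alt_count, total_depth, purity, cnt, m, conf = 0.95) {
  .assertThat(
    "multiplicity must be >= 1" = m >= 1,
    "total_depth must be > 0" = total_depth > 0,
    "purity must be in (0,1]" = purity > 0 & purity <= 1)
  n <- max(length(alt_count), length(total_depth))
  alt_count <- rep_len(alt_count, n); total_depth <- rep_len(total_depth, n)
  purity <- rep_len(purity, n); cnt <- rep_len(cnt, n); m <- rep_len(m, n)
  scale <- (purity * cnt + 2 * (1 - purity)) / (purity * m)
  vaf <- alt_count / total_depth
  a <- (1 - conf) / 2
  ## Clopper-Pearson bounds via beta quantiles
  lo <- ifelse(alt_count == 0, 0,
               stats::qbeta(a, alt_count, total_depth - alt_count + 1))
  hi <- ifelse(alt_count == total_depth, 1,
               stats::qbeta(1 - a, alt_count + 1, total_depth - alt_count))
  cap <- function(x) pmin(x, 1.5)
  data.frame(ccf = cap(vaf * scale), ci_low = cap(lo * scale),
             ci_high = cap(hi * scale), multiplicity = as.integer(m))
}

#' Classify mutations as clonal or subclonal
#'
#' Deterministic per-mutation rule: clonal iff the CCF upper confidence
#' bound reaches 0.9 and the point estimate reaches 0.7. A thresholded rule
#' on exact binomial intervals replaces cohort-level clustering; it is
#' calibrated on the synthetic-cohort generator (see the vignette).
#'
#' @param ccf data.frame from \code{\link{computeCcf}} (or numeric ccf with
#'   \code{ci_high} supplied separately)
#' @param ci_high upper CI bounds if \code{ccf} is numeric
#' @return character vector, "clonal" or "subclonal"
#' @export
classifyClonal <- function(ccf, ci_high = NULL) {
  if (is.data.frame(ccf)) { ci_high <- ccf$ci_high; ccf <- ccf$ccf }
  ifelse(ci_high >= 0.9 & ccf >= 0.7, "clonal", "subclonal")
}

## closed-form pi estimator; cap into [0,1]
.piPoint <- function(n1, n2, state) {
  num <- if (state == "2+1") 3 * n2 else 2 * n2
  pmin(pmax(num / (n1 + 2 * n2), 0), 1)
}

#' Time a copy-number gain in molecular time
#'
#' Estimates the fraction pi of clonal mutation accumulation elapsed when a
#' gain occurred, from counts of clonal mutations at multiplicity 1 (n1) and
#' multiplicity 2 (n2) within the gained region. Only states reachable by a
#' single gain or WGD are supported: 2+1, 2+0, 2+2. The 95% CI comes from a
#' multinomial bootstrap of (n1, n2).
#'
#' @param n1,n2 clonal mutation counts at multiplicity 1 and 2
#' @param state copy-number state, one of "2+1", "2+0", "2+2"
#' @param B bootstrap replicates (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return data.frame with state, n1, n2, pi, ci_low, ci_high
#' @export
#' @examples
#' timeGain(10, 10, "2+0")$pi    # 2*10/(10+20) = 0.667
timeGain <- function(n1, n2, state, B = 1000, seed = 1L) {
  state <- match.arg(state, .GAIN_STATES)
  .assertThat("n1, n2 must be non-negative" = n1 >= 0 && n2 >= 0)
  if (n1 + n2 == 0) stop("no clonal mutations in region: pi not estimable",
                         call. = FALSE)
  pi_hat <- .piPoint(n1, n2, state)
  n <- n1 + n2
  r <- withr::with_seed(seed, stats::rbinom(B, n, n2 / n))
  boot <- vapply(r, function(b2) .piPoint(n - b2, b2, state), numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  data.frame(state = state, n1 = n1, n2 = n2, pi = pi_hat,
             ci_low = min(ci[1], pi_hat), ci_high = max(ci[2], pi_hat),
             stringsAsFactors = FALSE)
}

#' Time whole-genome duplication by pooling 2+2 segments
#'
#' Sums multiplicity-1 and multiplicity-2 clonal counts across every 2+2
#' segment of a sample and applies the 2+2 estimator; a WGD duplicates all
#' such regions simultaneously, so pooling is the maximum-likelihood
#' combination under a shared pi.
#'
#' @param n1,n2 vectors of per-segment counts (parallel)
#' @param B,seed bootstrap controls as in \code{\link{timeGain}}
#' @return as \code{\link{timeGain}}, state fixed to "2+2"
#' @export
timeWgd <- function(n1, n2, B = 1000, seed = 1L) {
  if (!length(n1) || sum(n1) + sum(n2) == 0) {
    stop("no 2+2 segments with clonal mutations: WGD timing not applicable",
         call. = FALSE)
  }
  timeGain(sum(n1), sum(n2), "2+2", B = B, seed = seed)
}

#' Assign a relative-timing class to a mutation
#'
#' Subclonal mutations are by definition late. Within gained regions a
#' clonal mutation at multiplicity 2 predates the gain (early-clonal) and
#' one at multiplicity 1 postdates it (late-clonal); clonal mutations
#' outside gained states carry no within-clonal timing information
#' (clonal-NA).
#'
#' @param state segment copy-number state string, e.g. "2+1", "1+1"
#' @param m multiplicity
#' @param clonal_flag logical (or "clonal"/"subclonal")
#' @return one of "early-clonal", "late-clonal", "clonal-NA", "subclonal"
#' @export
assignMutationTiming <- function(state, m, clonal_flag) {
  if (is.character(clonal_flag)) clonal_flag <- clonal_flag == "clonal"
  n <- max(length(state), length(m), length(clonal_flag))
  state <- rep_len(state, n); m <- rep_len(m, n)
  clonal_flag <- rep_len(clonal_flag, n)
  gained <- state %in% .GAIN_STATES
  out <- rep("clonal-NA", n)
  out[!clonal_flag] <- "subclonal"
  out[clonal_flag & gained & m >= 2] <- "early-clonal"
  out[clonal_flag & gained & m == 1] <- "late-clonal"
  out
}

#' Clonal mutation rate per year
#'
#' @param burden clonal mutation count (optionally restricted to a
#'   clock-like signature subset upstream)
#' @param age age at sampling in years
#' @return mutations per year
#' @export
estimateClockRate <- function(burden, age) {
  if (age <= 0) stop("age must be positive", call. = FALSE)
  if (burden == 0) warning("zero clonal burden: clock rate 0")
  burden / age
}

#' Two-phase mutational clock
#'
#' Maps molecular time to calendar time under a piecewise-constant rate:
#' rate 1 (relative) through the first fraction c of life (pre-initiation),
#' rate k >= 1 afterwards. k = 1 recovers the constant clock.
#'
#' @param rate clonal mutations per year (mu); informational, not used by
#'   the time conversion itself
#' @param k acceleration factor (>= 1)
#' @param c fraction of calendar life elapsed at tumour initiation, in [0,1]
#' @return an object of class \code{ClockModel}
#' @export
clockModel <- function(rate = NA_real_, k = 1, c = 0) {
  .assertThat("k must be >= 1" = k >= 1, "c must be in [0,1]" = c >= 0 && c <= 1)
  structure(list(rate = rate, k = k, c = c), class = "ClockModel")
}

#' @export
print.ClockModel <- function(x, ...) {
  cat(sprintf("ClockModel: rate=%.3g mut/yr, acceleration k=%.3g, initiation fraction c=%.3g\n",
              x$rate, x$k, x$c))
  invisible(x)
}

#' Convert molecular time to years before sampling
#'
#' Under the two-phase clock the total mutation units over a life of length
#' A are M = c + k(1-c) (calendar units, rate-weighted). A gain at molecular
#' time pi sits at pi*M mutation units; inverting the piecewise map gives
#' the calendar fraction, and years before sampling = A * (1 - t_cal). With
#' k = 1 this is exactly A * (1 - pi). The pi CI is propagated through the
#' same monotone map.
#'
#' @param pi molecular time in [0,1] (vectorised)
#' @param age age at sampling in years
#' @param clock a \code{\link{clockModel}}
#' @param ci_low,ci_high optional CI bounds on pi to propagate
#' @return data.frame with years_before_sampling (and CI columns if given)
#' @export
#' @examples
#' convertToRealTime(0.5, 60, clockModel(k = 1))   # 30 years
convertToRealTime <- function(pi, age, clock = clockModel(), ci_low = NULL,
                              ci_high = NULL) {
  .assertThat("pi must be in [0,1]" = pi >= 0 & pi <= 1, "age > 0" = age > 0)
  k <- clock$k; cc <- clock$c
  tcal <- function(p) {
    M <- cc + k * (1 - cc)
    u <- p * M
    ifelse(u <= cc, u, cc + (u - cc) / k)
  }
  out <- data.frame(years_before_sampling = age * (1 - tcal(pi)))
  if (!is.null(ci_low)) {
    ## map is increasing in pi, so the years CI flips the pi CI
    out$ci_low <- age * (1 - tcal(ci_high))
    out$ci_high <- age * (1 - tcal(ci_low))
  }
  out
}

#' Per-sample gain and WGD timing over a cohort
#'
#' End-to-end convenience: for every sample, estimates multiplicity and CCF
#' for each mutation from read counts, purity and the covering segment,
#' classifies clonality, counts (n1, n2) per gained segment, and returns
#' per-segment gain timings plus a pooled WGD timing for samples with 2+2
#' segments.
#'
#' @param bundle a \linkS4class{CohortBundle}
#' @param B,seed bootstrap controls
#' @param min_mutations minimum clonal mutations per segment to report a
#'   timing (default 5)
#' @return data.frame of gain timings: sample_id, chrom, start, end, state,
#'   n1, n2, pi, ci_low, ci_high; pooled WGD rows carry chrom "WGD"
#' @export
timeCohortGains <- function(bundle, B = 1000, seed = 1L, min_mutations = 5) {
  muts <- annotateMultiplicity(bundle)
  segs <- segments(bundle)
  out <- list()
  for (sid in unique(segs$sample_id)) {
    ms <- muts[muts$sample_id == sid & muts$clonal == "clonal", , drop = FALSE]
    ss <- segs[segs$sample_id == sid, , drop = FALSE]
    wgd_n1 <- integer(0); wgd_n2 <- integer(0)
    for (j in seq_len(nrow(ss))) {
      st <- paste0(ss$major_cn[j], "+", ss$minor_cn[j])
      if (!st %in% .GAIN_STATES) next
      in_seg <- ms$chrom == ss$chrom[j] & ms$pos - 1L >= ss$start[j] &
        ms$pos - 1L < ss$end[j]
      n1 <- sum(ms$multiplicity[in_seg] == 1)
      n2 <- sum(ms$multiplicity[in_seg] >= 2)
      if (st == "2+2") { wgd_n1 <- c(wgd_n1, n1); wgd_n2 <- c(wgd_n2, n2) }
      if (n1 + n2 < min_mutations) next
      tg <- timeGain(n1, n2, st, B = B, seed = .childSeed(seed, j))
      out[[length(out) + 1L]] <- cbind(
        data.frame(sample_id = sid, chrom = ss$chrom[j], start = ss$start[j],
                   end = ss$end[j], stringsAsFactors = FALSE), tg)
    }
    if (length(wgd_n1) && sum(wgd_n1) + sum(wgd_n2) >= min_mutations) {
      tw <- timeWgd(wgd_n1, wgd_n2, B = B, seed = .childSeed(seed, 0L))
      out[[length(out) + 1L]] <- cbind(
        data.frame(sample_id = sid, chrom = "WGD", start = NA_integer_,
                   end = NA_integer_, stringsAsFactors = FALSE), tw)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Annotate mutations with multiplicity, CCF and clonality
#'
#' Joins each mutation to its covering copy-number segment and the sample's
#' purity, then applies \code{\link{estimateMultiplicity}},
#' \code{\link{computeCcf}} and \code{\link{classifyClonal}}. Mutations
#' outside any segment are dropped.
#'
#' @param bundle a \linkS4class{CohortBundle}
#' @return mutation data.frame with added columns major_cn, minor_cn, state,
#'   multiplicity, ccf, ci_low, ci_high, clonal
#' @export
annotateMultiplicity <- function(bundle) {
  muts <- mutations(bundle); segs <- segments(bundle); pl <- ploidyTable(bundle)
  rho <- stats::setNames(pl$purity, pl$sample_id)
  res <- list()
  for (sid in unique(muts$sample_id)) {
    m <- muts[muts$sample_id == sid, , drop = FALSE]
    s <- segs[segs$sample_id == sid, , drop = FALSE]
    if (!nrow(s) || is.na(rho[sid])) next
    idx <- rep(NA_integer_, nrow(m))
    for (ch in unique(m$chrom)) {
      sc <- which(s$chrom == ch)
      if (!length(sc)) next
      mi <- which(m$chrom == ch)
      p0 <- m$pos[mi] - 1L
      hit <- findInterval(p0, s$start[sc])
      ok <- hit >= 1 & p0 < s$end[sc][pmax(hit, 1)]
      idx[mi[ok]] <- sc[hit[ok]]
    }
    keep <- !is.na(idx)
    m <- m[keep, , drop = FALSE]; idx <- idx[keep]
    if (!nrow(m)) next
    m$major_cn <- s$major_cn[idx]; m$minor_cn <- s$minor_cn[idx]
    m$state <- paste0(m$major_cn, "+", m$minor_cn)
    m$multiplicity <- estimateMultiplicity(m$alt_count, m$total_depth,
                                           rho[sid], m$major_cn, m$minor_cn)
    cc <- computeCcf(m$alt_count, m$total_depth, rho[sid],
                     m$major_cn + m$minor_cn, m$multiplicity)
    m$ccf <- cc$ccf; m$ci_low <- cc$ci_low; m$ci_high <- cc$ci_high
    m$clonal <- classifyClonal(cc)
    res[[sid]] <- m
  }
  if (!length(res)) return(data.frame())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
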
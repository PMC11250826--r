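## Genome-instability indices: whole-genome duplication calling from ploidy
## and LOH fraction, the weighted genome instability index (wGII), tumour
## mutational burden, and arm-level copy-number recurrence testing with a
## within-sample permutation null.

#' Call whole-genome duplication
#'
#' Pan-cancer rule on the purity-corrected genome: WGD iff
#' \eqn{\psi > 2.9 - 2 \cdot hom}, where psi is tumour ploidy and hom the
#' fraction of the genome with LOH. Strict inequality at the boundary.
#'
#' @param ploidy tumour ploidy psi (vectorised)
#' @param loh_fraction genome fraction with minor copy number 0
#' @return logical WGD flags
#' @export
#' @examples
#' callWgd(4.0, 0.1)   # TRUE
#' callWgd(2.5, 0.2)   # FALSE: threshold exactly 2.5
callWgd <- function(ploidy, loh_fraction) {
  .assertThat("ploidy must be > 0" = ploidy > 0,
              "loh_fraction must be in [0,1]" =
                loh_fraction >= 0 & loh_fraction <= 1)
  ploidy > 2.9 - 2 * loh_fraction
}

#' Weighted genome instability index
#'
#' Per autosome, the length-weighted fraction of the covered genome whose
#' total copy number differs from the baseline; wGII is the unweighted mean
#' of the 22 per-chromosome fractions, so small chromosomes count as much
#' as large ones. Baseline defaults to round(ploidy) so that a uniformly
#' tetraploid genome scores 0.
#'
#' @param segs segment data.frame for one sample (0-based half-open)
#' @param ploidy sample ploidy (used for the default baseline)
#' @param baseline integer baseline copy number; default
#'   \code{roundHalfUp(ploidy)}
#' @return wGII in [0,1]
#' @export
computeWgii <- function(segs, ploidy = 2, baseline = NULL) {
  if (is.null(baseline)) baseline <- max(roundHalfUp(ploidy), 1)
  fracs <- vapply(split(segs, segs$chrom), function(s) {
    len <- sum(s$end - s$start)
    if (len == 0) return(NA_real_)
    ab <- (s$major_cn + s$minor_cn) != baseline
    sum((s$end - s$start)[ab]) / len
  }, numeric(1))
  if (anyNA(fracs)) {
    warning("chromosome(s) with zero covered length excluded from wGII")
    fracs <- fracs[!is.na(fracs)]
  }
  mean(fracs)
}

#' Tumour mutational burden per callable megabase
#'
#' @param muts mutation data.frame for one sample (or cohort; burden is
#'   computed over all rows given)
#' @param callable_mb callable genome size in Mb (> 0); the denominator is
#'   deliberately a parameter, as callable size is pipeline-specific
#' @param hypermutator_snv_mb SNV/Mb threshold above which the sample is
#'   flagged hypermutated (default 10)
#' @return list with snv_mb, indel_mb (two decimals) and hypermutator flag
#' @export
computeTmb <- function(muts, callable_mb, hypermutator_snv_mb = 10) {
  if (callable_mb <= 0) stop("callable_mb must be > 0", call. = FALSE)
  is_snv <- nchar(muts$ref) == 1 & nchar(muts$alt) == 1
  snv <- roundHalfUp(sum(is_snv) / callable_mb, 2)
  indel <- roundHalfUp(sum(!is_snv) / callable_mb, 2)
  list(snv_mb = snv, indel_mb = indel,
       hypermutator = snv > hypermutator_snv_mb)
}

#' Arm-level gain/loss calls from segments
#'
#' An arm is called gained (lost) when at least \code{frac} of its covered
#' length has total copy number above (below) the baseline.
#'
#' @param segs segment data.frame for one sample
#' @param arms data.frame with chrom, arm (p/q), start, end (0-based
#'   half-open)
#' @param baseline baseline total copy number (default 2)
#' @param frac length fraction required (default 0.5)
#' @return data.frame with arm, call in \{gain, loss, neutral\}
#' @export
callArms <- function(segs, arms, baseline = 2, frac = 0.5) {
  out <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    s <- segs[segs$chrom == a$chrom & segs$start < a$end & segs$end > a$start, ,
              drop = FALSE]
    call <- "neutral"
    if (nrow(s)) {
      w <- pmin(s$end, a$end) - pmax(s$start, a$start)
      tot <- sum(w)
      cn <- s$major_cn + s$minor_cn
      if (tot > 0) {
        if (sum(w[cn > baseline]) / tot >= frac) call <- "gain"
        else if (sum(w[cn < baseline]) / tot >= frac) call <- "loss"
      }
    }
    data.frame(arm = paste0(sub("^chr", "", a$chrom), a$arm), call = call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Arm-level recurrence test
#'
#' Whether particular arms are gained/lost more often than expected given
#' each tumour's overall CNA burden: the null shuffles each sample's arm
#' calls across arms (preserving its total gain and loss counts exactly);
#' the per-arm p-value is the fraction of permutations in which the arm's
#' alteration frequency reaches the observed one, BH-adjusted across arms
#' and directions.
#'
#' @param arm_calls data.frame with sample_id, arm, call
#' @param n_perm permutations (default 10000)
#' @param seed RNG seed
#' @return data.frame with arm, direction, observed count, p_value, q_value
#' @export
armRecurrence <- function(arm_calls, n_perm = 10000, seed = 1L) {
  sids <- unique(arm_calls$sample_id)
  if (length(sids) < 2) stop("need >= 2 samples for a recurrence null",
                             call. = FALSE)
  arms <- sort(unique(arm_calls$arm))
  ## sample x arm matrix of calls coded 0 / +1 (gain) / -1 (loss)
  M <- matrix(0L, length(sids), length(arms), dimnames = list(sids, arms))
  code <- c(neutral = 0L, gain = 1L, loss = -1L)
  M[cbind(match(arm_calls$sample_id, sids), match(arm_calls$arm, arms))] <-
    code[arm_calls$call]
  obs_gain <- colSums(M == 1L); obs_loss <- colSums(M == -1L)
  exc_gain <- integer(length(arms)); exc_loss <- integer(length(arms))
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      P <- t(apply(M, 1, sample))      # shuffle arms within each sample
      stopifnot(all(rowSums(P == 1L) == rowSums(M == 1L)))
      exc_gain <- exc_gain + (colSums(P == 1L) >= obs_gain)
      exc_loss <- exc_loss + (colSums(P == -1L) >= obs_loss)
    }
  })
  res <- rbind(
    data.frame(arm = arms, direction = "gain", observed = obs_gain,
               p_value = (1 + exc_gain) / (1 + n_perm), row.names = NULL),
    data.frame(arm = arms, direction = "loss", observed = obs_loss,
               p_value = (1 + exc_loss) / (1 + n_perm), row.names = NULL))
  keep <- res$observed > 0
  res$q_value <- NA_real_
  res$q_value[keep] <- stats::p.adjust(res$p_value[keep], method = "BH")
  res
}

#' Read chromosome-arm boundaries from a UCSC cytoband file
#'
#' @param path cytoBand.txt(.gz)-format file: chrom, start, end, band, stain
#' @return data.frame with chrom, arm, start, end (0-based half-open)
#' @export
readCytoband <- function(path) {
  cb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(cb)[1:4] <- c("chrom", "start", "end", "band")
  cb$arm <- substr(cb$band, 1, 1)
  cb <- cb[cb$arm %in% c("p", "q"), , drop = FALSE]
  agg <- stats::aggregate(cbind(start, end) ~ chrom + arm, data = cb,
                          FUN = function(x) x)
  data.frame(chrom = agg$chrom, arm = agg$arm,
             start = vapply(seq_len(nrow(agg)), function(i) min(cb$start[
               cb$chrom == agg$chrom[i] & cb$arm == agg$arm[i]]), numeric(1)),
             end = vapply(seq_len(nrow(agg)), function(i) max(cb$end[
               cb$chrom == agg$chrom[i] & cb$arm == agg$arm[i]]), numeric(1)),
             stringsAsFactors = FALSE)
}
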
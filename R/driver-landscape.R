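## Driver-gene landscape summaries: mutation frequencies, pairwise
## co-occurrence / mutual-exclusivity testing, the pathogenicity contrast
## between driver and non-driver missense SNVs, and headline cohort
## fractions reported to one decimal.

#' Fraction of tumours with a nonsynonymous mutation per driver gene
#'
#' A sample counts at most once per gene regardless of how many qualifying
#' mutations it carries. Nonsynonymous means missense, truncating or
#' inframe.
#'
#' @param bundle a \linkS4class{CohortBundle} (or a mutation data.frame)
#' @param genes non-empty character vector of driver genes
#' @return data.frame with gene, n_mutated, n_samples, frequency
#' @export
driverFrequencies <- function(bundle, genes) {
  if (!length(genes)) stop("gene list must be non-empty", call. = FALSE)
  muts <- if (is(bundle, "CohortBundle")) mutations(bundle) else bundle
  nsam <- if (is(bundle, "CohortBundle") && nrow(clinicalData(bundle)))
    length(unique(clinicalData(bundle)$sample_id)) else
    length(unique(muts$sample_id))
  nonsyn <- muts[muts$consequence %in% c("missense", "truncating", "inframe"), ]
  counts <- vapply(genes, function(g)
    length(unique(nonsyn$sample_id[nonsyn$gene == g])), integer(1))
  data.frame(gene = genes, n_mutated = counts, n_samples = nsam,
             frequency = counts / nsam, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Build a binary gene-by-sample mutation matrix
#'
#' @param muts mutation data.frame
#' @param genes genes to include
#' @param samples sample universe (defaults to samples present in muts)
#' @return logical matrix, genes in rows
#' @export
mutationMatrix <- function(muts, genes, samples = NULL) {
  if (is.null(samples)) samples <- unique(muts$sample_id)
  nonsyn <- muts[muts$consequence %in% c("missense", "truncating", "inframe"), ]
  m <- matrix(FALSE, length(genes), length(samples),
              dimnames = list(genes, samples))
  hit <- unique(nonsyn[nonsyn$gene %in% genes, c("gene", "sample_id")])
  hit <- hit[hit$sample_id %in% samples, , drop = FALSE]
  if (nrow(hit)) m[cbind(hit$gene, hit$sample_id)] <- TRUE
  m
}

#' Pairwise co-occurrence / mutual-exclusivity test
#'
#' Two-sided Fisher exact test on the 2x2 cross-tabulation of each gene
#' pair across samples; direction from the conditional odds ratio
#' (co-occurring if OR > 1, exclusive otherwise); Benjamini-Hochberg Q
#' across all tested pairs. Genes mutated in every sample or in none carry
#' no pairwise information and are skipped with a message.
#'
#' @param mat logical gene-by-sample matrix from \code{\link{mutationMatrix}}
#' @return data.frame with gene_a, gene_b, the 2x2 cells (both, a_only,
#'   b_only, neither), odds_ratio, direction, p_value, q_value
#' @export
cooccurrenceTest <- function(mat) {
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  keep <- rowSums(mat) > 0 & rowSums(mat) < ncol(mat)
  if (any(!keep)) message("skipping constant gene(s): ",
                          paste(rownames(mat)[!keep], collapse = ", "))
  mat <- mat[keep, , drop = FALSE]
  gn <- rownames(mat)
  if (length(gn) < 2) stop("fewer than 2 informative genes", call. = FALSE)
  pairs <- utils::combn(gn, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- mat[pairs[1, k], ]; b <- mat[pairs[2, k], ]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2, 2)
    ft <- stats::fisher.test(tab)
    data.frame(gene_a = pairs[1, k], gene_b = pairs[2, k],
               both = tab[1, 1], a_only = tab[2, 1], b_only = tab[1, 2],
               neither = tab[2, 2], odds_ratio = unname(ft$estimate),
               direction = if (ft$estimate > 1) "co-occurring" else "exclusive",
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Contrast pathogenic fractions between driver and non-driver mutations
#'
#' Reports the two proportions to one decimal and a two-sided association
#' p-value from the chi-squared test with continuity correction on the 2x2
#' table (Fisher exact below \code{exact_below} total observations).
#'
#' @param k_driver,n_driver pathogenic / total counts among driver-gene
#'   missense SNVs
#' @param k_nondriver,n_nondriver same among non-driver missense SNVs
#'   (optional; NA gives a one-group summary)
#' @param exact_below use Fisher's exact test when n_driver + n_nondriver
#'   falls below this (default 200)
#' @return list with pct_driver, pct_nondriver, p_value
#' @export
#' @examples
#' pathogenicityContrast(436, 602, 11112, 37297)$pct_driver   # 72.4
pathogenicityContrast <- function(k_driver, n_driver, k_nondriver = NA,
                                  n_nondriver = NA, exact_below = 200) {
  if (n_driver <= 0) stop("zero denominator", call. = FALSE)
  res <- list(pct_driver = pctOf(k_driver, n_driver),
              pct_nondriver = NA_real_, p_value = NA_real_)
  if (!is.na(k_nondriver)) {
    if (n_nondriver <= 0) stop("zero denominator", call. = FALSE)
    res$pct_nondriver <- pctOf(k_nondriver, n_nondriver)
    tab <- matrix(c(k_driver, n_driver - k_driver,
                    k_nondriver, n_nondriver - k_nondriver), 2, 2)
    res$p_value <- if (n_driver + n_nondriver < exact_below)
      stats::fisher.test(tab)$p.value
    else stats::chisq.test(tab, correct = TRUE)$p.value
  }
  res
}

#' Headline cohort fractions
#'
#' Emits counts and one-decimal percentages for named numerator/denominator
#' pairs: germline-carrier fraction, escape fraction, driver co-mutation
#' overlaps, or any other printed cohort summary.
#'
#' @param fractions named list, each element \code{c(numerator, denominator)}
#' @return data.frame with item, k, n, pct
#' @export
#' @examples
#' cohortReport(list(germline_carriers = c(22, 778)))   # 2.8
cohortReport <- function(fractions) {
  out <- lapply(names(fractions), function(nm) {
    kn <- fractions[[nm]]
    data.frame(item = nm, k = kn[1], n = kn[2],
               pct = if (kn[2] > 0) pctOf(kn[1], kn[2]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of tumours mutated in gene B among those mutated in gene A
#'
#' @param muts mutation data.frame
#' @param gene_a conditioning gene
#' @param gene_b target gene
#' @return list with k, n, pct
#' @export
comutationOverlap <- function(muts, gene_a, gene_b) {
  nonsyn <- muts[muts$consequence %in% c("missense", "truncating", "inframe"), ]
  sa <- unique(nonsyn$sample_id[nonsyn$gene == gene_a])
  sb <- unique(nonsyn$sample_id[nonsyn$gene == gene_b])
  k <- length(intersect(sa, sb)); n <- length(sa)
  list(k = k, n = n, pct = if (n > 0) pctOf(k, n) else NA_real_)
}
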
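## Genetic immune-escape classification. A tumour is classed as immune
## evading when it carries any of: LOH at an HLA class I gene (HLA-A/B/C),
## a nonsynonymous HLA mutation, or an inactivating alteration of an
## antigen-presenting gene (APG) - truncating, or biallelic nonsynonymous.

#' The 22-gene antigen-presenting gene set
#'
#' Default APG list used by \code{\link{apgInactivation}}; override via the
#' \code{apg_genes} argument to supply a custom panel.
#'
#' @return character vector of 22 gene symbols
#' @export
apgGeneSet <- function() {
  c("TAP1", "TAP2", "TAPBP", "B2M", "CALR", "CANX", "PDIA3", "ERAP1",
    "ERAP2", "HSPA5", "HSP90AA1", "HSP90AB1", "PSMB8", "PSMB9", "PSME1",
    "PSME2", "PSME3", "SEC61A1", "SEC61B", "SEC61G", "SAR1B", "CIITA")
}

#' Per-sample APG inactivation flag
#'
#' A sample is flagged when at least one APG carries a truncating mutation
#' or a biallelic nonsynonymous alteration (two hits, or one hit plus LOH).
#' Records for genes outside the APG list are ignored with a message.
#'
#' @param apg_muts data.frame with sample_id, gene, consequence,
#'   biallelic (logical)
#' @param samples sample universe for the output
#' @param apg_genes APG panel (default \code{\link{apgGeneSet}})
#' @return named logical vector over \code{samples}
#' @export
apgInactivation <- function(apg_muts, samples = unique(apg_muts$sample_id),
                            apg_genes = apgGeneSet()) {
  out <- stats::setNames(rep(FALSE, length(samples)), samples)
  if (!nrow(apg_muts)) return(out)
  off <- !apg_muts$gene %in% apg_genes
  if (any(off)) {
    message("ignoring ", sum(off), " record(s) for genes outside the APG list")
    apg_muts <- apg_muts[!off, , drop = FALSE]
  }
  nonsyn <- apg_muts$consequence %in% c("missense", "truncating", "inframe")
  inact <- apg_muts$consequence == "truncating" |
    (nonsyn & isTRUE_v(apg_muts$biallelic))
  hit <- unique(apg_muts$sample_id[inact])
  out[names(out) %in% hit] <- TRUE
  out
}

## vectorised isTRUE with NA -> FALSE
isTRUE_v <- function(x) !is.na(x) & x

#' Classify immune escape per tumour
#'
#' @param immune data.frame with sample_id, hla_loh_a, hla_loh_b, hla_loh_c
#'   (logical LOH flags per HLA class I gene), hla_mutation (logical
#'   nonsynonymous HLA mutation flag), apg_inactivated (logical, e.g. from
#'   \code{\link{apgInactivation}})
#' @return data.frame with sample_id, escape, and the three mechanism flags
#'   hla_loh, hla_mutation, apg_inactivation; \code{mechanisms} column
#'   lists them comma-separated
#' @export
classifyEscape <- function(immune) {
  loh <- isTRUE_v(immune$hla_loh_a) | isTRUE_v(immune$hla_loh_b) |
    isTRUE_v(immune$hla_loh_c)
  mut <- isTRUE_v(immune$hla_mutation)
  apg <- isTRUE_v(immune$apg_inactivated)
  mech <- mapply(function(l, m, a) paste(
    c("HLA-LOH", "HLA-mutation", "APG-inactivation")[c(l, m, a)],
    collapse = ","), loh, mut, apg)
  data.frame(sample_id = immune$sample_id, escape = loh | mut | apg,
             hla_loh = loh, hla_mutation = mut, apg_inactivation = apg,
             mechanisms = mech, stringsAsFactors = FALSE)
}

#' Cohort immune-escape summary
#'
#' @param calls data.frame from \code{\link{classifyEscape}}
#' @return data.frame of counts and one-decimal percentages per mechanism
#'   and overall
#' @export
escapeSummary <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  n <- nrow(calls)
  items <- c(escape_any = "escape", hla_loh = "hla_loh",
             hla_mutation = "hla_mutation",
             apg_inactivation = "apg_inactivation")
  out <- lapply(names(items), function(nm) {
    k <- sum(calls[[items[[nm]]]])
    data.frame(item = nm, k = k, n = n, pct = pctOf(k, n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
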
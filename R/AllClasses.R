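#' @import methods
NULL

## canonical column sets for the five cohort tables (internal representation;
## all coordinates 0-based half-open, converted at file boundaries only)
.MUT_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
               "consequence", "alt_count", "total_depth", "trinucleotide",
               "is_driver_gene", "pathogenic_flag")
.SEG_COLS <- c("sample_id", "chrom", "start", "end", "major_cn", "minor_cn")
.PLOIDY_COLS <- c("sample_id", "purity", "ploidy", "loh_fraction", "wgd_flag")
.SV_COLS <- c("sample_id", "chrom1", "start1", "end1", "chrom2", "start2",
              "end2", "sv_class", "complexity")
.CLIN_COLS <- c("sample_id", "age_at_sampling", "sex", "stage", "grade",
                "sarcomatoid", "necrosis", "os_time", "os_event", "css_time",
                "css_event", "pfs_time", "pfs_event", "tcra_fraction",
                "leibovich_group")
.CONSEQUENCES <- c("missense", "truncating", "inframe", "synonymous",
                   "noncoding")
.SV_CLASSES <- c("DEL", "TD", "UNCLASSIFIED")

#' CohortBundle: the validated cohort container
#'
#' Holds the five per-tumour tables every pipeline stage consumes (somatic
#' mutations, allele-specific copy-number segments, purity/ploidy, structural
#' variants, clinical records) plus optional binned covariate tracks and gene
#' annotation. All genomic intervals are stored 0-based half-open; conversion
#' to and from the 1-based file conventions happens only in
#' \code{\link{loadCohort}} / \code{\link{writeCohort}}.
#'
#' Sex chromosomes are excluded at load: every downstream statistic assumes a
#' normal copy number of 2.
#'
#' @slot mutations data.frame of somatic SNVs/indels with read counts
#' @slot segments data.frame of copy-number segments (major_cn >= minor_cn)
#' @slot ploidy data.frame of per-sample purity, ploidy and LOH fraction
#' @slot svs data.frame of structural variants in breakend-pair form
#' @slot clinical data.frame of clinical covariates and survival endpoints
#' @slot tracks data.frame of fixed-width genomic bins with covariate columns
#'   (chrom, start, end, then one numeric column per covariate), or empty
#' @slot genes data.frame gene annotation (gene, chrom, start, end,
#'   rt_quartile with 4 = latest-replicating), or empty
#'
#' @export
setClass("CohortBundle",
  representation(
    mutations = "data.frame",
    segments  = "data.frame",
    ploidy    = "data.frame",
    svs       = "data.frame",
    clinical  = "data.frame",
    tracks    = "data.frame",
    genes     = "data.frame"
  ),
  prototype(
    mutations = data.frame(), segments = data.frame(), ploidy = data.frame(),
    svs = data.frame(), clinical = data.frame(), tracks = data.frame(),
    genes = data.frame()
  )
)

setValidity("CohortBundle", function(object) {
  msgs <- character(0)
  m <- object@mutations; s <- object@segments; v <- object@svs
  p <- object@ploidy; cl <- object@clinical
  if (nrow(m)) {
    if (!all(.MUT_COLS %in% names(m))) msgs <- c(msgs, "mutations: missing columns")
    else {
      if (any(m$alt_count > m$total_depth)) msgs <- c(msgs, "mutations: alt_count > total_depth")
      if (any(m$pos < 1)) msgs <- c(msgs, "mutations: position < 1")
      if (!all(m$consequence %in% .CONSEQUENCES)) msgs <- c(msgs, "mutations: unknown consequence")
    }
  }
  if (nrow(s)) {
    if (!all(.SEG_COLS %in% names(s))) msgs <- c(msgs, "segments: missing columns")
    else {
      if (any(s$start >= s$end)) msgs <- c(msgs, "segments: start >= end")
      if (any(s$major_cn < s$minor_cn)) msgs <- c(msgs, "segments: major_cn < minor_cn")
      if (any(s$major_cn < 0 | s$minor_cn < 0)) msgs <- c(msgs, "segments: negative copy number")
    }
  }
  if (nrow(p)) {
    if (any(p$purity <= 0 | p$purity > 1)) msgs <- c(msgs, "ploidy: purity outside (0,1]")
    if (any(p$ploidy <= 0)) msgs <- c(msgs, "ploidy: ploidy <= 0")
    if (any(p$loh_fraction < 0 | p$loh_fraction > 1)) msgs <- c(msgs, "ploidy: loh_fraction outside [0,1]")
  }
  if (nrow(v)) {
    if (!all(v$sv_class %in% .SV_CLASSES)) msgs <- c(msgs, "svs: unknown sv_class")
    if (any(v$start1 > v$end1 | v$start2 > v$end2)) msgs <- c(msgs, "svs: invalid intervals")
  }
  if (nrow(cl)) {
    tm <- c("os_time", "css_time", "pfs_time")
    if (any(unlist(cl[tm]) < 0, na.rm = TRUE)) msgs <- c(msgs, "clinical: negative times")
    tf <- cl$tcra_fraction
    if (any(tf < 0 | tf > 1, na.rm = TRUE)) msgs <- c(msgs, "clinical: tcra_fraction outside [0,1]")
  }
  ## cross-references: every molecular sample must appear in the clinical table
  if (nrow(cl)) {
    known <- cl$sample_id
    for (tab in list(mutations = m, segments = s, svs = v, ploidy = p)) {
      if (nrow(tab) && !all(tab$sample_id %in% known)) {
        bad <- unique(setdiff(tab$sample_id, known))
        msgs <- c(msgs, paste0("unresolved sample_id(s): ",
                               paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a CohortBundle from in-memory tables
#'
#' @param mutations,segments,ploidy,svs,clinical,tracks,genes data.frames in
#'   the internal (0-based half-open) representation; missing tables default
#'   to empty.
#' @return a validated \linkS4class{CohortBundle}
#' @export
CohortBundle <- function(mutations = data.frame(), segments = data.frame(),
                         ploidy = data.frame(), svs = data.frame(),
                         clinical = data.frame(), tracks = data.frame(),
                         genes = data.frame()) {
  new("CohortBundle", mutations = mutations, segments = segments,
      ploidy = ploidy, svs = svs, clinical = clinical, tracks = tracks,
      genes = genes)
}

#' @rdname CohortBundle-accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))
#' @rdname CohortBundle-accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname CohortBundle-accessors
#' @export
setGeneric("ploidyTable", function(x) standardGeneric("ploidyTable"))
#' @rdname CohortBundle-accessors
#' @export
setGeneric("svRecords", function(x) standardGeneric("svRecords"))
#' @rdname CohortBundle-accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))
#' @rdname CohortBundle-accessors
#' @export
setGeneric("covariateTracks", function(x) standardGeneric("covariateTracks"))
#' @rdname CohortBundle-accessors
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' Accessors for CohortBundle slots
#'
#' @param x a \linkS4class{CohortBundle}
#' @return the corresponding data.frame
#' @name CohortBundle-accessors
#' @aliases mutations segments ploidyTable svRecords clinicalData
#'   covariateTracks geneAnnotation
NULL

#' @rdname CohortBundle-accessors
setMethod("mutations", "CohortBundle", function(x) x@mutations)
#' @rdname CohortBundle-accessors
setMethod("segments", "CohortBundle", function(x) x@segments)
#' @rdname CohortBundle-accessors
setMethod("ploidyTable", "CohortBundle", function(x) x@ploidy)
#' @rdname CohortBundle-accessors
setMethod("svRecords", "CohortBundle", function(x) x@svs)
#' @rdname CohortBundle-accessors
setMethod("clinicalData", "CohortBundle", function(x) x@clinical)
#' @rdname CohortBundle-accessors
setMethod("covariateTracks", "CohortBundle", function(x) x@tracks)
#' @rdname CohortBundle-accessors
setMethod("geneAnnotation", "CohortBundle", function(x) x@genes)

#' Number of tumours in the bundle
#'
#' @param x a CohortBundle
#' @export
setMethod("length", "CohortBundle", function(x) {
  length(unique(c(x@clinical$sample_id, x@mutations$sample_id,
                  x@segments$sample_id)))
})

setMethod("show", "CohortBundle", function(object) {
  cat("CohortBundle with", length(object), "tumours\n")
  cat("  mutations:", nrow(object@mutations),
      " segments:", nrow(object@segments),
      " SVs:", nrow(object@svs), "\n")
  cat("  clinical records:", nrow(object@clinical),
      " covariate bins:", nrow(object@tracks),
      " annotated genes:", nrow(object@genes), "\n")
})
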
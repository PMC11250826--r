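## Readers and writers for the cohort tables.
##
## File conventions: mutation positions and segment coordinates are 1-based
## (segments inclusive) in files; BEDPE and BED are 0-based half-open.
## Internally, mutation pos stays 1-based (a point), while all intervals
## (segments, SVs, tracks, genes) are 0-based half-open. Conversions happen
## here and nowhere else.

.readTsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ## chromosome names are labels, never numbers
  for (cc in intersect(c("chrom", "chrom1", "chrom2"), names(df))) {
    df[[cc]] <- as.character(df[[cc]])
  }
  df
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

.parseError <- function(file, rows, what) {
  stop(sprintf("%s: %s at line(s) %s (1 = first data row)", file, what,
               paste(utils::head(rows, 10), collapse = ",")), call. = FALSE)
}

#' Load a cohort from a directory of standard files
#'
#' Reads the mutation, segment, ploidy, SV, clinical and optional track/gene
#' files written by \code{\link{writeCohort}}, normalises coordinates to the
#' internal 0-based half-open convention, drops sex-chromosome records (all
#' downstream statistics assume normal copy number 2, valid on autosomes
#' only) and validates cross-references: every molecular record's sample must
#' appear in the clinical table.
#'
#' @param dir directory containing \code{mutations.tsv}, \code{segments.tsv},
#'   \code{ploidy.tsv}, \code{clinical.tsv}, \code{svs.bedpe} and optionally
#'   \code{tracks.tsv}, \code{genes.bed}
#' @param germline_indel_bed optional path to a BED of common germline
#'   indels; somatic indels within \code{indel_window} bp of one are removed
#'   (mirrors the upstream pipeline filter)
#' @param indel_window proximity window in bp (default 10)
#' @param keep_sex keep chrX/chrY records (default FALSE)
#' @return a validated \linkS4class{CohortBundle}
#' @export
loadCohort <- function(dir, germline_indel_bed = NULL, indel_window = 10,
                       keep_sex = FALSE) {
  pth <- function(f) file.path(dir, f)
  for (f in c("mutations.tsv", "segments.tsv", "ploidy.tsv", "clinical.tsv",
              "svs.bedpe")) {
    if (!file.exists(pth(f))) stop("missing cohort file: ", f, call. = FALSE)
  }
  m <- .readTsv(pth("mutations.tsv"))
  if (nrow(m)) {
    bad <- which(m$alt_count > m$total_depth | m$alt_count < 0 |
                 m$total_depth < 0)
    if (length(bad)) .parseError("mutations.tsv", bad, "alt_count/total_depth invariant violated")
    bad <- which(m$pos < 1)
    if (length(bad)) .parseError("mutations.tsv", bad, "position < 1")
    bad <- which(!m$consequence %in% .CONSEQUENCES)
    if (length(bad)) .parseError("mutations.tsv", bad, "unknown consequence")
  }

  s <- .readTsv(pth("segments.tsv"))
  if (nrow(s)) {
    bad <- which(s$start > s$end)   # file convention: 1-based inclusive
    if (length(bad)) .parseError("segments.tsv", bad, "start > end")
    bad <- which(s$major_cn < s$minor_cn)
    if (length(bad)) .parseError("segments.tsv", bad, "major_cn < minor_cn")
    s$start <- s$start - 1L         # -> 0-based half-open; inclusive end == half-open end
  }

  p <- .readTsv(pth("ploidy.tsv"))
  cl <- .readTsv(pth("clinical.tsv"))

  v <- .readTsv(pth("svs.bedpe"))
  if (nrow(v)) {
    ## BEDPE columns: chrom1 start1 end1 chrom2 start2 end2 name score
    ## strand1 strand2 sv_class complexity; name carries the sample id.
    v <- data.frame(sample_id = v$name, chrom1 = v$chrom1, start1 = v$start1,
                    end1 = v$end1, chrom2 = v$chrom2, start2 = v$start2,
                    end2 = v$end2, sv_class = v$sv_class,
                    complexity = v$complexity, stringsAsFactors = FALSE)
    bad <- which(!v$sv_class %in% .SV_CLASSES)
    if (length(bad)) .parseError("svs.bedpe", bad, "unknown sv_class")
  } else v <- data.frame()

  tracks <- if (file.exists(pth("tracks.tsv"))) .readTsv(pth("tracks.tsv")) else data.frame()
  genes <- if (file.exists(pth("genes.bed"))) {
    g <- utils::read.delim(pth("genes.bed"), header = FALSE,
                           stringsAsFactors = FALSE)
    names(g) <- c("chrom", "start", "end", "gene", "rt_quartile")[seq_len(ncol(g))]
    g
  } else data.frame()

  if (!keep_sex) {
    sex <- c("X", "Y", "chrX", "chrY")
    if (nrow(m)) m <- m[!m$chrom %in% sex, , drop = FALSE]
    if (nrow(s)) s <- s[!s$chrom %in% sex, , drop = FALSE]
    if (nrow(v)) v <- v[!(v$chrom1 %in% sex | v$chrom2 %in% sex), , drop = FALSE]
  }

  if (!is.null(germline_indel_bed) && nrow(m)) {
    m <- filterProximalIndels(m, germline_indel_bed, indel_window)
  }

  bundle <- CohortBundle(mutations = m, segments = s, ploidy = p, svs = v,
                         clinical = cl, tracks = tracks, genes = genes)
  bundle
}

#' Write a cohort bundle to a directory of standard files
#'
#' Inverse of \code{\link{loadCohort}}: emits TSVs with deterministic column
#' order, segments converted back to 1-based inclusive coordinates, SVs as
#' 12-column BEDPE, gene annotation as BED. Row order is preserved, so
#' \code{loadCohort(writeCohort(x))} reproduces \code{x} record-for-record
#' and a second write is byte-identical.
#'
#' @param bundle a \linkS4class{CohortBundle}
#' @param dir output directory (created if absent)
#' @return \code{dir}, invisibly
#' @export
writeCohort <- function(bundle, dir) {
  stopifnot(is(bundle, "CohortBundle"))
  validObject(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)

  m <- bundle@mutations
  if (!nrow(m)) m <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(.MUT_COLS))), .MUT_COLS)
  .writeTsv(m[, .MUT_COLS[.MUT_COLS %in% names(m)], drop = FALSE], pth("mutations.tsv"))

  s <- bundle@segments
  if (nrow(s)) {
    s <- s[, .SEG_COLS, drop = FALSE]
    s$start <- s$start + 1L   # back to 1-based inclusive
  } else s <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(.SEG_COLS))), .SEG_COLS)
  .writeTsv(s, pth("segments.tsv"))

  p <- bundle@ploidy
  if (!nrow(p)) p <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(.PLOIDY_COLS))), .PLOIDY_COLS)
  .writeTsv(p[, .PLOIDY_COLS[.PLOIDY_COLS %in% names(p)], drop = FALSE], pth("ploidy.tsv"))

  cl <- bundle@clinical
  if (!nrow(cl)) cl <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(.CLIN_COLS))), .CLIN_COLS)
  .writeTsv(cl[, .CLIN_COLS[.CLIN_COLS %in% names(cl)], drop = FALSE], pth("clinical.tsv"))

  v <- bundle@svs
  if (nrow(v)) {
    bedpe <- data.frame(chrom1 = v$chrom1, start1 = v$start1, end1 = v$end1,
                        chrom2 = v$chrom2, start2 = v$start2, end2 = v$end2,
                        name = v$sample_id, score = ".", strand1 = ".",
                        strand2 = ".", sv_class = v$sv_class,
                        complexity = v$complexity, stringsAsFactors = FALSE)
  } else {
    bedpe <- stats::setNames(data.frame(matrix(nrow = 0, ncol = 12)),
      c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name",
        "score", "strand1", "strand2", "sv_class", "complexity"))
  }
  .writeTsv(bedpe, pth("svs.bedpe"))

  if (nrow(bundle@tracks)) .writeTsv(bundle@tracks, pth("tracks.tsv"))
  g <- bundle@genes
  if (nrow(g)) {
    utils::write.table(g[, c("chrom", "start", "end", "gene", "rt_quartile")],
                       pth("genes.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Check per-sample segment lists for structural problems
#'
#' Report-only validation: flags overlapping segments, inter-segment gaps
#' larger than a tolerance, and major/minor copy-number inversions.
#'
#' @param segments data.frame of segments (internal 0-based half-open)
#' @param gap_tol maximum tolerated gap in bp between consecutive segments
#'   on a chromosome (default 1e6)
#' @return data.frame with columns sample_id, chrom, type
#'   (overlap/gap/cn_inversion), detail; zero rows if clean
#' @export
validateSegments <- function(segments, gap_tol = 1e6) {
  out <- list()
  if (nrow(segments)) {
    inv <- segments$major_cn < segments$minor_cn
    if (any(inv)) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = segments$sample_id[inv], chrom = segments$chrom[inv],
        type = "cn_inversion",
        detail = sprintf("major %d < minor %d", segments$major_cn[inv],
                         segments$minor_cn[inv]), stringsAsFactors = FALSE)
    }
    for (key in split(seq_len(nrow(segments)),
                      paste(segments$sample_id, segments$chrom))) {
      seg <- segments[key, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) < 2) next
      d <- seg$start[-1] - seg$end[-nrow(seg)]
      ov <- which(d < 0)
      gp <- which(d > gap_tol)
      if (length(ov)) out[[length(out) + 1L]] <- data.frame(
        sample_id = seg$sample_id[1], chrom = seg$chrom[1], type = "overlap",
        detail = sprintf("segments %d-%d overlap by %d bp", ov, ov + 1, -d[ov]),
        stringsAsFactors = FALSE)
      if (length(gp)) out[[length(out) + 1L]] <- data.frame(
        sample_id = seg$sample_id[1], chrom = seg$chrom[1], type = "gap",
        detail = sprintf("gap of %d bp after segment %d", d[gp], gp),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), chrom = character(0),
               type = character(0), detail = character(0))
}

#' Read somatic mutations from a minimal VCF
#'
#' Accepts a VCF 4.x with CHROM/POS/REF/ALT and a single tumour sample
#' carrying an AD (allelic depth) FORMAT field. Returns records in the
#' package's mutation-table layout; gene/consequence/context columns are
#' filled with placeholders for downstream annotation.
#'
#' @param path VCF file path (uncompressed or bgzipped)
#' @param sample_id sample identifier to assign to the records
#' @return mutation data.frame
#' @export
readMutationVcf <- function(path, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("readMutationVcf requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || !ncol(ad)) stop("VCF has no AD field", call. = FALSE)
  parts <- strsplit(ad[, 1], ",", fixed = TRUE)
  refd <- vapply(parts, function(x) as.integer(x[1]), integer(1))
  altd <- vapply(parts, function(x) as.integer(x[2]), integer(1))
  data.frame(
    sample_id = sample_id, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = "", consequence = "noncoding", alt_count = altd,
    total_depth = refd + altd, trinucleotide = NA_character_,
    is_driver_gene = FALSE, pathogenic_flag = NA,
    stringsAsFactors = FALSE)
}

#' Remove indels near common germline indels
#'
#' Drops insertion/deletion records (ref and alt of unequal length) lying
#' within \code{window} bp of any interval in a germline-indel BED file;
#' SNVs are never touched.
#'
#' @param mutations mutation data.frame
#' @param germline_bed path to a BED file (0-based half-open) of germline
#'   indel positions
#' @param window proximity in bp (default 10)
#' @return filtered mutation data.frame
#' @export
filterProximalIndels <- function(mutations, germline_bed, window = 10) {
  g <- utils::read.delim(germline_bed, header = FALSE, stringsAsFactors = FALSE)
  names(g)[1:3] <- c("chrom", "start", "end")
  is_indel <- nchar(mutations$ref) != nchar(mutations$alt)
  drop <- rep(FALSE, nrow(mutations))
  for (i in which(is_indel)) {
    gi <- g[g$chrom == mutations$chrom[i], , drop = FALSE]
    if (!nrow(gi)) next
    p0 <- mutations$pos[i] - 1L   # 0-based point
    drop[i] <- any(p0 >= gi$start - window & p0 < gi$end + window)
  }
  mutations[!drop, , drop = FALSE]
}
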
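test_that("write/load round-trips a generated cohort field-by-field", {
  b <- smallCohort()$cohort
  d <- withr::local_tempdir()
  writeCohort(b, d)
  b2 <- loadCohort(d)
  expect_equal(mutations(b2), mutations(b))
  expect_equal(segments(b2), segments(b))
  expect_equal(svRecords(b2), svRecords(b))
  expect_equal(clinicalData(b2), clinicalData(b))
  expect_equal(ploidyTable(b2), ploidyTable(b), tolerance = 1e-9)
})

test_that("a second write cycle is byte-identical (idempotence)", {
  b <- smallCohort()$cohort
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(b, d1)
  writeCohort(loadCohort(d1), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d2, f))),
                     unname(tools::md5sum(file.path(d1, f))), label = f)
  }
})

test_that("invariant violations surface as parse errors with line numbers", {
  b <- smallCohort()$cohort
  d <- withr::local_tempdir()
  writeCohort(b, d)
  m <- read.delim(file.path(d, "mutations.tsv"))
  m$alt_count[3] <- m$total_depth[3] + 5
  write.table(m, file.path(d, "mutations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(loadCohort(d), "alt_count.*line\\(s\\) 3")
})

test_that("segment coordinates survive the 1-based/half-open conversion", {
  ## ten random 1-based inclusive intervals: internal end equals file end,
  ## internal start is file start - 1, and re-serialisation restores both
  set.seed(11)
  starts <- sample(1e6, 10); ends <- starts + sample(1e5, 10)
  d <- withr::local_tempdir()
  clin <- data.frame(sample_id = "S1", age_at_sampling = 60, sex = "M",
                     stage = 1, grade = 2, sarcomatoid = FALSE,
                     necrosis = FALSE, os_time = 100, os_event = 0,
                     css_time = 100, css_event = 0, pfs_time = 100,
                     pfs_event = 0, tcra_fraction = 0.05,
                     leibovich_group = "low")
  seg_file <- data.frame(sample_id = "S1", chrom = "1", start = starts,
                         end = ends, major_cn = 1, minor_cn = 1)
  for (f in c("mutations.tsv", "ploidy.tsv", "svs.bedpe")) {
    writeCohort(CohortBundle(clinical = clin), d)   # writes empty skeletons
  }
  write.table(seg_file, file.path(d, "segments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  b <- loadCohort(d)
  expect_equal(segments(b)$start, starts - 1)
  expect_equal(segments(b)$end, ends)
  d2 <- withr::local_tempdir()
  writeCohort(b, d2)
  back <- read.delim(file.path(d2, "segments.tsv"))
  expect_equal(back$start, starts)
  expect_equal(back$end, ends)
})

test_that("empty cohort writes header-only files", {
  d <- withr::local_tempdir()
  writeCohort(CohortBundle(), d)
  for (f in c("mutations.tsv", "segments.tsv", "ploidy.tsv", "clinical.tsv",
              "svs.bedpe")) {
    lines <- readLines(file.path(d, f))
    expect_length(lines, 1)
  }
})

test_that("written BEDPE follows the 0-based half-open convention", {
  svs <- svRecords(smallCohort()$cohort)[1:5, ]
  d <- withr::local_tempdir()
  writeCohort(CohortBundle(svs = svs,
                           clinical = clinicalData(smallCohort()$cohort)), d)
  bed <- read.delim(file.path(d, "svs.bedpe"))
  expect_equal(bed$start1, svs$start1)   # no +1 shift on write
  expect_true(all(bed$end1 > bed$start1 & bed$end2 > bed$start2))
  expect_true(all(bed$start1 >= 0 & bed$start2 >= 0))
  expect_equal(ncol(bed), 12)            # BEDPE 10 cols + two annotations
})

test_that("validateSegments reports overlaps, gaps and CN inversions", {
  clean <- data.frame(sample_id = "S1", chrom = "1",
                      start = c(0, 100, 200), end = c(100, 200, 300),
                      major_cn = c(1, 2, 1), minor_cn = c(1, 1, 1))
  expect_equal(nrow(validateSegments(clean)), 0)

  overlap <- clean; overlap$start[2] <- 50
  rep1 <- validateSegments(overlap)
  expect_equal(rep1$type, "overlap")

  inv <- clean; inv$major_cn[1] <- 0; inv$minor_cn[1] <- 1
  expect_true("cn_inversion" %in% validateSegments(inv)$type)

  gap <- clean; gap$start[3] <- 200 + 2e6
  gap$end[3] <- gap$start[3] + 100
  expect_true("gap" %in% validateSegments(gap)$type)
})

test_that("cross-reference validation lists offending samples", {
  b <- smallCohort()$cohort
  m <- mutations(b)
  m$sample_id[1] <- "GHOST"
  expect_error(CohortBundle(mutations = m, segments = segments(b),
                            ploidy = ploidyTable(b), svs = svRecords(b),
                            clinical = clinicalData(b)),
               "GHOST")
})

test_that("indels near germline indels are filtered, SNVs kept", {
  muts <- data.frame(
    sample_id = "S1", chrom = "1", pos = c(1000, 1005, 5000),
    ref = c("A", "AT", "CT"), alt = c("G", "A", "C"),
    gene = "", consequence = "noncoding", alt_count = 5, total_depth = 50,
    trinucleotide = "ACA", is_driver_gene = FALSE, pathogenic_flag = NA)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t999\t1000", bed)   # germline indel at 1-based pos 1000
  out <- filterProximalIndels(muts, bed, window = 10)
  expect_equal(out$pos, c(1000, 5000))  # SNV kept, nearby indel dropped,
                                        # distant indel kept
})

test_that("minimal VCF with AD depths is read into the mutation layout", {
  skip_if_not_installed("vcfR")
  v <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOUR",
    "1\t12345\t.\tC\tT\t.\tPASS\t.\tAD\t30,10",
    "2\t999\t.\tG\tA\t.\tPASS\t.\tAD\t55,5"), v)
  m <- readMutationVcf(v, "S1")
  expect_equal(m$pos, c(12345L, 999L))
  expect_equal(m$alt_count, c(10L, 5L))
  expect_equal(m$total_depth, c(40L, 60L))
  expect_equal(unique(m$sample_id), "S1")
})
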
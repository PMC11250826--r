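miniBins <- function(n_chrom = 2, n_bins = 50, width = 1e5) {
  makeBins(data.frame(chrom = as.character(seq_len(n_chrom)),
                      length = n_bins * width), width)
}

test_that("breakend binning counts both ends of simple SVs only", {
  bins <- miniBins()
  svs <- data.frame(sample_id = "T001",
                    chrom1 = "1", start1 = 50, end1 = 51,
                    chrom2 = "1", start2 = 250000, end2 = 250001,
                    sv_class = "DEL", complexity = "simple")
  trk <- collectBreakpoints(svs, bins)
  expect_equal(trk$count[trk$chrom == "1" & trk$start == 0], 1)
  expect_equal(trk$count[trk$chrom == "1" & trk$start == 2e5], 1)
  expect_equal(sum(trk$count), 2)

  svs$complexity <- "complex"
  expect_equal(sum(collectBreakpoints(svs, bins)$count), 0)
})

test_that("total breakend count is conserved through binning", {
  bins <- miniBins(4, 40)
  svs <- plantSvHotspots(bins, 0.5, NULL, NULL, 20, seed = 3)
  trk <- collectBreakpoints(svs, bins)
  expect_equal(sum(trk$count), 2 * nrow(svs))
})

test_that("background fit recovers flat and covariate-driven intensities", {
  set.seed(4)
  bins <- miniBins(4, 100)
  bins$count <- rpois(nrow(bins), 2)
  bg <- fitBackground(bins, character(0))
  expect_lt(abs(mean(bg$mu) - 2) / 2, 0.1)
  ## Poisson data: either Poisson fallback or a very large NB dispersion
  expect_true(bg$family == "poisson" || bg$theta > 20)

  expect_error(fitBackground(transform(miniBins(), count = 0)),
               "all-zero")
})

test_that("a planted 2x covariate effect is recovered at 20,000 bins", {
  set.seed(5)
  nb <- 20000
  bins <- makeBins(data.frame(chrom = "1", length = nb * 1e5), 1e5)
  bins$cov <- rnorm(nb)
  bins$count <- rpois(nb, 2 * exp(log(2) * bins$cov))
  bg <- fitBackground(bins, "cov")
  expect_lt(abs(bg$coefficients[["cov"]] - log(2)) / log(2), 0.2)
})

test_that("segmentation finds step change-points and respects the penalty", {
  bins <- miniBins(1, 100)
  set.seed(6)
  bins$count <- rpois(100, 1)
  bins$count[41:60] <- rpois(20, 10)
  cand <- segmentDensity(bins, min_fold = 1.5)
  expect_gte(nrow(cand), 1)
  best <- cand[which.max(cand$observed), ]
  expect_lt(abs(best$first_bin - 41), 3)
  expect_lt(abs((best$first_bin + best$n_bins - 1) - 60), 3)

  ## homogeneous profile: a single segment per chromosome
  flat <- miniBins(3, 60)
  set.seed(7)
  flat$count <- rpois(nrow(flat), 2)
  all_seg <- segmentDensity(flat, min_fold = 0)
  expect_equal(nrow(all_seg), 3)

  ## infinite penalty: no change-points even over the step
  cand_inf <- segmentDensity(bins, gamma = 1e9, min_fold = 0)
  expect_equal(nrow(cand_inf), 1)
})

test_that("permutation p-values behave at the extremes", {
  bins <- miniBins(1, 60)
  set.seed(8)
  bins$count <- rpois(60, 2)
  bg <- fitBackground(bins, character(0))
  ## a cold candidate (observed below expected) is not significant
  cold <- data.frame(chrom = "1", start = 0, end = 5e5, first_bin = 1,
                     n_bins = 5, observed = 2, expected = 10)
  res <- callHotspots(cold, bins, bg, n_perm = 200, seed = 1)
  expect_gt(res$p_value, 0.5)
  expect_error(callHotspots(cold, bins, bg, n_perm = 50), "100")
})

test_that("planted hotspots are called and seeds only move p within MC error", {
  bins <- simulateCovariateTracks(miniBins(4, 60), seed = 2)
  hs <- data.frame(chrom = c("1", "3"), start = c(1e6, 2e6),
                   end = c(1.5e6, 2.5e6), fold = 10)
  svs <- plantSvHotspots(bins, 1, c(replication_timing = 0.3), hs,
                         n_tumours = 100, seed = 9)
  out1 <- svHotspots(svs, bins, n_perm = 300, seed = 1)
  out2 <- svHotspots(svs, bins, n_perm = 300, seed = 99)
  hit <- function(out, ch, s, e)
    any(out$chrom == ch & out$start < e & out$end > s)
  expect_true(hit(out1, "1", 1e6, 1.5e6))
  expect_true(hit(out1, "3", 2e6, 2.5e6))
  expect_true(hit(out2, "1", 1e6, 1.5e6))
  expect_true(hit(out2, "3", 2e6, 2.5e6))
})

test_that("fragile-site filter flags large late-replicating overlaps", {
  genes <- data.frame(chrom = c("1", "2"), start = c(0, 0),
                      end = c(7e5, 7e5), gene = c("LATE", "EARLY"),
                      rt_quartile = c(4, 1))
  hs <- data.frame(chrom = c("1", "2", "3"), start = 1e5, end = 2e5,
                   observed = 10, expected = 1)
  out <- filterFragile(hs, genes)
  expect_equal(out$fragile_flag, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(attr(out, "retained")), 2)

  ## short late gene does not trigger the flag
  short_ <- data.frame(chrom = "3", start = 0, end = 5e5, gene = "SHORTLATE",
                       rt_quartile = 4)
  expect_false(any(filterFragile(hs[3, ], short_)$fragile_flag))
  expect_false(any(filterFragile(hs, genes[0, ])$fragile_flag))
})

test_that("37 hotspots with 14 fragile leave 23 retained", {
  ## the cohort-scale worked example: fragile exclusion arithmetic
  hs <- data.frame(chrom = as.character(rep(1:22, length.out = 37)),
                   start = (1:37) * 1e5, end = (1:37) * 1e5 + 5e4,
                   observed = 20, expected = 2)
  genes <- data.frame(chrom = hs$chrom[1:14], start = hs$start[1:14] - 1e4,
                      end = hs$start[1:14] + 7e5,
                      gene = paste0("FRG", 1:14), rt_quartile = 4)
  out <- filterFragile(hs, genes)
  expect_equal(sum(out$fragile_flag), 14)
  expect_equal(nrow(attr(out, "retained")), 23)
})
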
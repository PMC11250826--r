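test_that("generation is deterministic given config and seed", {
  cfg <- simulationConfig(n_tumours = 15)
  g1 <- generateCohort(cfg, seed = 5)
  g2 <- generateCohort(cfg, seed = 5)
  expect_identical(mutations(g1$cohort), mutations(g2$cohort))
  expect_identical(svRecords(g1$cohort), svRecords(g2$cohort))
  expect_identical(clinicalData(g1$cohort), clinicalData(g2$cohort))
  expect_identical(g1$truth$gain_times, g2$truth$gain_times)
})

test_that("emitted tables pass load validation", {
  b <- smallCohort()$cohort
  expect_true(validObject(b))
  expect_equal(nrow(validateSegments(segments(b))), 0)
})

test_that("driver marginal frequencies hit their targets", {
  g <- generateCohort(
    simulationConfig(n_tumours = 200, n_background = 0, n_timed = 20),
    seed = 3)
  f <- mean(g$truth$driver_status[, "VHL"])
  ## 99% binomial interval for n=200, p=0.8
  expect_gt(f, 0.72)
  expect_lt(f, 0.88)
})

test_that("minus-infinity interaction log-odds forbids co-mutation", {
  cfg <- simulationConfig(
    n_tumours = 150, n_background = 0, n_timed = 20,
    interactions = data.frame(gene_a = "SETD2", gene_b = "BAP1",
                              log_odds = -Inf))
  g <- generateCohort(cfg, seed = 9)
  st <- g$truth$driver_status
  expect_equal(sum(st[, "SETD2"] & st[, "BAP1"]), 0)
  ## marginals still near target despite the exclusivity constraint
  expect_lt(abs(mean(st[, "SETD2"]) - 0.18), 0.1)

  ## marginals that cannot coexist with hard exclusivity must error
  bad <- simulationConfig(
    n_tumours = 50,
    interactions = data.frame(gene_a = "VHL", gene_b = "PBRM1",
                              log_odds = -Inf))
  expect_error(generateCohort(bad, seed = 1), "infeasible")
})

test_that("timed segments follow the gain accrual model", {
  ## pi 0 leaves every mutation at multiplicity 1
  m0 <- simulateTimedSegment("2+1", 0, 300, purity = 0.8, mean_depth = 80,
                             seed = 2)
  expect_true(all(m0$true_multiplicity == 1))

  ## state 2+1 at pi 0.5: expected m2 fraction is 0.5/(3-0.5) = 0.2
  m <- simulateTimedSegment("2+1", 0.5, 600, purity = 0.8, mean_depth = 80,
                            seed = 4)
  frac2 <- mean(m$true_multiplicity == 2)
  expect_lt(abs(frac2 - 0.2), 0.04)   # 3 binomial SDs at n ~ 600

  ## heterozygous diploid at purity 1: VAF centred on 0.5
  mh <- simulateTimedSegment("2+1", 0, 500, purity = 1, mean_depth = 100,
                             seed = 5)
  ## state has CNt 3; build the diploid check directly instead
  mm <- simulateTimedSegment("2+0", 0, 500, purity = 1, mean_depth = 100,
                             seed = 6)
  expect_lt(abs(mean(mm$alt_count / mm$total_depth) - 0.5), 0.01)
  expect_error(simulateTimedSegment("2+1", 0.5, 0, 0.8, 80), "n_expected")
})

test_that("planted SV hotspots have the configured intensity", {
  bins <- simulateCovariateTracks(makeBins(defaultGenome(), 1e5), seed = 1)

  ## zero base rate emits nothing
  expect_equal(nrow(plantSvHotspots(bins, 0, NULL, NULL, 10, seed = 1)), 0)

  ## 10x fold over 5 bins at base mean 1: expected 50 breakends, sd ~7.1
  hs <- data.frame(chrom = "2", start = 1e6, end = 1.5e6, fold = 10)
  svs <- plantSvHotspots(bins, 1, NULL, hs, n_tumours = 50, seed = 8)
  trk <- collectBreakpoints(svs, bins)
  hot <- trk$chrom == "2" & trk$start >= 1e6 & trk$end <= 1.5e6
  expect_lt(abs(sum(trk$count[hot]) - 50), 3 * sqrt(50))

  ## null per-bin counts are Poisson: variance/mean dispersion check
  sv0 <- plantSvHotspots(bins, 1, NULL, NULL, 50, seed = 9)
  cnt <- collectBreakpoints(sv0, bins)$count
  disp <- sum((cnt - mean(cnt))^2) / mean(cnt)   # ~ chisq df n-1 under Poisson
  n <- length(cnt)
  expect_gt(disp, qchisq(0.005, n - 1))
  expect_lt(disp, qchisq(0.995, n - 1))

  expect_error(plantSvHotspots(bins, 1, NULL,
                               data.frame(chrom = "1", start = 0, end = 1e5,
                                          fold = 0.5), 10),
               "fold")
})

test_that("simulated survival respects the proportional-hazards spec", {
  spec <- list(baseline_rate = log(2) / (5 * 365), log_hrs = c(x = log(0.6)),
               censor_rate = 0.3, max_followup = 15 * 365)
  feats <- data.frame(x = rep(0:1, each = 300))
  s <- simulateSurvival(feats, spec, seed = 21)
  fit <- survival::coxph(survival::Surv(s$time, s$event) ~ x, data = feats)
  expect_lt(abs(coef(fit) - log(0.6)), 0.15)

  ## censoring rate 1 yields zero events
  spec$censor_rate <- 1
  s1 <- simulateSurvival(feats, spec, seed = 3)
  expect_equal(sum(s1$event), 0)

  expect_error(simulateSurvival(feats, list(baseline_rate = 1,
                                            log_hrs = c(x = Inf),
                                            censor_rate = 0), 1),
               "non-finite")
})

test_that("null survival simulation is log-rank calibrated", {
  ## no effects planted: groups split on a random binary feature should
  ## reject at alpha = 0.01 about 1% of the time
  spec <- list(baseline_rate = log(2) / (5 * 365), log_hrs = numeric(0),
               censor_rate = 0.3, max_followup = 15 * 365)
  rejections <- vapply(1:50, function(r) {
    feats <- data.frame(g = withr::with_seed(1000 + r,
                                             rbinom(120, 1, 0.5)))
    s <- simulateSurvival(feats, spec, seed = 2000 + r)
    kmLogrank(s$time, s$event, feats$g)$p < 0.01
  }, logical(1))
  expect_gte(mean(!rejections), 0.95)
})

test_that("escape truth labels match the classifier input", {
  g <- smallCohort()
  esc <- attr(g$cohort, "immune")
  calls <- classifyEscape(esc)
  expect_identical(calls$escape, g$truth$escape$escape)
})
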
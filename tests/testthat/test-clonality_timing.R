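test_that("multiplicity follows the VAF decomposition with clamping", {
  expect_equal(estimateMultiplicity(50, 100, 1, 1, 1), 1L)
  ## VAF 0.5 at purity 0.5, CNt 3: m_raw = (0.5/0.5) * (1.5 + 1) = 2.5,
  ## half-up rounds to 2, within major_cn
  expect_equal(estimateMultiplicity(50, 100, 0.5, 2, 1), 2L)
  ## VAF 0.9 diploid: raw 1.8 rounds to 2, clamped to major_cn = 1
  expect_equal(estimateMultiplicity(90, 100, 1, 1, 1), 1L)
  expect_error(estimateMultiplicity(1, 0, 1, 1, 1), "depth")
  ## vectorised: VAF 0.5 at CNt 3 gives raw 1.5 -> 2; VAF 0.9 at CNt 2 gives 2
  expect_equal(estimateMultiplicity(c(50, 90), 100, 1, c(2, 2), c(1, 0)),
               c(2L, 2L))
})

test_that("CCF point estimates follow the linear map", {
  expect_equal(computeCcf(50, 100, 1, 2, 1)$ccf, 1.0)
  expect_equal(computeCcf(25, 100, 0.5, 2, 1)$ccf, 1.0)
  cc <- computeCcf(150, 100 * 2, 1, 2, 1)   # VAF beyond 0.5: capped
  expect_lte(cc$ccf, 1.5)
})

test_that("CCF estimator is calibrated at true CCF 0.4", {
  set.seed(31)
  n <- 1000; depth <- 100; rho <- 0.8; cnt <- 2
  vaf <- 0.4 * 1 * rho / (rho * cnt + 2 * (1 - rho))
  alt <- rbinom(n, depth, vaf)
  cc <- computeCcf(alt, depth, rho, cnt, 1)
  expect_lt(abs(mean(cc$ccf) - 0.4), 0.02)
  coverage <- mean(cc$ci_low <= 0.4 & cc$ci_high >= 0.4)
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.98)
})

test_that("clonality rule recovers a planted clonal/subclonal split", {
  expect_equal(classifyClonal(1.0, 1.1), "clonal")
  expect_equal(classifyClonal(0.3, 0.4), "subclonal")
  set.seed(7)
  n <- 2000; depth <- 80; rho <- 0.8
  clonal <- runif(n) < 0.7
  f <- ifelse(clonal, 1, runif(n, 0.15, 0.45))
  vaf <- f * rho / (rho * 2 + 2 * (1 - rho))
  alt <- rbinom(n, depth, vaf)
  calls <- classifyClonal(computeCcf(alt, depth, rho, 2, 1))
  expect_lt(abs(mean(calls == "clonal") - 0.7), 0.05)
})

test_that("gain-time closed forms match their definitions", {
  expect_equal(timeGain(50, 0, "2+1")$pi, 0)
  expect_equal(timeGain(10, 10, "2+0")$pi, 20 / 30)
  expect_equal(timeGain(20, 20, "2+1")$pi, 1)   # 60/60, capped at 1
  expect_error(timeGain(0, 0, "2+1"), "no clonal mutations")
  tg <- timeGain(30, 10, "2+1", B = 500, seed = 2)
  expect_true(tg$ci_low <= tg$pi && tg$pi <= tg$ci_high)
})

test_that("pi estimators are scale-invariant and monotone in n2", {
  for (state in c("2+1", "2+0", "2+2")) {
    for (a in c(2L, 5L)) {
      expect_equal(timeGain(7 * a, 3 * a, state)$pi,
                   timeGain(7, 3, state)$pi)
    }
    pis <- vapply(0:20, function(n2) timeGain(10, n2, state)$pi, numeric(1))
    expect_true(all(diff(pis) >= 0))
  }
})

test_that("closed forms agree with brute-force multinomial ML", {
  ## spot-check grid; the exhaustive sweep runs in the acceptance suite
  set.seed(5)
  for (i in 1:40) {
    n1 <- sample(0:30, 1); n2 <- sample(0:30, 1)
    if (n1 + n2 == 0) n1 <- 1
    state <- sample(c("2+1", "2+0", "2+2"), 1)
    expect_lt(abs(timeGain(n1, n2, state)$pi - gridPiML(n1, n2, state)),
              0.001)
  }
})

test_that("WGD timing pools 2+2 segments", {
  expect_equal(timeWgd(10, 10)$pi, timeGain(10, 10, "2+2")$pi)
  expect_equal(timeWgd(c(10, 30), c(10, 30))$pi, 2 * 40 / (40 + 80))
  expect_error(timeWgd(integer(0), integer(0)), "not applicable")
})

test_that("WGD timing recovers a planted pi of 0.8", {
  m <- simulateTimedSegment("2+2", 0.8, 800, purity = 0.85, mean_depth = 100,
                            seed = 12)
  mult <- estimateMultiplicity(m$alt_count, m$total_depth, 0.85, 2, 2)
  est <- timeWgd(sum(mult == 1), sum(mult >= 2), seed = 3)
  expect_lt(abs(est$pi - 0.8), 0.05)
})

test_that("timing classes follow the multiplicity rule", {
  expect_equal(assignMutationTiming("2+1", 1, FALSE), "subclonal")
  expect_equal(assignMutationTiming("2+2", 2, TRUE), "early-clonal")
  expect_equal(assignMutationTiming("2+1", 1, TRUE), "late-clonal")
  expect_equal(assignMutationTiming("1+1", 1, TRUE), "clonal-NA")
})

test_that("clock rate is burden over age, with truth recovery", {
  expect_equal(estimateClockRate(3000, 60), 50)
  expect_warning(r0 <- estimateClockRate(0, 50), "zero")
  expect_equal(r0, 0)
  expect_error(estimateClockRate(100, 0), "age")
  set.seed(17)
  burden <- rpois(1, 40 * 65)   # forward model: mu = 40/yr over 65 years
  expect_lt(abs(estimateClockRate(burden, 65) - 40) / 40, 0.1)
})

test_that("real-time conversion inverts the two-phase clock", {
  expect_equal(convertToRealTime(0.5, 60)$years_before_sampling, 30)
  expect_equal(convertToRealTime(1, 60)$years_before_sampling, 0)
  ## k=5, c=0.9: M = 1.4, pi*M = 0.7 <= c, so t_cal = 0.7 -> 18 years
  expect_equal(
    convertToRealTime(0.5, 60, clockModel(k = 5, c = 0.9))$years_before_sampling,
    18)
  ## monotone decreasing in pi for arbitrary valid clocks
  for (kk in c(1, 2, 8)) for (cc in c(0, 0.4, 0.95)) {
    y <- convertToRealTime(seq(0, 1, 0.05), 70,
                           clockModel(k = kk, c = cc))$years_before_sampling
    expect_true(all(diff(y) <= 1e-9))
  }
  ## CI propagation flips the interval through the monotone map
  out <- convertToRealTime(0.5, 60, clockModel(), ci_low = 0.4, ci_high = 0.6)
  expect_equal(out$ci_low, 60 * (1 - 0.6))
  expect_equal(out$ci_high, 60 * (1 - 0.4))
})

test_that("cohort-level timing recovers planted gain times", {
  g <- smallCohort()
  tg <- timeCohortGains(g$cohort, B = 200, seed = 3)
  tr <- g$truth$gain_times
  m <- merge(tg[tg$chrom %in% c("5", "WGD"), ], tr,
             by = c("sample_id", "chrom"))
  expect_gt(nrow(m), 10)
  expect_lt(mean(abs(m$pi - m$pi_true)), 0.05)
})
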
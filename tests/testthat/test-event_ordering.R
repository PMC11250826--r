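mkCalls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], event = r[[2]],
               timing = if (is.character(r[[3]])) r[[3]] else NA_character_,
               pi = if (is.numeric(r[[3]])) r[[3]] else NA_real_,
               stringsAsFactors = FALSE)))
}

test_that("pairwise precedence applies the class and pi rules", {
  pp <- pairwisePrecedence(mkCalls(list("s1", "A", "early-clonal"),
                                   list("s1", "B", "subclonal")))
  expect_equal(pp$wins["A", "B"], 1)
  expect_equal(pp$wins["B", "A"], 0)

  pp2 <- pairwisePrecedence(mkCalls(list("s1", "A", "clonal-NA"),
                                    list("s1", "B", "clonal-NA")))
  expect_equal(pp2$ties["A", "B"], 1)

  ## CNA pi within the 0.05 margin ties
  pp3 <- pairwisePrecedence(mkCalls(list("s1", "g5q", 0.2),
                                    list("s1", "g7", 0.22)))
  expect_equal(pp3$ties["g5q", "g7"], 1)
  pp4 <- pairwisePrecedence(mkCalls(list("s1", "g5q", 0.2),
                                    list("s1", "g7", 0.5)))
  expect_equal(pp4$wins["g5q", "g7"], 1)

  ## clonal-NA beats subclonal
  pp5 <- pairwisePrecedence(mkCalls(list("s1", "A", "clonal-NA"),
                                    list("s1", "B", "subclonal")))
  expect_equal(pp5$wins["A", "B"], 1)

  ## wins + losses + ties equals the co-occurrence count
  set.seed(2)
  cls <- c("early-clonal", "late-clonal", "subclonal", "clonal-NA")
  calls <- do.call(rbind, lapply(1:30, function(s) mkCalls(
    list(paste0("s", s), "A", sample(cls, 1)),
    list(paste0("s", s), "B", sample(cls, 1)))))
  pp6 <- pairwisePrecedence(calls)
  expect_equal(pp6$wins["A", "B"] + pp6$wins["B", "A"] +
                 pp6$ties["A", "B"], 30)
})

test_that("league ranks a dominant event first", {
  calls <- do.call(rbind, lapply(1:10, function(s) mkCalls(
    list(paste0("s", s), "A", "early-clonal"),
    list(paste0("s", s), "B", "subclonal"))))
  lg <- runLeague(calls, n_boot = 100, seed = 1)
  expect_equal(lg$position[lg$event == "A"], 1)
  expect_equal(lg$position[lg$event == "B"], 2)
  expect_true(all(lg$ci_low <= lg$mean_finishing_position &
                    lg$mean_finishing_position <= lg$ci_high))
})

test_that("symmetric records give equal mean positions", {
  calls <- do.call(rbind, lapply(1:40, function(s) {
    cls <- sample(c("early-clonal", "subclonal"))
    mkCalls(list(paste0("s", s), "A", cls[1]),
            list(paste0("s", s), "B", cls[2]))
  }))
  set.seed(1)
  lg <- runLeague(calls, n_boot = 200, seed = 4)
  expect_lt(abs(diff(lg$mean_finishing_position)), 0.5)
})

test_that("league recovers any total order (brute force, <= 5 events)", {
  set.seed(6)
  for (k in 3:5) {
    events <- LETTERS[1:k]
    perm <- sample(events)          # hidden true order
    W <- matrix(0, k, k, dimnames = list(events, events))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      W[perm[i], perm[j]] <- sample(3:10, 1)   # earlier always beats later
    }
    ## feed the matrix through the fitter via synthetic one-on-one calls
    calls <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
      do.call(rbind, lapply((i + 1):k, function(j) {
        n <- W[perm[i], perm[j]]
        do.call(rbind, lapply(seq_len(n), function(r) mkCalls(
          list(paste0(perm[i], perm[j], r), perm[i], "early-clonal"),
          list(paste0(perm[i], perm[j], r), perm[j], "subclonal"))))
      }))
    }))
    lg <- runLeague(calls, n_boot = 0)
    expect_equal(lg$event[order(lg$position)], perm)
  }
})

test_that("league positions are invariant to relabelling and duplication", {
  set.seed(8)
  calls <- do.call(rbind, lapply(1:25, function(s) mkCalls(
    list(paste0("s", s), "A",
         sample(c("early-clonal", "late-clonal"), 1, prob = c(0.8, 0.2))),
    list(paste0("s", s), "B",
         sample(c("early-clonal", "subclonal"), 1, prob = c(0.3, 0.7))))))
  lg1 <- runLeague(calls, n_boot = 0)
  ## duplicate every tumour
  dup <- calls; dup$sample_id <- paste0(dup$sample_id, "_copy")
  lg2 <- runLeague(rbind(calls, dup), n_boot = 0)
  expect_equal(lg2$position, lg1$position)
  ## relabel events
  swp <- calls; swp$event <- c(A = "Z", B = "Y")[swp$event]
  lg3 <- runLeague(swp, n_boot = 0)
  expect_equal(sort(lg3$position), sort(lg1$position))
})

test_that("clonality odds ratios follow the 2x2 construction", {
  counts <- data.frame(gene = c("VHL", "rest"), clonal = c(30, 300),
                       subclonal = c(10, 100))
  res <- clonalityOdds(counts)
  expect_equal(res$odds_ratio[1], (30 * 100) / (10 * 300))

  ## zero cell: continuity correction keeps the OR finite
  z <- clonalityOdds(data.frame(gene = c("g", "rest"), clonal = c(12, 100),
                                subclonal = c(0, 40)))
  expect_true(is.finite(z$odds_ratio[1]) && z$odds_ratio[1] > 0)

  ## transposing clonal/subclonal inverts the OR
  a <- clonalityOdds(data.frame(gene = c("g", "r"), clonal = c(20, 50),
                                subclonal = c(5, 80)))$odds_ratio[1]
  b <- clonalityOdds(data.frame(gene = c("g", "r"), clonal = c(5, 80),
                                subclonal = c(20, 50)))$odds_ratio[1]
  expect_equal(a, 1 / b)
})
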
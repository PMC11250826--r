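## Synthetic-cohort generator with planted ground truth for every pipeline
## stage: true gain times, true mutation multiplicities and clonality, true
## driver frequencies and interaction log-odds, planted SV hotspots over
## covariate tracks, true immune-escape labels and true log-hazard-ratios.
## The emulated cohort is a scaled-down whole-genome renal-cancer study:
## 22 autosomes of 10 Mb each, whole-chromosome copy-number events, and a
## handful of recurrent driver genes at realistic marginal frequencies.

#' Reduced autosomal genome used by the simulator
#'
#' @param chrom_length chromosome length in bp (default 10 Mb)
#' @return data.frame with chrom ("1".."22"), length, centromere position
#' @export
defaultGenome <- function(chrom_length = 1e7) {
  data.frame(chrom = as.character(1:22), length = chrom_length,
             centromere = round(0.4 * chrom_length),
             stringsAsFactors = FALSE)
}

#' The 96 single-base-substitution context channels
#'
#' Pyrimidine-centred trinucleotides crossed with the three alternative
#' bases, keyed \code{"<tri>:<alt>"}.
#'
#' @return character vector of length 96
#' @export
contexts96 <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (mid in c("C", "T")) for (up in bases) for (dn in bases) {
    tri <- paste0(up, mid, dn)
    for (alt in setdiff(bases, mid)) out <- c(out, paste0(tri, ":", alt))
  }
  out
}

#' Simulation configuration with study-scale defaults
#'
#' Defaults encode the cohort conditions the pipeline is designed for:
#' driver marginal frequencies near those reported for ccRCC (VHL 0.80,
#' PBRM1 0.50, SETD2 0.18, BAP1 0.10, ...), 3p loss in 90% of tumours, a
#' timed 5q gain (state 2+1) in 60%, WGD probability 0.166, immune-escape
#' mechanism rates 5.9% / 0.5% / 3.1% (HLA LOH / HLA mutation / APG
#' inactivation), a protective VHL survival effect HR 0.6, and a
#' clock of 40 clonal mutations per year with a constant-rate default
#' (k = 1).
#'
#' @param n_tumours cohort size
#' @param ... overrides for any element of the default list (see source)
#' @return list of class \code{SimulationConfig}
#' @export
simulationConfig <- function(n_tumours = 200, ...) {
  cfg <- list(
    n_tumours = n_tumours,
    genome = defaultGenome(),
    purity_shape = c(8, 4),          # Beta: mean 2/3, typical FFPE-free range
    mean_depth = 80,
    drivers = data.frame(
      gene = c("VHL", "PBRM1", "SETD2", "BAP1", "KDM5C", "STAG2"),
      chrom = c("3", "3", "3", "3", "1", "2"),
      freq = c(0.80, 0.50, 0.18, 0.10, 0.07, 0.03),
      p_early = c(0.70, 0.50, 0.30, 0.30, 0.10, 0.10),
      p_late = c(0.20, 0.30, 0.40, 0.40, 0.30, 0.30),
      p_subclonal = c(0.10, 0.20, 0.30, 0.30, 0.60, 0.60),
      stringsAsFactors = FALSE),
    interactions = data.frame(gene_a = character(0), gene_b = character(0),
                              log_odds = numeric(0)),
    p_3p_loss = 0.9,
    p_5q_gain = 0.6,
    pi_5q = c(0.05, 0.5),            # uniform range of true gain times
    wgd_prob = 0.166,
    pi_wgd = c(0.3, 0.9),
    wgd_timed_chroms = c("7", "12", "16"),
    n_timed = 500,                   # expected clonal muts per timed segment
    n_background = 10,               # expected passenger muts per chromosome
    subclonal_frac = 0.3,            # fraction of passengers that are subclonal
    subclonal_ccf = c(0.1, 0.5),
    context_probs = NULL,            # NULL = uniform over the 96 channels
    sv = list(bin_size = 1e5, base_rate = 0.2,
              covariate_effects = c(replication_timing = 0.3),
              hotspots = data.frame(chrom = c("5", "11"),
                                    start = c(2e6, 4e6), end = c(2.5e6, 4.5e6),
                                    fold = c(10, 10)),
              complex_rate = 0.05, n_per_tumour = NA),
    escape = list(hla_loh = 0.059, hla_mutation = 0.005,
                  apg_inactivation = 0.031),
    survival = list(baseline_rate = log(2) / (5 * 365),  # median OS 5 years
                    log_hrs = c(VHL = log(0.6)),
                    censor_rate = 0.4, max_followup = 15 * 365),
    clock = list(mu = 40, k = 1, c = 0.5),
    germline_carrier_rate = 0.028,
    callable_mb = 3000)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  .assertThat(
    "n_tumours must be >= 1" = cfg$n_tumours >= 1,
    "probabilities must lie in [0,1]" = all(c(
      cfg$drivers$freq, cfg$p_3p_loss, cfg$p_5q_gain, cfg$wgd_prob,
      unlist(cfg$escape)) >= 0 & c(
      cfg$drivers$freq, cfg$p_3p_loss, cfg$p_5q_gain, cfg$wgd_prob,
      unlist(cfg$escape)) <= 1),
    "hotspot folds must be >= 1" = all(cfg$sv$hotspots$fold >= 1))
  class(cfg) <- "SimulationConfig"
  cfg
}

## ---- driver status: Ising-like sampler with calibrated fields ----------

## joint sampler over binary gene indicators: P(x) prop exp(sum h x +
## sum J x_a x_b); fields h calibrated by damped fixed point to hit the
## target marginals. Components of the interaction graph are enumerated
## exactly (gene panels are small).
.sampleDrivers <- function(drivers, interactions, n) {
  genes <- drivers$gene
  k <- length(genes)
  J <- matrix(0, k, k, dimnames = list(genes, genes))
  if (nrow(interactions)) {
    for (i in seq_len(nrow(interactions))) {
      a <- interactions$gene_a[i]; b <- interactions$gene_b[i]
      J[a, b] <- J[b, a] <- interactions$log_odds[i]
    }
  }
  ## connected components of the interaction graph
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (J[i, j] != 0 && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  X <- matrix(0L, n, k, dimnames = list(NULL, genes))
  for (cp in unique(comp)) {
    idx <- which(comp == cp)
    kk <- length(idx)
    states <- as.matrix(expand.grid(rep(list(0:1), kk)))
    target <- drivers$freq[idx]
    h <- stats::qlogis(pmin(pmax(target, 1e-6), 1 - 1e-6))
    Jc <- J[idx, idx, drop = FALSE]
    pair_term <- apply(states, 1, function(s) {
      v <- 0
      if (kk > 1) for (a in seq_len(kk - 1)) for (b in (a + 1):kk) {
        if (s[a] == 1 && s[b] == 1) v <- v + Jc[a, b]
      }
      v
    })
    marg <- function(h) {
      lw <- states %*% h + pair_term
      lw[is.nan(lw)] <- -Inf                   # -Inf interaction, both mutated
      w <- exp(lw - max(lw)); w <- w / sum(w)
      list(m = as.vector(t(states) %*% w), w = w)
    }
    ok <- FALSE
    for (it in 1:200) {
      mg <- marg(h)
      err <- target - mg$m
      if (max(abs(err)) < 1e-4) { ok <- TRUE; break }
      h <- h + 0.8 * (stats::qlogis(pmin(pmax(target, 1e-6), 1 - 1e-6)) -
                      stats::qlogis(pmin(pmax(mg$m, 1e-9), 1 - 1e-9)))
    }
    if (!ok) stop("interaction spec infeasible: target marginals unreachable",
                  call. = FALSE)
    draw <- sample(nrow(states), n, replace = TRUE, prob = marg(h)$w)
    X[, idx] <- states[draw, , drop = FALSE]
  }
  X == 1L
}

## ---- mutation-level forward models -------------------------------------

## expected VAF of a mutation at multiplicity m and cancer cell fraction f
.expVaf <- function(m, f, purity, cnt) {
  f * m * purity / (purity * cnt + 2 * (1 - purity))
}

.drawContexts <- function(n, context_probs = NULL) {
  ch <- contexts96()
  if (is.null(context_probs)) context_probs <- rep(1 / 96, 96)
  pick <- sample(ch, n, replace = TRUE, prob = context_probs)
  tri <- substr(pick, 1, 3)
  list(tri = tri, ref = substr(tri, 2, 2), alt = substr(pick, 5, 5))
}

#' Simulate clonal mutations in a timed gained segment
#'
#' Forward model of the gain clock. For a gain at molecular time pi the
#' per-unit-time allele-copy weights give the expected split between
#' multiplicity-2 (pre-gain, duplicated) and multiplicity-1 mutations:
#' 2+1: (pi, 3-2 pi); 2+0: (pi, 2-2 pi); 2+2: (2 pi, 4-4 pi). Read counts
#' are binomial around the expected VAF at Poisson depth.
#'
#' @param state "2+1", "2+0" or "2+2"
#' @param pi_true true molecular time in [0,1]
#' @param n_expected expected clonal mutation count (Poisson)
#' @param purity tumour purity
#' @param mean_depth mean sequencing depth
#' @param seed RNG seed
#' @param chrom,sample_id record labels
#' @param chrom_length chromosome length for positions
#' @param context_probs optional 96-channel probabilities
#' @return mutation data.frame with an extra true_multiplicity column
#' @export
simulateTimedSegment <- function(state, pi_true, n_expected, purity,
                                 mean_depth, seed = 1L, chrom = "1",
                                 sample_id = "S1", chrom_length = 1e7,
                                 context_probs = NULL) {
  state <- match.arg(state, c("2+1", "2+0", "2+2"))
  .assertThat("pi_true must be in [0,1]" = pi_true >= 0 && pi_true <= 1,
              "n_expected must be > 0" = n_expected > 0)
  withr::with_seed(seed, {
    w <- switch(state,
      "2+1" = c(3 - 2 * pi_true, pi_true),
      "2+0" = c(2 - 2 * pi_true, pi_true),
      "2+2" = c(4 - 4 * pi_true, 2 * pi_true))
    cnt <- switch(state, "2+1" = 3, "2+0" = 2, "2+2" = 4)
    n <- stats::rpois(1, n_expected)
    if (n == 0) return(.emptyMutations())
    m <- 1L + stats::rbinom(n, 1, w[2] / sum(w))
    depth <- pmax(stats::rpois(n, mean_depth), 1)
    alt <- stats::rbinom(n, depth, .expVaf(m, 1, purity, cnt))
    ctx <- .drawContexts(n, context_probs)
    data.frame(
      sample_id = sample_id, chrom = chrom,
      pos = sort(ceiling(stats::runif(n) * chrom_length)), ref = ctx$ref,
      alt = ctx$alt, gene = "", consequence = "noncoding",
      alt_count = alt, total_depth = depth, trinucleotide = ctx$tri,
      is_driver_gene = FALSE, pathogenic_flag = NA,
      true_multiplicity = m, true_clonal = TRUE,
      stringsAsFactors = FALSE)
  })
}

.emptyMutations <- function() {
  data.frame(sample_id = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), gene = character(0),
             consequence = character(0), alt_count = integer(0),
             total_depth = integer(0), trinucleotide = character(0),
             is_driver_gene = logical(0), pathogenic_flag = logical(0),
             true_multiplicity = integer(0), true_clonal = logical(0),
             stringsAsFactors = FALSE)
}

## passenger mutations on an unperturbed (or gained) chromosome; clonal
## muts follow the segment's accrual model, a configured fraction is
## subclonal at low CCF
.simulateChromosomeMutations <- function(n_expected, state, pi_true, purity,
                                         mean_depth, chrom, sample_id,
                                         chrom_length, subclonal_frac,
                                         subclonal_ccf, context_probs) {
  n <- stats::rpois(1, n_expected)
  if (n == 0) return(.emptyMutations())
  sub <- stats::runif(n) < subclonal_frac
  cnt <- switch(state, "1+1" = 2, "1+0" = 1, "2+1" = 3, "2+0" = 2, "2+2" = 4)
  mclon <- if (state %in% c("2+1", "2+0", "2+2")) {
    w <- switch(state, "2+1" = c(3 - 2 * pi_true, pi_true),
                "2+0" = c(2 - 2 * pi_true, pi_true),
                "2+2" = c(4 - 4 * pi_true, 2 * pi_true))
    1L + stats::rbinom(n, 1, w[2] / sum(w))
  } else rep(1L, n)
  m <- ifelse(sub, 1L, mclon)
  f <- ifelse(sub, stats::runif(n, subclonal_ccf[1], subclonal_ccf[2]), 1)
  depth <- pmax(stats::rpois(n, mean_depth), 1)
  alt <- stats::rbinom(n, depth, .expVaf(m, f, purity, cnt))
  ctx <- .drawContexts(n, context_probs)
  data.frame(
    sample_id = sample_id, chrom = chrom,
    pos = sort(ceiling(stats::runif(n) * chrom_length)), ref = ctx$ref, alt = ctx$alt,
    gene = "", consequence = sample(c("synonymous", "noncoding"), n, TRUE),
    alt_count = alt, total_depth = depth, trinucleotide = ctx$tri,
    is_driver_gene = FALSE, pathogenic_flag = NA,
    true_multiplicity = m, true_clonal = !sub, stringsAsFactors = FALSE)
}

## ---- SV forward model ---------------------------------------------------

#' Plant structural-variant breakends over a covariate background
#'
#' Per-bin breakend counts are Poisson with mean
#' base_rate x exp(covariate effects) x fold(bin), fold >= 1 inside planted
#' hotspot intervals and 1 elsewhere. Breakends are paired within
#' chromosomes into simple SV records (one unpaired breakend per chromosome
#' is dropped).
#'
#' @param bins bin data.frame with covariate columns
#' @param base_rate baseline expected breakends per bin (cohort-wide)
#' @param covariate_effects named log-linear effects on the bin covariates
#' @param hotspots data.frame chrom/start/end/fold (fold >= 1)
#' @param n_tumours tumours to spread the SVs across
#' @param seed RNG seed
#' @return SV data.frame (complexity "simple")
#' @export
plantSvHotspots <- function(bins, base_rate, covariate_effects = NULL,
                            hotspots = NULL, n_tumours = 1, seed = 1L) {
  if (!is.null(hotspots) && nrow(hotspots) && any(hotspots$fold < 1)) {
    stop("hotspot fold must be >= 1", call. = FALSE)
  }
  withr::with_seed(seed, {
    mu <- rep(base_rate, nrow(bins))
    if (length(covariate_effects)) {
      for (nm in names(covariate_effects)) {
        mu <- mu * exp(covariate_effects[[nm]] * bins[[nm]])
      }
    }
    fold <- rep(1, nrow(bins))
    if (!is.null(hotspots) && nrow(hotspots)) {
      for (i in seq_len(nrow(hotspots))) {
        hit <- bins$chrom == hotspots$chrom[i] &
          bins$start >= hotspots$start[i] & bins$end <= hotspots$end[i]
        fold[hit] <- pmax(fold[hit], hotspots$fold[i])
      }
    }
    counts <- stats::rpois(nrow(bins), mu * fold)
    if (sum(counts) == 0) return(.emptySvs())
    be <- data.frame(
      chrom = rep(bins$chrom, counts),
      pos = unlist(lapply(which(counts > 0), function(b)
        bins$start[b] + floor(stats::runif(counts[b]) *
                              (bins$end[b] - bins$start[b])))))
    out <- list()
    for (ch in unique(be$chrom)) {
      p <- sample(be$pos[be$chrom == ch])      # shuffle before pairing
      np <- floor(length(p) / 2)
      if (np == 0) next
      a <- p[seq_len(np) * 2 - 1]; b <- p[seq_len(np) * 2]
      lo <- pmin(a, b); hi <- pmax(a, b)
      out[[ch]] <- data.frame(
        sample_id = sprintf("T%03d", sample.int(n_tumours, np, replace = TRUE)),
        chrom1 = ch, start1 = lo, end1 = lo + 1L,
        chrom2 = ch, start2 = hi, end2 = hi + 1L,
        sv_class = sample(c("DEL", "TD", "UNCLASSIFIED"), np, TRUE,
                          prob = c(0.45, 0.3, 0.25)),
        complexity = "simple", stringsAsFactors = FALSE)
    }
    if (!length(out)) return(.emptySvs())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

.emptySvs <- function() {
  data.frame(sample_id = character(0), chrom1 = character(0),
             start1 = integer(0), end1 = integer(0), chrom2 = character(0),
             start2 = integer(0), end2 = integer(0), sv_class = character(0),
             complexity = character(0), stringsAsFactors = FALSE)
}

#' Simulate covariate tracks over genome bins
#'
#' @param bins from \code{\link{makeBins}}
#' @param seed RNG seed
#' @return bins with six standard-normal-ish covariate columns (gc on its
#'   natural scale)
#' @export
simulateCovariateTracks <- function(bins, seed = 1L) {
  withr::with_seed(seed, {
    n <- nrow(bins)
    bins$gc <- stats::rnorm(n, 0.45, 0.05)
    for (nm in c("replication_timing", "gene_density",
                 "chromatin_accessibility", "repeats", "expression")) {
      bins[[nm]] <- stats::rnorm(n)
    }
    bins
  })
}

## ---- survival forward model ---------------------------------------------

#' Simulate survival endpoints under proportional hazards
#'
#' Exponential event times with hazard baseline_rate x exp(X beta),
#' independent exponential censoring calibrated to the requested censoring
#' fraction, and administrative censoring at max_followup.
#'
#' @param features data.frame containing the columns named in log_hrs
#' @param spec list with baseline_rate (per day), log_hrs (named),
#'   censor_rate in [0,1], max_followup (days)
#' @param seed RNG seed
#' @return data.frame with time (days) and event (0/1)
#' @export
simulateSurvival <- function(features, spec, seed = 1L) {
  if (length(spec$log_hrs) && any(!is.finite(unlist(spec$log_hrs)))) {
    stop("non-finite log hazard ratio", call. = FALSE)
  }
  n <- nrow(features)
  withr::with_seed(seed, {
    lp <- rep(0, n)
    for (nm in names(spec$log_hrs)) {
      lp <- lp + spec$log_hrs[[nm]] * as.numeric(features[[nm]])
    }
    tt <- stats::rexp(n, rate = spec$baseline_rate * exp(lp))
    if (spec$censor_rate >= 1) {
      return(data.frame(time = pmin(tt, spec$max_followup), event = 0L))
    }
    if (spec$censor_rate > 0) {
      crate <- spec$baseline_rate * spec$censor_rate / (1 - spec$censor_rate)
      cc <- stats::rexp(n, rate = crate)
    } else cc <- rep(Inf, n)
    cc <- pmin(cc, spec$max_followup)
    data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
  })
}

## per-tumour driver timing classes drawn from gene-specific probabilities;
## the planted cohort order is the genes sorted by expected class rank
.simulateEventCalls <- function(drivers, status) {
  out <- list()
  for (g in seq_len(nrow(drivers))) {
    sids <- rownames(status)[status[, drivers$gene[g]]]
    if (!length(sids)) next
    cls <- sample(c("early-clonal", "late-clonal", "subclonal"),
                  length(sids), replace = TRUE,
                  prob = c(drivers$p_early[g], drivers$p_late[g],
                           drivers$p_subclonal[g]))
    out[[g]] <- data.frame(sample_id = sids, event = drivers$gene[g],
                           timing = cls, pi = NA_real_,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## ---- the full generator -------------------------------------------------

#' Generate a synthetic cohort with known truth
#'
#' Deterministic given (config, seed). Emits a validated
#' \linkS4class{CohortBundle} plus a TruthSet list holding every planted
#' quantity: per-segment true gain times, per-mutation true multiplicity
#' and clonality, the driver status matrix, planted SV hotspot intervals,
#' true escape labels and mechanisms, driver timing-class calls with the
#' planted cohort order, true log-hazard-ratios and germline-carrier flags.
#'
#' @param config a \code{\link{simulationConfig}}
#' @param seed integer RNG seed
#' @return list with elements \code{cohort} and \code{truth}
#' @export
generateCohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  gen <- config$genome
  sids <- sprintf("T%03d", seq_len(config$n_tumours))
  withr::with_seed(seed, {
    purity <- stats::rbeta(config$n_tumours, config$purity_shape[1],
                           config$purity_shape[2])
    purity <- pmin(pmax(purity, 0.15), 0.98)
    status <- .sampleDrivers(config$drivers, config$interactions,
                             config$n_tumours)
    rownames(status) <- sids
    wgd <- stats::runif(config$n_tumours) < config$wgd_prob
    loss3 <- stats::runif(config$n_tumours) < config$p_3p_loss
    gain5 <- !wgd & stats::runif(config$n_tumours) < config$p_5q_gain
    pi5 <- stats::runif(config$n_tumours, config$pi_5q[1], config$pi_5q[2])
    piw <- stats::runif(config$n_tumours, config$pi_wgd[1], config$pi_wgd[2])

    muts <- list(); segs <- list(); gain_truth <- list()
    for (i in seq_along(sids)) {
      sid <- sids[i]
      ## whole-chromosome copy-number states
      st <- stats::setNames(rep("1+1", nrow(gen)), gen$chrom)
      if (wgd[i]) {
        st[] <- "2+2"
        if (loss3[i]) st["3"] <- "2+0"
      } else {
        if (loss3[i]) st["3"] <- "1+0"
        if (gain5[i]) st["5"] <- "2+1"
      }
      cn <- t(vapply(st, function(s)
        as.integer(strsplit(s, "+", fixed = TRUE)[[1]]), integer(2)))
      segs[[sid]] <- data.frame(
        sample_id = sid, chrom = gen$chrom, start = 0L, end = gen$length,
        major_cn = cn[, 1], minor_cn = cn[, 2], stringsAsFactors = FALSE)

      ## mutations: timed segments on designated chromosomes, light
      ## passenger background elsewhere (same accrual model per state)
      for (ch in gen$chrom) {
        pi_ch <- if (wgd[i]) piw[i] else if (ch == "5" && gain5[i]) pi5[i]
                 else NA
        timed <- (!wgd[i] && ch == "5" && gain5[i]) ||
          (wgd[i] && ch %in% config$wgd_timed_chroms)
        n_exp <- config$n_background + if (timed) config$n_timed else 0
        muts[[paste(sid, ch)]] <- .simulateChromosomeMutations(
          n_exp, st[[ch]], if (is.na(pi_ch)) 0 else pi_ch, purity[i],
          config$mean_depth, ch, sid, gen$length[gen$chrom == ch],
          config$subclonal_frac, config$subclonal_ccf, config$context_probs)
      }
      if (!wgd[i] && gain5[i]) {
        gain_truth[[length(gain_truth) + 1L]] <- data.frame(
          sample_id = sid, chrom = "5", state = "2+1", pi_true = pi5[i],
          stringsAsFactors = FALSE)
      }
      if (wgd[i]) {
        gain_truth[[length(gain_truth) + 1L]] <- data.frame(
          sample_id = sid, chrom = "WGD", state = "2+2", pi_true = piw[i],
          stringsAsFactors = FALSE)
      }
    }
    muts <- do.call(rbind, muts)
    segs <- do.call(rbind, segs)
    rownames(muts) <- rownames(segs) <- NULL

    ## driver mutation records (clonal unless the timing class says
    ## subclonal), placed on their genes' chromosomes
    calls <- .simulateEventCalls(config$drivers, status)
    if (!is.null(calls) && nrow(calls)) {
      dmap <- match(calls$event, config$drivers$gene)
      ch <- config$drivers$chrom[dmap]
      st_of <- function(sid, ch) {
        s <- segs[segs$sample_id == sid & segs$chrom == ch, ]
        paste0(s$major_cn[1], "+", s$minor_cn[1])
      }
      drows <- lapply(seq_len(nrow(calls)), function(j) {
        sid <- calls$sample_id[j]
        state <- st_of(sid, ch[j])
        cnt <- sum(as.integer(strsplit(state, "+", fixed = TRUE)[[1]]))
        sub <- calls$timing[j] == "subclonal"
        m <- 1L
        f <- if (sub) stats::runif(1, 0.15, 0.4) else 1
        rho <- purity[match(sid, sids)]
        depth <- max(stats::rpois(1, config$mean_depth), 1)
        alt <- stats::rbinom(1, depth, .expVaf(m, f, rho, cnt))
        ctx <- .drawContexts(1, config$context_probs)
        data.frame(
          sample_id = sid, chrom = ch[j],
          pos = 1e5L + dmap[j] * 1000L, ref = ctx$ref, alt = ctx$alt,
          gene = calls$event[j],
          consequence = sample(c("missense", "truncating"), 1,
                               prob = c(0.7, 0.3)),
          alt_count = alt, total_depth = depth, trinucleotide = ctx$tri,
          is_driver_gene = TRUE,
          pathogenic_flag = stats::runif(1) < 0.72,
          true_multiplicity = m, true_clonal = !sub,
          stringsAsFactors = FALSE)
      })
      muts <- rbind(muts, do.call(rbind, drows))
    }

    ## purity/ploidy table from the emitted segments
    pl <- do.call(rbind, lapply(seq_along(sids), function(i) {
      s <- segs[segs$sample_id == sids[i], ]
      w <- s$end - s$start
      data.frame(sample_id = sids[i], purity = round(purity[i], 4),
                 ploidy = round(sum(w * (s$major_cn + s$minor_cn)) / sum(w), 4),
                 loh_fraction = round(sum(w[s$minor_cn == 0]) / sum(w), 4),
                 wgd_flag = wgd[i], stringsAsFactors = FALSE)
    }))

    ## SVs over covariate tracks with planted hotspots
    bins <- simulateCovariateTracks(
      makeBins(gen, config$sv$bin_size), seed = .childSeed(seed, 11L))
    svs <- plantSvHotspots(bins, config$sv$base_rate,
                           config$sv$covariate_effects, config$sv$hotspots,
                           config$n_tumours, seed = .childSeed(seed, 12L))
    if (config$sv$complex_rate > 0) {
      ncx <- stats::rpois(1, config$sv$complex_rate * nrow(bins))
      if (ncx > 0) {
        b <- sample(nrow(bins), ncx, replace = TRUE)
        p <- bins$start[b] + sample.int(config$sv$bin_size, ncx, TRUE) - 1L
        svs <- rbind(svs, data.frame(
          sample_id = sample(sids, ncx, replace = TRUE),
          chrom1 = bins$chrom[b], start1 = p, end1 = p + 1L,
          chrom2 = bins$chrom[b], start2 = p + 1000L, end2 = p + 1001L,
          sv_class = "UNCLASSIFIED", complexity = "complex",
          stringsAsFactors = FALSE))
      }
    }

    ## gene annotation: driver genes plus large late-replicating (fragile)
    ## and matched early-replicating genes for the hotspot filter
    genes <- rbind(
      data.frame(chrom = config$drivers$chrom, start = 1e5,
                 end = 1.5e5 + 1000 * seq_len(nrow(config$drivers)),
                 gene = config$drivers$gene,
                 rt_quartile = 2, stringsAsFactors = FALSE),
      data.frame(chrom = c("2", "4", "16"), start = c(1e6, 3e6, 5e6),
                 end = c(1.9e6, 3.8e6, 5.8e6),
                 gene = c("FRG1L", "FRG2L", "FRG3L"),
                 rt_quartile = 4, stringsAsFactors = FALSE),
      data.frame(chrom = "6", start = 1e6, end = 1.9e6, gene = "BIGEARLY",
                 rt_quartile = 1, stringsAsFactors = FALSE))

    ## immune escape
    esc <- data.frame(
      sample_id = sids,
      hla_loh_a = stats::runif(config$n_tumours) < config$escape$hla_loh / 3,
      hla_loh_b = stats::runif(config$n_tumours) < config$escape$hla_loh / 3,
      hla_loh_c = stats::runif(config$n_tumours) < config$escape$hla_loh / 3,
      hla_mutation = stats::runif(config$n_tumours) < config$escape$hla_mutation,
      apg_inactivated = stats::runif(config$n_tumours) <
        config$escape$apg_inactivation,
      stringsAsFactors = FALSE)

    ## clinical + survival
    age <- round(pmin(pmax(stats::rnorm(config$n_tumours, 62, 10), 30), 90))
    feats <- data.frame(status * 1L)
    feats$escape <- classifyEscape(esc)$escape * 1L
    surv <- simulateSurvival(feats, config$survival,
                             seed = .childSeed(seed, 13L))
    surv_css <- surv
    surv_css$event <- surv$event * stats::rbinom(config$n_tumours, 1, 0.7)
    clin <- data.frame(
      sample_id = sids, age_at_sampling = age,
      sex = sample(c("M", "F"), config$n_tumours, TRUE, prob = c(0.7, 0.3)),
      stage = sample(1:4, config$n_tumours, TRUE,
                     prob = c(0.4, 0.15, 0.3, 0.15)),
      grade = sample(1:4, config$n_tumours, TRUE,
                     prob = c(0.1, 0.35, 0.4, 0.15)),
      sarcomatoid = stats::runif(config$n_tumours) < 0.1,
      necrosis = stats::runif(config$n_tumours) < 0.3,
      os_time = round(surv$time), os_event = surv$event,
      css_time = round(surv_css$time), css_event = surv_css$event,
      pfs_time = round(surv$time * stats::runif(config$n_tumours, 0.5, 1)),
      pfs_event = surv$event,
      tcra_fraction = round(stats::rbeta(config$n_tumours, 2, 20), 4),
      leibovich_group = sample(c("low", "intermediate", "high"),
                               config$n_tumours, TRUE),
      stringsAsFactors = FALSE)

    germline <- stats::runif(config$n_tumours) < config$germline_carrier_rate

    truth <- list(
      gain_times = if (length(gain_truth)) do.call(rbind, gain_truth)
                   else data.frame(),
      mutation_truth = muts[, c("sample_id", "chrom", "pos",
                                "true_multiplicity", "true_clonal")],
      driver_status = status,
      event_calls = calls,
      planted_order = config$drivers$gene[order(
        config$drivers$p_early * 1 + config$drivers$p_late * 2 +
          config$drivers$p_subclonal * 3)],
      sv_hotspots = config$sv$hotspots,
      escape = classifyEscape(esc),
      log_hrs = config$survival$log_hrs,
      germline_carrier = stats::setNames(germline, sids),
      wgd_flag = stats::setNames(wgd, sids),
      clock = config$clock)

    bundle <- CohortBundle(
      mutations = muts[, .MUT_COLS],
      segments = segs, ploidy = pl, svs = svs, clinical = clin,
      tracks = bins, genes = genes)
    validObject(bundle)
    ## immune inputs ride along for the escape stage
    attr(bundle, "immune") <- esc
    list(cohort = bundle, truth = truth)
  })
}
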
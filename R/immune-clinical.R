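## Clinico-genomic association scans and survival analysis: Kaplan-Meier
## curves with the log-rank test, Cox proportional-hazards fits with Efron
## tie handling, and regression scans (logistic / linear / negative
## binomial) adjusted for sex, age, stage and grade with BH correction.

#' Kaplan-Meier curves and log-rank test
#'
#' @param time follow-up times (days)
#' @param event event indicators (1 = event, 0 = censored)
#' @param group group labels
#' @return list with \code{fit} (a \code{survfit} object) and \code{p}
#'   (two-sided log-rank p; NA with a single group)
#' @export
kmLogrank <- function(time, event, group) {
  df <- data.frame(time = time, event = event, group = as.factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  p <- NA_real_
  if (nlevels(df$group) >= 2 && sum(event) >= 1) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    p <- stats::pchisq(sd_$chisq, df = nlevels(df$group) - 1,
                       lower.tail = FALSE)
  }
  list(fit = fit, p = p)
}

#' Cox proportional-hazards fit per covariate
#'
#' Each covariate is fitted in its own model alongside the adjusters
#' (partial likelihood, Efron ties); hazard ratio, Wald CI and two-sided p
#' are reported per covariate. Separation or non-convergence flags the row
#' without an estimate.
#'
#' @param data data.frame holding times, events, covariates and adjusters
#' @param time,event column names of the endpoint
#' @param covariates character vector of covariate columns to scan
#' @param adjusters character vector of adjustment columns (may be empty)
#' @param endpoint label recorded in the output (e.g. "OS")
#' @return data.frame with feature, hr, ci_low, ci_high, p, n, n_events,
#'   endpoint, flag
#' @export
coxFit <- function(data, time, event, covariates, adjusters = character(0),
                   endpoint = "OS") {
  n_ev <- sum(data[[event]])
  if (n_ev < 5 * length(covariates)) {
    warning("fewer than 5 events per scanned covariate; estimates unstable")
  }
  out <- lapply(covariates, function(cv) {
    row <- data.frame(feature = cv, hr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_, n = nrow(data),
                      n_events = n_ev, endpoint = endpoint, flag = "",
                      stringsAsFactors = FALSE)
    if (length(unique(data[[cv]])) < 2) {
      stop("covariate '", cv, "' is constant", call. = FALSE)
    }
    fml <- stats::as.formula(paste0(
      "survival::Surv(", time, ", ", event, ") ~ ", cv,
      if (length(adjusters)) paste0(" + ", paste(adjusters, collapse = " + "))
      else ""))
    fit <- tryCatch(
      survival::coxph(fml, data = data, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        f <- suppressWarnings(survival::coxph(fml, data = data,
                                              ties = "efron"))
        attr(f, "warned") <- conditionMessage(w)
        f
      })
    if (is.null(fit)) { row$flag <- "non-convergence"; return(row) }
    sm <- summary(fit)
    i <- 1L   # scanned covariate is the first term
    beta <- sm$coefficients[i, "coef"]
    se <- sm$coefficients[i, "se(coef)"]
    if (!is.finite(beta) || !is.finite(se) || se > 50) {
      row$flag <- "separation"; return(row)
    }
    z <- stats::qnorm(0.975)
    row$hr <- exp(beta); row$ci_low <- exp(beta - z * se)
    row$ci_high <- exp(beta + z * se)
    row$p <- 2 * stats::pnorm(-abs(beta / se))
    if (!is.null(attr(fit, "warned"))) row$flag <- attr(fit, "warned")
    row
  })
  do.call(rbind, out)
}

#' Adjusted association scan over genomic features
#'
#' Regresses each clinical outcome on each genomic feature with the
#' requested family (logistic for binary outcomes, linear for continuous,
#' negative binomial for counts), always adjusting for the supplied
#' clinical covariates; BH across all scanned features.
#'
#' @param data data.frame holding outcome, features and adjusters
#' @param outcome outcome column name
#' @param features character vector of feature columns
#' @param family one of "logistic", "linear", "negative-binomial"
#' @param adjusters adjustment columns (default sex, age, stage, grade
#'   where present)
#' @return data.frame with feature, estimate (OR / beta / rate ratio),
#'   ci_low, ci_high, p, q, flag
#' @export
associationScan <- function(data, outcome, features,
                            family = c("logistic", "linear",
                                       "negative-binomial"),
                            adjusters = intersect(
                              c("sex", "age_at_sampling", "stage", "grade"),
                              names(data))) {
  family <- match.arg(family)
  if (length(unique(data[[outcome]])) < 2) {
    stop("outcome '", outcome, "' is constant", call. = FALSE)
  }
  out <- lapply(features, function(fv) {
    fml <- stats::as.formula(paste0(
      outcome, " ~ ", fv,
      if (length(adjusters)) paste0(" + ", paste(adjusters, collapse = " + "))
      else ""))
    fit <- tryCatch(switch(family,
      logistic = stats::glm(fml, data = data, family = stats::binomial()),
      linear = stats::lm(fml, data = data),
      `negative-binomial` = MASS::glm.nb(fml, data = data)),
      error = function(e) NULL)
    row <- data.frame(feature = fv, estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
    if (is.null(fit)) { row$flag <- "non-convergence"; return(row) }
    co <- summary(fit)$coefficients
    beta <- co[2, 1]; se <- co[2, 2]
    if (!is.finite(se) || se > 50) { row$flag <- "quasi-separation"; return(row) }
    z <- stats::qnorm(0.975)
    expit <- family != "linear"
    tr <- if (expit) exp else identity
    row$estimate <- tr(beta); row$ci_low <- tr(beta - z * se)
    row$ci_high <- tr(beta + z * se)
    row$p <- 2 * stats::pnorm(-abs(beta / se))
    row
  })
  res <- do.call(rbind, out)
  res$q <- bhAdjust(ifelse(is.na(res$p), 1, res$p))
  res$q[is.na(res$p)] <- NA_real_
  res
}
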
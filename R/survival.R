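#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Survival-analysis eligibility filter
#'
#' Survival analyses are restricted to patients with microsatellite-stable
#' tumors and a macroscopically complete liver resection: MSI patients and
#' R2 patients are removed, and the removal counts are reported.
#'
#' @param patients Patient-level data.frame with `msi_status`
#'   (`MSI`/`MSS`) and `r_status` (`R0`/`R1`/`R2`).
#' @param quiet Suppress the removal message.
#' @return The eligible subset, with an attribute `removed` =
#'   `c(msi = ..., r2 = ...)`.
#' @export
survivalEligible <- function(patients, quiet = FALSE) {
  msi <- patients$msi_status == "MSI"
  r2 <- patients$r_status == "R2"
  keep <- !msi & !r2
  if (!quiet)
    message(sum(msi), " MSI and ", sum(r2 & !msi),
            " additional R2 patient(s) removed; ", sum(keep), " retained")
  out <- patients[keep, , drop = FALSE]
  attr(out, "removed") <- c(msi = sum(msi), r2 = sum(r2 & !msi))
  out
}

#' Encode follow-up into cancer-specific survival time and event
#'
#' Time runs from start of treatment; death from the cancer is the event
#' and deaths from other causes are censored at their time.
#'
#' @param patients Patient-level data.frame with `followup_months` and
#'   `event` in `c("CRC death", "other death", "alive")`.
#' @return data.frame with `time` (months) and `status` (1 = cancer
#'   death, 0 = censored).
#' @export
cssEncode <- function(patients) {
  stopifnot(all(patients$event %in% EVENT_LEVELS))
  data.frame(time = patients$followup_months,
             status = as.integer(patients$event == "CRC death"))
}

#' Kaplan-Meier estimate and five-year cancer-specific survival
#'
#' Product-limit estimator; `fiveYearCSS()` reads the curve at 60 months
#' with last-value-carried-forward when no step falls exactly at 60.
#'
#' @param time Follow-up in months.
#' @param status Event indicator (1 = cancer death).
#' @param group Optional grouping factor.
#' @return `kmEstimate()`: a `survfit` object. `fiveYearCSS()`: survival
#'   probability (per group when grouped), as a proportion in \[0, 1\].
#' @export
kmEstimate <- function(time, status, group = NULL) {
  if (is.null(group))
    survfit(Surv(time, status) ~ 1)
  else
    survfit(Surv(time, status) ~ group)
}

#' @rdname kmEstimate
#' @param fit A `survfit` object.
#' @param at Time point in months (default 60).
#' @export
fiveYearCSS <- function(fit, at = 60) {
  s <- summary(fit, times = at, extend = TRUE)
  out <- s$surv
  if (!is.null(s$strata) && length(s$strata))
    names(out) <- sub("^group=", "", as.character(s$strata))
  out
}

#' Two-group log-rank test
#'
#' @param time,status Survival encoding (see [cssEncode()]).
#' @param group Factor with exactly two non-empty levels.
#' @return list with `chisq`, `df` (= 1) and `p.value`.
#' @export
logrankTest <- function(time, status, group) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2L) stop("logrankTest needs exactly two non-empty groups")
  sd <- survdiff(Surv(time, status) ~ g)
  list(chisq = unname(sd$chisq), df = 1L,
       p.value = pchisq(sd$chisq, 1, lower.tail = FALSE))
}

#' Log-rank test for trend over ordered groups
#'
#' One-degree-of-freedom score test contrasting each group's observed
#' minus expected event counts, weighted by equally spaced group scores
#' (1..k in factor-level order by default). The signed statistic `z`
#' flips sign when the group order is reversed; with fewer than three
#' groups the test defers to the ordinary log-rank test.
#'
#' @param time,status Survival encoding.
#' @param group Ordered factor (ordering = factor levels).
#' @param scores Optional numeric group scores.
#' @return list with `z` (signed trend statistic), `chisq`, `df` and
#'   `p.value`.
#' @export
logrankTrend <- function(time, status, group, scores = NULL) {
  g <- droplevels(factor(group, levels = if (is.factor(group)) levels(group)
                                          else sort(unique(group))))
  k <- nlevels(g)
  if (k < 3L) {
    lr <- logrankTest(time, status, g)
    return(list(z = NA_real_, chisq = lr$chisq, df = 1L, p.value = lr$p.value))
  }
  if (is.null(scores)) scores <- seq_len(k)
  sd <- survdiff(Surv(time, status) ~ g)
  u <- sd$obs - sd$exp
  v <- drop(t(scores) %*% sd$var %*% scores)
  if (v <= 0) return(list(z = NA_real_, chisq = NA_real_, df = 1L,
                          p.value = NA_real_))
  z <- sum(scores * u) / sqrt(v)
  list(z = z, chisq = z^2, df = 1L,
       p.value = pchisq(z^2, 1, lower.tail = FALSE))
}

#' Cox proportional-hazards regression (Efron ties)
#'
#' Univariable mode fits one model per covariate; multivariable mode fits
#' all covariates jointly. Hazard ratios with Wald 95% confidence
#' intervals and Wald p-values are reported per coefficient.
#' Non-convergence or likely separation (|log HR| > 10) is flagged.
#'
#' @param data data.frame containing `time`, `status` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param mode `"univariable"` or `"multivariable"`.
#' @return data.frame with `variable`, `term`, `HR`, `ci_low`, `ci_high`,
#'   `p.value`, `n`, `events`, `mode`, `flag`.
#' @export
coxFit <- function(data, covariates, mode = c("univariable", "multivariable")) {
  mode <- match.arg(mode)
  fitOne <- function(covs) {
    sub <- data[complete.cases(data[, c("time", "status", covs), drop = FALSE]), ,
                drop = FALSE]
    for (cv in covs) {
      v <- sub[[cv]]
      if (length(unique(v[!is.na(v)])) < 2L)
        stop("covariate '", cv, "' is constant")
    }
    f <- as.formula(paste("Surv(time, status) ~",
                          paste(sprintf("`%s`", covs), collapse = " + ")))
    flag <- "ok"
    fit <- withCallingHandlers(
      coxph(f, data = sub, ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
          flag <<- "separation_or_nonconvergence"
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    co <- s$coefficients
    if (any(abs(co[, "coef"]) > 10)) flag <- "separation_or_nonconvergence"
    data.frame(variable = rep(paste(covs, collapse = "+"), nrow(co)),
               term = rownames(co),
               HR = unname(co[, "exp(coef)"]),
               ci_low = unname(s$conf.int[, "lower .95"]),
               ci_high = unname(s$conf.int[, "upper .95"]),
               p.value = unname(co[, "Pr(>|z|)"]),
               n = s$n, events = s$nevent, mode = mode, flag = flag,
               row.names = NULL)
  }
  if (mode == "univariable")
    do.call(rbind, lapply(covariates, fitOne))
  else
    fitOne(covariates)
}

#' Group-association test (rank-sum or exact)
#'
#' Wilcoxon rank-sum test for a continuous variable across two groups;
#' Fisher's exact test on the contingency table for a categorical
#' variable. P-values are not adjusted for multiple testing. Degenerate
#' inputs (constant continuous variable, a contingency dimension of one)
#' return `NA` with a status attribute.
#'
#' @param x The variable (numeric, or factor/character for categorical).
#' @param group Two-level grouping factor.
#' @return p-value, with attribute `test` and (when degenerate) `status`.
#' @export
groupAssociationTest <- function(x, group) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2L) stop("groupAssociationTest needs two groups")
  if (is.numeric(x)) {
    if (length(unique(x[!is.na(x)])) < 2L)
      return(structure(NA_real_, test = "wilcoxon", status = "degenerate"))
    p <- suppressWarnings(wilcox.test(x ~ g)$p.value)
    structure(p, test = "wilcoxon")
  } else {
    tab <- table(x, g)
    if (any(dim(tab) < 2L))
      return(structure(NA_real_, test = "fisher", status = "degenerate"))
    structure(fisher.test(tab)$p.value, test = "fisher")
  }
}

#' Stratified survival analysis (KM + log-rank/trend + Cox)
#'
#' Runs the package's survival conventions on precomputed strata: a
#' Kaplan-Meier fit per stratum, the two-group log-rank test (2 strata)
#' or the log-rank trend test over the factor-level order (>= 3 strata),
#' and a univariable Cox model using the factor's first level as the
#' reference group. Strata without events are flagged.
#'
#' @param time,status Survival encoding.
#' @param strata Factor of stratum labels; level order defines the trend
#'   ordering and the Cox reference (first level).
#' @return list with `km` (`survfit`), `five_year_css`, `test`
#'   (log-rank or trend result), `cox` (per-stratum HRs vs reference),
#'   `n`, `events`, `flagged_strata`.
#' @export
stratifiedSurvival <- function(time, status, strata) {
  s <- droplevels(as.factor(strata))
  ok <- !is.na(time) & !is.na(status) & !is.na(s)
  time <- time[ok]; status <- status[ok]; s <- droplevels(s[ok])
  if (nlevels(s) < 2L) stop("need at least two strata")
  km <- kmEstimate(time, status, s)
  test <- if (nlevels(s) == 2L) logrankTest(time, status, s)
          else logrankTrend(time, status, s)
  cox <- coxFit(data.frame(time = time, status = status, stratum = s),
                "stratum", mode = "univariable")
  evs <- tapply(status, s, sum)
  list(km = km, five_year_css = fiveYearCSS(km), test = test, cox = cox,
       n = length(time), events = sum(status),
       flagged_strata = names(evs)[evs == 0])
}
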
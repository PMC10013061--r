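#' Mann-Whitney comparison of a feature between two groups
#'
#' Two-sided Mann-Whitney U test (continuity-corrected normal
#' approximation with midrank tie correction, the convention of mainstream
#' clinical statistics software) plus the median and interquartile range
#' per group, matching the usual "median (IQR)" presentation.
#'
#' @param values_a,values_b Numeric vectors (missing values dropped);
#'   conventionally survivors first, non-survivors second.
#' @param feature Feature name for the report row.
#' @return One-row data frame: `feature`, `median_a`, `q1_a`, `q3_a`,
#'   `median_b`, `q1_b`, `q3_b`, `U`, `p_value`.
#' @export
mann_whitney_compare <- function(values_a, values_b, feature = "feature") {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)
  )
  qa <- stats::quantile(values_a, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- stats::quantile(values_b, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(feature = feature,
             median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
             median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
             U = unname(wt$statistic), p_value = wt$p.value,
             stringsAsFactors = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Cox regression (Efron tie handling) for one or two
#' covariates, reporting per covariate the log-hazard coefficient, its
#' standard error, the hazard ratio with Wald 95% CI
#' (exp(beta +- 1.96 SE)) and the Wald p-value. Rows with any missing
#' covariate are dropped (complete-case).
#'
#' @param time,event Follow-up time and event indicator (1 = event).
#' @param covariates Data frame of 1 or 2 numeric columns.
#' @return Data frame with one row per covariate: `term`, `beta`, `sem`,
#'   `hr`, `ci_lower`, `ci_upper`, `p_value`; attribute `converged`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(ncol(covariates) >= 1, ncol(covariates) <= 2)
  ok <- stats::complete.cases(covariates) & !is.na(time) & !is.na(event)
  time <- time[ok]
  event <- event[ok]
  covariates <- covariates[ok, , drop = FALSE]
  if (sum(event) < 1) stop("no events in the data", call. = FALSE)
  if (any(vapply(covariates, function(v) stats::var(v) == 0, logical(1)))) {
    stop("constant covariate supplied", call. = FALSE)
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  sem <- unname(sqrt(diag(stats::vcov(fit))))
  z <- beta / sem
  res <- data.frame(term = names(covariates),
                    beta = beta, sem = sem,
                    hr = exp(beta),
                    ci_lower = exp(beta - 1.96 * sem),
                    ci_upper = exp(beta + 1.96 * sem),
                    p_value = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  attr(res, "converged") <- converged
  res
}

#' Combined severity-deviation prognostic index
#'
#' Linear predictor `beta1 * meld + beta2 * delta`, where the coefficients
#' come from a converged bivariate Cox model of MELD and a parenclitic
#' deviation. The same arithmetic serves any severity score in place of
#' MELD.
#'
#' @param beta1 Cox coefficient of the severity score.
#' @param meld Severity score value(s).
#' @param beta2 Cox coefficient of the deviation.
#' @param delta Deviation value(s).
#' @return Numeric vector of index values.
#' @export
#' @examples
#' combined_index(0.119, 12, 0.061, 2.08) # 1.5549
combined_index <- function(beta1, meld, beta2, delta) {
  beta1 * meld + beta2 * delta
}

#' ROC curve with Youden-optimal cutoff
#'
#' Empirical ROC analysis of a prognostic score against a binary outcome
#' (1 = non-survivor). The AUC is the normalised Mann-Whitney statistic
#' computed from midranks (tied score pairs count 1/2), identical to the
#' trapezoidal area under the empirical ROC curve. The optimal cutoff
#' maximises Youden's J = sensitivity + specificity - 1 over observed score
#' values, predicting non-survival for scores at or above the cutoff; ties
#' in J are broken toward the lower cutoff (favouring sensitivity). Scores
#' are assumed "higher = worse"; if the raw AUC falls below 0.5 the
#' orientation is flipped (prediction for scores at or below the cutoff)
#' and the result flagged. The 95% CI uses the Hanley-McNeil standard
#' error.
#'
#' @param scores Numeric prognostic scores.
#' @param labels Binary outcome, 1 = event/non-survivor.
#' @return List of class `parenclitic_roc`: `auc`, `ci_lower`, `ci_upper`,
#'   `cutoff`, `sensitivity`, `specificity`, `direction` (`">="` or
#'   `"<="`), `flipped`, `n_pos`, `n_neg`.
#' @export
roc_with_cutoff <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.integer(labels[ok])
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  flipped <- auc < 0.5

  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cand <- sort(unique(scores))
  if (!flipped) {
    sens <- vapply(cand, function(c) mean(pos >= c), numeric(1))
    spec <- vapply(cand, function(c) mean(neg < c), numeric(1))
  } else {
    sens <- vapply(cand, function(c) mean(pos <= c), numeric(1))
    spec <- vapply(cand, function(c) mean(neg > c), numeric(1))
  }
  j <- sens + spec - 1
  best <- which(j == max(j))
  pick <- best[which.min(cand[best])]

  a_eff <- max(auc, 1 - auc)
  q1 <- a_eff / (2 - a_eff)
  q2 <- 2 * a_eff^2 / (1 + a_eff)
  se <- sqrt((a_eff * (1 - a_eff) + (n1 - 1) * (q1 - a_eff^2) +
                (n0 - 1) * (q2 - a_eff^2)) / (n1 * n0))
  structure(list(auc = auc,
                 ci_lower = max(0, auc - 1.96 * se),
                 ci_upper = min(1, auc + 1.96 * se),
                 cutoff = cand[pick],
                 sensitivity = sens[pick],
                 specificity = spec[pick],
                 direction = if (flipped) "<=" else ">=",
                 flipped = flipped,
                 n_pos = n1, n_neg = n0),
            class = "parenclitic_roc")
}

#' Kaplan-Meier curves and log-rank (Mantel-Cox) test
#'
#' Product-limit survival estimates per group and the 1-df Mantel-Cox
#' chi-square comparing them, for a binary grouping (typically
#' "predicted non-survivor" vs "predicted survivor" from a ROC cutoff).
#'
#' @param time,event Follow-up time and event indicator.
#' @param group Binary or factor group labels.
#' @return List of class `parenclitic_km`: `curves` (data frame with
#'   `group`, `time`, `n_risk`, `n_event`, `surv`), `chisq`, `p_value`,
#'   `n_per_group`.
#' @export
km_logrank <- function(time, event, group) {
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]
  event <- event[ok]
  group <- as.factor(group[ok])
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need two non-empty groups", call. = FALSE)
  if (sum(event) < 1) stop("no events in the data", call. = FALSE)
  dat <- data.frame(time = time, event = event, group = group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  chisq <- unname(sd_$chisq)
  p <- stats::pchisq(chisq, df = nlevels(group) - 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sm <- summary(sf, censored = TRUE)
  curves <- data.frame(
    group = sub("^group=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    surv = sm$surv, stringsAsFactors = FALSE)
  structure(list(curves = curves, chisq = chisq, p_value = p,
                 n_per_group = table(group)),
            class = "parenclitic_km")
}
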
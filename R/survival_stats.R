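# Survival machinery the biomarker-selection procedure relies on. Kaplan-Meier,
# log-rank and Cox go through the survival package; ROC AUC is the rank-based
# Mann-Whitney concordance; Spearman goes through stats::cor.test.

#' Kaplan-Meier product-limit estimate
#'
#' @param data Data frame with survival columns.
#' @param time,event Column names (strings) of follow-up time (months, > 0)
#'   and event indicator (1 = event, 0 = censored).
#' @return An object of class `km_fit` wrapping `survival::survfit`, with a
#'   tidy step table in `$steps`.
#' @export
km_fit <- function(data, time = "time_months", event = "event") {
  tt <- data[[time]]; ee <- data[[event]]
  if (any(tt <= 0)) stop("survival times must be positive")
  if (!all(ee %in% c(0, 1))) stop("event indicator must be 0/1")
  sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
  structure(list(
    survfit = sf,
    steps = tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                           n_event = sf$n.event, survival = sf$surv)),
    class = "km_fit")
}

#' Survival probability at a time point
#'
#' Right-continuous step value of the product-limit estimate; the 5-year rate
#' is `survival_at(fit, 60)` for time in months.
#'
#' @param fit A [km_fit()] object.
#' @param t Time(s) at which to evaluate.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  st <- fit$steps
  vapply(t, function(ti) {
    i <- findInterval(ti, st$time)
    if (i == 0) 1.0 else st$survival[i]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank statistic (observed minus expected events
#' over the hypergeometric variance, summed across event times) with a
#' chi-square tail p-value.
#'
#' @param data Data frame.
#' @param time,event,group Column names: time (months), event (0/1), and a
#'   two-level grouping variable.
#' @return A tibble with `chisq`, `df`, `p_value`, and observed/expected
#'   event counts per group.
#' @export
logrank_test <- function(data, time = "time_months", event = "event",
                         group = "group") {
  tt <- data[[time]]; ee <- data[[event]]; gg <- data[[group]]
  if (length(unique(gg)) < 2) stop("need two non-empty groups")
  if (sum(ee) < 1) stop("log-rank undefined with zero events")
  sd <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  df <- length(sd$n) - 1
  tibble::tibble(chisq = sd$chisq, df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed_1 = sd$obs[1], expected_1 = sd$exp[1],
                 observed_2 = sd$obs[2], expected_2 = sd$exp[2])
}

#' ROC area under the curve (Mann-Whitney concordance)
#'
#' Probability that a randomly chosen event patient scores higher than a
#' randomly chosen event-free patient, with 0.5 credit for ties. Orientation:
#' higher score means higher predicted risk, so a discriminative risk score
#' gives AUC > 0.5. `NA` labels (e.g. patients censored before the outcome
#' horizon) are dropped with their scores.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = event), same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)  # midranks handle ties with 0.5 credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dichotomise survival at a horizon for ROC analysis
#'
#' Label 1 if the event occurred by `horizon_months`, 0 if followed event-free
#' past the horizon, and `NA` (excluded) if censored before the horizon
#' without an event.
#'
#' @param time_months,event Survival records.
#' @param horizon_months Outcome horizon (default 60 = 5 years).
#' @return Integer vector of 1/0/NA labels.
#' @export
event_by_horizon <- function(time_months, event, horizon_months = 60) {
  dplyr::case_when(
    event == 1 & time_months <= horizon_months ~ 1L,
    time_months >= horizon_months ~ 0L,
    TRUE ~ NA_integer_)
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood maximisation (Breslow ties by default) with Wald
#' p-values; supports the usual univariate and multivariate designs (clinical
#' covariates plus one imaging biomarker). Non-convergence or monotone
#' likelihood (complete separation, detected as an extreme coefficient or an
#' exploded standard error) is flagged per term, never returned silently.
#'
#' @param data Data frame.
#' @param covariates Character vector of covariate column names.
#' @param time,event Column names of the endpoint.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_fit_result`; `tidy()` gives one row per
#'   term (`estimate` = log hazard ratio, `std_error`, `p_value`, `flagged`),
#'   `glance()` the model-level summary.
#' @export
cox_fit <- function(data, covariates, time = "time_months", event = "event",
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(data[[event]]) < 1) stop("Cox model undefined with zero events")
  if (nrow(data) <= length(covariates)) stop("need more patients than covariates")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  flagged <- warned | is.na(co[, "coef"]) | !is.finite(co[, "se(coef)"]) |
    co[, "se(coef)"] > 1e3 | abs(co[, "coef"]) > 15
  flagged[is.na(flagged)] <- TRUE
  structure(list(
    coxph = fit,
    terms = tibble::tibble(
      term = rownames(co),
      estimate = co[, "coef"],
      hazard_ratio = co[, "exp(coef)"],
      std_error = co[, "se(coef)"],
      statistic = co[, "z"],
      p_value = co[, "Pr(>|z|)"],
      flagged = unname(flagged)),
    n = s$n, n_events = s$nevent, ties = ties,
    loglik = fit$loglik[length(fit$loglik)]),
    class = "cox_fit_result")
}

#' @rdname cox_fit
#' @param x A `cox_fit_result`.
#' @param ... Unused.
#' @export
tidy.cox_fit_result <- function(x, ...) x$terms

#' @rdname cox_fit
#' @export
glance.cox_fit_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 ties = x$ties, any_flagged = any(x$terms$flagged))
}

#' @export
print.cox_fit_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): %d patients, %d events\n",
              x$ties, x$n, x$n_events))
  print(x$terms)
  invisible(x)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of midranks, p-value from the asymptotic
#' t-approximation.
#'
#' @param x,y Paired numeric samples, n >= 3.
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero variance in ranks: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
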
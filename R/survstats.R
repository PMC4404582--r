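# Survival statistics: two-sample log-rank, Kaplan-Meier curves, uni- and
# multivariate Cox models (Efron ties), and Harrell's concordance index for
# a binary risk grouping.

.check_surv <- function(times, events) {
  if (length(times) != length(events)) {
    stop("'times' and 'events' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all survival times must be strictly positive", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  invisible(NULL)
}

#' Two-sample log-rank test
#'
#' Standard observed-versus-expected log-rank chi-square with 1 degree of
#' freedom; the P value is the upper tail of the chi-square distribution.
#' Symmetric in the group labels.
#'
#' @param times survival times in years.
#' @param events 0/1 event indicators.
#' @param groups two-level factor or character vector of group labels.
#' @return A list with \code{chisq} and \code{p_value}.
#' @export
logrank_two_groups <- function(times, events, groups) {
  .check_surv(times, events)
  groups <- factor(groups)
  if (nlevels(groups) != 2L || any(tabulate(groups) == 0L)) {
    stop("exactly two non-empty groups required", call. = FALSE)
  }
  if (sum(events) == 0) {
    stop("no events observed; log-rank P undefined", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(chisq = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit curve
#'
#' @param times survival times.
#' @param events 0/1 event indicators.
#' @return A data.frame of the right-continuous step function with columns
#'   \code{time}, \code{surv}, \code{n_risk}, \code{n_event}; the curve
#'   starts at S(0) = 1.
#' @export
km_curve <- function(times, events) {
  .check_surv(times, events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, sf$time), surv = c(1, sf$surv),
             n_risk = c(length(times), sf$n.risk),
             n_event = c(0, sf$n.event))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a curve from \code{\link{km_curve}}.
#' @param t times at which to read off survival probability.
#' @return Survival probabilities (right-continuous step interpolation).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    km$surv[max(which(km$time <= ti))]
  }, numeric(1))
}

.cox_result <- function(fit, term) {
  s <- summary(fit)
  coef <- s$coefficients[term, "coef"]
  se <- s$coefficients[term, "se(coef)"]
  converged <- is.finite(coef) && is.finite(se) && se < 50 && abs(coef) < 50
  list(hr = exp(coef), log_hr = coef,
       ci = exp(coef + c(-1, 1) * 1.96 * se),
       p_value = s$coefficients[term, "Pr(>|z|)"],
       se = se, converged = converged)
}

#' Univariate Cox proportional-hazards model for a binary grouping
#'
#' Partial-likelihood fit with Efron tie handling; HR = exp(coef) with a
#' 95% Wald confidence interval and two-sided Wald P. Monotone-likelihood
#' fits (complete separation of event times) are flagged not converged.
#'
#' @param groups two-level grouping; the hazard ratio is for the second
#'   level relative to the first.
#' @param times,events survival data.
#' @return A list with \code{hr}, \code{log_hr}, \code{ci}, \code{p_value},
#'   \code{se} and \code{converged}.
#' @export
cox_univariate <- function(groups, times, events) {
  .check_surv(times, events)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two group levels required", call. = FALSE)
  if (any(tapply(events, groups, sum) < 1)) {
    stop("each group needs at least one event", call. = FALSE)
  }
  fit <- survival::coxph(survival::Surv(times, events) ~ groups,
                         ties = "efron")
  .cox_result(fit, 1L)
}

#' Multivariate Cox model: group effect adjusted for covariates
#'
#' Categorical covariates are dummy-coded; samples with missing covariate
#' values are dropped complete-case (the count is returned). A rank-deficient
#' design is an error naming the collinear columns. With an empty covariate
#' set the result equals \code{\link{cox_univariate}} exactly.
#'
#' @param groups two-level grouping of interest.
#' @param covariates data.frame of adjustment covariates (may have zero
#'   columns).
#' @param times,events survival data.
#' @return As \code{\link{cox_univariate}} for the group term, plus
#'   \code{n_used} and \code{n_dropped}.
#' @export
cox_multivariate <- function(groups, covariates, times, events) {
  .check_surv(times, events)
  groups <- factor(groups)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    out <- cox_univariate(groups, times, events)
    out$n_used <- length(times)
    out$n_dropped <- 0L
    return(out)
  }
  covariates <- as.data.frame(covariates)
  # drop all-missing covariates, then complete cases
  all_na <- vapply(covariates, function(x) all(is.na(x)), logical(1))
  covariates <- covariates[, !all_na, drop = FALSE]
  keep <- stats::complete.cases(covariates)
  n_dropped <- sum(!keep)
  df <- data.frame(.time = times[keep], .event = events[keep],
                   .group = groups[keep], covariates[keep, , drop = FALSE])
  mm <- stats::model.matrix(~ ., data = df[, -(1:2), drop = FALSE])
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1L):ncol(mm)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = "efron")
  out <- .cox_result(fit, grep("^\\.group", names(stats::coef(fit)))[1L])
  out$n_used <- sum(keep)
  out$n_dropped <- n_dropped
  out
}

#' Harrell's concordance index for a binary risk grouping
#'
#' Computed over comparable pairs: a pair is comparable when the smaller
#' observed time belongs to a subject who had the event (pairs whose smaller
#' time is censored, and pairs with tied times, are not comparable). A
#' concordant pair has the earlier-failing subject at higher risk; tied risk
#' contributes 1/2.
#'
#' @param risk per-sample risk score (high = 1 for a binary grouping, but
#'   any numeric ordering works).
#' @param times,events survival data.
#' @return The concordance index in [0, 1].
#' @export
concordance_index <- function(risk, times, events) {
  .check_surv(times, events)
  stopifnot(length(risk) == length(times))
  n <- length(times)
  # pair (i, j) comparable iff times[i] < times[j] and events[i] == 1
  ti <- matrix(times, n, n)            # ti[i, j] = times[i]
  comp <- (ti < t(ti)) & (events == 1L)
  diag(comp) <- FALSE
  n_comp <- sum(comp)
  if (n_comp == 0L) stop("no comparable pairs", call. = FALSE)
  ri <- matrix(risk, n, n)
  conc <- sum(comp & (ri > t(ri))) + 0.5 * sum(comp & (ri == t(ri)))
  conc / n_comp
}
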
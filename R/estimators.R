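#' Kaplan-Meier estimate with Greenwood standard errors
#'
#' Product-limit estimator with the Greenwood variance of \eqn{\log \hat S}
#' (\eqn{\sum d/(r(r-d))}) and log-scale 95\% confidence intervals
#' \eqn{\hat S \exp(\pm 1.96\, \mathrm{se}(\log \hat S))}.
#'
#' @param ipd data frame with columns `time` and `status` (0 = censored,
#'   any positive value = event).
#' @return list with `surv` (a [step_function()]), and vectors `time`,
#'   `n_risk`, `n_event`, `estimate`, `se_log`, `lower`, `upper` at the
#'   event times.
#' @export
kaplan_meier <- function(ipd) {
  if (nrow(ipd) == 0L) stop("no rows in ipd")
  fit <- survival::survfit(survival::Surv(time, status > 0) ~ 1,
                           data = ipd, conf.type = "log")
  ev <- fit$n.event > 0
  list(surv = step_function(fit$time[ev], fit$surv[ev], 1),
       time = fit$time[ev], n_risk = fit$n.risk[ev], n_event = fit$n.event[ev],
       estimate = fit$surv[ev], se_log = fit$std.err[ev],
       lower = fit$lower[ev], upper = fit$upper[ev])
}

#' Aalen-Johansen cumulative incidence estimates
#'
#' \eqn{\hat F_j(t) = \sum_{i: t_i \le t} (d_{ij}/r_i)\, \hat S(t_i-)} where
#' \eqn{\hat S} is the all-cause Kaplan-Meier estimate.
#'
#' @param ipd data frame with `time` and `status` in `0:m`.
#' @param m number of competing causes (default: `max(status)`).
#' @return named list of [step_function()]s, one CIF per cause.
#' @export
aalen_johansen <- function(ipd, m = max(ipd$status)) {
  if (nrow(ipd) == 0L) stop("no rows in ipd")
  st <- factor(ipd$status, levels = 0:m)
  if (all(ipd$status == 0)) {
    return(stats::setNames(
      replicate(m, step_function(numeric(), numeric(), 0), simplify = FALSE),
      as.character(seq_len(m))))
  }
  fit <- survival::survfit(survival::Surv(ipd$time, st) ~ 1)
  states <- fit$states
  out <- lapply(seq_len(m), function(j) {
    col <- which(states == as.character(j))
    keep <- c(TRUE, diff(fit$pstate[, col]) != 0) & fit$pstate[, col] > 0
    step_function(fit$time[keep], fit$pstate[keep, col], 0)
  })
  stats::setNames(out, as.character(seq_len(m)))
}

#' Weibull maximum likelihood fit
#'
#' Fits the Weibull model in the hazard parametrization
#' \eqn{h(t) = \lambda^\alpha \alpha t^{\alpha-1}} (cumulative hazard
#' \eqn{H(t) = (\lambda t)^\alpha}) by maximum likelihood via
#' `survival::survreg`, reparametrized so that `log_rate` \eqn{= \log\lambda}
#' and `log_shape` \eqn{= \log\alpha}.
#'
#' @param ipd data frame with `time` and `status`.
#' @param fix_shape optional fixed shape value (e.g. 1 for the exponential
#'   model).
#' @return list with `log_rate`, `log_shape`, their standard errors and the
#'   2x2 covariance matrix.
#' @export
fit_weibull <- function(ipd, fix_shape = NULL) {
  if (all(ipd$status == 0))
    stop("all observations censored: Weibull parameters are not identifiable")
  args <- list(formula = survival::Surv(time, status > 0) ~ 1,
               data = ipd, dist = "weibull")
  if (!is.null(fix_shape)) args$scale <- 1 / fix_shape
  fit <- do.call(survival::survreg, args)
  # survreg: S(t) = exp(-(t e^{-mu})^{1/sigma});  lambda = e^{-mu}, alpha = 1/sigma
  mu <- unname(stats::coef(fit)[1L])
  if (is.null(fix_shape)) {
    # (log lambda, log alpha) = (-mu, -log sigma): the Jacobian is -I, so the
    # covariance of the transformed parameters equals vcov(mu, log sigma)
    cov <- unname(stats::vcov(fit))
    out <- list(log_rate = -mu, log_shape = -log(fit$scale),
                se = sqrt(diag(cov)), cov = cov)
  } else {
    out <- list(log_rate = -mu, log_shape = log(fix_shape),
                se = c(sqrt(stats::vcov(fit)[1, 1]), 0),
                cov = matrix(c(stats::vcov(fit)[1, 1], 0, 0, 0), 2, 2))
  }
  out
}

#' Cox proportional hazards fit for a binary group covariate
#'
#' Breslow tie handling (coarsened reporting grids create many ties).
#'
#' @param ipd data frame with `time`, `status` and a 0/1 column `group`.
#' @return list with `log_hr`, `se` and the `coxph` fit object.
#' @export
fit_cox <- function(ipd) {
  fit <- survival::coxph(survival::Surv(time, status > 0) ~ group,
                         data = ipd, ties = "breslow")
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta) || abs(beta) > 15)
    stop("Cox partial likelihood is monotone (group separation); log HR diverges")
  list(log_hr = beta, se = sqrt(stats::vcov(fit)[1, 1]), fit = fit)
}

#' Grambsch-Therneau proportional hazards test statistic
#'
#' Chi-squared statistic (1 df) from regressing the scaled Schoenfeld
#' residuals on time; the identity time transform is used.
#'
#' @param cox_fit result of [fit_cox()] (or a `coxph` fit).
#' @return the test statistic.
#' @export
grambsch_therneau <- function(cox_fit) {
  fit <- if (inherits(cox_fit, "coxph")) cox_fit else cox_fit$fit
  zph <- survival::cox.zph(fit, transform = "identity", global = FALSE)
  unname(zph$table[1L, "chisq"])
}

#' Restricted mean survival time difference
#'
#' \eqn{\int_0^\tau \hat S(t)\,dt} per arm from the Kaplan-Meier step
#' functions (exact piecewise-constant integration), differenced as group 1
#' minus group 0.
#'
#' @param ipd data frame with `time`, `status`, `group`.
#' @param tau upper time point of the restriction.
#' @return the RMST difference.
#' @export
rmst_difference <- function(ipd, tau) {
  rmst1 <- integrate_step(kaplan_meier(ipd[ipd$group == 1, ])$surv, tau)
  rmst0 <- integrate_step(kaplan_meier(ipd[ipd$group == 0, ])$surv, tau)
  rmst1 - rmst0
}

#' Cause-specific Cox model
#'
#' Treats events of other causes as censoring and fits [fit_cox()].
#'
#' @param ipd data frame with `time`, `status` in `0:m`, `group`.
#' @param cause the cause of interest.
#' @return as [fit_cox()].
#' @export
fit_cause_specific_cox <- function(ipd, cause) {
  ipd$status <- as.integer(ipd$status == cause)
  fit_cox(ipd)
}

#' Fine-Gray subdistribution hazard model
#'
#' Proportional subdistribution hazards fit via the weighted partial
#' likelihood with inverse-probability-of-censoring weights estimated from
#' the pooled censoring Kaplan-Meier (`cmprsk::crr`).
#'
#' @param ipd data frame with `time`, `status` in `0:m`, `group`.
#' @param cause the cause of interest.
#' @return list with `log_shr` (log subdistribution hazard ratio) and `se`.
#' @export
fit_fine_gray <- function(ipd, cause) {
  fit <- cmprsk::crr(ftime = ipd$time, fstatus = ipd$status,
                     cov1 = matrix(ipd$group, ncol = 1), failcode = cause,
                     cencode = 0)
  list(log_shr = unname(fit$coef[1L]), se = sqrt(fit$var[1, 1]), fit = fit)
}
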
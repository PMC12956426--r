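#' Scenario configuration for the evaluation harness
#'
#' Defaults reproduce the evaluation study conditions: Weibull event times
#' with shape 0.8 and rate 0.2 (hazard \eqn{h(t)=\lambda^\alpha\alpha
#' t^{\alpha-1}}), independent Uniform(2, 8) censoring (about 39\% censored,
#' about 76 events per dataset of 125), reporting times coarsened up to the
#' next multiple of 0.05, curve values rounded to 3 decimals, numbers at
#' risk reported at integer times 0..8, a log hazard ratio of -0.5 for the
#' treated arm in the two-arm scenario, and the competing-risks generator
#' with parameters `(kappa, lambda01, alpha1, lambda02, alpha2, beta1,
#' beta2) = (0.6, 0.4, 1.2, 0.2, 1.5, -0.3, 0.3)` under Uniform(1, 6)
#' censoring with at-risk reporting at 0..5.
#'
#' @param n sample size per arm.
#' @param shape,rate Weibull parameters \eqn{\alpha,\lambda}.
#' @param cens_bounds censoring distribution bounds (uniform).
#' @param resolution reporting-time coarsening resolution.
#' @param decimals decimals the curve values are rounded to when emulating
#'   digitization (`Inf` disables rounding).
#' @param at_risk_times report times for the emitted at-risk table; `NULL`
#'   reports at every distinct observed time (full at-risk information).
#' @param log_hr log hazard ratio applied to the treated arm's hazard
#'   (negative = protective) in the two-arm scenario.
#' @param cr_params named competing-risks parameter vector
#'   `(kappa, lambda01, alpha1, lambda02, alpha2, beta1, beta2)`.
#' @param cr_cens_bounds,cr_at_risk_times censoring bounds and at-risk report
#'   times for the competing-risks scenario.
#' @param reps replicate count for [run_scenario()].
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @return a list of class `survqp_config`.
#' @export
scenario_config <- function(n = 125, shape = 0.8, rate = 0.2,
                            cens_bounds = c(2, 8), resolution = 0.05,
                            decimals = 3, at_risk_times = 0:8,
                            log_hr = -0.5,
                            cr_params = c(kappa = 0.6, lambda01 = 0.4,
                                          alpha1 = 1.2, lambda02 = 0.2,
                                          alpha2 = 1.5, beta1 = -0.3,
                                          beta2 = 0.3),
                            cr_cens_bounds = c(1, 6), cr_at_risk_times = 0:5,
                            reps = 1000, seed = 1) {
  stopifnot(resolution > 0, decimals >= 0, reps >= 1, n >= 1)
  structure(as.list(environment()), class = "survqp_config")
}

#' Coarsen reporting times
#'
#' Rounds times up to the next multiple of `resolution` (ties are created
#' intentionally, emulating reporting to the nearest day/week).
#'
#' @param times positive times.
#' @param resolution grid width.
#' @return coarsened times, snapped to 10 decimals to keep grid values exact.
#' @export
coarsen <- function(times, resolution = 0.05) {
  round(resolution * ceiling(times / resolution - 1e-9), 10)
}

#' Simulate the single-arm Weibull dataset
#'
#' Event times by inverse-CDF from \eqn{H(t) = (\lambda t)^\alpha}, censoring
#' uniform on `cens_bounds`; observed times coarsened to the reporting grid.
#'
#' @param config a [scenario_config()].
#' @param rep replicate number; the RNG seed is `config$seed + rep`.
#' @return data frame `time`, `status` (1 = event, 0 = censored).
#' @export
simulate_base <- function(config = scenario_config(), rep = 1) {
  set.seed(config$seed + rep)
  sim_weibull_arm(config$n, config$shape, config$rate, 0,
                  config$cens_bounds, config$resolution)
}

sim_weibull_arm <- function(n, shape, rate, log_hr, cens_bounds, resolution) {
  # H(t) = (rate * t)^shape * exp(log_hr);  T = H^{-1}(-log U)
  ev <- (-log(stats::runif(n)) * exp(-log_hr))^(1 / shape) / rate
  cn <- stats::runif(n, cens_bounds[1], cens_bounds[2])
  data.frame(time = coarsen(pmin(ev, cn), resolution),
             status = as.integer(ev <= cn))
}

#' Simulate the two-arm proportional-hazards dataset
#'
#' Arm 0 as [simulate_base()]; arm 1 shares the shape parameter (ensuring
#' proportionality) with the hazard multiplied by `exp(log_hr)`.
#'
#' @inheritParams simulate_base
#' @return data frame `time`, `status`, `group` (0/1).
#' @export
simulate_two_arm <- function(config = scenario_config(), rep = 1) {
  set.seed(config$seed + rep)
  arm0 <- sim_weibull_arm(config$n, config$shape, config$rate, 0,
                          config$cens_bounds, config$resolution)
  arm1 <- sim_weibull_arm(config$n, config$shape, config$rate, config$log_hr,
                          config$cens_bounds, config$resolution)
  rbind(cbind(arm0, group = 0L), cbind(arm1, group = 1L))
}

#' Simulate the two-cause competing-risks dataset
#'
#' Cause 1 follows the proportional subdistribution hazards (Fine-Gray)
#' model \eqn{F_1(t;Z) = 1 - (1 - \kappa(1 - e^{-\lambda_{01} t^{\alpha_1}}))
#' ^{\exp(\beta_1 Z)}}, so the Fine-Gray fit for cause 1 is correctly
#' specified.  Cause 2 occurs with the complementary probability
#' \eqn{(1-\kappa)^{\exp(\beta_1 Z)}} and conditional time CDF
#' \eqn{1 - \exp(-\lambda_{02} t^{\alpha_2} e^{\beta_2 Z})}, under which the
#' cause-2 models are misspecified.  Censoring uniform on
#' `cr_cens_bounds`; observed times coarsened.
#'
#' @inheritParams simulate_base
#' @return data frame `time`, `status` (0/1/2), `group` (0/1).
#' @export
simulate_competing <- function(config = scenario_config(), rep = 1) {
  set.seed(config$seed + rep)
  p <- config$cr_params
  one_arm <- function(z) {
    n <- config$n
    p1 <- 1 - (1 - p["kappa"])^exp(p["beta1"] * z)
    cause <- ifelse(stats::runif(n) < p1, 1L, 2L)
    u <- stats::runif(n)
    t1 <- cr_cause1_time(u, z, p, p1)
    t2 <- (-log(1 - u) / (p["lambda02"] * exp(p["beta2"] * z)))^(1 / p["alpha2"])
    ev <- ifelse(cause == 1L, t1, t2)
    cn <- stats::runif(n, config$cr_cens_bounds[1], config$cr_cens_bounds[2])
    data.frame(time = coarsen(pmin(ev, cn), config$resolution),
               status = ifelse(ev <= cn, cause, 0L), group = z)
  }
  rbind(one_arm(0L), one_arm(1L))
}

# Inverse of the conditional cause-1 CDF F1(t; z) / F1(Inf; z) at u.
cr_cause1_time <- function(u, z, p, p1) {
  # F1(t; z) = 1 - (1 - kappa (1 - exp(-lambda01 t^alpha1)))^{exp(beta1 z)}
  inner <- (1 - u * p1)^exp(-p["beta1"] * z)
  arg <- 1 - (1 - inner) / p["kappa"]
  (-log(arg) / p["lambda01"])^(1 / p["alpha1"])
}

#' Emulate the published-figure information channels
#'
#' Computes the Kaplan-Meier curve (or per-cause Aalen-Johansen cumulative
#' incidence curves) of a true dataset, rounds the values to the configured
#' number of decimals to emulate digitization error, and emits the auxiliary
#' channels: marked censoring times (every distinct censoring time becomes a
#' tick), the at-risk table at the configured report times, and total event
#' counts (per cause for competing risks).
#'
#' @param ipd a true (already coarsened) single-arm dataset.
#' @param config a [scenario_config()].
#' @param competing emulate cumulative incidence curves (`TRUE`) or a
#'   Kaplan-Meier curve (`FALSE`).
#' @return list with `curve` (a [digitized_curve()]), `ticks`, `at_risk`,
#'   `n`, `total_events`.
#' @export
emulate_digitization <- function(ipd, config = scenario_config(),
                                 competing = FALSE) {
  rnd <- function(x) if (is.finite(config$decimals)) round(x, config$decimals) else x
  n <- nrow(ipd)
  if (!competing) {
    km <- kaplan_meier(ipd)
    curve <- digitized_curve(km$time, rnd(km$estimate), mode = "km")
    report <- config$at_risk_times
    if (is.null(report)) report <- c(0, sort(unique(ipd$time)))
    total_events <- sum(ipd$status > 0)
  } else {
    m <- max(ipd$status, 1)
    cifs <- aalen_johansen(ipd, m = m)
    tabs <- lapply(cifs, function(f) data.frame(time = f$time, value = rnd(f$value)))
    curve <- merge_cif_curves(tabs, names(cifs))
    report <- config$cr_at_risk_times
    if (is.null(report)) report <- c(0, sort(unique(ipd$time)))
    total_events <- vapply(seq_len(m), function(j) sum(ipd$status == j), numeric(1))
  }
  ticks <- sort(unique(ipd$time[ipd$status == 0]))
  counts <- vapply(report, function(tau) sum(ipd$time >= tau - 1e-9), numeric(1))
  list(curve = curve,
       ticks = ticks,
       at_risk = at_risk_table(report, counts),
       n = n, total_events = total_events)
}
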
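#' Integrated absolute discrepancy between two survival curves
#'
#' \eqn{\Delta S = \int_0^\tau |\hat{\hat S}(t) - \hat S(t)|\,dt} where the
#' two Kaplan-Meier estimates come from the reconstructed and the true data;
#' the integral of the two step functions is computed exactly.
#'
#' @param recon,truth data frames with `time` and `status`.
#' @param horizon upper limit \eqn{\tau}; defaults to the maximum follow-up
#'   time in the true data.
#' @return non-negative scalar.
#' @export
delta_S <- function(recon, truth, horizon = max(truth$time)) {
  integrate_abs_diff(kaplan_meier(recon)$surv, kaplan_meier(truth)$surv,
                     horizon)
}

#' Integrated absolute discrepancy between two at-risk processes
#'
#' \eqn{\Delta Y = \int_0^\tau |\hat Y(t) - Y(t)|\,dt} on the number of
#' persons at risk implied by the reconstructed and the true data.
#'
#' @inheritParams delta_S
#' @return non-negative scalar.
#' @export
delta_Y <- function(recon, truth, horizon = max(truth$time)) {
  integrate_abs_diff(atrisk_process(recon$time), atrisk_process(truth$time),
                     horizon)
}

variant_channels <- function(variant) {
  switch(variant,
    ticks_full = c(ticks = TRUE,  at_risk = TRUE,  totals = TRUE),
    no_ticks   = c(ticks = FALSE, at_risk = TRUE,  totals = TRUE),
    ticks_nd   = c(ticks = TRUE,  at_risk = FALSE, totals = TRUE),
    ticks_only = c(ticks = TRUE,  at_risk = FALSE, totals = FALSE),
    stop("unknown variant: ", variant))
}

# Reconstruct one emulated arm under an information variant.
reconstruct_variant <- function(emu, variant, competing = FALSE,
                                options = recon_options()) {
  ch <- variant_channels(variant)
  ticks <- if (ch[["ticks"]]) emu$ticks else NULL
  at_risk <- if (ch[["at_risk"]]) emu$at_risk else NULL
  totals <- if (ch[["totals"]]) emu$total_events else NULL
  if (competing)
    reconstruct_cif(emu$curve, at_risk = at_risk, ticks = ticks, n = emu$n,
                    total_events = totals, options = options)
  else
    reconstruct_km(emu$curve, at_risk = at_risk, ticks = ticks, n = emu$n,
                   total_events = totals, options = options)
}

#' Run a simulation scenario
#'
#' For each replicate, simulates a true dataset, emulates the published
#' figure (curve values rounded, ticks, at-risk table, event totals),
#' reconstructs pseudo-IPD under each requested information variant, and
#' records curve discrepancies and paired estimator differences
#' (pseudo-IPD estimate minus true-IPD estimate; bias and RMSE are defined
#' against the true-IPD estimate, not the population parameter).
#'
#' @param scenario `"base"` (single arm: \eqn{\Delta S}, \eqn{\Delta Y},
#'   Weibull log-rate and log-shape), `"two_arm"` (Cox log HR, Weibull PH
#'   log HR, Grambsch-Therneau statistic, RMST difference at `tau = 5`) or
#'   `"competing"` (cause-specific and Fine-Gray log HRs for both causes,
#'   plus per-cause \eqn{\Delta F}).
#' @param variants information variants: any of `"ticks_full"`,
#'   `"no_ticks"`, `"ticks_nd"`, `"ticks_only"`.
#' @param config a [scenario_config()]; `config$reps` replicates are run
#'   with per-replicate seed `config$seed + rep`.
#' @param options reconstruction options.
#' @return object of class `survqp_eval`: list with `per_rep` (long data
#'   frame of per-replicate measures), `summary` (mean/bias, RMSE and their
#'   Monte Carlo standard errors per variant and measure), `failures`
#'   (replicates excluded because a stage failed, with messages) and the
#'   `config` used.
#' @export
run_scenario <- function(scenario = c("base", "two_arm", "competing"),
                         variants = "ticks_full",
                         config = scenario_config(),
                         options = recon_options()) {
  scenario <- match.arg(scenario)
  per_rep <- list(); failures <- list()
  for (r in seq_len(config$reps)) {
    res <- tryCatch(run_one_rep(scenario, variants, config, r, options),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, message = conditionMessage(res))
    } else {
      per_rep[[length(per_rep) + 1L]] <- res
    }
  }
  per_rep <- do.call(rbind, per_rep)
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(rep = integer(), message = character())
  summ <- do.call(rbind, lapply(split(per_rep, per_rep[c("variant", "measure")],
                                      drop = TRUE),
    function(d) {
      x <- d$value; R <- length(x)
      data.frame(variant = d$variant[1L], measure = d$measure[1L], reps = R,
                 mean = mean(x), se_mean = stats::sd(x) / sqrt(R),
                 rmse = sqrt(mean(x^2)),
                 se_rmse = if (mean(x^2) > 0)
                   stats::sd(x^2) / (2 * sqrt(mean(x^2)) * sqrt(R)) else 0)
    }))
  rownames(summ) <- NULL
  structure(list(scenario = scenario, per_rep = per_rep, summary = summ,
                 failures = failures, config = config),
            class = "survqp_eval")
}

run_one_rep <- function(scenario, variants, config, r, options) {
  out <- list()
  add <- function(variant, measure, value)
    out[[length(out) + 1L]] <<- data.frame(rep = r, variant = variant,
                                           measure = measure, value = value)
  if (scenario == "base") {
    truth <- simulate_base(config, r)
    emu <- emulate_digitization(truth, config)
    fit_true <- fit_weibull(truth)
    for (v in variants) {
      recon <- reconstruct_variant(emu, v, options = options)
      add(v, "delta_S", delta_S(recon, truth))
      add(v, "delta_Y", delta_Y(recon, truth))
      fit_rec <- fit_weibull(recon)
      add(v, "d_log_rate", fit_rec$log_rate - fit_true$log_rate)
      add(v, "d_log_shape", fit_rec$log_shape - fit_true$log_shape)
    }
  } else if (scenario == "two_arm") {
    truth <- simulate_two_arm(config, r)
    emus <- lapply(0:1, function(z)
      emulate_digitization(truth[truth$group == z, c("time", "status")], config))
    cox_t <- fit_cox(truth)
    gt_t <- grambsch_therneau(cox_t)
    rmst_t <- rmst_difference(truth, tau = 5)
    wph_t <- weibull_ph_loghr(truth)
    for (v in variants) {
      recon <- pool_arms(lapply(0:1, function(z)
        reconstruct_variant(emus[[z + 1L]], v, options = options)))
      cox_r <- fit_cox(recon)
      add(v, "d_cox_loghr", cox_r$log_hr - cox_t$log_hr)
      add(v, "d_weibull_loghr", weibull_ph_loghr(recon) - wph_t)
      add(v, "d_gt_stat", grambsch_therneau(cox_r) - gt_t)
      add(v, "d_rmst", rmst_difference(recon, tau = 5) - rmst_t)
    }
  } else {
    truth <- simulate_competing(config, r)
    emus <- lapply(0:1, function(z)
      emulate_digitization(truth[truth$group == z, c("time", "status")],
                           config, competing = TRUE))
    cs_t <- lapply(1:2, function(k) fit_cause_specific_cox(truth, k)$log_hr)
    fg_t <- lapply(1:2, function(k) fit_fine_gray(truth, k)$log_shr)
    for (v in variants) {
      recon <- pool_arms(lapply(0:1, function(z)
        reconstruct_variant(emus[[z + 1L]], v, competing = TRUE,
                            options = options)))
      for (k in 1:2) {
        add(v, paste0("d_csh_loghr_", k),
            fit_cause_specific_cox(recon, k)$log_hr - cs_t[[k]])
        add(v, paste0("d_fg_loghr_", k),
            fit_fine_gray(recon, k)$log_shr - fg_t[[k]])
      }
    }
  }
  do.call(rbind, out)
}

pool_arms <- function(arms) {
  pooled <- rbind(cbind(as.data.frame(arms[[1L]]), group = 0L),
                  cbind(as.data.frame(arms[[2L]]), group = 1L))
  pooled
}

# Weibull proportional-hazards log HR from the AFT fit: beta_PH = -beta_AFT / sigma.
weibull_ph_loghr <- function(ipd) {
  fit <- survival::survreg(survival::Surv(time, status > 0) ~ group,
                           data = ipd, dist = "weibull")
  -unname(stats::coef(fit)[2L]) / fit$scale
}

#' @export
print.survqp_eval <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d replicates (%d failed)\n", x$scenario,
              x$config$reps, nrow(x$failures)))
  print(x$summary, digits = 4)
  invisible(x)
}
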
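test_that("kaplan_meier reproduces product-limit arithmetic and Greenwood", {
  ipd <- data.frame(time = c(1, 1.5, 2, 3), status = c(1, 0, 1, 1))
  km <- kaplan_meier(ipd)
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$estimate, c(0.75, 0.375, 0))
  # Greenwood term at the first event: d/(r(r-d)) = 1/(4*3)
  expect_equal(km$se_log[1L], sqrt(1 / 12))
  # log-scale CI: S * exp(+-1.96 se(log S))
  expect_equal(km$upper[1L], min(1, 0.75 * exp(qnorm(0.975) * sqrt(1 / 12))))

  allc <- data.frame(time = 1:3, status = 0)
  expect_equal(eval_step(kaplan_meier(allc)$surv, 1:3), rep(1, 3))
  expect_error(kaplan_meier(allc[0, ]), "no rows")
})

test_that("aalen_johansen matches hand-computed CIFs and reduces to 1 - KM", {
  ipd <- data.frame(time = 1:3, status = c(1, 2, 1))
  cif <- aalen_johansen(ipd, m = 2)
  expect_equal(eval_step(cif[["1"]], 1:3), c(1/3, 1/3, 2/3))
  expect_equal(eval_step(cif[["2"]], 1:3), c(0, 1/3, 1/3))

  set.seed(2)
  one <- sim_small(40)
  f1 <- aalen_johansen(one, m = 1)[["1"]]
  km <- kaplan_meier(one)
  expect_equal(eval_step(f1, km$time), 1 - km$estimate)

  allc <- data.frame(time = 1:3, status = 0)
  expect_equal(eval_step(aalen_johansen(allc, m = 2)[["1"]], 3), 0)
})

test_that("CIFs plus all-cause survival sum to one without censoring", {
  set.seed(12)
  n <- 60
  ipd <- data.frame(time = sample(1:20, n, TRUE) / 4,
                    status = sample(1:2, n, TRUE))
  cif <- aalen_johansen(ipd, m = 2)
  km <- kaplan_meier(ipd)
  tot <- eval_step(cif[["1"]], km$time) + eval_step(cif[["2"]], km$time) +
    km$estimate
  expect_equal(tot, rep(1, length(km$time)))
})

test_that("fit_weibull uses the h(t) = lambda^a a t^(a-1) parametrization", {
  # shape fixed at 1: exponential MLE rate = events / total time
  ipd <- data.frame(time = c(1, 2, 3), status = 1)
  fit <- fit_weibull(ipd, fix_shape = 1)
  expect_equal(exp(fit$log_rate), 3 / 6, tolerance = 1e-6)

  # parameter recovery at large n, no censoring, no coarsening
  set.seed(99)
  n <- 20000
  tt <- (-log(runif(n)))^(1 / 0.8) / 0.2
  fit2 <- fit_weibull(data.frame(time = tt, status = 1))
  expect_lt(abs(fit2$log_rate - log(0.2)), 3 * fit2$se[1L])
  expect_lt(abs(fit2$log_shape - log(0.8)), 3 * fit2$se[2L])

  expect_error(fit_weibull(data.frame(time = 1:3, status = 0)),
               "not identifiable")
})

test_that("fit_weibull agrees with an independent PH-Weibull implementation", {
  set.seed(23)
  ipd <- sim_small(200)
  ours <- fit_weibull(ipd)
  # flexsurv's weibullPH: H(t) = m t^a, so m = lambda^alpha, a = alpha
  ff <- flexsurv::flexsurvreg(survival::Surv(time, status) ~ 1, data = ipd,
                              dist = "weibullPH")
  a <- unname(ff$res["shape", "est"]); m <- unname(ff$res["scale", "est"])
  expect_equal(ours$log_shape, log(a), tolerance = 1e-4)
  expect_equal(ours$log_rate, log(m) / a, tolerance = 1e-4)
})

test_that("fit_cox recovers the two-arm log hazard ratio", {
  set.seed(17)
  cfg <- scenario_config(n = 5000, reps = 1, seed = 17, resolution = 1e-6)
  ipd <- simulate_two_arm(cfg, 1)
  fit <- fit_cox(ipd)
  expect_lt(abs(fit$log_hr - (-0.5)), 3 * fit$se)

  # exchangeable groups: log HR near zero
  set.seed(18)
  one <- sim_small(400)
  one$group <- sample(rep(0:1, 200))
  fit0 <- fit_cox(one)
  expect_lt(abs(fit0$log_hr), 3 * fit0$se)

  # monotone likelihood is reported, not silently returned
  toy <- data.frame(time = c(1, 2), status = 1, group = c(1, 0))
  expect_error(suppressWarnings(fit_cox(toy)), "diverges")
})

test_that("grambsch_therneau behaves as a chi-squared(1) statistic under PH", {
  set.seed(31)
  stats <- replicate(300, {
    cfg <- scenario_config(n = 60, reps = 1, seed = sample.int(1e6, 1))
    ipd <- simulate_two_arm(cfg, 1)
    grambsch_therneau(fit_cox(ipd))
  })
  expect_gt(mean(stats), 0.75)
  expect_lt(mean(stats), 1.3)

  # a strong built-in time-varying effect is detected
  set.seed(32)
  pow <- replicate(40, {
    n <- 150
    g <- rep(0:1, each = n)
    t0 <- rexp(n, 1); t1 <- ifelse(runif(n) < 0.5, rexp(n, 6), rexp(n, 0.2))
    ipd <- data.frame(time = c(t0, t1), status = 1, group = g)
    grambsch_therneau(fit_cox(ipd)) > qchisq(0.95, 1)
  })
  expect_gt(mean(pow), 0.8)
})

test_that("rmst_difference integrates the KM step functions exactly", {
  two <- data.frame(time = rep(c(1, 2), 2), status = 1,
                    group = rep(0:1, each = 2))
  expect_equal(rmst_difference(two, tau = 2), 0)

  # S = 1 to t=1 then 0.5 on [1, 5): RMST(5) = 1 + 4 * 0.5 = 3
  arm1 <- data.frame(time = c(1, 6), status = c(1, 1), group = 1)
  arm0 <- data.frame(time = 6, status = 1, group = 0)   # S = 1 on [0, 5]
  expect_equal(rmst_difference(rbind(arm1, arm0), tau = 5), 3 - 5)
})

test_that("cause-specific Cox equals Cox with other causes censored", {
  set.seed(41)
  cfg <- scenario_config(n = 300, reps = 1, seed = 41)
  ipd <- simulate_competing(cfg, 1)
  cs <- fit_cause_specific_cox(ipd, 1)
  manual <- ipd; manual$status <- as.integer(manual$status == 1)
  expect_equal(cs$log_hr, fit_cox(manual)$log_hr)
  # single-cause data: identical to the plain Cox fit
  single <- ipd[ipd$status != 2, ]
  expect_equal(fit_cause_specific_cox(single, 1)$log_hr,
               fit_cox(single)$log_hr)
})

test_that("fine_gray equals Cox without censoring or competing events", {
  set.seed(51)
  n <- 300
  ipd <- data.frame(time = rexp(n) * exp(-0.4 * rep(0:1, each = n / 2)),
                    status = 1, group = rep(0:1, each = n / 2))
  fg <- fit_fine_gray(ipd, 1)
  cx <- fit_cox(ipd)
  expect_equal(fg$log_shr, cx$log_hr, tolerance = 1e-4)
})

test_that("fine_gray recovers the subdistribution log HR of the generator", {
  set.seed(52)
  cfg <- scenario_config(n = 5000, reps = 1, seed = 52, resolution = 1e-6)
  ipd <- simulate_competing(cfg, 1)
  fg <- fit_fine_gray(ipd, 1)
  expect_lt(abs(fg$log_shr - (-0.3)), 3 * fg$se)
})
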
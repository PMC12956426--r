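test_that("the KM objective reproduces hand-evaluated residuals", {
  # o = (0.25, 0.5), N = 4: residuals vanish at d = (1, 1.5), c = 0
  crv <- digitized_curve(c(1, 2), c(0.75, 0.375))
  pr <- prepare_problem(crv, n = 4)
  qp <- build_km_qp(pr)
  x_zero_resid <- counts_to_x(qp, cbind(c(1, 1.5)), c(0, 0))
  expect_equal(qp_objective(qp, x_zero_resid, regularized = FALSE), 0,
               tolerance = 1e-12)
  x0 <- numeric(nrow(qp$layout))
  expect_equal(qp_objective(qp, x0, regularized = FALSE), 1 + 4) # 1^2 + 2^2
})

test_that("with no ticks no variables are eliminated (p = 2 x grid size)", {
  crv <- digitized_curve(c(1, 2, 3), c(0.75, 0.5, 0.25))
  qp <- build_km_qp(prepare_problem(crv, n = 6))
  expect_equal(nrow(qp$layout), 2L * 3L)
})

test_that("solve_continuous recovers the tiny exact instance", {
  ti <- tiny_instance()
  pr <- prepare_problem(ti$curve, at_risk = ti$at_risk, ticks = ti$ticks)
  qp <- build_km_qp(pr)
  sol <- solve_continuous(qp)
  expect_equal(sol$W, 0, tolerance = 1e-10)
  expect_equal(drop(sol$d)[pr$o > 0], c(1, 1, 1), tolerance = 1e-6)
  expect_equal(sol$c[pr$is_tick], 1, tolerance = 1e-6)
  # the attained objective is no worse than a feasible caller-supplied point
  x_true <- counts_to_x(qp, cbind(as.numeric(pr$o > 0)), as.numeric(pr$is_tick))
  expect_lte(sol$objective, qp_objective(qp, x_true) + 1e-9)
})

test_that("a flat curve with no constraints reconstructs to all-censored", {
  crv <- digitized_curve(c(1, 2), c(1, 1))
  ipd <- reconstruct_km(crv, n = 5)
  expect_equal(nrow(ipd), 5L)
  expect_true(all(ipd$status == 0))
  expect_true(all(ipd$time == 2))
})

test_that("dropping the tick but adding NE keeps the event solution", {
  ti <- tiny_instance()
  ipd <- reconstruct_km(ti$curve, at_risk = ti$at_risk, total_events = 3)
  cnt <- attr(ipd, "counts")
  expect_equal(cnt$d[cnt$time %in% c(1, 2, 3)], c(1, 1, 1))
  expect_equal(sum(cnt$d), 3)
  # censoring mass of one subject sits in period 1 (before 2.5)
  expect_equal(sum(cnt$c[cnt$time < 2.5]), 1)
})

test_that("integerized reconstructions are insensitive to epsilon", {
  ti <- tiny_instance()
  d_hats <- lapply(c(1e-4, 1e-3, 1e-2), function(eps) {
    ipd <- reconstruct_km(ti$curve, at_risk = ti$at_risk, ticks = ti$ticks,
                          options = recon_options(epsilon = eps))
    attr(ipd, "counts")$d
  })
  expect_equal(d_hats[[1L]], d_hats[[2L]])
  expect_equal(d_hats[[2L]], d_hats[[3L]])
})

test_that("infeasible inputs produce structured reports and relaxation", {
  # at-risk demands 5 leavers in [0, 1.5) but the grid has no candidate there
  crv <- digitized_curve(c(2, 3), c(0.5, 0.25))
  ar <- at_risk_table(c(0, 1.5), c(6, 1))
  qp <- build_km_qp(prepare_problem(crv, at_risk = ar, ticks = 2.2))
  expect_true(length(qp$infeasible) > 0)
  expect_error(solve_continuous(qp), "infeasible")
  expect_error(reconstruct_km(crv, at_risk = ar, ticks = 2.2),
               "infeasible after all relaxations")

  # two visible decrements but only one leaver: d >= 1 is relaxed, not fatal
  crv2 <- digitized_curve(c(1.6, 2.0), c(0.8, 0.6))
  ar2 <- at_risk_table(c(0, 1.5, 3), c(5, 5, 4))
  ipd <- reconstruct_km(crv2, at_risk = ar2)
  expect_s3_class(ipd, "survqp_ipd")
  expect_true(any(grepl("relaxed d>=1", attr(ipd, "relaxations"))))
  cnt <- attr(ipd, "counts")
  expect_equal(sum(cnt$d) + sum(cnt$c), 1)  # the period equality still holds
})

test_that("solver tolerances hold on simulated problems", {
  set.seed(3)
  truth <- sim_small(80)
  emu <- exact_emulation(truth)
  pr <- prepare_problem(emu$curve, at_risk = emu$at_risk, ticks = emu$ticks,
                        total_events = emu$total_events)
  qp <- build_km_qp(pr)
  sol <- solve_continuous(qp)
  expect_lt(max(abs(drop(qp$Aeq %*% sol$x) - qp$beq)), 1e-8)
  expect_true(all(sol$x >= -1e-8))
})
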
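test_that("digitized_curve sorts, collapses duplicates and clips", {
  crv <- digitized_curve(c(2, 1), c(0.5, 0.8))
  expect_equal(crv$time, c(1, 2))
  expect_equal(drop(crv$value), c(0.8, 0.5))

  expect_warning(crv2 <- digitized_curve(1, 1.004), "clipped")
  expect_equal(unname(drop(crv2$value)), 1)
  expect_error(digitized_curve(1, 1.02), "outside")
  expect_error(digitized_curve(numeric(), numeric()), "empty")
  expect_error(digitized_curve(c(1, 2), c(0.9, NA)), "missing")

  # step corners at the same time keep the post-step value
  crv3 <- digitized_curve(c(1, 1, 2), c(0.9, 0.7, 0.5))
  expect_equal(drop(crv3$value), c(0.7, 0.5))
})

test_that("enforce_monotone clips and drops flat points unless protected", {
  crv <- digitized_curve(c(1, 2, 3), c(0.8, 0.81, 0.6))
  out <- enforce_monotone(crv)
  expect_equal(out$time, c(1, 3))
  expect_equal(drop(out$value), c(0.8, 0.6))

  mono <- digitized_curve(c(1, 2), c(0.9, 0.4))
  expect_equal(enforce_monotone(mono), mono)

  cif <- digitized_curve(c(1, 2, 3), cbind(c(0.1, 0.09, 0.3)), mode = "cif")
  out2 <- enforce_monotone(cif)
  expect_equal(out2$time, c(1, 3))
  expect_equal(drop(out2$value), c(0.1, 0.3))

  # protected (tick/at-risk) times survive the drop
  out3 <- enforce_monotone(crv, keep = 2)
  expect_equal(out3$time, c(1, 2, 3))
})

test_that("compute_decrements follows o_i = 1 - s_i/s_{i-1}", {
  expect_equal(compute_decrements(c(0.75, 0.375, 0)), c(0.25, 0.5, 1))
  expect_equal(compute_decrements(c(0.9, 0.9)), c(0.1, 0))
  expect_equal(compute_decrements(1), 0)
  expect_error(compute_decrements(c(0, 0.5)), "rises from zero")
  # Nelson-Aalen mode uses cumulative hazard increments
  expect_equal(compute_decrements(c(0.2, 0.5), mode = "nelson-aalen"),
               c(0.2, 0.3))
})

test_that("compute_cif_increments matches the competing-risks identity", {
  f <- rbind(c(1/3, 0), c(1/3, 1/3))
  expect_equal(compute_cif_increments(f), rbind(c(1/3, 0), c(0, 1/2)))
  # single cause reduces to KM decrements on s = 1 - f
  s <- c(0.75, 0.375)
  expect_equal(drop(compute_cif_increments(cbind(1 - s))),
               compute_decrements(s))
  expect_equal(compute_cif_increments(rbind(0.2, 0.2))[2L, ], 0)
  expect_warning(compute_cif_increments(rbind(c(0.6, 0.4), c(0.6, 0.4))),
                 "exhausts")
})

test_that("prepare_problem merges the candidate grid and classifies ticks", {
  crv <- digitized_curve(c(1, 2, 3), c(0.75, 0.5, 0.25))
  pr <- prepare_problem(crv, at_risk = at_risk_table(c(0, 2.5), c(6, 2)),
                        ticks = 1.5)
  expect_equal(pr$time, c(1, 1.5, 2, 2.5, 3))
  expect_equal(which(pr$period == 1L), 1:3)        # C_1 = {1, 1.5, 2}
  expect_equal(pr$time[pr$tick_zero], 1.5)         # C* = {1.5}
  expect_equal(drop(pr$o), c(0.25, 0, 1/3, 0, 0.5))
  expect_equal(pr$leaving, 4)

  # no ticks / no at-risk: the grid is the curve's own
  pr2 <- prepare_problem(crv, n = 6)
  expect_equal(pr2$time, crv$time)
  expect_true(all(pr2$period == 0L))

  # a tick at an event time leaves both d and c active
  pr3 <- prepare_problem(crv, n = 6, ticks = 2)
  expect_false(pr3$tick_zero[pr3$time == 2])
  expect_true(pr3$is_tick[pr3$time == 2])
})

test_that("prepare_problem is idempotent on its own grid", {
  crv <- digitized_curve(c(1, 2, 3), c(0.75, 0.5, 0.25))
  ar <- at_risk_table(c(0, 2.5), c(6, 2))
  pr <- prepare_problem(crv, at_risk = ar, ticks = 1.5)
  crv2 <- digitized_curve(pr$time, pr$value[, 1L])
  pr2 <- prepare_problem(crv2, at_risk = ar, ticks = 1.5,
                         keep_flat_curve_points = FALSE)
  expect_equal(pr2$time, pr$time)
  expect_equal(pr2$o, pr$o)
  expect_equal(pr2$period, pr$period)
})

test_that("prepare_problem validates inputs", {
  crv <- digitized_curve(c(1, 2, 3), c(0.75, 0.5, 0.25))
  expect_error(prepare_problem(crv), "required")
  expect_error(at_risk_table(c(0, 1), c(5, 6)), "non-increasing")
  expect_error(at_risk_table(c(1, 2), c(5, 4)), "time 0")
  expect_error(prepare_problem(crv, n = 2), "below the number")
  expect_error(prepare_problem(crv, n = 10, total_events = 2), "below")
  expect_error(prepare_problem(crv, at_risk = at_risk_table(0, 8), n = 6),
               "disagrees")
})

test_that("periods partition the grid up to the last report time", {
  set.seed(11)
  truth <- sim_small(60)
  emu <- exact_emulation(truth)
  pr <- prepare_problem(emu$curve, at_risk = emu$at_risk, ticks = emu$ticks,
                        total_events = emu$total_events)
  expect_equal(sum(pr$period > 0) + sum(pr$period == 0), length(pr$time))
  # every non-tail grid time lies in exactly one half-open period
  tau <- emu$at_risk$time
  for (i in which(pr$period > 0)) {
    j <- pr$period[i]
    expect_true(pr$time[i] >= tau[j] && pr$time[i] < tau[j + 1L])
  }
})
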
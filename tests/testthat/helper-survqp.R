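# Shared fixtures, all generated in code.

# The worked 4-subject example: events at 1, 2, 3 (one each), one censoring
# at 1.5; digitized survival (0.75, 0.375, 0); at-risk 4 at t=0, 1 at t=2.5.
tiny_instance <- function() {
  list(curve = digitized_curve(c(1, 2, 3), c(0.75, 0.375, 0)),
       at_risk = at_risk_table(c(0, 2.5), c(4, 1)),
       ticks = 1.5, n = 4)
}

# Small Weibull dataset in the evaluation study's parametrization.
sim_small <- function(n, shape = 0.8, rate = 0.2, cens = c(2, 8),
                      resolution = 0.05) {
  ev <- (-log(runif(n)))^(1 / shape) / rate
  cn <- runif(n, cens[1], cens[2])
  data.frame(time = coarsen(pmin(ev, cn), resolution),
             status = as.integer(ev <= cn))
}

# Full-information emulation: exact curve values, every censoring a tick,
# at-risk reported at every distinct observed time, total events known.
exact_emulation <- function(truth) {
  km <- kaplan_meier(truth)
  tt <- sort(unique(truth$time))
  list(curve = digitized_curve(km$time, km$estimate),
       at_risk = at_risk_table(c(0, tt), c(
         nrow(truth), vapply(tt, function(tau) sum(truth$time >= tau), 0))),
       ticks = sort(unique(truth$time[truth$status == 0])),
       n = nrow(truth), total_events = sum(truth$status > 0))
}

# Aggregate pseudo-IPD rows back into per-time event/censoring counts.
ipd_counts <- function(ipd, m = 1) {
  tt <- sort(unique(ipd$time))
  d <- sapply(seq_len(m), function(k)
    vapply(tt, function(t) sum(ipd$time == t & ipd$status == k), 0))
  data.frame(time = tt, d = d,
             c = vapply(tt, function(t) sum(ipd$time == t & ipd$status == 0), 0))
}

expect_same_counts <- function(recon, truth, m = 1) {
  a <- ipd_counts(as.data.frame(recon), m)
  b <- ipd_counts(truth, m)
  expect_equal(a, b, ignore_attr = TRUE)
}

# One random tiny identified instance for the oracle-equivalence property:
# total events always supplied; ticks and a mid-study at-risk row optional.
random_tiny_instance <- function() {
  repeat {
    n <- sample(4:8, 1)
    ev <- round(rexp(n, 0.5), 1) + 0.1
    cn <- round(runif(n, 0.2, 3), 1)
    truth <- data.frame(time = pmin(ev, cn), status = as.integer(ev <= cn))
    if (sum(truth$status) == 0) next
    km <- kaplan_meier(truth)
    dec <- sample(c(2, 3, Inf), 1)
    vals <- if (is.finite(dec)) cummin(round(km$estimate, dec)) else km$estimate
    if (any(vals <= 0)) next
    crv <- digitized_curve(km$time, vals)
    tt <- sort(unique(truth$time))
    ar <- if (runif(1) < 0.5)
      at_risk_table(c(0, stats::median(tt)),
                    c(n, sum(truth$time >= stats::median(tt))))
    ticks <- if (runif(1) < 0.7) sort(unique(truth$time[truth$status == 0]))
    rec <- tryCatch(
      reconstruct_km(crv, at_risk = ar, ticks = ticks, n = n,
                     total_events = sum(truth$status)),
      error = function(e) NULL)
    if (is.null(rec)) next
    qp <- attr(rec, "qp")
    if (nrow(qp$layout) > 12) next
    orc <- tryCatch(exhaustive_oracle(qp), error = function(e) NULL)
    if (is.null(orc) || !isTRUE(orc$feasible)) next
    cnt <- attr(rec, "counts")
    xh <- tryCatch(counts_to_x(qp, as.matrix(cnt$d), cnt$c),
                   error = function(e) NULL)
    if (is.null(xh)) next
    return(list(qp = qp, heuristic = qp_objective(qp, xh),
                oracle = orc$objective))
  }
}
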
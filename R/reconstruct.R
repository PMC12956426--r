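#' Reconstruct pseudo-IPD from a digitized Kaplan-Meier curve
#'
#' Full pipeline: [prepare_problem()] merges the curve, at-risk and tick
#' inputs onto one candidate grid; [build_km_qp()] assembles the quadratic
#' program; the continuous solution is integerized by cumulative midpoint
#' rounding ([round_events()], [round_censorings()]); the integer counts are
#' expanded into one row per subject.
#'
#' @param curve a [digitized_curve()] in `"km"` or `"nelson-aalen"` mode.
#' @param at_risk optional [at_risk_table()].
#' @param ticks optional numeric vector of marked censoring times.
#' @param n total sample size (taken from `at_risk` when omitted).
#' @param total_events optional total number of events `NE`.
#' @param options see [recon_options()].
#' @return a `data.frame` of class `survqp_ipd` with columns `time` and
#'   `status` (0 = censored, 1 = event), one row per subject.  Attributes:
#'   `counts` (per-grid-time integer events/censorings), `W` (attained
#'   curve-fit criterion of the continuous solution), `objective`,
#'   `relaxations` (constraint relaxations applied, if any), `tail_censored`
#'   (subjects never observed to leave, censored at the last grid time) and
#'   `problem`.
#' @examples
#' crv <- digitized_curve(c(1, 2, 3), c(0.75, 0.375, 0))
#' ar  <- at_risk_table(c(0, 2.5), c(4, 1))
#' reconstruct_km(crv, at_risk = ar, ticks = 1.5)
#' @export
reconstruct_km <- function(curve, at_risk = NULL, ticks = NULL, n = NULL,
                           total_events = NULL, options = recon_options()) {
  problem <- prepare_problem(curve, at_risk = at_risk, ticks = ticks, n = n,
                             total_events = total_events)
  reconstruct_problem(problem, options)
}

#' Reconstruct competing-risks pseudo-IPD from digitized cumulative
#' incidence curves
#'
#' @param curves a `"cif"`-mode [digitized_curve()] (one column per cause),
#'   or a named list of per-cause two-column tables / single-cause curves to
#'   be merged onto a common grid with values carried forward.
#' @param total_events either a single pooled event total or a per-cause
#'   vector `NE_j` (named or in cause order).
#' @inheritParams reconstruct_km
#' @return a `survqp_ipd` data frame with `status` in `0:m` (0 = censored,
#'   `k` = event of cause `k`), with the same attributes as
#'   [reconstruct_km()].
#' @export
reconstruct_cif <- function(curves, at_risk = NULL, ticks = NULL, n = NULL,
                            total_events = NULL, options = recon_options()) {
  if (inherits(curves, "survqp_curve")) {
    curve <- curves
    if (curve$mode != "cif")
      curve <- digitized_curve(curve$time, 1 - curve$value, mode = "cif")
  } else {
    stopifnot(is.list(curves), length(curves) >= 1L)
    tabs <- lapply(curves, function(x) {
      if (inherits(x, "survqp_curve")) data.frame(time = x$time, value = x$value[, 1L])
      else as.data.frame(x)[1:2]
    })
    labels <- if (!is.null(names(curves))) names(curves)
              else as.character(seq_along(curves))
    curve <- merge_cif_curves(tabs, labels)
  }
  if (!is.null(total_events) && !is.null(names(total_events)) &&
      length(total_events) > 1L)
    total_events <- total_events[colnames(curve$value)]
  problem <- prepare_problem(curve, at_risk = at_risk, ticks = ticks, n = n,
                             total_events = total_events)
  reconstruct_problem(problem, options)
}

# Shared back half of the reconstruction pipeline.
reconstruct_problem <- function(problem, options = recon_options()) {
  fit <- solve_with_relaxation(problem, options)
  sol <- fit$solution
  d_hat <- round_events(sol$d)
  rc <- round_censorings(sol$c, d_hat, problem$period, problem$leaving,
                         d_tilde = sol$d)
  out <- counts_to_ipd(problem, rc$d_hat, rc$c_hat,
                       W = sol$W, objective = sol$objective,
                       relaxations = c(fit$relaxations, rc$notes),
                       continuous = sol, options = options)
  attr(out, "qp") <- fit$qp
  out
}

counts_to_ipd <- function(problem, d_hat, c_hat, W = NA_real_,
                          objective = NA_real_, relaxations = character(),
                          continuous = NULL, options = recon_options()) {
  d_hat <- as.matrix(d_hat)
  n_grid <- length(problem$time)
  midpoint <- options$midpoint_censoring
  if (is.null(midpoint)) midpoint <- !problem$ticks_available

  cens_time <- problem$time
  if (midpoint && n_grid > 1L) {
    nxt <- c(problem$time[-1L], problem$time[n_grid])
    cens_time <- (problem$time + nxt) / 2
    cens_time[n_grid] <- problem$time[n_grid]
  }

  rows_t <- numeric(0); rows_s <- integer(0)
  for (j in seq_len(ncol(d_hat))) {
    ev <- d_hat[, j] > 0
    rows_t <- c(rows_t, rep(problem$time[ev], d_hat[ev, j]))
    rows_s <- c(rows_s, rep(j, sum(d_hat[, j])))
  }
  cz <- c_hat > 0
  rows_t <- c(rows_t, rep(cens_time[cz], c_hat[cz]))
  rows_s <- c(rows_s, rep(0L, sum(c_hat)))

  leftover <- problem$n - length(rows_t)
  if (leftover < 0) stop("internal error: reconstructed counts exceed N")
  if (leftover > 0) {
    rows_t <- c(rows_t, rep(problem$time[n_grid], leftover))
    rows_s <- c(rows_s, rep(0L, leftover))
  }
  ord <- order(rows_t, rows_s)
  ipd <- data.frame(time = rows_t[ord], status = rows_s[ord])
  structure(ipd,
            counts = data.frame(time = problem$time, d = d_hat, c = c_hat),
            W = W, objective = objective, relaxations = relaxations,
            tail_censored = leftover, problem = problem,
            continuous = continuous,
            class = c("survqp_ipd", "data.frame"))
}

#' @export
as.data.frame.survqp_ipd <- function(x, ...) {
  data.frame(time = x$time, status = x$status)
}

#' @export
print.survqp_ipd <- function(x, ...) {
  m <- max(x$status)
  cat(sprintf("Pseudo-IPD: %d subjects, %d event(s)%s, %d censored\n",
              nrow(x), sum(x$status > 0),
              if (m > 1) sprintf(" over %d causes", m) else "",
              sum(x$status == 0)))
  if (!is.na(attr(x, "W")))
    cat(sprintf("  continuous objective W = %.6g", attr(x, "W")))
  if (length(attr(x, "relaxations")))
    cat(";", length(attr(x, "relaxations")), "relaxation(s) applied")
  cat("\n")
  invisible(x)
}
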
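#' Reconstruction options
#'
#' @param epsilon ridge weight on the censoring variables,
#'   \eqn{\epsilon \sum_i c_i^2}, added to keep the objective matrix positive
#'   definite and to prefer evenly spread censorings among otherwise
#'   indistinguishable allocations.  0.001 is a robust default; the
#'   integerized solution is insensitive to it over several orders of
#'   magnitude.
#' @param ridge small uniform diagonal added to the whole objective matrix
#'   for numerical positive-definiteness (the event block can be singular,
#'   e.g. trailing grid times with zero decrement).
#' @param force_tick_censoring when tick marks are supplied, additionally
#'   require at least one censoring at every tick that does not coincide
#'   with a decrement (`c >= 1` on the set `C*`).  Dropped automatically if
#'   it makes the program infeasible.
#' @param midpoint_censoring place reconstructed censorings at the midpoint
#'   of the interval to the next grid time, as appropriate when the true
#'   censoring times are unknown.  Default (`NULL`): enabled exactly when no
#'   tick marks are supplied.
#' @return a list of options for [reconstruct_km()] / [reconstruct_cif()].
#' @export
recon_options <- function(epsilon = 0.001, ridge = 1e-8,
                          force_tick_censoring = TRUE,
                          midpoint_censoring = NULL) {
  stopifnot(epsilon >= 0, ridge >= 0)
  list(epsilon = epsilon, ridge = ridge,
       force_tick_censoring = force_tick_censoring,
       midpoint_censoring = midpoint_censoring)
}

# Internal QP builder shared by the KM and CIF paths.  `state` carries the
# infeasibility-relaxation bookkeeping:
#   $drop_tick_min  - drop the optional c >= 1 tick constraints
#   $relax_d        - linear indices (into the o matrix) with d >= 1 relaxed to 0
#   $extra_c        - grid indices where an eliminated censoring slot is
#                     reactivated (trusted-tick mode only)
build_qp <- function(problem, options = recon_options(),
                     state = list(drop_tick_min = FALSE,
                                  relax_d = integer(), extra_c = integer())) {
  n <- length(problem$time); m <- problem$m
  o <- problem$o; N <- problem$n

  # event slots: any retained curve point (a zero decrement may hide a
  # rounded-away step) except ticks without a decrement (the set C*)
  d_active <- (o > 0) | (problem$d_slot & !problem$tick_zero)   # n x m
  if (problem$ticks_available) {
    c_active <- problem$is_tick
    c_active[state$extra_c] <- TRUE
  } else {
    c_active <- rep(TRUE, n)
  }

  layout <- rbind(
    if (any(d_active))
      data.frame(type = "d", i = row(o)[d_active], j = col(o)[d_active]),
    if (any(c_active))
      data.frame(type = "c", i = which(c_active), j = NA_integer_)
  )
  layout <- layout[order(layout$type, layout$j, layout$i), ]
  rownames(layout) <- NULL
  p <- nrow(layout)
  if (p == 0L) stop("no free variables: curve is flat and all slots eliminated")

  # residual rows: one per (i, j) with o_ij > 0;
  # r_ij = o_ij * N - o_ij * sum_{k<i} (sum_l d_kl + c_k) - d_ij
  ridx <- which(d_active, arr.ind = TRUE)
  nr <- nrow(ridx)
  M <- matrix(0, nr, p)
  a <- numeric(nr)
  var_i <- layout$i; var_j <- layout$j; var_d <- layout$type == "d"
  for (r in seq_len(nr)) {
    i <- ridx[r, 1L]; j <- ridx[r, 2L]
    oij <- o[i, j]
    a[r] <- oij * N
    before <- var_i < i
    M[r, before] <- oij
    M[r, var_d & var_i == i & var_j == j] <- M[r, var_d & var_i == i & var_j == j] + 1
  }

  Q <- 2 * crossprod(M)
  diag(Q)[!var_d] <- diag(Q)[!var_d] + 2 * options$epsilon
  diag(Q) <- diag(Q) + options$ridge
  q <- -2 * drop(crossprod(M, a))

  # bounds: d >= 1 only where the curve actually shows a decrement
  lb <- rep(0, p)
  lb[var_d] <- as.numeric(o[cbind(var_i[var_d], var_j[var_d])] > 0)
  if (length(state$relax_d)) {
    relaxed <- var_d & ((var_j - 1L) * n + var_i) %in% state$relax_d
    lb[relaxed] <- 0
  }
  if (problem$ticks_available && options$force_tick_censoring &&
      !state$drop_tick_min) {
    lb[!var_d & var_i %in% which(problem$tick_zero)] <- 1
  }
  ub <- rep(N, p)

  # equality constraints: at-risk periods, then totals
  Aeq <- NULL; beq <- numeric(); eq_label <- character()
  for (jj in seq_along(problem$leaving)) {
    members <- layout$i %in% which(problem$period == jj)
    if (!any(members) && problem$leaving[jj] == 0) next
    Aeq <- rbind(Aeq, as.numeric(members))
    beq <- c(beq, problem$leaving[jj])
    eq_label <- c(eq_label, sprintf("period_%d", jj))
  }
  if (problem$totals_available) {
    ne <- problem$total_events
    if (problem$mode == "cif" && length(ne) > 1L) {
      for (jj in seq_len(m)) {
        Aeq <- rbind(Aeq, as.numeric(var_d & var_j == jj))
        beq <- c(beq, ne[jj])
        eq_label <- c(eq_label, sprintf("events_cause_%d", jj))
      }
    } else {
      Aeq <- rbind(Aeq, as.numeric(var_d))
      beq <- c(beq, sum(ne))
      eq_label <- c(eq_label, "events_total")
    }
  }

  # structured pre-solve feasibility screen on the equality rows
  infeasible <- character()
  if (!is.null(Aeq)) {
    for (r in seq_len(nrow(Aeq))) {
      sel <- Aeq[r, ] > 0
      if (sum(lb[sel]) > beq[r] + 1e-9)
        infeasible <- c(infeasible, sprintf(
          "%s: lower bounds demand %g > %g", eq_label[r], sum(lb[sel]), beq[r]))
      if (sum(ub[sel]) < beq[r] - 1e-9)
        infeasible <- c(infeasible, sprintf(
          "%s: capacity %g < %g", eq_label[r], sum(ub[sel]), beq[r]))
    }
  }
  if (sum(beq[grepl("^period", eq_label)]) > N)
    infeasible <- c(infeasible, "period leaving counts exceed N")

  # global patient-count cap sum(d + c) <= N, restricted to the variables not
  # already pinned by a period equality (the tail), so the cap is never
  # linearly dependent on the equality rows
  in_tail <- layout$i %in% which(problem$period == 0L)
  cap_budget <- N - sum(problem$leaving)
  if (any(in_tail) && sum(lb[in_tail]) > cap_budget + 1e-9)
    infeasible <- c(infeasible, sprintf(
      "tail: lower bounds demand %g > remaining capacity %g",
      sum(lb[in_tail]), cap_budget))

  structure(list(
    layout = layout, Q = Q, q = q, M = M, a = a,
    Aeq = Aeq, beq = beq, eq_label = eq_label,
    lb = lb, ub = ub, N = N,
    cap_vars = in_tail, cap_budget = cap_budget,
    epsilon = options$epsilon, problem = problem, state = state,
    infeasible = infeasible
  ), class = "survqp_qp")
}

#' Assemble the Kaplan-Meier reconstruction quadratic program
#'
#' Expands the objective
#' \eqn{W = \sum_i (o_i (N - \sum_{j<i}(d_j + c_j)) - d_i)^2 + \epsilon \sum_i c_i^2}
#' into symmetric-matrix form \eqn{\frac12 x'Qx + q'x} over the stacked
#' event/censoring variables, with per-period at-risk equalities
#' \eqn{\sum_{i \in C_j} (d_i + c_i) = R_{j-1} - R_j}, an optional
#' total-events equality, bounds \eqn{d_i \ge 1} at decrement points and
#' \eqn{0 \le c_i \le N}, and trusted-tick variable elimination.
#'
#' @param problem a [prepare_problem()] result in `"km"` or `"nelson-aalen"`
#'   mode.
#' @param options see [recon_options()].
#' @return an object of class `survqp_qp` (objective, constraint system and
#'   variable layout); field `infeasible` carries a structured report when
#'   the equality rows are detectably inconsistent with the bounds.
#' @export
build_km_qp <- function(problem, options = recon_options()) {
  stopifnot(problem$mode %in% c("km", "nelson-aalen"))
  build_qp(problem, options)
}

#' Assemble the competing-risks reconstruction quadratic program
#'
#' The multi-cause analogue of [build_km_qp()]: residuals
#' \eqn{r_{ij} = o_{ij}(N - \sum_{k<i}(\sum_l d_{kl} + c_k)) - d_{ij}} over
#' per-cause event blocks plus one censoring block, with either per-cause or
#' pooled total-event equalities.  With a single cause the program is
#' identical to [build_km_qp()] on `s = 1 - f`.
#'
#' @inheritParams build_km_qp
#' @return an object of class `survqp_qp`.
#' @export
build_cif_qp <- function(problem, options = recon_options()) {
  stopifnot(problem$mode == "cif")
  build_qp(problem, options)
}

#' Evaluate the quadratic objective of a reconstruction program
#'
#' @param qp a `survqp_qp`.
#' @param x variable vector in the program's layout order.
#' @param regularized include the \eqn{\epsilon \sum c^2} term (`TRUE`) or
#'   return the pure curve-fit criterion `W` (`FALSE`).
#' @return scalar objective value.
#' @export
qp_objective <- function(qp, x, regularized = TRUE) {
  W <- sum((qp$a - drop(qp$M %*% x))^2)
  if (regularized) W + qp$epsilon * sum(x[qp$layout$type == "c"]^2) else W
}

#' Map per-grid-time counts into a program's variable layout
#'
#' @param qp a `survqp_qp`.
#' @param d_hat event counts (matrix, one column per cause).
#' @param c_hat censoring counts per grid time.
#' @return numeric vector `x` in the program's layout order (counts at
#'   eliminated slots must be zero).
#' @export
counts_to_x <- function(qp, d_hat, c_hat) {
  d_hat <- as.matrix(d_hat)
  isd <- qp$layout$type == "d"
  x <- numeric(nrow(qp$layout))
  x[isd] <- d_hat[cbind(qp$layout$i[isd], qp$layout$j[isd])]
  x[!isd] <- c_hat[qp$layout$i[!isd]]
  placed <- sum(x)
  if (abs(placed - (sum(d_hat) + sum(c_hat))) > 1e-9)
    stop("counts at eliminated variable slots cannot be represented")
  x
}

#' @export
print.survqp_qp <- function(x, ...) {
  cat(sprintf("Quadratic program: %d variables (%d event, %d censoring), %d equalities\n",
              nrow(x$layout), sum(x$layout$type == "d"),
              sum(x$layout$type == "c"), length(x$beq)))
  if (length(x$infeasible))
    cat("  INFEASIBLE:", paste(x$infeasible, collapse = "; "), "\n")
  invisible(x)
}
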
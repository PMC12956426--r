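#' Solve the continuous reconstruction program
#'
#' Solves the (regularized, hence strictly convex) quadratic program with the
#' Goldfarb-Idnani dual active-set method (`quadprog::solve.QP`).  Equality
#' rows come first; bound constraints and the global
#' \eqn{\sum (d + c) \le N} inequality follow.
#'
#' @param qp a [build_km_qp()] / [build_cif_qp()] result.
#' @return list with `x` (solution vector in layout order), `d` (matrix of
#'   continuous event counts per grid time and cause), `c` (continuous
#'   censoring counts per grid time), `W` (attained curve-fit criterion,
#'   without the \eqn{\epsilon} term) and `objective` (with it).
#' @export
solve_continuous <- function(qp) {
  if (length(qp$infeasible))
    stop("infeasible constraint system: ",
         paste(qp$infeasible, collapse = "; "), call. = FALSE)
  p <- nrow(qp$layout)

  # presolve: equality rows that pin a single remaining variable fix it and
  # are eliminated (common when at-risk tables report at every observed
  # time); the reduced system is what the dual active-set method sees, and
  # removing the pinned variables avoids degenerate, exactly-tight bound
  # constraints that the solver would otherwise reject
  fixed <- rep(NA_real_, p)
  Aeq <- if (is.null(qp$Aeq)) matrix(0, 0, p) else qp$Aeq
  beq <- qp$beq
  keep_row <- rep(TRUE, length(beq))
  repeat {
    changed <- FALSE
    for (r in which(keep_row)) {
      inrow <- which(Aeq[r, ] != 0)
      free <- inrow[is.na(fixed[inrow])]
      b_eff <- beq[r] - sum(Aeq[r, inrow] * ifelse(is.na(fixed[inrow]), 0,
                                                   fixed[inrow]))
      if (length(free) == 0L) {
        if (abs(b_eff) > 1e-9)
          stop("infeasible: equality row ", qp$eq_label[r],
               " unsatisfiable after presolve", call. = FALSE)
        keep_row[r] <- FALSE; changed <- TRUE
      } else if (length(free) == 1L) {
        val <- b_eff / Aeq[r, free]
        if (val < qp$lb[free] - 1e-9 || val > qp$ub[free] + 1e-9)
          stop("infeasible: ", qp$eq_label[r], " pins a variable at ", val,
               " outside its bounds", call. = FALSE)
        fixed[free] <- val
        keep_row[r] <- FALSE; changed <- TRUE
      }
    }
    if (!changed) break
  }

  free <- which(is.na(fixed))
  xf <- ifelse(is.na(fixed), 0, fixed)
  if (length(free) == 0L) {
    x <- pmax(xf, 0)
    return(finish_solution(qp, x))
  }
  Qr <- qp$Q[free, free, drop = FALSE]
  qr <- qp$q[free] + drop(qp$Q[free, -free, drop = FALSE] %*% xf[-free])
  if (length(free) == p) qr <- qp$q
  Aeq_r <- Aeq[keep_row, free, drop = FALSE]
  beq_r <- beq[keep_row] -
    drop(Aeq[keep_row, , drop = FALSE] %*% xf)
  neq <- nrow(Aeq_r)
  pr <- length(free)
  Amat <- cbind(
    if (neq) t(Aeq_r),
    diag(pr),                     # x >= lb
    -diag(pr)                     # -x >= -ub
  )
  bvec <- c(beq_r, qp$lb[free], -qp$ub[free])
  if (any(qp$cap_vars)) {         # -sum(x_tail) >= -(N - sum leaving)
    budget <- qp$cap_budget - sum(xf * qp$cap_vars)
    Amat <- cbind(Amat, -as.numeric(qp$cap_vars[free]))
    bvec <- c(bvec, -budget)
  }
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = Qr, dvec = -qr, Amat = Amat, bvec = bvec,
                       meq = neq),
    error = function(e) stop("continuous QP failed: ", conditionMessage(e),
                             call. = FALSE))
  x <- xf
  x[free] <- sol$solution
  x <- pmax(x, 0)
  finish_solution(qp, x)
}

finish_solution <- function(qp, x) {
  n <- length(qp$problem$time); m <- qp$problem$m
  dmat <- matrix(0, n, m)
  cvec <- numeric(n)
  isd <- qp$layout$type == "d"
  dmat[cbind(qp$layout$i[isd], qp$layout$j[isd])] <- x[isd]
  cvec[qp$layout$i[!isd]] <- x[!isd]
  # constraint residual check (solver tolerance)
  if (length(qp$beq)) {
    resid <- drop(qp$Aeq %*% x) - qp$beq
    if (any(abs(resid) > 1e-6))
      warning("equality constraint residual ", max(abs(resid)), " exceeds tolerance")
  }
  list(x = x, d = dmat, c = cvec,
       W = qp_objective(qp, x, regularized = FALSE),
       objective = qp_objective(qp, x, regularized = TRUE))
}

# Solve with the infeasibility-relaxation ladder:
#   1. as specified;
#   2. drop the optional c >= 1 tick constraints;
#   3. reactivate censoring slots at non-tick grid points inside periods whose
#      equality row lacks capacity (trusted-tick mode only);
#   4. relax d >= 1 to d >= 0 one variable at a time, smallest o first.
# Each step is logged; a hard error is raised only if the equality rows
# conflict among themselves.
solve_with_relaxation <- function(problem, options) {
  state <- list(drop_tick_min = FALSE, relax_d = integer(), extra_c = integer())
  log <- character()
  o_lin <- problem$o
  relax_order <- order(o_lin[o_lin > 0])          # among active d, smallest o first
  active_lin <- which(o_lin > 0)
  repeat {
    qp <- build_qp(problem, options, state)
    if (!length(qp$infeasible)) {
      res <- tryCatch(solve_continuous(qp), error = function(e) e)
      if (!inherits(res, "error"))
        return(list(qp = qp, solution = res, relaxations = log))
      msg <- conditionMessage(res)
    } else msg <- paste(qp$infeasible, collapse = "; ")

    if (!state$drop_tick_min && problem$ticks_available &&
        options$force_tick_censoring && any(problem$tick_zero)) {
      state$drop_tick_min <- TRUE
      log <- c(log, "dropped optional c>=1 tick constraints")
      next
    }
    if (problem$ticks_available) {
      # reactivate censoring slots in under-capacity periods
      bad <- grep("^period_.*capacity", qp$infeasible, value = TRUE)
      bad_periods <- as.integer(sub("^period_(\\d+):.*", "\\1", bad))
      bad_periods <- bad_periods[!is.na(bad_periods)]
      cand <- which(problem$period %in% bad_periods & !problem$is_tick)
      cand <- setdiff(cand, state$extra_c)
      if (length(cand)) {
        state$extra_c <- c(state$extra_c, cand)
        log <- c(log, sprintf("reactivated %d censoring slot(s) in period(s) %s",
                              length(cand), paste(unique(bad_periods), collapse = ",")))
        next
      }
    }
    remaining <- setdiff(active_lin[relax_order], state$relax_d)
    if (length(remaining)) {
      state$relax_d <- c(state$relax_d, remaining[1L])
      log <- c(log, sprintf("relaxed d>=1 at grid index %d",
                            ((remaining[1L] - 1L) %% nrow(o_lin)) + 1L))
      next
    }
    if (problem$ticks_available && length(state$extra_c) < sum(!problem$is_tick)) {
      state$extra_c <- which(!problem$is_tick)
      log <- c(log, "reactivated all censoring slots")
      next
    }
    stop("reconstruction infeasible after all relaxations: ", msg, call. = FALSE)
  }
}
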
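#' Integerize continuous event counts by cumulative midpoint rounding
#'
#' \eqn{\hat d_i = \lfloor 0.5 + \sum_{j \le i} \tilde d_j \rfloor -
#' \lfloor 0.5 + \sum_{j < i} \tilde d_j \rfloor}: rounding the cumulative
#' sum (half up, deterministically) distributes the fractional event mass
#' while preserving the rounded total.  Prepending zeros does not change
#' subsequent outputs.
#'
#' @param d_tilde non-negative continuous event counts, in time order (a
#'   matrix is rounded column-wise, one column per cause).
#' @return integer counts of the same shape.
#' @export
round_events <- function(d_tilde) {
  if (is.matrix(d_tilde)) return(apply(d_tilde, 2L, round_events))
  as.integer(diff(c(0L, floor(0.5 + cumsum(d_tilde)))))
}

#' Integerize censoring counts with per-period rescaling
#'
#' Scales the continuous censoring counts within each at-risk period `j` by
#' \eqn{V_j = (R_{j-1} - R_j) / (\sum_{i \in C_j} \hat d_i + \tilde c_i)}
#' so that after cumulative midpoint rounding every period equality holds
#' exactly (period-boundary cumulative sums are integers, so the floors
#' telescope period by period).  Times outside any period (the tail) are
#' rounded unscaled.
#'
#' @param c_tilde continuous censoring counts per grid time.
#' @param d_hat integerized event counts (matrix, one column per cause).
#' @param period period index per grid time (0 = unconstrained tail).
#' @param leaving leaving count `R_{j-1} - R_j` per period.
#' @param d_tilde continuous event counts, used only to pick which cell to
#'   repair when rounding makes a period's events exceed (or, with no
#'   censoring slots, undershoot) its leaving count.
#' @return list with `c_hat` (integer censorings), possibly repaired `d_hat`,
#'   and a character vector `notes` describing any repairs.
#' @export
round_censorings <- function(c_tilde, d_hat, period, leaving,
                             d_tilde = d_hat) {
  d_hat <- as.matrix(d_hat); d_tilde <- as.matrix(d_tilde)
  n <- length(c_tilde)
  notes <- character()
  u <- c_tilde                                 # scaled continuous censorings
  for (j in seq_along(leaving)) {
    idx <- which(period == j)
    if (!length(idx)) next
    Dj <- sum(d_hat[idx, ])
    Lj <- leaving[j]
    while (Dj > Lj) {                          # rounding overshoot: repair d
      sub_hat <- d_hat[idx, , drop = FALSE]
      excess <- sub_hat - d_tilde[idx, , drop = FALSE]
      excess[sub_hat <= 0] <- -Inf             # only cells with events to give up
      cell <- arrayInd(which.max(excess), dim(excess))
      d_hat[idx[cell[1L]], cell[2L]] <- d_hat[idx[cell[1L]], cell[2L]] - 1L
      notes <- c(notes, sprintf("period %d: decremented rounded-up event at grid index %d",
                                j, idx[cell[1L]]))
      Dj <- Dj - 1L
    }
    resid <- Lj - Dj
    cs <- sum(c_tilde[idx])
    if (cs > 0) {
      u[idx] <- c_tilde[idx] * resid / cs
    } else if (resid > 0) {
      # no continuous censoring mass in the period: spread the residual
      u[idx] <- resid / length(idx)
      notes <- c(notes, sprintf("period %d: distributed %d censoring(s) uniformly",
                                j, resid))
    }
  }
  c_hat <- as.integer(diff(c(0L, floor(0.5 + cumsum(u)))))
  # the telescoping argument guarantees the equalities; assert it
  for (j in seq_along(leaving)) {
    idx <- which(period == j)
    if (length(idx) && sum(d_hat[idx, ]) + sum(c_hat[idx]) != leaving[j])
      stop("internal error: period equality violated after integerization")
  }
  list(c_hat = c_hat, d_hat = d_hat, notes = notes)
}

#' Exhaustive integer oracle for small reconstruction programs
#'
#' Enumerates every integer-feasible point of the program (respecting the
#' equality rows, bounds and the global `sum(x) <= N` cap) and returns the
#' global integer optimum.  This is a test oracle standing in for a
#' mixed-integer QP solver; it refuses problems with more than `max_vars`
#' free variables.
#'
#' @param qp a `survqp_qp`.
#' @param max_vars enumeration limit.
#' @return list with `x` (optimal integer vector), `objective` (regularized),
#'   `W`, or `feasible = FALSE` when no integer point satisfies the
#'   constraints.
#' @export
exhaustive_oracle <- function(qp, max_vars = 12L) {
  p <- nrow(qp$layout)
  if (p > max_vars)
    stop("refusing exhaustive enumeration over ", p, " > ", max_vars, " variables")
  Aeq <- qp$Aeq; beq <- qp$beq
  lb <- as.integer(ceiling(qp$lb - 1e-9)); ub <- as.integer(floor(qp$ub + 1e-9))
  # tighten bounds from the equality rows
  if (!is.null(Aeq)) {
    for (r in seq_len(nrow(Aeq))) {
      sel <- which(Aeq[r, ] > 0)
      for (k in sel) {
        others <- setdiff(sel, k)
        ub[k] <- min(ub[k], beq[r] - sum(lb[others]))
        lb[k] <- max(lb[k], beq[r] - sum(ub[others]))
      }
    }
  }
  ub <- pmin(ub, qp$N)
  if (any(ub < lb)) return(list(feasible = FALSE))
  if (prod(ub - lb + 1) > 5e6)
    stop("enumeration space too large (", prod(ub - lb + 1), " points)")

  best <- NULL; best_obj <- Inf
  x <- integer(p)
  eqsum <- function(x, upto) if (is.null(Aeq)) numeric() else
    drop(Aeq[, seq_len(upto), drop = FALSE] %*% x[seq_len(upto)])
  recurse <- function(k) {
    if (k > p) {
      if (!is.null(Aeq) && any(abs(drop(Aeq %*% x) - beq) > 1e-9)) return()
      if (sum(x) > qp$N) return()
      obj <- qp_objective(qp, x)
      if (obj < best_obj - 1e-12) { best_obj <<- obj; best <<- x }
      return()
    }
    for (v in lb[k]:ub[k]) {
      x[k] <<- v
      # prune on equality rows that are already fully determined
      ok <- TRUE
      if (!is.null(Aeq)) {
        partial <- eqsum(x, k)
        rest_lb <- if (k < p) drop(Aeq[, (k + 1):p, drop = FALSE] %*% lb[(k + 1):p]) else 0
        rest_ub <- if (k < p) drop(Aeq[, (k + 1):p, drop = FALSE] %*% ub[(k + 1):p]) else 0
        ok <- all(partial + rest_lb <= beq + 1e-9) && all(partial + rest_ub >= beq - 1e-9)
      }
      if (ok && sum(x[seq_len(k)]) <= qp$N) recurse(k + 1L)
    }
    x[k] <<- lb[k]
  }
  recurse(1L)
  if (is.null(best)) return(list(feasible = FALSE))
  list(feasible = TRUE, x = best, objective = best_obj,
       W = qp_objective(qp, best, regularized = FALSE))
}
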
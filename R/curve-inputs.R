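#' Digitized survival or cumulative incidence curve
#'
#' Container for the coordinates extracted from a published plot, e.g. a
#' WebPlotDigitizer export.  In `"km"` mode `value` holds survival
#' probabilities \eqn{s_i}; in `"cif"` mode it holds one column of cumulative
#' incidence per competing cause \eqn{f_{ij}}; in `"nelson-aalen"` mode it
#' holds the cumulative hazard, whose increments play the role of the
#' decrements.
#'
#' @param time positive times, in study time units.
#' @param value numeric vector, or a matrix with one column per cause in
#'   `"cif"` mode.
#' @param mode `"km"`, `"cif"` or `"nelson-aalen"`.
#' @param causes optional cause labels (defaults to column names or `1:m`).
#' @return object of class `survqp_curve` with fields `time` (sorted),
#'   `value` (matrix, one column per cause; a single column outside `"cif"`
#'   mode) and `mode`.
#' @details Rows are sorted by time; exact duplicate rows are collapsed; when
#'   several rows share a time (a digitized step corner) the post-step value
#'   is kept (minimum in `"km"` mode, maximum otherwise).  Probabilities
#'   outside `[0, 1]` by at most 0.01 are clipped with a warning; values
#'   further outside are rejected.
#' @export
digitized_curve <- function(time, value, mode = c("km", "cif", "nelson-aalen"),
                            causes = NULL) {
  mode <- match.arg(mode)
  value <- as.matrix(value)
  time <- as.numeric(time)
  if (length(time) == 0L) stop("empty curve")
  if (nrow(value) != length(time))
    stop("'time' and 'value' lengths differ")
  if (anyNA(time) || anyNA(value)) stop("non-numeric or missing cells in curve")
  if (any(time < 0)) stop("negative times in curve")
  if (mode != "nelson-aalen") {
    if (any(value < -0.01) || any(value > 1.01))
      stop("curve values outside [-0.01, 1.01]; check the digitization")
    if (any(value < 0) || any(value > 1)) {
      warning("curve values slightly outside [0, 1] clipped")
      value <- pmin(pmax(value, 0), 1)
    }
  } else if (any(value < 0)) {
    stop("cumulative hazard values must be non-negative")
  }
  if (is.null(causes))
    causes <- if (!is.null(colnames(value))) colnames(value)
              else as.character(seq_len(ncol(value)))
  colnames(value) <- causes
  ord <- order(time)
  time <- time[ord]; value <- value[ord, , drop = FALSE]
  # collapse duplicate times, keeping the post-step value
  if (anyDuplicated(time)) {
    agg <- if (mode == "km") min else max
    keep <- !duplicated(time, fromLast = FALSE)
    for (tt in unique(time[duplicated(time)])) {
      rows <- which(time == tt)
      value[rows[1L], ] <- apply(value[rows, , drop = FALSE], 2L, agg)
    }
    first <- !duplicated(time)
    time <- time[first]; value <- value[first, , drop = FALSE]
  }
  if (mode != "cif" && ncol(value) != 1L)
    stop("a single value column is expected outside 'cif' mode")
  if (mode == "cif" && any(rowSums(value) > 1 + 1e-8))
    stop("cumulative incidences sum to more than 1")
  structure(list(time = time, value = value, mode = mode),
            class = "survqp_curve")
}

#' @export
print.survqp_curve <- function(x, ...) {
  cat(sprintf("Digitized %s curve: %d points, %d cause(s), time span [%g, %g]\n",
              x$mode, length(x$time), ncol(x$value), min(x$time), max(x$time)))
  invisible(x)
}

#' Read a digitized curve from a delimited text file
#'
#' Expects a header row and columns `time,value` (one file per cause in CIF
#' mode), decimal point `.`.
#'
#' @param path file path(s); several paths (or a named vector) give one cause
#'   per file in `"cif"` mode, with names used as cause labels.
#' @param mode see [digitized_curve()].
#' @param sep field separator.
#' @return a `survqp_curve`.
#' @export
read_curve <- function(path, mode = c("km", "cif", "nelson-aalen"), sep = ",") {
  mode <- match.arg(mode)
  read1 <- function(p) {
    tab <- utils::read.table(p, header = TRUE, sep = sep)
    if (ncol(tab) < 2L) stop("expected columns time,value in ", p)
    if (!is.numeric(tab[[1L]]) || !is.numeric(tab[[2L]]))
      stop("non-numeric cells in ", p)
    tab[1:2]
  }
  if (length(path) == 1L) {
    tab <- read1(path)
    return(digitized_curve(tab[[1L]], tab[[2L]], mode = mode))
  }
  if (mode != "cif") stop("multiple curve files are only meaningful in CIF mode")
  tabs <- lapply(path, read1)
  labels <- if (!is.null(names(path))) names(path) else as.character(seq_along(path))
  merge_cif_curves(tabs, labels)
}

# Merge per-cause (time, value) tables onto a common time grid, carrying each
# CIF forward between its own observation points.
merge_cif_curves <- function(tabs, labels) {
  grid <- sort(unique(unlist(lapply(tabs, function(x) x[[1L]]))))
  val <- sapply(tabs, function(x) {
    f <- step_function(x[[1L]], cummax(x[[2L]][order(x[[1L]])]), 0)
    eval_step(f, grid)
  })
  digitized_curve(grid, val, mode = "cif", causes = labels)
}

#' Repair monotonicity of a digitized curve
#'
#' Digitization error occasionally makes raw curves locally non-monotone.
#' Survival values are clipped from above by their running minimum
#' (`s_i := min(s_i, s_{i-1})`); cumulative incidence / cumulative hazard
#' columns are clipped from below by their running maximum.  Clipping keeps
#' the later point, which digitizers place more reliably at step corners.
#' Points left with a zero decrement (all causes) are dropped unless their
#' time appears in `keep` (tick or at-risk report times).
#'
#' @param curve a `survqp_curve`.
#' @param keep times that must survive the zero-decrement drop.
#' @param tol time-matching tolerance for `keep`.
#' @return a `survqp_curve`.
#' @export
enforce_monotone <- function(curve, keep = numeric(), tol = NULL) {
  if (is.null(tol)) tol <- 1e-9 * max(curve$time, 1)
  v <- curve$value
  if (curve$mode == "km") {
    v[, 1L] <- cummin(pmin(v[, 1L], 1))
  } else {
    for (j in seq_len(ncol(v))) v[, j] <- cummax(v[, j])
  }
  prev <- rbind(if (curve$mode == "km") 1 else 0, v[-nrow(v), , drop = FALSE])
  flat <- rowSums(abs(v - prev) > 0) == 0L
  protected <- vapply(curve$time, function(t) any(abs(keep - t) <= tol), logical(1L))
  drop <- flat & !protected
  drop[length(drop)] <- FALSE   # keep the end of follow-up as an anchor
  digitized_curve(curve$time[!drop], v[!drop, , drop = FALSE],
                  mode = curve$mode)
}

#' Relative decrements of a survival curve
#'
#' `o_i = 1 - s_i / s_{i-1}` with `s_0 = 1` implied.  Under a perfect
#' reconstruction `o_i r_i = d_i` where `r_i` is the number at risk.  For a
#' Nelson-Aalen input the increment of the cumulative hazard is used instead.
#'
#' @param values survival probabilities (non-increasing) or cumulative hazard
#'   (non-decreasing) when `mode = "nelson-aalen"`.
#' @param mode `"km"` or `"nelson-aalen"`.
#' @return vector of fractions `o`, one per input point.
#' @export
compute_decrements <- function(values, mode = c("km", "nelson-aalen")) {
  mode <- match.arg(mode)
  if (mode == "nelson-aalen") return(diff(c(0, values)))
  prev <- c(1, values[-length(values)])
  if (any(prev == 0 & values > 0)) stop("survival rises from zero: invalid curve")
  o <- ifelse(prev > 0, 1 - values / prev, NA_real_)
  if (anyNA(o)) {
    first0 <- which(prev == 0)[1L]
    stop("curve reaches zero before point ", first0,
         "; truncate the grid at the first zero")
  }
  o
}

#' Relative increments of cumulative incidence curves
#'
#' `o_ij = (f_ij - f_{i-1,j}) / (1 - sum_l f_{i-1,l})` with `f_0j = 0`
#' implied, so that `o_ij r_i = d_ij`.  With a single cause this equals
#' [compute_decrements()] applied to `s = 1 - f`.
#'
#' @param f matrix of cumulative incidences, one column per cause.
#' @return matrix of increments with the same shape; if some denominator is
#'   non-positive the grid is truncated there with a warning.
#' @export
compute_cif_increments <- function(f) {
  f <- as.matrix(f)
  prev <- rbind(0 * f[1L, ], f[-nrow(f), , drop = FALSE])
  denom <- 1 - rowSums(prev)
  if (any(denom <= 1e-12)) {
    cut <- which(denom <= 1e-12)[1L]
    warning("cumulative incidence exhausts the risk set at row ", cut,
            "; grid truncated")
    f <- f[seq_len(cut - 1L), , drop = FALSE]
    return(compute_cif_increments(f))
  }
  sweep(f - prev, 1L, denom, "/")
}

#' Numbers-at-risk table
#'
#' @param time report times, starting at 0.
#' @param n_risk non-increasing, non-negative integer counts; the count at
#'   time 0 is the sample size `N`.
#' @return object of class `survqp_atrisk`.
#' @export
at_risk_table <- function(time, n_risk) {
  time <- as.numeric(time); n_risk <- as.numeric(n_risk)
  if (length(time) != length(n_risk) || length(time) == 0L)
    stop("at-risk table needs matching time and n_risk columns")
  ord <- order(time)
  time <- time[ord]; n_risk <- n_risk[ord]
  if (is.unsorted(time, strictly = TRUE)) stop("duplicate at-risk report times")
  if (time[1L] != 0) stop("at-risk table must start at time 0 (R0 = N)")
  if (any(n_risk < 0) || any(abs(n_risk - round(n_risk)) > 1e-8))
    stop("at-risk counts must be non-negative integers")
  if (is.unsorted(rev(n_risk))) stop("at-risk counts must be non-increasing")
  structure(list(time = time, n_risk = as.integer(round(n_risk))),
            class = "survqp_atrisk")
}

#' Read an at-risk table (columns `time,n_risk`) from a delimited file
#' @param path file path.
#' @param sep field separator.
#' @return a `survqp_atrisk`.
#' @export
read_at_risk <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  at_risk_table(tab[[1L]], tab[[2L]])
}

#' Prepare a reconstruction problem
#'
#' Builds the candidate time grid (curve times, at-risk report times and tick
#' times merged within tolerance), recomputes decrements/increments on the
#' merged grid (values carried forward at inserted times, so inserted times
#' have zero decrement), assigns each grid time to a half-open at-risk period
#' `C_j = [tau_{j-1}, tau_j)` and classifies ticks.
#'
#' @param curve a [digitized_curve()].
#' @param at_risk optional [at_risk_table()].
#' @param ticks optional numeric vector of marked censoring times.
#' @param n total sample size; taken from `at_risk` when omitted.
#' @param total_events optional total event count `NE`; in CIF mode either a
#'   single pooled total or a named/per-cause vector `NE_j`.
#' @param keep_flat_curve_points retain digitized curve points whose
#'   decrement is zero after monotonicity repair as candidate event slots
#'   (with `d >= 0` rather than `d >= 1`).  Zero decrements typically arise
#'   when value rounding hides a small step, so these times are plausible
#'   event locations; keeping them matters when a total-events constraint
#'   forces more events than there are visible decrements.  Default `TRUE`
#'   when a total-events count is supplied, `FALSE` otherwise.
#' @param tol time-merging tolerance; defaults to `1e-9 * max(time)`.
#' @return object of class `survqp_problem`; see Details.
#' @details Fields: `time` (grid), `o` (increment matrix, one column per
#'   cause), `period` (0 for the unconstrained tail at or beyond the last
#'   report time), `leaving` (`R_{j-1} - R_j` per period), `is_tick`,
#'   `is_curve`, `tick_zero` (ticks at which no decrement occurs, the set
#'   `C*`), `n`, `total_events`, and availability flags.  Points beyond the
#'   last report time form an unconstrained tail; a global inequality
#'   `sum(d + c) <= N` is always added downstream.
#' @export
prepare_problem <- function(curve, at_risk = NULL, ticks = NULL, n = NULL,
                            total_events = NULL,
                            keep_flat_curve_points = !is.null(total_events),
                            tol = NULL) {
  stopifnot(inherits(curve, "survqp_curve"))
  if (!is.null(at_risk)) stopifnot(inherits(at_risk, "survqp_atrisk"))
  ticks <- sort(unique(as.numeric(ticks)))
  if (is.null(tol)) tol <- 1e-9 * max(curve$time, ticks, 1)

  if (is.null(n)) {
    if (is.null(at_risk)) stop("total sample size 'n' is required when no at-risk table is given")
    n <- at_risk$n_risk[1L]
  } else if (!is.null(at_risk) && at_risk$n_risk[1L] != n) {
    stop("'n' disagrees with the at-risk count at time 0")
  }

  keep <- c(ticks, at_risk$time)
  if (keep_flat_curve_points) keep <- c(keep, curve$time)
  curve <- enforce_monotone(curve, keep = keep, tol = tol)

  tau <- if (is.null(at_risk)) numeric() else at_risk$time[-1L]
  grid <- merge_within_tol(sort(c(curve$time, tau, ticks)), tol)

  m <- ncol(curve$value)
  # carry curve values forward onto the merged grid
  v0 <- if (curve$mode == "km") 1 else 0
  vals <- sapply(seq_len(m), function(j)
    eval_step(step_function(curve$time, curve$value[, j], v0), grid + tol))
  vals <- matrix(vals, nrow = length(grid), ncol = m)

  if (curve$mode == "km") {
    s <- vals[, 1L]
    if (any(s == 0)) {  # stop the grid at the first zero of the curve
      cut <- which(s == 0)[1L]
      grid <- grid[seq_len(cut)]
      vals <- vals[seq_len(cut), , drop = FALSE]
      s <- vals[, 1L]
    }
    o <- matrix(compute_decrements(s), ncol = 1L)
  } else if (curve$mode == "nelson-aalen") {
    o <- matrix(compute_decrements(vals[, 1L], mode = "nelson-aalen"), ncol = 1L)
  } else {
    o <- compute_cif_increments(vals)
    if (nrow(o) < length(grid)) {
      grid <- grid[seq_len(nrow(o))]
      vals <- vals[seq_len(nrow(o)), , drop = FALSE]
    }
  }
  o[o < 0] <- 0  # guard against residual float noise

  near <- function(x, set) vapply(x, function(t) any(abs(set - t) <= tol), logical(1L))
  is_tick <- near(grid, ticks)
  is_curve <- near(grid, curve$time)

  if (!is.null(at_risk)) {
    tau_full <- at_risk$time
    period <- findInterval(grid + tol, tau_full)
    period[period > length(tau_full) - 1L] <- 0L   # tail at/after last report
    leaving <- -diff(at_risk$n_risk)
    if (sum(leaving) > n) stop("at-risk table implies more than N subjects leaving")
  } else {
    period <- rep(0L, length(grid))
    leaving <- numeric()
  }

  min_events <- sum(o > 0)
  if (n < min_events)
    stop("sample size N is below the number of observed decrement points")
  if (!is.null(total_events)) {
    if (curve$mode == "cif" && length(total_events) > 1L) {
      if (length(total_events) != m)
        stop("per-cause total_events must have one entry per cause")
      if (any(colSums(o > 0) > total_events))
        stop("per-cause total events below the number of increment points")
    } else if (sum(total_events) < min_events) {
      stop("total events below the number of decrement points")
    }
  }

  structure(list(
    time = grid, o = o, m = m, causes = colnames(curve$value),
    mode = curve$mode, value = vals,
    is_tick = is_tick, is_curve = is_curve,
    tick_zero = is_tick & rowSums(o > 0) == 0L,
    d_slot = is_curve | rowSums(o > 0) > 0L,
    period = period, leaving = leaving, at_risk = at_risk,
    n = n, total_events = total_events,
    ticks_available = length(ticks) > 0L,
    at_risk_available = !is.null(at_risk),
    totals_available = !is.null(total_events),
    tol = tol
  ), class = "survqp_problem")
}

merge_within_tol <- function(x, tol) {
  if (length(x) < 2L) return(x)
  keep <- c(TRUE, diff(x) > tol)
  x[keep]
}

#' @export
print.survqp_problem <- function(x, ...) {
  cat(sprintf("Reconstruction problem: %d grid times, %d cause(s), N = %d\n",
              length(x$time), x$m, x$n))
  cat(sprintf("  ticks: %s, at-risk periods: %d, total events: %s\n",
              if (x$ticks_available) sum(x$is_tick) else "none",
              length(x$leaving),
              if (x$totals_available) paste(x$total_events, collapse = "+")
              else "unknown"))
  invisible(x)
}
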
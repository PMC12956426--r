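#' Right-continuous step function
#'
#' Light-weight representation of a right-continuous step function, used for
#' Kaplan-Meier curves, cumulative incidence functions and at-risk processes.
#'
#' @param time jump times (strictly increasing).
#' @param value value taken from each jump time onwards (right-continuous).
#' @param value0 value before the first jump.
#' @return an object of class `survqp_step` with fields `time`, `value`,
#'   `value0`.
#' @export
step_function <- function(time, value, value0) {
  stopifnot(length(time) == length(value), length(value0) == 1L)
  if (is.unsorted(time, strictly = TRUE))
    stop("step function jump times must be strictly increasing")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 value0 = as.numeric(value0)),
            class = "survqp_step")
}

#' Evaluate a step function
#'
#' @param f a [step_function()].
#' @param t numeric vector of evaluation points.
#' @return `f(t)`, right-continuous.
#' @export
eval_step <- function(f, t) {
  idx <- findInterval(t, f$time)
  c(f$value0, f$value)[idx + 1L]
}

#' @export
print.survqp_step <- function(x, ...) {
  cat("Step function with", length(x$time), "jumps on [",
      if (length(x$time)) min(x$time) else NA, ",",
      if (length(x$time)) max(x$time) else NA, "]\n")
  invisible(x)
}

#' Integrated absolute difference of two step functions
#'
#' Computes the exact integral of `|f(t) - g(t)|` over `[0, upper]` by
#' piecewise-constant integration over the union of the two breakpoint sets;
#' there is no quadrature error.
#'
#' @param f,g [step_function()] objects.
#' @param upper upper limit of integration.
#' @return non-negative scalar.
#' @export
integrate_abs_diff <- function(f, g, upper) {
  brk <- sort(unique(c(0, f$time, g$time, upper)))
  brk <- brk[brk <= upper]
  if (max(brk) < upper) brk <- c(brk, upper)
  left <- brk[-length(brk)]
  width <- diff(brk)
  sum(width * abs(eval_step(f, left) - eval_step(g, left)))
}

#' Integral of a step function (e.g. restricted mean survival time)
#' @param f a [step_function()].
#' @param upper upper limit of integration.
#' @return the exact integral of `f` over `[0, upper]`.
#' @export
integrate_step <- function(f, upper) {
  brk <- sort(unique(c(0, f$time, upper)))
  brk <- brk[brk <= upper]
  if (max(brk) < upper) brk <- c(brk, upper)
  left <- brk[-length(brk)]
  sum(diff(brk) * eval_step(f, left))
}

# At-risk process Y(t) = #{i : T_i > t} as a right-continuous step function
# starting from n at t = 0 (the integral is insensitive to the boundary
# convention at the jump points themselves).
atrisk_process <- function(time) {
  tt <- sort(unique(time))
  n <- length(time)
  left <- n - cumsum(tabulate(match(time, tt), nbins = length(tt)))
  step_function(tt, left, n)
}
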
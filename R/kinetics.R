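#' Time-activity curve constructors
#'
#' A fitted time-activity curve (TAC) is either biexponential,
#' `A(t) = a1 exp(-lambda1 t) + a2 exp(-lambda2 t)` (the low-uptake
#' compartment model; a mono-exponential is the special case `a2 = 0`), or
#' piecewise linear-exponential (the high-uptake compartment model: a
#' linear segment through the first two sample points, back-extrapolated to
#' t = 0 and clamped at zero, followed by an exponential tail fitted to the
#' later points).  Both forms are evaluable via [predict()] and analytically
#' integrable over `[0, Inf)` via [integrate_curve()].
#'
#' @param a1,a2 Amplitudes in MBq (non-negative).
#' @param lambda1,lambda2 Rate constants in 1/h with
#'   `lambda1 >= lambda2 > 0`.
#' @param times,activities Optional sample data retained for inspection.
#' @return An object of class `c("tac_biexp", "tac")`.
#' @export
tac_biexponential <- function(a1, lambda1, a2 = 0, lambda2 = lambda1,
                              times = NULL, activities = NULL) {
  if (a1 < 0 || a2 < 0) stop("amplitudes must be >= 0", call. = FALSE)
  if (lambda1 <= 0 || lambda2 <= 0)
    stop("rate constants must be > 0", call. = FALSE)
  if (lambda1 < lambda2) {  # enforce ordering convention
    tmp <- a1; a1 <- a2; a2 <- tmp
    tmp <- lambda1; lambda1 <- lambda2; lambda2 <- tmp
  }
  structure(
    list(form = "biexponential", a1 = a1, lambda1 = lambda1,
         a2 = a2, lambda2 = lambda2, mono = (a2 == 0 || lambda1 == lambda2),
         times = times, activities = activities),
    class = c("tac_biexp", "tac")
  )
}

#' @rdname tac_biexponential
#' @param t1,t2 Times (h) bounding the linear segment, `0 <= t1 < t2`.
#' @param a_t1 Activity at `t1` (MBq), the measured first point.
#' @param slope Slope of the linear segment in MBq/h.
#' @param tail_value Tail activity at `t2` (MBq), the anchor of the
#'   exponential tail.
#' @param lambda_tail Tail rate constant in 1/h (> 0).
#' @return For `tac_piecewise()`, an object of class
#'   `c("tac_piecewise", "tac")`.
#' @export
tac_piecewise <- function(t1, a_t1, t2, slope, tail_value, lambda_tail,
                          times = NULL, activities = NULL) {
  if (!(t1 >= 0 && t2 > t1)) stop("need 0 <= t1 < t2", call. = FALSE)
  if (a_t1 < 0 || tail_value < 0) stop("activities must be >= 0", call. = FALSE)
  if (lambda_tail <= 0) stop("lambda_tail must be > 0", call. = FALSE)
  structure(
    list(form = "piecewise_linear_exponential", t1 = t1, a_t1 = a_t1,
         t2 = t2, slope = slope, tail_value = tail_value,
         lambda_tail = lambda_tail, times = times, activities = activities),
    class = c("tac_piecewise", "tac")
  )
}

#' @export
print.tac <- function(x, ...) {
  if (inherits(x, "tac_biexp")) {
    if (isTRUE(x$mono))
      cat(sprintf("Mono-exponential TAC: A(t) = %.4g exp(-%.4g t)\n",
                  x$a1 + x$a2, x$lambda1))
    else
      cat(sprintf(
        "Biexponential TAC: A(t) = %.4g exp(-%.4g t) + %.4g exp(-%.4g t)\n",
        x$a1, x$lambda1, x$a2, x$lambda2))
  } else {
    cat(sprintf(
      "Piecewise TAC: linear (%g h, %.4g MBq) slope %.4g MBq/h to %g h, then %.4g exp(-%.4g (t-%g))\n",
      x$t1, x$a_t1, x$t2, x$slope, x$tail_value, x$lambda_tail, x$t2))
  }
  cat(sprintf("  time-integrated activity: %.6g MBq*h\n", integrate_curve(x)))
  invisible(x)
}

#' Evaluate a time-activity curve
#'
#' @param object A `tac` object.
#' @param t Times in hours (vector allowed).
#' @param ... Unused.
#' @return Activities in MBq, non-negative.
#' @export
predict.tac_biexp <- function(object, t, ...) {
  object$a1 * exp(-object$lambda1 * t) + object$a2 * exp(-object$lambda2 * t)
}

#' @export
predict.tac_piecewise <- function(object, t, ...) {
  lin <- pmax(0, object$a_t1 + object$slope * (t - object$t1))
  tail_ <- object$tail_value * exp(-object$lambda_tail * (t - object$t2))
  ifelse(t < object$t2, lin, tail_)
}

#' @export
plot.tac <- function(x, t_max = NULL, ...) {
  if (is.null(t_max))
    t_max <- if (!is.null(x$times)) max(x$times) * 1.2 else 200
  tt <- seq(0, t_max, length.out = 400)
  plot(tt, predict(x, tt), type = "l", xlab = "time after injection (h)",
       ylab = "activity (MBq)", ...)
  if (!is.null(x$times)) points(x$times, x$activities, pch = 19)
  invisible(x)
}

.check_tac_samples <- function(times, activities) {
  if (length(times) != length(activities) || length(times) < 4L)
    stop("need at least 4 paired time points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(activities)) || any(activities <= 0))
    stop("activities must be positive", call. = FALSE)
}

# mono-exponential fit: log-linear LS init, Levenberg-Marquardt polish
.fit_monoexp <- function(times, activities) {
  fit0 <- lm(log(activities) ~ times)
  lam <- max(-unname(coef(fit0)[2L]), 1e-6)
  amp <- exp(unname(coef(fit0)[1L]))
  res <- try(minpack.lm::nls.lm(
    par = c(log_a = log(amp), log_l = log(lam)),
    fn = function(p) activities - exp(p[1L]) * exp(-exp(p[2L]) * times),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15)
  ), silent = TRUE)
  if (!inherits(res, "try-error")) {
    amp <- exp(res$par[[1L]]); lam <- exp(res$par[[2L]])
  }
  list(a = amp, lambda = max(lam, 1e-6))
}

#' Fit the low-uptake compartment time-activity curve
#'
#' Constrained least-squares biexponential fit
#' `A(t) = a1 exp(-lambda1 t) + a2 exp(-lambda2 t)` with
#' `a1, a2 >= 0` and `lambda1 >= lambda2 > 0`, initialised from a
#' log-linear fit of the last two points (slow phase) and the early-point
#' residuals (fast phase).  Falls back to a mono-exponential when the
#' biexponential fit fails to converge, the fast amplitude vanishes, or the
#' two rate constants collapse (relative difference below 1e-3).  A warning
#' is raised when the slow rate constant falls below the 177Lu physical
#' decay constant ([lu177_lambda_phys]), since whole-body clearance cannot
#' be slower than physical decay.
#'
#' @param times Strictly increasing times in hours (the protocol uses 2,
#'   24, 48, 168 h).
#' @param activities Positive activities in MBq, one per time.
#' @return A `tac_biexp` curve (see [tac_biexponential()]).
#' @export
fit_low_curve <- function(times, activities) {
  .check_tac_samples(times, activities)
  n <- length(times)

  # slow-phase init from the last two points
  l2_0 <- (log(activities[n - 1L]) - log(activities[n])) /
    (times[n] - times[n - 1L])
  l2_0 <- min(max(l2_0, 1e-4), 1)
  a2_0 <- activities[n] * exp(l2_0 * times[n])

  # fast-phase init from residuals of the first two points
  r <- activities - a2_0 * exp(-l2_0 * times)
  if (r[1L] > 0 && r[2L] > 0 && r[1L] > r[2L]) {
    l1_0 <- (log(r[1L]) - log(r[2L])) / (times[2L] - times[1L])
    a1_0 <- r[1L] * exp(l1_0 * times[1L])
  } else {
    l1_0 <- max(10 * l2_0, 0.3)
    a1_0 <- max(r[1L], 0.05 * activities[1L])
  }
  l1_0 <- min(max(l1_0, 2 * l2_0), 20)

  # bounded LM on (a1, l1, a2, l2); amplitudes on linear scale with lower
  # bound 0, rates log-free but bounded below via the constraint vector
  fn <- function(p) activities -
    (p[1L] * exp(-p[2L] * times) + p[3L] * exp(-p[4L] * times))
  fit <- try(minpack.lm::nls.lm(
    par = c(a1 = a1_0, l1 = l1_0, a2 = a2_0, l2 = l2_0),
    lower = c(0, 1e-6, 0, 1e-6), upper = c(Inf, 50, Inf, 50),
    fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  ), silent = TRUE)

  use_mono <- inherits(fit, "try-error")
  if (!use_mono) {
    p <- fit$par
    if (p[["l1"]] < p[["l2"]]) p <- p[c("a2", "l2", "a1", "l1")]
    a1 <- p[[1L]]; l1 <- p[[2L]]; a2 <- p[[3L]]; l2 <- p[[4L]]
    tot <- a1 + a2
    rel_dl <- abs(l1 - l2) / max(l1, l2)
    use_mono <- tot <= 0 || a1 / tot < 1e-6 || a2 / tot < 1e-6 ||
      rel_dl < 1e-3
  }
  if (use_mono) {
    m <- .fit_monoexp(times, activities)
    curve <- tac_biexponential(m$a, m$lambda, 0, m$lambda,
                               times = times, activities = activities)
  } else {
    curve <- tac_biexponential(a1, l1, a2, l2,
                               times = times, activities = activities)
  }
  if (curve$lambda2 < lu177_lambda_phys)
    warning(sprintf(
      "slow rate constant %.3g /h is below the 177Lu physical decay constant %.3g /h",
      curve$lambda2, lu177_lambda_phys), call. = FALSE)
  curve
}

#' Fit the high-uptake compartment time-activity curve
#'
#' Piecewise model: a linear segment through the first two measured points
#' (back-extrapolated to t = 0 and clamped at zero), and a mono-exponential
#' tail fitted by log-linear least squares to points 2 through 4.  The tail
#' is anchored at the regression's own prediction at `t2` rather than the
#' measured second point; any discontinuity against the measured value is
#' reported via a message.  A degenerate tail (non-decaying later points)
#' is guarded at `lambda = 1e-6` /h with a warning.
#'
#' @inheritParams fit_low_curve
#' @return A `tac_piecewise` curve (see [tac_piecewise()]).
#' @export
fit_high_curve <- function(times, activities) {
  .check_tac_samples(times, activities)
  n <- length(times)
  t1 <- times[1L]; t2 <- times[2L]
  slope <- (activities[2L] - activities[1L]) / (t2 - t1)

  tt <- times[2L:n]; aa <- activities[2L:n]
  reg <- lm(log(aa) ~ tt)
  lambda <- -unname(coef(reg)[2L])
  anchor <- exp(unname(predict(reg, newdata = data.frame(tt = t2))))
  if (lambda <= 1e-6) {
    warning("non-decaying tail; clamping lambda_tail to 1e-6 /h",
            call. = FALSE)
    lambda <- 1e-6
  }
  disc <- anchor - activities[2L]
  if (abs(disc) > 1e-9 * max(activities))
    message(sprintf(
      "high-curve junction: tail anchor %.6g MBq vs measured %.6g MBq at %g h (diff %.3g)",
      anchor, activities[2L], t2, disc))

  tac_piecewise(t1 = t1, a_t1 = activities[1L], t2 = t2, slope = slope,
                tail_value = anchor, lambda_tail = lambda,
                times = times, activities = activities)
}

#' Analytic time-integrated activity of a fitted curve
#'
#' Integrates a time-activity curve over `[0, Inf)` in closed form:
#' `a1/lambda1 + a2/lambda2` for the biexponential; for the piecewise form,
#' the exact integral of the zero-clamped linear segment on `[0, t2]` plus
#' the tail integral `tail_value / lambda_tail`.  The result is the total
#' number of decays in the compartment, in MBq*h.
#'
#' @param curve A `tac` or `conc_curve` object.
#' @return Time-integrated activity in MBq*h (for a concentration curve,
#'   MBq*h/g).
#' @export
integrate_curve <- function(curve) UseMethod("integrate_curve")

#' @export
integrate_curve.tac_biexp <- function(curve) {
  if (curve$lambda1 <= 0 || (curve$a2 > 0 && curve$lambda2 <= 0))
    stop("rate constants must be positive for integration", call. = FALSE)
  curve$a1 / curve$lambda1 + if (curve$a2 > 0) curve$a2 / curve$lambda2 else 0
}

#' @export
integrate_curve.tac_piecewise <- function(curve) {
  if (curve$lambda_tail <= 0)
    stop("lambda_tail must be positive for integration", call. = FALSE)
  v0 <- curve$a_t1 - curve$slope * curve$t1          # linear value at t = 0
  v2 <- curve$a_t1 + curve$slope * (curve$t2 - curve$t1)  # at t = t2
  if (v0 >= 0 && v2 >= 0) {
    lin <- (v0 + v2) / 2 * curve$t2
  } else if (v0 < 0) {
    t0 <- curve$t1 - curve$a_t1 / curve$slope        # zero crossing
    lin <- v2 * (curve$t2 - t0) / 2
  } else {
    t0 <- curve$t1 - curve$a_t1 / curve$slope
    lin <- v0 * t0 / 2
  }
  lin + curve$tail_value / curve$lambda_tail
}

#' Convert an activity curve to a concentration curve
#'
#' Scales a compartment time-activity curve by the compartment mass; with
#' unit density, MBq/g and MBq/mL are interchangeable.  The time-integrated
#' concentration (MBq*h/g) is the time-integrated activity divided by the
#' mass.
#'
#' @param curve A `tac` object.
#' @param mass_g Compartment mass in grams (> 0).
#' @return An object of class `conc_curve` wrapping the curve.
#' @export
to_concentration <- function(curve, mass_g) {
  stopifnot(inherits(curve, "tac"))
  if (!is.finite(mass_g) || mass_g <= 0)
    stop("mass_g must be positive", call. = FALSE)
  structure(list(curve = curve, mass_g = mass_g), class = "conc_curve")
}

#' @export
predict.conc_curve <- function(object, t, ...) {
  predict(object$curve, t) / object$mass_g
}

#' @export
integrate_curve.conc_curve <- function(curve) {
  integrate_curve(curve$curve) / curve$mass_g
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("Concentration curve (mass %.6g g):\n", x$mass_g))
  print(x$curve)
  invisible(x)
}
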
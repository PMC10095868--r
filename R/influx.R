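#' Cumulative water-influx schedules for stomatal opening
#'
#' During stomatal opening, osmotically driven water uptake by a guard cell is
#' well described by a monotone cumulative curve that starts at zero and
#' asymptotically approaches the total volume gained between the closed and
#' open states. `influx_schedule()` builds such a curve in one of three shape
#' families:
#'
#' * `"mb_cdf"` — the cumulative distribution function of the
#'   Maxwell--Boltzmann speed distribution. Its cubic onset gives the slow
#'   start / rapid rise / asymptotic saturation ("S-curve") expected of
#'   diffusive water transfer.
#' * `"sat_exp"` — a saturating exponential `1 - exp(-t/scale)`, which rises
#'   fastest at `t = 0` ("logarithmic growth": no initial lag).
#' * `"logistic"` — a symmetric sigmoid, provided as a third family for
#'   sensitivity studies.
#'
#' Each raw shape `F` is min--max normalized on `[0, T_influx]`,
#' `W(t) = dV_total * (F(t) - F(0)) / (F(T_influx) - F(0))`, then clamped so
#' that `W(t) = dV_total` exactly for all `t >= T_influx`. Hence `W(0) = 0` and
#' `W(T_influx) = dV_total` hold exactly, whatever the scale constant.
#'
#' @param shape One of `"mb_cdf"`, `"sat_exp"`, `"logistic"`.
#' @param dv_total Total water volume taken up over the schedule (um^3); > 0.
#' @param t_influx Duration of the influx (s); > 0. The curve is clamped at
#'   its normalized endpoint from this time onward.
#' @param scale Shape-specific time constant (s); > 0. Defaults keep >= 99%
#'   of the raw curve inside `[0, t_influx]` so normalization is a small
#'   correction: `t_influx/6` (mb_cdf), `t_influx/5` (sat_exp),
#'   `t_influx/10` (logistic).
#' @param midpoint Inflection time of the logistic (s); ignored by the other
#'   shapes. Defaults to `t_influx/2`.
#'
#' @return An object of class `influx_schedule`.
#' @seealso [cumulative_volume()], [influx_rate()]
#' @examples
#' s <- influx_schedule("mb_cdf", dv_total = 912, t_influx = 3600)
#' cumulative_volume(s, c(0, 1800, 3600, 7200))
#' @export
influx_schedule <- function(shape = c("mb_cdf", "sat_exp", "logistic"),
                            dv_total, t_influx, scale = NULL, midpoint = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(dv_total) || length(dv_total) != 1L || !is.finite(dv_total) ||
      dv_total <= 0) {
    stop("`dv_total` must be a single positive number (um^3)", call. = FALSE)
  }
  if (!is.numeric(t_influx) || length(t_influx) != 1L || !is.finite(t_influx) ||
      t_influx <= 0) {
    stop("`t_influx` must be a single positive duration (s)", call. = FALSE)
  }
  if (is.null(scale)) {
    scale <- switch(shape,
      mb_cdf   = t_influx / 6,
      sat_exp  = t_influx / 5,
      logistic = t_influx / 10
    )
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be a single positive duration (s)", call. = FALSE)
  }
  if (shape == "logistic") {
    if (is.null(midpoint)) midpoint <- t_influx / 2
    if (!is.numeric(midpoint) || length(midpoint) != 1L || !is.finite(midpoint)) {
      stop("`midpoint` must be a single time (s) for the logistic shape",
           call. = FALSE)
    }
  } else {
    midpoint <- NA_real_
  }

  f0 <- .influx_raw(shape, 0, scale, midpoint)
  fT <- .influx_raw(shape, t_influx, scale, midpoint)
  if (!(fT > f0)) {
    stop("degenerate schedule: raw shape does not increase on [0, t_influx]",
         call. = FALSE)
  }

  structure(
    list(shape = shape, dv_total = dv_total, t_influx = t_influx,
         scale = scale, midpoint = midpoint, f0 = f0, fT = fT),
    class = "influx_schedule"
  )
}

# Raw (unnormalized) shape functions and their time derivatives. x = t/scale.
# mb_cdf is the CDF of the Maxwell-Boltzmann speed density ~ x^2 exp(-x^2/2):
#   F(t) = erf(x/sqrt(2)) - sqrt(2/pi) * x * exp(-x^2/2),
# with erf(x/sqrt(2)) = 2*pnorm(x) - 1.
.influx_raw <- function(shape, t, a, m) {
  switch(shape,
    mb_cdf = {
      x <- t / a
      2 * stats::pnorm(x) - 1 - sqrt(2 / pi) * x * exp(-x^2 / 2)
    },
    sat_exp = 1 - exp(-t / a),
    logistic = stats::plogis((t - m) / a)
  )
}

.influx_raw_rate <- function(shape, t, a, m) {
  switch(shape,
    mb_cdf = {
      x <- t / a
      sqrt(2 / pi) * x^2 * exp(-x^2 / 2) / a
    },
    sat_exp = exp(-t / a) / a,
    logistic = {
      s <- stats::plogis((t - m) / a)
      s * (1 - s) / a
    }
  )
}

#' Cumulative influx volume at given times
#'
#' Evaluates the normalized, clamped cumulative water-influx curve `W(t)` of a
#' schedule. The value is exactly 0 at `t = 0`, non-decreasing, and exactly
#' `dv_total` for every `t >= t_influx`.
#'
#' @param s An [influx_schedule()].
#' @param t Time(s) in seconds; must be `>= 0`. Vectorized.
#' @return Cumulative influx volume(s) in um^3, in `[0, dv_total]`.
#' @export
cumulative_volume <- function(s, t) {
  stopifnot(inherits(s, "influx_schedule"))
  if (!is.numeric(t) || anyNA(t)) stop("`t` must be numeric", call. = FALSE)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  raw <- .influx_raw(s$shape, pmin(t, s$t_influx), s$scale, s$midpoint)
  w <- s$dv_total * (raw - s$f0) / (s$fT - s$f0)
  w <- pmin(pmax(w, 0), s$dv_total)
  w[t >= s$t_influx] <- s$dv_total
  w
}

#' Instantaneous influx rate
#'
#' The time derivative of [cumulative_volume()]. Because the schedule is
#' clamped at its endpoint, the rate is identically 0 for `t > t_influx`; at
#' `t = t_influx` the left-hand derivative is returned.
#'
#' @inheritParams cumulative_volume
#' @return Influx rate(s) in um^3/s, `>= 0`.
#' @export
influx_rate <- function(s, t) {
  stopifnot(inherits(s, "influx_schedule"))
  if (!is.numeric(t) || anyNA(t)) stop("`t` must be numeric", call. = FALSE)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  r <- s$dv_total * .influx_raw_rate(s$shape, t, s$scale, s$midpoint) /
    (s$fT - s$f0)
  r[t > s$t_influx] <- 0
  pmax(r, 0)
}

#' @export
print.influx_schedule <- function(x, ...) {
  cat(sprintf(
    "<influx_schedule> shape=%s  dV_total=%.6g um^3  T_influx=%.6g s  scale=%.6g s%s\n",
    x$shape, x$dv_total, x$t_influx, x$scale,
    if (is.finite(x$midpoint)) sprintf("  midpoint=%.6g s", x$midpoint) else ""
  ))
  invisible(x)
}
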
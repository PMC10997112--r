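# Parameterization of a walking system: pendulum eigenfrequency plus the
# four control parameters of the foot-placement law.

#' Gravitational acceleration used throughout the package (m s^-2)
#' @keywords internal
.g <- 9.81

#' Pendulum eigenfrequency from leg length
#'
#' The linearized single-link inverted pendulum with a rigid leg of length
#' `l` has eigenfrequency `omega = sqrt(g / l)` with `g` = 9.81 m s^-2.
#'
#' @param l Effective leg length in metres (vertical distance from the
#'   center of mass to the contact point). Must be positive.
#' @return Eigenfrequency in s^-1.
#' @examples
#' eigenfrequency_from_leg_length(1)    # ~3.13 s^-1, typical adult
#' eigenfrequency_from_leg_length(0.77)
#' @export
eigenfrequency_from_leg_length <- function(l) {
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0)
    stop("leg length `l` must be a single positive number (metres)")
  sqrt(.g / l)
}

#' Construct a walking-system parameter set
#'
#' A walking system couples the linearized inverted pendulum (one
#' biomechanical parameter, the eigenfrequency `omega`) with a
#' proportional-derivative foot-placement controller (offset `b_o`,
#' proportional gain `b_p`, derivative gain `b_d`) stepping at a fixed
#' period `t_step`. Either `omega` or `leg_length` must be given (exactly
#' one), and either `t_step` or `cadence` (steps per minute,
#' `t_step = 60 / cadence`).
#'
#' The stepping `mode` selects the control law: `"progressive"`
#' (anterior-posterior walking, constant offset each step) or
#' `"alternating"` (medial-lateral sway, offset sign flips each step).
#' The two modes share all stability properties; only the offset term
#' differs.
#'
#' @param b_p Proportional gain (dimensionless).
#' @param b_d Derivative gain (seconds).
#' @param t_step Step duration in seconds.
#' @param cadence Stepping rate in steps per minute (alternative to
#'   `t_step`).
#' @param omega Pendulum eigenfrequency in s^-1.
#' @param leg_length Effective leg length in metres (alternative to
#'   `omega`).
#' @param b_o Constant foot-placement offset in metres (default 0). Sets
#'   average step length/width; has no effect on stability.
#' @param mode `"progressive"` or `"alternating"`.
#' @return An object of class `walker_params`.
#' @examples
#' walker_params(b_p = 2.5, b_d = 0.6, t_step = 0.5, omega = 3.13,
#'               b_o = 0.02, mode = "alternating")
#' @export
walker_params <- function(b_p, b_d, t_step = NULL, cadence = NULL,
                          omega = NULL, leg_length = NULL, b_o = 0,
                          mode = c("progressive", "alternating")) {
  mode <- match.arg(mode)
  if (is.null(omega) == is.null(leg_length))
    stop("supply exactly one of `omega` or `leg_length`")
  if (is.null(t_step) == is.null(cadence))
    stop("supply exactly one of `t_step` or `cadence`")
  if (!is.null(leg_length)) omega <- eigenfrequency_from_leg_length(leg_length)
  if (!is.null(cadence)) {
    if (!is.numeric(cadence) || cadence <= 0)
      stop("`cadence` must be positive (steps per minute)")
    t_step <- 60 / cadence
  }
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a single finite number", nm))
    x
  }
  omega <- chk(omega, "omega"); t_step <- chk(t_step, "t_step")
  b_o <- chk(b_o, "b_o"); b_p <- chk(b_p, "b_p"); b_d <- chk(b_d, "b_d")
  if (omega <= 0) stop("`omega` must be positive")
  if (t_step <= 0) stop("`t_step` must be positive")
  structure(list(omega = omega,
                 leg_length = if (is.null(leg_length)) .g / omega^2 else leg_length,
                 b_o = b_o, b_p = b_p, b_d = b_d,
                 t_step = t_step, mode = mode),
            class = "walker_params")
}

#' @export
print.walker_params <- function(x, ...) {
  cat("Walking system parameters\n")
  cat(sprintf("  omega  = %.6g s^-1  (leg length %.4g m)\n", x$omega, x$leg_length))
  cat(sprintf("  b_o    = %.6g m\n  b_p    = %.6g\n  b_d    = %.6g s\n",
              x$b_o, x$b_p, x$b_d))
  cat(sprintf("  t_step = %.6g s  (cadence %.4g steps/min)\n",
              x$t_step, 60 / x$t_step))
  cat(sprintf("  mode   = %s stepping\n", x$mode))
  invisible(x)
}

#' Hyperbolic half-step constants
#'
#' Shorthand constants `c = cosh(omega * t_step / 2)` and
#' `s = sinh(omega * t_step / 2)` describing closed-form propagation over
#' half a step. They satisfy `c^2 - s^2 = 1`.
#'
#' @param omega Eigenfrequency, s^-1.
#' @param t_step Step duration, s.
#' @return A list with elements `c` and `s`.
#' @export
half_step_constants <- function(omega, t_step) {
  if (!is.numeric(omega) || any(omega <= 0)) stop("`omega` must be positive")
  if (!is.numeric(t_step) || any(t_step <= 0)) stop("`t_step` must be positive")
  a <- omega * t_step / 2
  list(c = cosh(a), s = sinh(a))
}
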
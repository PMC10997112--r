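# Closed-form continuous dynamics of the linearized inverted pendulum, the
# foot-placement control law, and event-driven simulation of the hybrid
# walking system.

#' Continuous pendulum state
#'
#' State of the hybrid walking system at a point in time: absolute
#' center-of-mass position `x` and velocity `v`, contact-point position
#' `p` (piecewise constant between steps) and the 0-based index `n` of the
#' current step. The relative position `q = x - p` drives both the
#' dynamics and the controller.
#'
#' @param t Time, s.
#' @param x CoM position, m.
#' @param v CoM velocity, m s^-1.
#' @param p Contact-point position, m.
#' @param n Current step index (0-based).
#' @return An object of class `pendulum_state`.
#' @export
pendulum_state <- function(t = 0, x = 0, v = 0, p = 0, n = 0L) {
  vals <- c(t = t, x = x, v = v, p = p)
  if (!all(is.finite(vals))) stop("pendulum state components must be finite")
  structure(list(t = t, x = x, v = v, p = p, n = as.integer(n)),
            class = "pendulum_state")
}

#' @export
print.pendulum_state <- function(x, ...) {
  cat(sprintf("pendulum state @ t = %.4g s (step %d): x = %.6g m, v = %.6g m/s, p = %.6g m, q = %.6g m\n",
              x$t, x$n, x$x, x$v, x$p, x$x - x$p))
  invisible(x)
}

#' Midstance state
#'
#' Discrete state of the walking system at midstance of step `n`
#' (time `t = n * t_step`, with `t = 0` itself a midstance): position `q`
#' of the CoM relative to the contact point and velocity `v`. This is the
#' state the foot-placement controller senses, and the state in which the
#' step-to-step map and its stability analysis are expressed.
#'
#' @param q Relative CoM position at midstance, m.
#' @param v CoM velocity at midstance, m s^-1.
#' @param n Step index (0-based).
#' @return An object of class `midstance_state`.
#' @export
midstance_state <- function(q, v, n = 0L) {
  if (!all(is.finite(c(q, v)))) stop("midstance state must be finite")
  structure(list(q = q, v = v, n = as.integer(n)), class = "midstance_state")
}

#' @export
print.midstance_state <- function(x, ...) {
  cat(sprintf("midstance state (step %d): q = %.6g m, v = %.6g m/s\n",
              x$n, x$q, x$v))
  invisible(x)
}

# Closed-form flow of (q, v) over a horizon dt (no step in between):
#   q(dt) = q0*cosh(w dt) + v0/w*sinh(w dt)
#   v(dt) = q0*w*sinh(w dt) + v0*cosh(w dt)
.flow_qv <- function(q, v, dt, omega) {
  ch <- cosh(omega * dt); sh <- sinh(omega * dt)
  list(q = q * ch + v * sh / omega,
       v = q * omega * sh + v * ch)
}

#' Propagate the pendulum state over a step-free interval
#'
#' Exact closed-form solution of the linearized pendulum equations
#' `x' = v`, `v' = omega^2 (x - p)`: hyperbolic propagation of the
#' relative position and velocity. No numerical integration is involved.
#' The caller must ensure `dt` does not cross a step event.
#'
#' @param state A [pendulum_state()].
#' @param dt Duration, s (non-negative).
#' @param omega Eigenfrequency, s^-1.
#' @return The propagated `pendulum_state` (same `p`, same `n`).
#' @export
propagate_state <- function(state, dt, omega) {
  stopifnot(inherits(state, "pendulum_state"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("`dt` must be a single non-negative number")
  f <- .flow_qv(state$x - state$p, state$v, dt, omega)
  pendulum_state(t = state$t + dt, x = state$p + f$q, v = f$v,
                 p = state$p, n = state$n)
}

#' Foot-placement control law
#'
#' The controller selects the next contact point from the midstance CoM
#' state of the current step:
#' \deqn{p_{n+1} = p_n + b_o + b_p q_n + b_d v_n}{p[n+1] = p[n] + b_o + b_p q[n] + b_d v[n]}
#' for progressive stepping; for alternating stepping the offset sign
#' flips each step, `(-1)^n b_o`. The parity convention starts at step
#' `n = 0` with sign `+1`; which physical side that represents is an
#' arbitrary labeling.
#'
#' @param params A [walker_params()].
#' @param ms A [midstance_state()] (supplies `q`, `v` and the parity
#'   index `n`).
#' @param p_n Current contact-point position, m.
#' @return The new contact-point position, m.
#' @export
foot_placement <- function(params, ms, p_n = 0) {
  stopifnot(inherits(params, "walker_params"), inherits(ms, "midstance_state"))
  off <- if (params$mode == "alternating") (-1)^ms$n * params$b_o else params$b_o
  p_n + off + params$b_p * ms$q + params$b_d * ms$v
}

# One full step of the exact step-to-step recursion expressed in relative
# coordinates, with optional additive noise on the realized placement and
# optional sensory noise on the controller inputs. Returns the next
# midstance (q, v) and the placement displacement actually taken.
.step_once <- function(params, q, v, n, eps = 0, eta_q = 0, eta_v = 0) {
  om <- params$omega
  off <- if (params$mode == "alternating") (-1)^n * params$b_o else params$b_o
  dp <- off + params$b_p * (q + eta_q) + params$b_d * (v + eta_v) + eps
  half <- .flow_qv(q, v, params$t_step / 2, om)   # state just before the step
  q_new <- half$q - dp                            # re-express w.r.t. new contact
  nxt <- .flow_qv(q_new, half$v, params$t_step / 2, om)
  list(q = nxt$q, v = nxt$v, dp = dp)
}

#' Exact midstance-to-midstance map
#'
#' Composition of half-step closed-form propagation, the foot-placement
#' law, and the remaining half-step: the exact (affine) step-to-step map
#' of the walking system on midstance states. Its Jacobian at the
#' periodic-orbit reference state is the transition matrix returned by
#' [transition_matrix()].
#'
#' @param params A [walker_params()].
#' @param ms A [midstance_state()].
#' @return The [midstance_state()] at step `n + 1`.
#' @export
midstance_map <- function(params, ms) {
  stopifnot(inherits(params, "walker_params"), inherits(ms, "midstance_state"))
  r <- .step_once(params, ms$q, ms$v, ms$n)
  midstance_state(r$q, r$v, ms$n + 1L)
}

#' Instantaneous perturbation event
#'
#' An additive offset applied instantaneously to the CoM position and/or
#' velocity at a stated time during simulation. When a perturbation
#' coincides exactly with a step event, the perturbation is applied first,
#' so the controller senses the perturbed state.
#'
#' @param time Application time, s (non-negative).
#' @param dx Position offset, m.
#' @param dv Velocity offset, m s^-1.
#' @return An object of class `perturbation_event`.
#' @export
perturbation_event <- function(time, dx = 0, dv = 0) {
  if (!is.finite(time) || time < 0) stop("perturbation `time` must be >= 0")
  if (!all(is.finite(c(dx, dv)))) stop("perturbation offsets must be finite")
  structure(list(time = time, dx = dx, dv = dv), class = "perturbation_event")
}

#' Simulate the walking system
#'
#' Event-driven simulation of the hybrid walking system. Between events
#' the state follows the exact hyperbolic closed form (no discretization
#' error); events are step events at `t = (n + 1/2) * t_step`, midstances
#' at `t = n * t_step`, optional instantaneous perturbations, and the
#' uniform sampling grid. The simulation starts at `t = 0`, a midstance,
#' and runs for `n_steps` steps, ending at the midstance
#' `t = n_steps * t_step`.
#'
#' Tie-break at coincident times: perturbations are applied first, then
#' midstance bookkeeping, then the step event, then sampling (samples
#' therefore record the post-event state).
#'
#' @param params A [walker_params()].
#' @param init Initial [pendulum_state()] at `t = 0` (a midstance), or
#'   `NULL` to start on the periodic orbit reference state with `p = 0`.
#' @param n_steps Number of steps to simulate (>= 1).
#' @param dt Sampling interval, s (default 0.005). Sampling density does
#'   not affect the computed states.
#' @param perturbations A list of [perturbation_event()]s (or a single
#'   one), all within the simulated horizon.
#' @return An object of class `walker_trajectory`: a list with
#'   `samples` (data.frame `t`, `x`, `v`, `p`, `q`, `step_idx`),
#'   `step_events` (data.frame `time`, `p_old`, `p_new`, `step`),
#'   `midstances` (data.frame `n`, `t`, `q`, `v`, `p` of exact midstance
#'   states), and `params`.
#' @export
simulate_walker <- function(params, init = NULL, n_steps = 10L, dt = 0.005,
                            perturbations = NULL) {
  stopifnot(inherits(params, "walker_params"))
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("`n_steps` must be >= 1")
  if (inherits(perturbations, "perturbation_event"))
    perturbations <- list(perturbations)
  if (!is.null(perturbations) &&
      !all(vapply(perturbations, inherits, TRUE, "perturbation_event")))
    stop("`perturbations` must be perturbation_event objects")
  Ts <- params$t_step
  t_end <- n_steps * Ts
  if (is.null(init)) {
    ref <- periodic_orbit(params)
    init <- pendulum_state(t = 0, x = ref$q, v = ref$v, p = 0, n = 0L)
  }
  stopifnot(inherits(init, "pendulum_state"))
  if (abs(init$t) > 1e-12) stop("`init` must be at t = 0 (a midstance)")

  pt <- if (is.null(perturbations)) numeric(0) else
    vapply(perturbations, `[[`, 0, "time")
  if (any(pt > t_end + 1e-9))
    stop("perturbation times must lie within the simulated horizon")

  # Event table; priority resolves coincident times:
  # perturbation (0) < midstance (1) < step (2) < sample (3).
  ev <- rbind(
    if (length(pt)) data.frame(time = pt, prio = 0, id = seq_along(pt)),
    data.frame(time = (0:n_steps) * Ts, prio = 1, id = 0:n_steps),
    data.frame(time = ((0:(n_steps - 1)) + 0.5) * Ts, prio = 2,
               id = 0:(n_steps - 1)),
    data.frame(time = seq(0, t_end + 1e-9, by = dt), prio = 3, id = NA)
  )
  ev <- ev[order(ev$time, ev$prio), ]

  x <- init$x; v <- init$v; p <- init$p
  t0 <- 0; x0 <- x; v0 <- v                  # anchor of the current arc
  n <- 0L
  om <- params$omega
  ns <- sum(ev$prio == 3)
  samples <- data.frame(t = numeric(ns), x = numeric(ns), v = numeric(ns),
                        p = numeric(ns), q = numeric(ns),
                        step_idx = integer(ns))
  step_events <- data.frame(time = numeric(n_steps), p_old = numeric(n_steps),
                            p_new = numeric(n_steps), step = integer(n_steps))
  mids <- data.frame(n = 0:n_steps, t = (0:n_steps) * Ts, q = NA_real_,
                     v = NA_real_, p = NA_real_)
  last_mid <- NULL
  si <- 0L
  for (k in seq_len(nrow(ev))) {
    tk <- ev$time[k]
    f <- .flow_qv(x0 - p, v0, tk - t0, om)
    x <- p + f$q; v <- f$v
    pr <- ev$prio[k]
    if (pr == 0) {                                   # perturbation
      pe <- perturbations[[ev$id[k]]]
      x <- x + pe$dx; v <- v + pe$dv
      t0 <- tk; x0 <- x; v0 <- v
    } else if (pr == 1) {                            # midstance bookkeeping
      i <- ev$id[k] + 1L
      mids$q[i] <- x - p; mids$v[i] <- v; mids$p[i] <- p
      last_mid <- midstance_state(x - p, v, ev$id[k])
    } else if (pr == 2) {                            # step event
      p_new <- foot_placement(params, last_mid, p)
      step_events[ev$id[k] + 1L, ] <- list(tk, p, p_new, ev$id[k] + 1L)
      p <- p_new
      n <- n + 1L
      t0 <- tk; x0 <- x; v0 <- v
    } else {                                         # sample
      si <- si + 1L
      samples[si, ] <- list(tk, x, v, p, x - p, n)
    }
  }
  structure(list(samples = samples, step_events = step_events,
                 midstances = mids, params = params,
                 perturbations = perturbations),
            class = "walker_trajectory")
}

#' @export
print.walker_trajectory <- function(x, ...) {
  cat(sprintf("walker trajectory: %d steps, %d samples over %.4g s (%s stepping)\n",
              nrow(x$step_events), nrow(x$samples),
              max(x$samples$t), x$params$mode))
  invisible(x)
}
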
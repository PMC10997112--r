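# Periodic orbits, step-to-step error propagation, and the closed-form
# stability region in control-gain space.

#' Periodic-orbit reference state
#'
#' Every walking system away from two degenerate parameter lines has a
#' periodic orbit of the relative state (q, v). For progressive stepping
#' the period is `t_step` and the midstance reference state is
#' `q_ref = 0`, `v_ref = b_o / (2 s / omega - b_d)`. For alternating
#' stepping the period is `2 t_step` and the reference state is
#' `q_ref(n) = (-1)^n b_o / (2 c - b_p)`, `v_ref = 0`; the returned state
#' is the even-parity (`n = 0`) branch.
#'
#' On the degenerate lines (`b_d = 2 s / omega` for progressive,
#' `b_p = 2 c` for alternating) the closed-form denominator vanishes and
#' no periodic orbit with the stated structure exists (unless `b_o = 0`);
#' an explicit singular-orbit error is raised rather than returning
#' infinities.
#'
#' @param params A [walker_params()].
#' @return A [midstance_state()] with `n = 0`: the reference state. For
#'   alternating systems the odd-parity branch is the same state with the
#'   sign of `q` flipped.
#' @export
periodic_orbit <- function(params) {
  stopifnot(inherits(params, "walker_params"))
  hs <- half_step_constants(params$omega, params$t_step)
  if (params$mode == "progressive") {
    den <- 2 * hs$s / params$omega - params$b_d
    if (abs(den) < 1e-12 && params$b_o != 0)
      stop(structure(class = c("walkstab_singular_orbit", "error", "condition"),
                     list(message = "singular orbit: b_d = 2 s / omega makes the progressive reference velocity undefined",
                          call = sys.call(-1))))
    v_ref <- if (params$b_o == 0) 0 else params$b_o / den
    midstance_state(0, v_ref, 0L)
  } else {
    den <- 2 * hs$c - params$b_p
    if (abs(den) < 1e-12 && params$b_o != 0)
      stop(structure(class = c("walkstab_singular_orbit", "error", "condition"),
                     list(message = "singular orbit: b_p = 2 c makes the alternating reference position undefined",
                          call = sys.call(-1))))
    q_ref <- if (params$b_o == 0) 0 else params$b_o / den
    midstance_state(q_ref, 0, 0L)
  }
}

#' Parity-aware reference state at step n
#'
#' Reference midstance state of the periodic orbit at step `n`. For
#' progressive systems this is independent of `n`; for alternating
#' systems the sign of `q_ref` follows the parity `(-1)^n`.
#'
#' @param params A [walker_params()].
#' @param n Step index (vectorized).
#' @return A list with vectors `q` and `v`.
#' @export
reference_state <- function(params, n = 0L) {
  ref <- periodic_orbit(params)
  if (params$mode == "alternating")
    list(q = (-1)^n * ref$q, v = rep(ref$v, length(n)))
  else
    list(q = rep(ref$q, length(n)), v = rep(ref$v, length(n)))
}

#' Step-to-step transition matrix
#'
#' The linearization A of the exact midstance-to-midstance map about the
#' periodic orbit. Deviations delta_n = (q_n - q_ref, v_n - v_ref)
#' propagate as delta_{n+1} = A delta_n, with
#' \deqn{A = \begin{pmatrix} c^2 + s^2 - c b_p & (2 s / \omega - b_d) c \\
#'   (2 c - b_p) s \omega & c^2 + s^2 - s \omega b_d \end{pmatrix}}
#' where `c`, `s` are the [half_step_constants()]. A is identical for
#' progressive and alternating stepping and does not involve `b_o`.
#'
#' @param params A [walker_params()].
#' @return A 2x2 numeric matrix.
#' @export
transition_matrix <- function(params) {
  stopifnot(inherits(params, "walker_params"))
  hs <- half_step_constants(params$omega, params$t_step)
  cc <- hs$c; ss <- hs$s; om <- params$omega
  matrix(c(cc^2 + ss^2 - cc * params$b_p, (2 * ss / om - params$b_d) * cc,
           (2 * cc - params$b_p) * ss * om, cc^2 + ss^2 - ss * om * params$b_d),
         2, 2, byrow = TRUE)
}

# Closed-form eigenvalues of a 2x2 matrix from trace and determinant.
.eig2 <- function(A) {
  tr <- A[1, 1] + A[2, 2]
  dt <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- tr^2 - 4 * dt
  if (disc >= 0) {
    r <- sqrt(disc)
    lam <- complex(real = c((tr + r) / 2, (tr - r) / 2), imaginary = c(0, 0))
  } else {
    r <- sqrt(-disc)
    lam <- complex(real = c(tr / 2, tr / 2), imaginary = c(r / 2, -r / 2))
  }
  list(values = lam, trace = tr, det = dt, disc = disc)
}

#' Spectral norm (largest absolute eigenvalue) of a 2x2 matrix
#'
#' Computed in closed form from the characteristic polynomial
#' `lambda^2 - trace lambda + det = 0`; for a complex pair the common
#' modulus is `sqrt(det)`. The periodic orbit is asymptotically stable
#' iff this value is below 1.
#'
#' @param A A 2x2 numeric matrix with finite entries.
#' @return A non-negative scalar.
#' @export
spectral_norm <- function(A) {
  if (!is.matrix(A) || !all(dim(A) == c(2, 2)) || !all(is.finite(A)))
    stop("`A` must be a finite 2x2 matrix")
  max(Mod(.eig2(A)$values))
}

#' Stability assessment of a walking system
#'
#' Builds the transition matrix, computes its eigenvalues and spectral
#' norm rho in closed form, and evaluates the three closed-form
#' inequalities delimiting the stability region:
#' `2 c - b_p > 0`, `2 s / omega - b_d < 0`, and
#' `b_d < b_p c / (omega s)`. The `stable` verdict uses the eigenvalue
#' criterion `rho < 1 - 1e-12`; points with `|rho - 1| <= 1e-12` are
#' flagged `marginal` and reported as not asymptotically stable. The
#' inequality flags are carried independently so the two criteria can be
#' cross-checked.
#'
#' @param params A [walker_params()].
#' @return An object of class `stability_report`: list with `A`, `trace`,
#'   `det`, `eigenvalues` (complex pair), `rho`, `inequalities` (named
#'   logical vector of the three conditions), `stable`, `marginal`, and
#'   the `params`.
#' @export
stability_report <- function(params) {
  stopifnot(inherits(params, "walker_params"))
  A <- transition_matrix(params)
  e <- .eig2(A)
  rho <- max(Mod(e$values))
  hs <- half_step_constants(params$omega, params$t_step)
  ineq <- c(bp_below_2c   = 2 * hs$c - params$b_p > 0,
            bd_above_2s_w = 2 * hs$s / params$omega - params$b_d < 0,
            bd_below_line = params$b_d < params$b_p * hs$c / (params$omega * hs$s))
  tol <- 1e-12
  structure(list(A = A, trace = e$trace, det = e$det,
                 eigenvalues = e$values, rho = rho,
                 inequalities = ineq,
                 stable = rho < 1 - tol,
                 marginal = abs(rho - 1) <= tol,
                 params = params),
            class = "stability_report")
}

#' Is a walking system asymptotically stable?
#'
#' Convenience wrapper around [stability_report()] returning just the
#' eigenvalue-criterion verdict.
#'
#' @param params A [walker_params()].
#' @return `TRUE` iff the spectral norm of the transition matrix is below
#'   1 (with tolerance 1e-12).
#' @export
is_stable <- function(params) stability_report(params)$stable

#' @export
print.stability_report <- function(x, ...) {
  cat("Step-to-step stability report\n")
  cat(sprintf("  A = [%.6g %.6g; %.6g %.6g]\n", x$A[1, 1], x$A[1, 2],
              x$A[2, 1], x$A[2, 2]))
  cat(sprintf("  trace = %.6g, det = %.6g\n", x$trace, x$det))
  ev <- x$eigenvalues
  cat(sprintf("  eigenvalues: %.6g%+.6gi, %.6g%+.6gi\n",
              Re(ev[1]), Im(ev[1]), Re(ev[2]), Im(ev[2])))
  cat(sprintf("  spectral norm rho = %.6g\n", x$rho))
  cat(sprintf("  inequalities: b_p < 2c: %s; b_d > 2s/omega: %s; b_d < b_p c/(omega s): %s\n",
              x$inequalities[1], x$inequalities[2], x$inequalities[3]))
  cat(sprintf("  verdict: %s%s\n",
              if (x$stable) "stable" else "not asymptotically stable",
              if (x$marginal) " (marginal, rho = 1)" else ""))
  invisible(x)
}

#' Vertices of the triangular stability region
#'
#' The stable gain pairs (b_p, b_d) form a triangle bounded by the lines
#' `b_p = 2c`, `b_d = 2s/omega` and `b_d = b_p c / (omega s)`. The
#' pairwise intersections are returned in closed form:
#' `(2 s^2 / c, 2 s / omega)`, `(2 c, 2 s / omega)` and
#' `(2 c, 2 c^2 / (omega s))`. On each boundary line the spectral norm is
#' exactly 1.
#'
#' @param omega Eigenfrequency, s^-1.
#' @param t_step Step duration, s.
#' @return A 3x2 matrix with columns `b_p`, `b_d`.
#' @export
region_vertices <- function(omega, t_step) {
  hs <- half_step_constants(omega, t_step)
  cc <- hs$c; ss <- hs$s
  m <- matrix(c(2 * ss^2 / cc, 2 * ss / omega,
                2 * cc,        2 * ss / omega,
                2 * cc,        2 * cc^2 / (omega * ss)),
              nrow = 3, byrow = TRUE)
  colnames(m) <- c("b_p", "b_d")
  m
}

#' Sample the spectral norm over a gain grid
#'
#' Evaluates rho(A) on a rectangular (b_p, b_d) grid in closed form, for
#' heatmap rendering of the stability region. The default ranges and
#' resolution comfortably resolve the triangle for typical human
#' parameters.
#'
#' @param omega Eigenfrequency, s^-1.
#' @param t_step Step duration, s.
#' @param bp_range,bd_range Length-2 numeric ranges for the two gains.
#' @param resolution Number of grid points per axis (length 1 or 2,
#'   >= 2); defaults to 351 x 161.
#' @return An object of class `stability_region`: list with `grid`
#'   (data.frame `b_p`, `b_d`, `rho`, `stable`), `vertices`,
#'   `bp_interval`, `bd_interval`, `omega`, `t_step`.
#' @export
region_grid <- function(omega, t_step, bp_range = c(0, 3.5),
                        bd_range = c(0, 1.6), resolution = c(351L, 161L)) {
  if (length(resolution) == 1L) resolution <- rep(resolution, 2L)
  if (any(resolution < 2L)) stop("`resolution` must be >= 2 per axis")
  if (diff(bp_range) <= 0 || diff(bd_range) <= 0)
    stop("grid ranges must be non-empty")
  hs <- half_step_constants(omega, t_step)
  cc <- hs$c; ss <- hs$s
  bp <- seq(bp_range[1], bp_range[2], length.out = resolution[1])
  bd <- seq(bd_range[1], bd_range[2], length.out = resolution[2])
  g <- expand.grid(b_p = bp, b_d = bd, KEEP.OUT.ATTRS = FALSE)
  # vectorized closed form: trace/determinant of A over the grid
  a11 <- cc^2 + ss^2 - cc * g$b_p
  a12 <- (2 * ss / omega - g$b_d) * cc
  a21 <- (2 * cc - g$b_p) * ss * omega
  a22 <- cc^2 + ss^2 - ss * omega * g$b_d
  tr <- a11 + a22; dt <- a11 * a22 - a12 * a21
  disc <- tr^2 - 4 * dt
  rt <- sqrt(pmax(disc, 0))
  rho <- ifelse(disc >= 0, pmax(abs(tr + rt), abs(tr - rt)) / 2,
                sqrt(pmax(dt, 0)))
  g$rho <- rho
  g$stable <- rho < 1
  structure(list(grid = g, vertices = region_vertices(omega, t_step),
                 bp_interval = c(2 * ss^2 / cc, 2 * cc),
                 bd_interval = c(2 * ss / omega, 2 * cc^2 / (omega * ss)),
                 omega = omega, t_step = t_step),
            class = "stability_region")
}

#' @export
print.stability_region <- function(x, ...) {
  cat(sprintf("stability region (omega = %.4g, t_step = %.4g): %d grid points, %.1f%% stable\n",
              x$omega, x$t_step, nrow(x$grid), 100 * mean(x$grid$stable)))
  cat(sprintf("  b_p in [%.4g, %.4g], b_d in [%.4g, %.4g]\n",
              x$bp_interval[1], x$bp_interval[2],
              x$bd_interval[1], x$bd_interval[2]))
  invisible(x)
}

#' Stability-region limits as a function of cadence
#'
#' Converts cadences (steps per minute) to step times `t_step = 60 /
#' cadence` and returns the projections of the stability triangle onto
#' the two gain axes at each cadence: `b_p` in `[2 s^2 / c, 2 c]` and
#' `b_d` in `[2 s / omega, 2 c^2 / (omega s)]`. All four endpoints grow
#' as cadence decreases: slower-paced walking requires higher control
#' gains.
#'
#' @param omega Eigenfrequency, s^-1.
#' @param cadence_range Length-2 range of cadences, or a vector of
#'   cadences used as-is (steps per minute).
#' @param resolution Number of cadences when a range is given.
#' @return A data.frame with columns `cadence`, `t_step`, `bp_min`,
#'   `bp_max`, `bd_min`, `bd_max`.
#' @export
region_vs_cadence <- function(omega, cadence_range = c(60, 140),
                              resolution = 81L) {
  cad <- if (length(cadence_range) == 2L)
    seq(cadence_range[1], cadence_range[2], length.out = resolution)
  else as.numeric(cadence_range)
  if (any(cad <= 0)) stop("cadences must be positive")
  ts <- 60 / cad
  a <- omega * ts / 2
  cc <- cosh(a); ss <- sinh(a)
  data.frame(cadence = cad, t_step = ts,
             bp_min = 2 * ss^2 / cc, bp_max = 2 * cc,
             bd_min = 2 * ss / omega, bd_max = 2 * cc^2 / (omega * ss))
}

#' Constant-XCoM-offset (Hof) controller gains
#'
#' Placing each foot at a constant offset from the extrapolated center of
#' mass corresponds to the special case `b_p = c + s`,
#' `b_d = (c + s) / omega` of the PD foot-placement law. These gains lie
#' well inside the stability region; the transition matrix they produce
#' has near-zero determinant (one near-deadbeat eigenvalue).
#'
#' @param omega Eigenfrequency, s^-1.
#' @param t_step Step duration, s.
#' @return Named numeric vector `c(b_p = , b_d = )`.
#' @export
hof_gains <- function(omega, t_step) {
  hs <- half_step_constants(omega, t_step)
  c(b_p = hs$c + hs$s, b_d = (hs$c + hs$s) / omega)
}

#' Extrapolated center of mass (XCoM)
#'
#' The XCoM combines relative position and velocity into `q + v / omega`.
#' It is the basis of the Margin of Stability and of the constant-offset
#' foot-placement rule ([hof_gains()]).
#'
#' @param q Relative CoM position, m (vectorized).
#' @param v CoM velocity, m s^-1.
#' @param omega Eigenfrequency, s^-1 (> 0).
#' @return XCoM position relative to the contact point, m.
#' @export
xcom <- function(q, v, omega) {
  if (any(omega <= 0)) stop("`omega` must be positive")
  q + v / omega
}

#' Minimal recurrence period of the relative state
#'
#' Simulates the system from its periodic-orbit reference state with
#' exact closed-form propagation and returns the smallest sampled time
#' `t > 0` at which the relative state (q, v) returns to its initial
#' value within `tol`. For progressive stepping this is `t_step`; for
#' alternating stepping, `2 t_step` (the offset sign needs two steps to
#' come back around).
#'
#' @param params A [walker_params()].
#' @param tol Recurrence tolerance on both `q` (m) and `v` (m s^-1).
#' @param dt Sampling interval for the recurrence scan, s.
#' @param horizon_steps Number of steps to scan.
#' @return The minimal recurrence time, s.
#' @export
recurrence_period <- function(params, tol = 1e-6, dt = 0.005,
                              horizon_steps = 6L) {
  ref <- periodic_orbit(params)
  traj <- simulate_walker(params, n_steps = horizon_steps, dt = dt)
  s <- traj$samples
  hit <- s$t > dt / 2 & abs(s$q - ref$q) < tol & abs(s$v - ref$v) < tol
  if (!any(hit)) stop("no recurrence detected within the scanned horizon")
  s$t[which(hit)[1]]
}
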
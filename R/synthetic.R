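# Synthetic gait generation: noisy walkers, perturbation experiments, and
# the packaged fixture registry.

#' Noise specification for synthetic gait
#'
#' Per-step motor noise is additive Gaussian on the realized foot
#' placement (standard deviation `sigma_p`); optional sensory noise
#' perturbs only the controller's inputs (the sensed midstance `q` and
#' `v`), never the recorded true state. Each channel draws from its own
#' seeded stream, so toggling sensory noise does not shift the motor
#' draws. Zero standard deviations reproduce the deterministic system
#' exactly.
#'
#' @param sigma_p Motor noise s.d. on foot placement, m.
#' @param sigma_sense_q Sensory noise s.d. on sensed position, m.
#' @param sigma_sense_v Sensory noise s.d. on sensed velocity, m s^-1.
#' @param seed Integer seed; identical seed and spec give a
#'   bitwise-identical dataset.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_p = 0, sigma_sense_q = 0, sigma_sense_v = 0,
                       seed = 1L) {
  sds <- c(sigma_p, sigma_sense_q, sigma_sense_v)
  if (!all(is.finite(sds)) || any(sds < 0))
    stop("noise standard deviations must be finite and >= 0")
  structure(list(sigma_p = sigma_p, sigma_sense_q = sigma_sense_q,
                 sigma_sense_v = sigma_sense_v, seed = as.integer(seed)),
            class = "noise_spec")
}

# Evaluate a function with a temporary RNG state, restoring the caller's.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic noisy walk
#'
#' Iterates the exact step-to-step dynamics from the deterministic
#' periodic orbit, adding per-step Gaussian motor noise to the realized
#' foot placement (and, optionally, sensory noise to the state the
#' controller sees). The recorded true states always satisfy the
#' closed-form between-step dynamics exactly; noise enters only through
#' the designated channels. The resulting step table has the statistical
#' structure the gain-estimation regression assumes: midstance state
#' linearly driving the next placement plus independent placement noise.
#'
#' For unstable parameters the walk may diverge; generation aborts with a
#' divergence error (condition class `walkstab_divergence`) reporting the
#' step reached once `|q|` exceeds `q_bound`.
#'
#' @param params A [walker_params()].
#' @param noise A [noise_spec()].
#' @param n_steps Number of steps to generate (>= 2).
#' @param q_bound Divergence guard on the relative position, m.
#' @return A `step_table` data.frame (columns as in
#'   [collect_step_table()]) with attributes `mode`, `t_step`, `params`,
#'   `noise`.
#' @export
generate_noisy_walk <- function(params, noise = noise_spec(), n_steps,
                                q_bound = 10) {
  stopifnot(inherits(params, "walker_params"), inherits(noise, "noise_spec"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("`n_steps` must be >= 2")
  eps <- .with_seed(noise$seed, stats::rnorm(n_steps)) * noise$sigma_p
  eta <- .with_seed(noise$seed + 1L, {
    list(q = stats::rnorm(n_steps), v = stats::rnorm(n_steps))
  })
  eta_q <- eta$q * noise$sigma_sense_q
  eta_v <- eta$v * noise$sigma_sense_v

  ref <- periodic_orbit(params)
  q <- ref$q; v <- ref$v; p <- 0
  out <- data.frame(n = 0:(n_steps - 1L),
                    t_mid = (0:(n_steps - 1L)) * params$t_step,
                    q = NA_real_, v = NA_real_, p = NA_real_,
                    p_next = NA_real_, delta_p = NA_real_,
                    parity = (-1)^(0:(n_steps - 1L)))
  for (i in seq_len(n_steps)) {
    st <- .step_once(params, q, v, i - 1L,
                     eps = eps[i], eta_q = eta_q[i], eta_v = eta_v[i])
    out$q[i] <- q; out$v[i] <- v; out$p[i] <- p
    out$p_next[i] <- p + st$dp; out$delta_p[i] <- st$dp
    q <- st$q; v <- st$v; p <- p + st$dp
    if (!is.finite(q) || abs(q) > q_bound)
      stop(structure(class = c("walkstab_divergence", "error", "condition"),
                     list(message = sprintf(
                       "walk diverged at step %d (|q| > %g m); parameters are likely unstable",
                       i, q_bound), call = sys.call(-1))))
  }
  structure(out, class = c("step_table", "data.frame"),
            mode = params$mode, t_step = params$t_step,
            params = params, noise = noise)
}

#' Perturbation experiment across parameter sets
#'
#' Replicates the canonical perturbation protocol: each system starts on
#' the (shared) periodic orbit, an instantaneous perturbation is applied
#' at a stated time, and the deviation of the midstance state from the
#' parity-aware reference is tracked at every subsequent midstance. All
#' parameter sets must share the same reference state (for alternating
#' stepping the reference is independent of `b_d`, so a derivative-gain
#' sweep qualifies).
#'
#' @param params_list A list of [walker_params()].
#' @param perturbation A [perturbation_event()].
#' @param horizon Total simulated time, s.
#' @param dt Sampling interval passed to the simulator, s.
#' @return A data.frame with columns `system` (index into
#'   `params_list`), `b_p`, `b_d`, `n`, `t_mid`, `dev` (Euclidean norm of
#'   the midstance deviation), with the parameter list attached as
#'   attribute `params_list`.
#' @export
perturbation_experiment <- function(params_list, perturbation, horizon,
                                    dt = 0.01) {
  stopifnot(is.list(params_list), length(params_list) >= 1L,
            inherits(perturbation, "perturbation_event"))
  refs <- lapply(params_list, periodic_orbit)
  r0 <- refs[[1]]
  same <- vapply(refs, function(r)
    abs(r$q - r0$q) < 1e-12 && abs(r$v - r0$v) < 1e-12, TRUE)
  if (!all(same))
    stop("all parameter sets must share the same periodic-orbit reference state")
  out <- vector("list", length(params_list))
  for (i in seq_along(params_list)) {
    pp <- params_list[[i]]
    n_steps <- ceiling(horizon / pp$t_step)
    traj <- simulate_walker(pp, n_steps = n_steps, dt = dt,
                            perturbations = list(perturbation))
    m <- traj$midstances
    rf <- reference_state(pp, m$n)
    out[[i]] <- data.frame(system = i, b_p = pp$b_p, b_d = pp$b_d,
                           n = m$n, t_mid = m$t,
                           dev = sqrt((m$q - rf$q)^2 + (m$v - rf$v)^2))
  }
  structure(do.call(rbind, out), params_list = params_list)
}

#' Packaged synthetic fixtures
#'
#' A small registry of deterministic, seed-pinned synthetic datasets used
#' in tests and documentation:
#' \describe{
#'   \item{`"stable-noisy-small"`}{200 steps of the alternating example
#'     walker (omega = 3.13, b_o = 0.02, b_p = 2.5, b_d = 0.6,
#'     t_step = 0.5) with motor noise sigma_p = 0.01 m, seed 1. Shipped
#'     as a CSV in `inst/extdata/`.}
#'   \item{`"hof-walker"`}{2000 steps of an alternating walker using the
#'     constant-XCoM-offset gains ([hof_gains()]), sigma_p = 0.01 m,
#'     seed 2. Regenerated on demand (too long to ship as text).}
#'   \item{`"perturbation-quartet"`}{Deviation series of the derivative-gain
#'     quartet b_d in {0.3, 0.6, 1.1, 1.5} under a +1 cm position
#'     perturbation at t = 1 s, horizon 10 s. Shipped as a CSV.}
#' }
#' Every fixture is a pure function of its registered parameters and
#' seed, so the shipped CSVs can be regenerated bit-identically.
#'
#' @param name Fixture name (see above).
#' @return A list with elements `name`, `data` (data.frame) and `config`
#'   (the generating parameters).
#' @export
fixture_dataset <- function(name) {
  switch(name,
    "stable-noisy-small" = {
      pp <- walker_params(omega = 3.13, b_o = 0.02, b_p = 2.5, b_d = 0.6,
                          t_step = 0.5, mode = "alternating")
      ns <- noise_spec(sigma_p = 0.01, seed = 1L)
      list(name = name, data = generate_noisy_walk(pp, ns, n_steps = 200L),
           config = list(params = pp, noise = ns, n_steps = 200L))
    },
    "hof-walker" = {
      hg <- hof_gains(3.13, 0.5)
      pp <- walker_params(omega = 3.13, b_o = 0.02, b_p = hg[["b_p"]],
                          b_d = hg[["b_d"]], t_step = 0.5,
                          mode = "alternating")
      ns <- noise_spec(sigma_p = 0.01, seed = 2L)
      list(name = name, data = generate_noisy_walk(pp, ns, n_steps = 2000L),
           config = list(params = pp, noise = ns, n_steps = 2000L))
    },
    "perturbation-quartet" = {
      pl <- lapply(c(0.3, 0.6, 1.1, 1.5), function(bd)
        walker_params(omega = 3.13, b_o = 0.02, b_p = 2.5, b_d = bd,
                      t_step = 0.5, mode = "alternating"))
      pe <- perturbation_event(time = 1, dx = 0.01)
      list(name = name,
           data = perturbation_experiment(pl, pe, horizon = 10),
           config = list(params_list = pl, perturbation = pe, horizon = 10))
    },
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 "stable-noisy-small, hof-walker, perturbation-quartet"))
  )
}
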
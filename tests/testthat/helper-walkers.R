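# Shared example walkers and random-parameter generator for the suite.

example_progressive <- function(b_d = 0.6)
  walker_params(omega = 3.13, b_o = -0.05, b_p = 2.5, b_d = b_d,
                t_step = 0.5, mode = "progressive")

example_alternating <- function(b_d = 0.6, b_p = 2.5, b_o = 0.02)
  walker_params(omega = 3.13, b_o = b_o, b_p = b_p, b_d = b_d,
                t_step = 0.5, mode = "alternating")

# Uniformly random parameter tuples covering both modes and a broad range
# of gains, step times and eigenfrequencies.
random_params <- function(n, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    walker_params(omega = runif(1, 2, 5),
                  b_o = runif(1, -0.1, 0.1),
                  b_p = runif(1, 0, 4),
                  b_d = runif(1, 0, 2),
                  t_step = runif(1, 0.3, 1.0),
                  mode = sample(c("progressive", "alternating"), 1)))
}

# Central finite-difference Jacobian of the midstance map at a state.
fd_jacobian <- function(params, q0, v0, h = 1e-6) {
  f <- function(q, v) {
    m <- midstance_map(params, midstance_state(q, v, 0L))
    c(m$q, m$v)
  }
  cbind((f(q0 + h, v0) - f(q0 - h, v0)) / (2 * h),
        (f(q0, v0 + h) - f(q0, v0 - h)) / (2 * h))
}
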
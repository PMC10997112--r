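# Periodic orbits, transition matrix, spectral norm, stability region.

test_that("periodic orbit closed forms match the step-to-step recurrence", {
  pp <- example_progressive()
  rp <- periodic_orbit(pp)
  expect_equal(rp$q, 0)
  expect_equal(rp$v, 1.0551, tolerance = 1e-4)
  m <- midstance_map(pp, rp)
  expect_equal(c(m$q, m$v), c(rp$q, rp$v), tolerance = 1e-9)

  pa <- example_alternating()
  ra <- periodic_orbit(pa)
  expect_equal(ra$q, 0.13870, tolerance = 1e-4)
  expect_equal(ra$v, 0)
  one <- midstance_map(pa, ra)
  expect_equal(c(one$q, one$v), c(-ra$q, ra$v), tolerance = 1e-9) # parity flip
  two <- midstance_map(pa, one)
  expect_equal(c(two$q, two$v), c(ra$q, ra$v), tolerance = 1e-9)

  # zero offset puts the orbit at rest for either mode
  for (mode in c("progressive", "alternating")) {
    p0 <- walker_params(omega = 3.13, b_o = 0, b_p = 2.5, b_d = 0.6,
                        t_step = 0.5, mode = mode)
    r0 <- periodic_orbit(p0)
    expect_equal(c(r0$q, r0$v), c(0, 0))
  }
})

test_that("degenerate orbit denominators raise a singular-orbit error", {
  hs <- half_step_constants(3.13, 0.5)
  bad_prog <- walker_params(omega = 3.13, b_o = -0.05, b_p = 2.5,
                            b_d = 2 * hs$s / 3.13, t_step = 0.5,
                            mode = "progressive")
  expect_error(periodic_orbit(bad_prog), class = "walkstab_singular_orbit")
  bad_alt <- walker_params(omega = 3.13, b_o = 0.02, b_p = 2 * hs$c,
                           b_d = 0.6, t_step = 0.5, mode = "alternating")
  expect_error(periodic_orbit(bad_alt), class = "walkstab_singular_orbit")
})

test_that("orbit recurrence periods are t_step (progressive) and 2 t_step (alternating)", {
  expect_equal(recurrence_period(example_progressive()), 0.5)
  expect_equal(recurrence_period(example_alternating()), 1.0)
})

test_that("transition matrix boundary identities hold exactly", {
  hs <- half_step_constants(3.13, 0.5)
  # b_p = 2c: one eigenvalue exactly -1
  A1 <- transition_matrix(walker_params(omega = 3.13, b_p = 2 * hs$c,
                                        b_d = 0.7, t_step = 0.5))
  expect_equal(A1[2, 1], 0)
  expect_equal(min(Re(eigen(A1)$values)), -1, tolerance = 1e-12)
  # b_d = 2s/omega: one eigenvalue exactly +1
  A2 <- transition_matrix(walker_params(omega = 3.13, b_p = 1.8,
                                        b_d = 2 * hs$s / 3.13, t_step = 0.5))
  expect_equal(A2[1, 2], 0)
  expect_equal(max(Re(eigen(A2)$values)), 1, tolerance = 1e-12)
})

test_that("transition matrix equals the FD Jacobian over a random sweep and ignores b_o and mode", {
  for (params in random_params(25, seed = 7L)) {
    ref <- tryCatch(periodic_orbit(params), error = function(e) NULL)
    if (is.null(ref)) next
    expect_equal(fd_jacobian(params, ref$q, ref$v),
                 transition_matrix(params), tolerance = 1e-6)
  }
  base <- example_alternating()
  for (b_o in c(-0.2, 0, 0.1)) {
    for (mode in c("progressive", "alternating")) {
      pp <- walker_params(omega = 3.13, b_o = b_o, b_p = 2.5, b_d = 0.6,
                          t_step = 0.5, mode = mode)
      expect_identical(transition_matrix(pp), transition_matrix(base))
      expect_identical(stability_report(pp)$stable,
                       stability_report(base)$stable)
    }
  }
})

test_that("spectral norm handles real and complex spectra in closed form", {
  expect_equal(spectral_norm(diag(2)), 1)
  expect_equal(spectral_norm(matrix(c(0, -2, 2, 0), 2)), 2) # complex pair
  # derivative-gain quartet around the example walker
  rho <- function(b_d) spectral_norm(transition_matrix(example_alternating(b_d)))
  expect_equal(rho(0.3), 1.735, tolerance = 1e-3)
  expect_equal(rho(0.6), 0.857, tolerance = 1e-3)
  expect_equal(rho(1.5), 1.3248, tolerance = 1e-3)
  A <- transition_matrix(example_alternating(1.5))
  e <- eigen(A)$values
  expect_true(all(Im(e) != 0)) # oscillatory divergence
})

test_that("stability verdicts match the published quartet and mark boundaries marginal", {
  expect_true(is_stable(example_alternating(0.6)))
  expect_true(is_stable(example_alternating(1.1)))
  expect_false(is_stable(example_alternating(0.3)))
  expect_false(is_stable(example_alternating(1.5)))
  hs <- half_step_constants(3.13, 0.5)
  marg <- stability_report(walker_params(omega = 3.13, b_p = 2 * hs$c,
                                         b_d = 0.7, t_step = 0.5))
  expect_false(marg$stable)
  expect_true(marg$marginal)
})

test_that("inequality criterion is equivalent to the eigenvalue criterion", {
  set.seed(11)
  n <- 4000
  om <- runif(n, 2, 5); ts <- runif(n, 0.3, 1.0)
  bp <- runif(n, 0, 4); bd <- runif(n, 0, 2)
  for (i in seq_len(n)) {
    pp <- walker_params(omega = om[i], b_p = bp[i], b_d = bd[i],
                        t_step = ts[i])
    rep <- stability_report(pp)
    if (abs(rep$rho - 1) < 1e-6) next # boundary excluded
    expect_identical(all(rep$inequalities), rep$rho < 1)
  }
})

test_that("region vertices sit on the boundary with spectral norm exactly 1", {
  V <- region_vertices(3.13, 0.5)
  expect_equal(unname(V[1, ]), c(1.1314, 0.5526), tolerance = 1e-4)
  expect_equal(unname(V[2, ]), c(2.6442, 0.5526), tolerance = 1e-4)
  expect_equal(unname(V[3, ]), c(2.6442, 1.2915), tolerance = 1e-4)
  for (i in 1:3) {
    pp <- walker_params(omega = 3.13, b_p = V[i, 1], b_d = V[i, 2],
                        t_step = 0.5)
    expect_equal(spectral_norm(transition_matrix(pp)), 1, tolerance = 1e-9)
  }
  # degenerate-step-time limit: the bottom edge collapses onto the b_p
  # axis between 0 and 2, while the apex b_d = 2c^2/(omega s) diverges
  Vt <- region_vertices(3.13, 1e-4)
  expect_equal(unname(Vt[1, ]), c(0, 0), tolerance = 1e-3)
  expect_equal(unname(Vt[2, ]), c(2, 0), tolerance = 1e-3)
  expect_gt(Vt[3, "b_d"], 1e3)
})

test_that("grid stability agrees with the triangle geometry", {
  reg <- region_grid(3.13, 0.5, resolution = c(71L, 41L))
  V <- reg$vertices
  # barycentric point-in-triangle test, strict interior/exterior margin
  inside <- function(bp, bd, margin) {
    s1 <- bp - V[2, 1]                       # right of b_p = 2c line
    s2 <- V[1, 2] - bd                       # below b_d = 2s/omega line
    hs <- half_step_constants(3.13, 0.5)
    s3 <- bd - bp * hs$c / (3.13 * hs$s)     # above the diagonal line
    all(c(s1, s2, s3) < -margin)
  }
  g <- reg$grid
  margin <- 0.02
  for (k in seq_len(nrow(g))) {
    if (inside(g$b_p[k], g$b_d[k], margin)) expect_lt(g$rho[k], 1)
  }
  out <- !vapply(seq_len(nrow(g)), function(k)
    inside(g$b_p[k], g$b_d[k], -margin), TRUE)
  expect_true(all(g$rho[out] >= 1 - 1e-9))
  # single-point grid at the canonical example gains is stable
  one <- region_grid(3.13, 0.5, bp_range = c(2.5, 2.5 + 1e-9),
                     bd_range = c(0.6, 0.6 + 1e-9), resolution = 2L)
  expect_true(all(one$grid$stable))
})

test_that("Hof constant-XCoM-offset gains are feasible with near-deadbeat response", {
  hg <- hof_gains(3.13, 0.5)
  expect_equal(unname(hg), c(2.1869, 0.6987), tolerance = 1e-4)
  for (ts in seq(0.3, 1.0, by = 0.05)) {
    h <- hof_gains(3.13, ts)
    rep <- stability_report(walker_params(omega = 3.13, b_p = h[["b_p"]],
                                          b_d = h[["b_d"]], t_step = ts))
    expect_true(all(rep$inequalities))
    expect_true(rep$stable)
  }
  rep5 <- stability_report(walker_params(omega = 3.13, b_p = hg[["b_p"]],
                                         b_d = hg[["b_d"]], t_step = 0.5))
  expect_equal(rep5$det, 0, tolerance = 1e-12)
  # a fine grid can do no better than reach the Hof point's rho continuously
  reg <- region_grid(3.13, 0.5, resolution = c(141L, 81L))
  expect_lte(min(reg$grid$rho), rep5$rho)
})

test_that("XCoM is q + v/omega and constant along an escaping asymptote", {
  expect_equal(xcom(0.3, 0, 3.13), 0.3)
  expect_equal(xcom(0, 3.13, 3.13), 1)
  # on the invariant line v = -omega q the XCoM stays fixed over time
  om <- 3.13
  q0 <- 0.1; v0 <- -om * q0
  st <- pendulum_state(x = q0, v = v0, p = 0)
  for (dtau in c(0.1, 0.4, 0.9)) {
    pr <- propagate_state(st, dtau, om)
    expect_equal(xcom(pr$x - pr$p, pr$v, om), 0, tolerance = 1e-12)
  }
})

test_that("stability-region limits shift to higher gains at lower cadence", {
  sw <- region_vs_cadence(3.13, c(60, 140), resolution = 41L)
  # three endpoints decrease monotonically as cadence increases
  for (col in c("bp_min", "bp_max", "bd_min"))
    expect_true(all(diff(sw[[col]]) < 0))
  # the upper b_d limit 2c^2/(omega s) is unimodal: it dips at the cadence
  # where omega * t_step / 2 = asinh(1) and rises on either side
  cad_star <- 60 * 3.13 / (2 * asinh(1))
  i_min <- which.min(sw$bd_max)
  expect_equal(sw$cadence[i_min], cad_star, tolerance = 0.02)
  expect_true(all(diff(sw$bd_max[sw$cadence <= cad_star]) < 0))
  expect_true(all(diff(sw$bd_max[sw$cadence > cad_star + 2]) > 0))
  expect_gt(sw$bd_max[1], sw$bd_max[nrow(sw)])  # still higher at 60 than 140
  at120 <- region_vs_cadence(3.13, 120)
  expect_equal(at120$bd_min, 0.5526, tolerance = 1e-4)
  expect_equal(at120$bd_max, 1.2915, tolerance = 1e-4)
  expect_equal(at120$t_step, 0.5)
  # single-cadence query consistent with the vertex closed forms
  V <- region_vertices(3.13, 0.5)
  expect_equal(at120$bp_min, unname(V[1, "b_p"]))
  expect_equal(at120$bp_max, unname(V[2, "b_p"]))
})

test_that("stability triangle grows with leg length at fixed step time", {
  area <- function(l) {
    V <- region_vertices(eigenfrequency_from_leg_length(l), 0.5)
    abs((V[2, 1] - V[1, 1]) * (V[3, 2] - V[2, 2])) / 2
  }
  ls <- seq(0.7, 1.3, by = 0.1)
  expect_true(all(diff(vapply(ls, area, 0)) > 0))
})
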
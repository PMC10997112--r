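# Regression-based estimation of the foot-placement control gains from
# step-level gait data.

#' Build a step table from a trajectory
#'
#' Extracts one record per completed step from a simulated trajectory:
#' the exact midstance state (closed-form, not nearest-sample
#' interpolation), the contact point of the step, the next foot
#' placement, and their difference `delta_p = p_next - p`. These are the
#' data the gain-estimation regression consumes. A simulation over `N`
#' step periods yields `N` records (midstances `0 .. N-1`, each paired
#' with the placement that follows it).
#'
#' @param traj A `walker_trajectory` from [simulate_walker()].
#' @return A data.frame of class `step_table` with columns `n`, `t_mid`,
#'   `q`, `v`, `p`, `p_next`, `delta_p`, `parity`; the generating `mode`
#'   and `t_step` are attached as attributes.
#' @export
collect_step_table <- function(traj) {
  stopifnot(inherits(traj, "walker_trajectory"))
  n_steps <- nrow(traj$step_events)
  if (n_steps < 2L) stop("insufficient data: trajectory must contain at least 2 steps")
  m <- traj$midstances[seq_len(n_steps), ]
  tab <- data.frame(n = m$n, t_mid = m$t, q = m$q, v = m$v, p = m$p,
                    p_next = traj$step_events$p_new,
                    delta_p = traj$step_events$p_new - m$p,
                    parity = (-1)^m$n)
  structure(tab, class = c("step_table", "data.frame"),
            mode = traj$params$mode, t_step = traj$params$t_step)
}

.as_step_table <- function(table) {
  need <- c("n", "q", "v", "delta_p", "parity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("step table lacks column(s): ", paste(miss, collapse = ", "))
  table
}

# Fit delta_p on a chosen set of regressors, with a parity term for
# alternating data; errors on rank deficiency naming the aliased columns.
.fit_gains <- function(table, mode, predictors) {
  df <- data.frame(delta_p = table$delta_p, q = table$q, v = table$v,
                   parity = table$parity)
  terms <- c(if (mode == "alternating") "parity", predictors)
  fml <- stats::reformulate(terms, response = "delta_p")
  fit <- stats::lm(fml, data = df)
  co <- stats::coef(fit)
  if (anyNA(co))
    stop(structure(class = c("walkstab_singular_design", "error", "condition"),
                   list(message = paste0("singular regression design; collinear or constant column(s): ",
                                         paste(names(co)[is.na(co)], collapse = ", ")),
                        call = sys.call(-1))))
  fit
}

#' Estimate foot-placement control gains by linear regression
#'
#' Ordinary least squares of the step-to-step placement displacement
#' `delta_p` on the midstance state: `delta_p ~ q + v` for progressive
#' data, `delta_p ~ parity + q + v` for alternating data (the explicit
#' parity regressor absorbs the sign-flipping offset, and its coefficient
#' estimates `b_o`). Under the generating control law the slopes on `q`
#' and `v` identify the gains `b_p` and `b_d` directly; with additive
#' motor noise on the realized placement the estimator is unbiased and
#' consistent.
#'
#' Adjusted R-squared is the headline fit diagnostic; single-predictor
#' adjusted R-squared values (position only, velocity only) are computed
#' alongside via [single_predictor_r2()].
#'
#' @param table A `step_table` (from [collect_step_table()],
#'   [generate_noisy_walk()] or [read_step_table_csv()]).
#' @param mode Stepping mode of the data; defaults to the table's `mode`
#'   attribute.
#' @return An object of class `gain_estimate`: list with `bp_hat`,
#'   `bd_hat`, `bo_hat`, `intercept`, `se_bp`, `se_bd`, `r2_adj`,
#'   `r2_q_only`, `r2_v_only`, `n_steps`, `mode`.
#' @export
estimate_gains <- function(table, mode = attr(table, "mode")) {
  table <- .as_step_table(table)
  if (is.null(mode)) stop("`mode` is required when the table carries no mode attribute")
  mode <- match.arg(mode, c("progressive", "alternating"))
  n <- nrow(table)
  n_min <- if (mode == "alternating") 4L else 3L
  if (n < n_min)
    stop(sprintf("insufficient data: need at least %d steps for %s-mode estimation", n_min, mode))
  fit <- .fit_gains(table, mode, c("q", "v"))
  sm <- summary(fit)
  co <- sm$coefficients
  r2s <- single_predictor_r2(table, mode)
  structure(list(bp_hat = co["q", "Estimate"],
                 bd_hat = co["v", "Estimate"],
                 bo_hat = if (mode == "alternating") co["parity", "Estimate"]
                          else co["(Intercept)", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 se_bp = co["q", "Std. Error"],
                 se_bd = co["v", "Std. Error"],
                 r2_adj = sm$adj.r.squared,
                 r2_q_only = r2s[["r2_q_only"]],
                 r2_v_only = r2s[["r2_v_only"]],
                 n_steps = n, mode = mode),
            class = "gain_estimate")
}

#' @export
print.gain_estimate <- function(x, ...) {
  cat(sprintf("Foot-placement gain estimates (%s stepping, n = %d steps)\n",
              x$mode, x$n_steps))
  cat(sprintf("  b_p = %.4f (SE %.4f)\n  b_d = %.4f (SE %.4f)\n  b_o = %.5f\n",
              x$bp_hat, x$se_bp, x$bd_hat, x$se_bd, x$bo_hat))
  cat(sprintf("  adjusted R^2 = %.4f (q only: %.4f, v only: %.4f)\n",
              x$r2_adj, x$r2_q_only, x$r2_v_only))
  invisible(x)
}

#' Single-predictor fit diagnostics
#'
#' Adjusted R-squared of the reduced regressions that use only the
#' midstance position `q` or only the velocity `v` as predictor (plus
#' intercept, and the parity term for alternating data). Comparing these
#' with the full-model adjusted R-squared shows how much explanatory
#' power each state variable carries on its own.
#'
#' @inheritParams estimate_gains
#' @return Named list `r2_q_only`, `r2_v_only`.
#' @export
single_predictor_r2 <- function(table, mode = attr(table, "mode")) {
  table <- .as_step_table(table)
  if (is.null(mode)) stop("`mode` is required when the table carries no mode attribute")
  mode <- match.arg(mode, c("progressive", "alternating"))
  list(r2_q_only = summary(.fit_gains(table, mode, "q"))$adj.r.squared,
       r2_v_only = summary(.fit_gains(table, mode, "v"))$adj.r.squared)
}
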
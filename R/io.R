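# CSV serialization with fixed schemas and provenance headers.

# Column schemas; all units are SI and carried in the column names.
.schemas <- list(
  trajectory = c("t_s", "x_m", "v_mps", "p_m", "q_m", "step_idx"),
  step_table = c("n", "t_mid_s", "q_m", "v_mps", "p_m", "p_next_m",
                 "delta_p_m", "parity"),
  region     = c("b_p", "b_d", "rho", "stable"),
  sweep      = c("cadence_spm", "t_step_s", "bp_min", "bp_max",
                 "bd_min", "bd_max")
)

# Provenance header: '#'-prefixed key-value lines before the CSV header.
.provenance_lines <- function(extra = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("walkstab")),
                  error = function(e) "unknown")
  c(sprintf("# walkstab %s", ver),
    if (length(extra)) paste0("# ", names(extra), " = ",
                              vapply(extra, format, "")))
}

.write_schema_csv <- function(df, path, schema, extra = NULL, digits = 15L) {
  cols <- .schemas[[schema]]
  stopifnot(ncol(df) == length(cols))
  names(df) <- cols
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf(paste0("%.", digits, "g"), x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(extra), con)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_schema_csv <- function(path, schema) {
  cols <- .schemas[[schema]]
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "character")
  miss <- setdiff(cols, names(df))
  extra <- setdiff(names(df), cols)
  if (length(miss) || length(extra))
    stop(sprintf("%s schema mismatch in '%s'%s%s", schema, path,
                 if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")) else "",
                 if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""))
  df <- df[cols]
  # locale-independent numeric parsing: as.numeric always uses '.'
  df[] <- lapply(df, as.numeric)
  df
}

#' Write / read a trajectory CSV
#'
#' Columns `t_s, x_m, v_mps, p_m, q_m, step_idx` with a `#`-prefixed
#' provenance header. Numeric values are written with 15 significant
#' digits, so a round trip is lossless well beyond 12 significant
#' digits.
#'
#' @param traj A `walker_trajectory`.
#' @param path Output/input file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns the samples data.frame with columns
#'   `t`, `x`, `v`, `p`, `q`, `step_idx`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "walker_trajectory"))
  pp <- traj$params
  .write_schema_csv(traj$samples, path, "trajectory",
                    extra = list(omega = pp$omega, b_o = pp$b_o,
                                 b_p = pp$b_p, b_d = pp$b_d,
                                 t_step = pp$t_step, mode = pp$mode))
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- .read_schema_csv(path, "trajectory")
  names(df) <- c("t", "x", "v", "p", "q", "step_idx")
  df$step_idx <- as.integer(df$step_idx)
  df
}

#' Write / read a step-table CSV
#'
#' Columns `n, t_mid_s, q_m, v_mps, p_m, p_next_m, delta_p_m, parity`.
#' The stepping mode is recorded in the provenance header and restored
#' as the table's `mode` attribute on read.
#'
#' @param table A `step_table`.
#' @param path Output/input file path.
#' @param digits Significant digits for numeric formatting.
#' @return `write_step_table_csv` returns `path` invisibly;
#'   `read_step_table_csv` returns a `step_table`.
#' @export
write_step_table_csv <- function(table, path, digits = 15L) {
  table <- .as_step_table(table)
  cols <- c("n", "t_mid", "q", "v", "p", "p_next", "delta_p", "parity")
  .write_schema_csv(as.data.frame(table)[cols], path, "step_table",
                    extra = list(mode = attr(table, "mode") %||% "unknown",
                                 t_step = attr(table, "t_step") %||% NA),
                    digits = digits)
}

#' @rdname write_step_table_csv
#' @export
read_step_table_csv <- function(path) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_kv <- function(key) {
    ln <- grep(sprintf("^# %s = ", key), hdr, value = TRUE)
    if (length(ln)) sub(sprintf("^# %s = ", key), "", ln[1]) else NULL
  }
  df <- .read_schema_csv(path, "step_table")
  names(df) <- c("n", "t_mid", "q", "v", "p", "p_next", "delta_p", "parity")
  df$n <- as.integer(df$n)
  ts <- get_kv("t_step")
  structure(df, class = c("step_table", "data.frame"),
            mode = get_kv("mode"),
            t_step = if (!is.null(ts)) as.numeric(ts) else NULL)
}

#' Write a stability-region grid CSV
#'
#' Columns `b_p, b_d, rho, stable` (stable as 0/1), one row per grid
#' point.
#'
#' @param region A `stability_region` from [region_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(region, path) {
  stopifnot(inherits(region, "stability_region"))
  g <- region$grid
  g$stable <- as.integer(g$stable)
  .write_schema_csv(g, path, "region",
                    extra = list(omega = region$omega,
                                 t_step = region$t_step))
}

#' @rdname write_region_csv
#' @export
read_region_csv <- function(path) {
  df <- .read_schema_csv(path, "region")
  df$stable <- df$stable != 0
  df
}

#' Write a cadence-sweep CSV
#'
#' Columns `cadence_spm, t_step_s, bp_min, bp_max, bd_min, bd_max`, one
#' row per cadence.
#'
#' @param sweep A data.frame from [region_vs_cadence()].
#' @param path Output file path.
#' @param omega Eigenfrequency recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path, omega = NA) {
  .write_schema_csv(sweep, path, "sweep", extra = list(omega = omega))
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- .read_schema_csv(path, "sweep")
  names(df) <- c("cadence", "t_step", "bp_min", "bp_max", "bd_min", "bd_max")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
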
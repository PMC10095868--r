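#' Write a trajectory as CSV
#'
#' Canonical plain-text output: one row per time step with the fixed header
#' `time_s,cumulative_influx_um3,turgor_MPa,cell_volume_um3,creep_strain`.
#' Values are written with 17 significant digits so that reading the file
#' back reproduces every double bit-exactly.
#'
#' @param traj A `gc_trajectory` from [run_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "gc_trajectory"))
  lines <- c(
    "time_s,cumulative_influx_um3,turgor_MPa,cell_volume_um3,creep_strain",
    sprintf("%.17g,%.17g,%.17g,%.17g,%.17g",
            traj$t, traj$W, traj$p, traj$V_cell, traj$eps_c)
  )
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) stop(sprintf("cannot write %s: %s", path,
                                                   conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write run summary and resolved configuration as JSON
#'
#' Serializes the headline statistics under the documented keys
#' (`p_peak_MPa`, `t_peak_s`, `p_final_MPa`, `V_final_um3`,
#' `vol_increase_pct`) together with the full resolved configuration echo, so
#' the run can be reproduced from this file alone.
#'
#' @param stats A `gc_summary` from [summarize_trajectory()].
#' @param config_echo Resolved configuration list (the `echo` element
#'   returned by [load_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(stats, config_echo, path) {
  stopifnot(inherits(stats, "gc_summary"))
  payload <- list(
    p_peak_MPa = stats$p_peak,
    t_peak_s = stats$t_peak,
    p_final_MPa = stats$p_final,
    V_final_um3 = stats$V_final,
    vol_increase_pct = stats$vol_increase_pct,
    config = config_echo
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

# Leveled, timestamped logging to standard error.
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

.log_state <- new.env(parent = emptyenv())
.log_state$level <- 2L

set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  .log_state$level <- .log_levels[[level]]
  invisible(level)
}

log_msg <- function(level, fmt, ...) {
  if (.log_levels[[level]] < .log_state$level) return(invisible(NULL))
  msg <- sprintf(fmt, ...)
  cat(sprintf("%s [%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              toupper(level), msg), file = stderr())
  invisible(NULL)
}
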
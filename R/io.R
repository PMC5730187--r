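#' Read and write trial tables
#'
#' Trial sequences are stored as plain CSV with one row per trial and the
#' documented `trial_sequence` columns (`trial`, `block_id`, `task`,
#' `cue_pitch`, `cue_composition`, `u_s`, `u_t`, `validity_s`, `validity_t`,
#' `y_s`, `y_t`, `rt`).
#'
#' @param trials A `trial_sequence`.
#' @param path File path.
#' @return `read_trials()` returns a `trial_sequence`; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial", "block_id", "task", "u_s", "u_t")
  missing <- setdiff(required, names(trials))
  if (length(missing))
    stop("trial table lacks required column(s): ",
         paste(missing, collapse = ", "))
  class(trials) <- c("trial_sequence", "data.frame")
  trials
}

#' Read and write contingency schedules
#'
#' A schedule is stored as CSV with one row per trial and columns `trial`,
#' `validity_s`, `validity_t`; change points are recovered from the validity
#' series on read.
#'
#' @param schedule A `contingency_schedule`.
#' @param path File path.
#' @return `read_schedule()` returns a `contingency_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "contingency_schedule"))
  write.csv(data.frame(trial = seq_len(schedule$n_trials),
                       validity_s = schedule$spatial$validity,
                       validity_t = schedule$temporal$validity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- read.csv(path)
  series <- function(v) {
    cp <- which(diff(v) != 0) + 1L
    len <- diff(c(1L, cp, length(v) + 1L))
    list(validity = v, change_points = cp, run_lengths = len,
         volatility_mean = rep(NA_integer_, length(len)))
  }
  structure(list(spatial = series(x$validity_s),
                 temporal = series(x$validity_t),
                 n_trials = nrow(x),
                 series_correlation = cor(x$validity_s, x$validity_t),
                 attempts = NA_integer_, seed = NA_integer_),
            class = "contingency_schedule")
}

#' The package's stored default schedule pair
#'
#' One accepted decorrelated schedule pair (960 trials, default
#' configuration, generator seed 20) shipped for regression tests and as a
#' fixed session shared across simulated cohorts, mirroring the use of a
#' precomputed validity series for all participants.
#'
#' @return A `contingency_schedule`.
#' @export
default_schedule <- function() {
  read_schedule(system.file("extdata", "default_schedule.csv",
                            package = "hgfcue", mustWork = TRUE))
}
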
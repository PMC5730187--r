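#' Session configuration for the dual-contingency cueing task
#'
#' Bundles the structural parameters of a simulated session: block structure,
#' the set of cue-validity levels, and the volatility regime governing how
#' often validity changes.  Defaults reproduce the standard session: 20
#' alternating task blocks of on average 48 trials (960 trials total), validity
#' levels \{90, 70, 50, 30, 10\}\%, validity run lengths drawn around a
#' volatility mean of 16, 32 or 48 trials (global range 8--54), and the
#' volatility mean advancing after every 5 validity changes.
#'
#' @param n_blocks Number of task blocks (alternating spatial/temporal).
#' @param mean_block_len Mean block length in trials.
#' @param block_len_range Length-2 integer vector, inclusive bounds on block
#'   length.
#' @param validity_levels Cue-validity levels as probabilities in (0, 1).
#' @param volatility_means Mean validity run lengths (trials) cycled through
#'   as the volatility regime changes.
#' @param runs_per_volatility Number of validity runs per volatility regime.
#' @param run_len_range Length-2 integer vector, inclusive global bounds on
#'   validity run length.
#' @param max_series_correlation Acceptance threshold on the absolute Pearson
#'   correlation between the spatial and temporal trial-wise validity series.
#' @param rng_seed Optional integer seed used by the generator functions when
#'   no explicit seed is passed.
#'
#' @return An object of class `session_config` (a named list).
#' @examples
#' cfg <- session_config()
#' cfg$n_blocks * cfg$mean_block_len # 960 trials by default
#' @export
session_config <- function(n_blocks = 20,
                           mean_block_len = 48,
                           block_len_range = c(38, 58),
                           validity_levels = c(0.9, 0.7, 0.5, 0.3, 0.1),
                           volatility_means = c(16, 32, 48),
                           runs_per_volatility = 5,
                           run_len_range = c(8, 54),
                           max_series_correlation = 1e-4,
                           rng_seed = NULL) {
  stopifnot(n_blocks >= 1, mean_block_len >= 1,
            length(block_len_range) == 2,
            block_len_range[1] <= mean_block_len,
            mean_block_len <= block_len_range[2],
            length(run_len_range) == 2, run_len_range[1] >= 1,
            run_len_range[1] <= run_len_range[2],
            runs_per_volatility >= 1,
            max_series_correlation > 0)
  if (any(validity_levels <= 0 | validity_levels >= 1))
    stop("validity levels must lie strictly in (0, 1)")
  if (anyDuplicated(validity_levels))
    stop("validity levels must be distinct")
  if (any(volatility_means < run_len_range[1] |
          volatility_means > run_len_range[2]))
    stop("volatility means must lie within run_len_range")
  structure(list(
    n_blocks = as.integer(n_blocks),
    mean_block_len = as.integer(mean_block_len),
    block_len_range = as.integer(block_len_range),
    validity_levels = validity_levels,
    volatility_means = as.integer(volatility_means),
    runs_per_volatility = as.integer(runs_per_volatility),
    run_len_range = as.integer(run_len_range),
    max_series_correlation = max_series_correlation,
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("Session configuration:\n")
  cat(sprintf("  %d blocks x ~%d trials (range %d-%d), %d trials total\n",
              x$n_blocks, x$mean_block_len, x$block_len_range[1],
              x$block_len_range[2], x$n_blocks * x$mean_block_len))
  cat(sprintf("  validity levels: %s\n",
              paste(x$validity_levels, collapse = ", ")))
  cat(sprintf("  volatility means: %s trials (%d runs each)\n",
              paste(x$volatility_means, collapse = "/"),
              x$runs_per_volatility))
  invisible(x)
}

# Draw one validity run-length series plus validity levels for a single
# contingency dimension.  Run lengths are uniform on a symmetric integer
# window centred on the active volatility mean; the half-width is the largest
# value keeping the window inside run_len_range, so each regime's mean run
# length equals its volatility mean and the global range is attained.
# Volatility means are cycled in shuffled complete permutations so that each
# regime is equally represented over time.
generate_validity_series <- function(cfg, n_trials) {
  lo <- cfg$run_len_range[1]; hi <- cfg$run_len_range[2]
  half <- pmin(cfg$volatility_means - lo, hi - cfg$volatility_means)
  n_levels <- length(cfg$validity_levels)
  if (n_levels < 2)
    stop("at least two validity levels are required (consecutive levels ",
         "must not repeat)")
  validity <- numeric(n_trials)
  run_len <- integer(0)
  run_vol <- integer(0)
  filled <- 0L
  level <- sample.int(n_levels, 1)
  vol_order <- sample(seq_along(cfg$volatility_means))
  vol_pos <- 1L
  runs_in_regime <- 0L
  while (filled < n_trials) {
    m_idx <- vol_order[vol_pos]
    m <- cfg$volatility_means[m_idx]
    len <- m + sample.int(2L * half[m_idx] + 1L, 1) - half[m_idx] - 1L
    take <- min(len, n_trials - filled)
    validity[(filled + 1L):(filled + take)] <- cfg$validity_levels[level]
    run_len <- c(run_len, take)
    run_vol <- c(run_vol, m)
    filled <- filled + take
    # next validity level, never repeating the current one
    level <- sample(setdiff(seq_len(n_levels), level), 1)
    runs_in_regime <- runs_in_regime + 1L
    if (runs_in_regime == cfg$runs_per_volatility) {
      runs_in_regime <- 0L
      vol_pos <- vol_pos + 1L
      if (vol_pos > length(vol_order)) {
        vol_order <- sample(seq_along(cfg$volatility_means))
        vol_pos <- 1L
      }
    }
  }
  list(validity = validity,
       change_points = cumsum(run_len[-length(run_len)]) + 1L,
       run_lengths = run_len,
       volatility_mean = run_vol)
}

#' Generate a pair of decorrelated cue-validity schedules
#'
#' Draws independent spatial and temporal validity series (piecewise-constant
#' validity with run lengths governed by the cycling volatility regime) and,
#' by default, redraws the pair with incremented sub-seeds until the absolute
#' Pearson correlation between the two trial-wise validity series falls below
#' `cfg$max_series_correlation`.
#'
#' @param cfg A [session_config()].
#' @param n_trials Number of trials to cover (defaults to the session total).
#' @param seed Integer seed; defaults to `cfg$rng_seed`.
#' @param decorrelate If `TRUE` (default), apply the rejection loop enforcing
#'   the decorrelation criterion; if `FALSE`, accept the first draw (useful
#'   for schedule-statistics studies where the criterion is irrelevant).
#' @param max_attempts Upper bound on rejection-sampling attempts.
#'
#' @return An object of class `contingency_schedule`: a list with per-trial
#'   validity vectors (`$spatial`, `$temporal`), per-dimension change points
#'   and run lengths, the realized correlation `$series_correlation`, and the
#'   number of attempts used.
#' @examples
#' sch <- generate_validity_schedule(session_config(), 960, seed = 1,
#'                                   decorrelate = FALSE)
#' mean(sch$spatial$run_lengths) # close to 32 on average
#' @export
generate_validity_schedule <- function(cfg, n_trials = NULL, seed = NULL,
                                       decorrelate = TRUE,
                                       max_attempts = 100000L) {
  stopifnot(inherits(cfg, "session_config"))
  if (is.null(n_trials)) n_trials <- cfg$n_blocks * cfg$mean_block_len
  stopifnot(n_trials > 0)
  if (is.null(seed)) seed <- cfg$rng_seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max %/% 2L, 1)
  for (attempt in seq_len(if (decorrelate) max_attempts else 1L)) {
    set.seed(seed + attempt - 1L)
    sp <- generate_validity_series(cfg, n_trials)
    te <- generate_validity_series(cfg, n_trials)
    r <- cor(sp$validity, te$validity)
    if (!decorrelate || abs(r) <= cfg$max_series_correlation) {
      return(structure(list(
        spatial = sp, temporal = te,
        n_trials = as.integer(n_trials),
        series_correlation = r,
        attempts = attempt,
        seed = as.integer(seed)
      ), class = "contingency_schedule"))
    }
  }
  stop("failed to satisfy the decorrelation criterion |r| <= ",
       cfg$max_series_correlation, " within ", max_attempts,
       " attempts; relax the criterion or check the configuration")
}

#' @export
print.contingency_schedule <- function(x, ...) {
  cat(sprintf(paste0("Contingency schedule: %d trials, %d/%d validity runs ",
                     "(spatial/temporal)\n  series correlation %.2e ",
                     "(%d attempt%s)\n"),
              x$n_trials, length(x$spatial$run_lengths),
              length(x$temporal$run_lengths), x$series_correlation,
              x$attempts, if (x$attempts == 1) "" else "s"))
  invisible(x)
}

# Block lengths: uniform integer draws on block_len_range adjusted by
# single-trial steps (staying in range) until they sum to the session total,
# so the default session always has exactly n_blocks * mean_block_len trials.
draw_block_lengths <- function(cfg) {
  n_total <- cfg$n_blocks * cfg$mean_block_len
  lo <- cfg$block_len_range[1]; hi <- cfg$block_len_range[2]
  len <- sample(lo:hi, cfg$n_blocks, replace = TRUE)
  excess <- sum(len) - n_total
  while (excess != 0) {
    i <- sample.int(cfg$n_blocks, 1)
    if (excess > 0 && len[i] > lo) {
      len[i] <- len[i] - 1L; excess <- excess - 1L
    } else if (excess < 0 && len[i] < hi) {
      len[i] <- len[i] + 1L; excess <- excess + 1L
    }
  }
  len
}

#' Generate a trial sequence from a validity schedule
#'
#' Draws cue features uniformly and target features in contingency space
#' according to the scheduled validity of each dimension: `u = 1` (the
#' cue-target association holds) with probability equal to the current
#' validity.  Blocks alternate between the spatial and the temporal task,
#' starting from a randomly drawn task.
#'
#' @param schedule A `contingency_schedule`.
#' @param cfg The [session_config()] used to build the block structure.
#' @param seed Integer seed for cue/target sampling (a stream separate from
#'   schedule generation, so trials can be redrawn on a fixed schedule).
#'
#' @return A `trial_sequence`: a data frame with one row per trial and columns
#'   `trial`, `block_id`, `task` ("spatial"/"temporal"), `cue_pitch`,
#'   `cue_composition` (0/1), `u_s`, `u_t` (target features in contingency
#'   space), `validity_s`, `validity_t`, and response placeholders `y_s`,
#'   `y_t`, `rt` (NA until an agent responds).
#' @examples
#' cfg <- session_config()
#' sch <- generate_validity_schedule(cfg, seed = 1, decorrelate = FALSE)
#' tr <- generate_trials(sch, cfg, seed = 2)
#' table(tr$task, tr$block_id)[, 1:4]
#' @export
generate_trials <- function(schedule, cfg, seed = NULL) {
  stopifnot(inherits(schedule, "contingency_schedule"),
            inherits(cfg, "session_config"))
  n <- schedule$n_trials
  if (n != cfg$n_blocks * cfg$mean_block_len)
    stop("schedule does not cover the configured session length")
  if (!is.null(seed)) set.seed(seed)
  block_len <- draw_block_lengths(cfg)
  block_id <- rep(seq_len(cfg$n_blocks), block_len)
  first_task <- sample(c("spatial", "temporal"), 1)
  other_task <- setdiff(c("spatial", "temporal"), first_task)
  task <- rep(rep_len(c(first_task, other_task), cfg$n_blocks), block_len)
  v_s <- schedule$spatial$validity
  v_t <- schedule$temporal$validity
  trials <- data.frame(
    trial = seq_len(n),
    block_id = block_id,
    task = task,
    cue_pitch = rbinom(n, 1, 0.5),
    cue_composition = rbinom(n, 1, 0.5),
    u_s = rbinom(n, 1, v_s),
    u_t = rbinom(n, 1, v_t),
    validity_s = v_s,
    validity_t = v_t,
    y_s = NA_integer_,
    y_t = NA_integer_,
    rt = NA_real_,
    stringsAsFactors = FALSE
  )
  class(trials) <- c("trial_sequence", "data.frame")
  trials
}

#' Simulate an agent performing the task
#'
#' Runs the observer model forward on the presented outcomes (belief updates
#' use the actual targets `u`, never the sampled responses) and samples the
#' block task's response on every trial from the relevance-weighted logistic
#' response model.  Optionally attaches log-normal reaction times as a stub
#' for exercising the RT filter.
#'
#' @param trials A `trial_sequence` from [generate_trials()].
#' @param observer An [observer_params()] object.
#' @param responder A [response_params()] object.
#' @param seed Integer seed for response (and RT) sampling.
#' @param simulate_rt If `TRUE` (default), fill `rt` with log-normal draws
#'   (median 0.5 s, sdlog 0.25); purely a placeholder for filter tests.
#'
#' @return The trial sequence with `y_s`/`y_t` filled on the corresponding
#'   task's trials (the other dimension's response stays NA) and `rt` filled
#'   if requested.
#' @export
simulate_agent <- function(trials, observer, responder, seed = NULL,
                           simulate_rt = TRUE) {
  stopifnot(inherits(trials, "trial_sequence"),
            inherits(observer, "observer_params"),
            inherits(responder, "response_params"))
  if (!is.null(seed)) set.seed(seed)
  traj_s <- filter_beliefs(trials, observer, "spatial")
  traj_t <- filter_beliefs(trials, observer, "temporal")
  ms <- 2 * traj_s$muhat1 - 1
  mt <- 2 * traj_t$muhat1 - 1
  sgn <- if (isTRUE(responder$literal_sign)) -1 else 1
  spatial <- trials$task == "spatial"
  x <- ifelse(spatial,
              responder$zeta_s_rel * ms + responder$zeta_t_irrel * mt,
              responder$zeta_t_rel * mt + responder$zeta_s_irrel * ms)
  p1 <- plogis(sgn * x) # probability of response y = 1
  y <- rbinom(nrow(trials), 1, p1)
  trials$y_s <- ifelse(spatial, y, NA_integer_)
  trials$y_t <- ifelse(spatial, NA_integer_, y)
  if (simulate_rt)
    trials$rt <- rlnorm(nrow(trials), meanlog = log(0.5), sdlog = 0.25)
  trials
}

# Dispatch to the configured observer's filter.
filter_beliefs <- function(trials, observer, dimension) {
  if (observer$variant == "RW") rw_filter(trials, observer, dimension)
  else hgf_filter(trials, observer, dimension)
}

#' Scored response and correctness helpers
#'
#' `scored_response()` returns the response given on each trial for the
#' current block's task (NA where no response was recorded);
#' `response_correct()` marks whether it matched the target feature of that
#' task's dimension in contingency space.
#'
#' @param trials A `trial_sequence`.
#' @return An integer (response) or logical (correctness) vector, one entry
#'   per trial.
#' @export
scored_response <- function(trials) {
  ifelse(trials$task == "spatial", trials$y_s, trials$y_t)
}

#' @rdname scored_response
#' @export
response_correct <- function(trials) {
  y <- scored_response(trials)
  u <- ifelse(trials$task == "spatial", trials$u_s, trials$u_t)
  y == u
}
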
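#' Discard implausibly slow trials by the RT rule
#'
#' Removes trials whose reaction time exceeds `median(rt) + 2 * sd(rt)`,
#' with median and (sample) SD computed over all responded trials.  Trials
#' without an RT pass through untouched (they are excluded from accuracy
#' later as non-responses, not here).
#'
#' @param trials A `trial_sequence`.
#' @return The filtered `trial_sequence`.
#' @export
filter_trials <- function(trials) {
  rt <- trials$rt
  responded <- !is.na(rt)
  if (!any(responded)) return(trials)
  cutoff <- median(rt[responded]) + 2 * sd(rt[responded])
  if (is.na(cutoff)) cutoff <- Inf # single responded trial: SD undefined
  keep <- !responded | rt <= cutoff
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Within-run trial index and run length for one dimension's validity series.
run_index <- function(change_points, n_trials) {
  starts <- c(1L, change_points)
  ends <- c(change_points - 1L, n_trials)
  len <- ends - starts + 1L
  list(index = sequence(len), run_length = rep(len, len))
}

#' Mark the stable second half of each constant-validity run
#'
#' Early trials of a validity run still reflect the previously learned
#' contingency, so condition summaries use only the later trials of each
#' run.  Within a run of length `L`, a trial is retained when its within-run
#' index exceeds `ceiling(L / 2)` (so the final `floor(L / 2)` trials;
#' length-1 runs contribute nothing).  The selection is made per dimension
#' independently, since the two validity series have independent change
#' points.
#'
#' @param trials A `trial_sequence`.
#' @param schedule The `contingency_schedule` the trials were generated from.
#' @return The trial sequence with logical columns `stable_s` and `stable_t`
#'   marking, per dimension, membership in the stable second half.
#' @export
stable_second_half <- function(trials, schedule) {
  stopifnot(inherits(schedule, "contingency_schedule"))
  n <- schedule$n_trials
  if (any(trials$trial < 1 | trials$trial > n))
    stop("trial numbers fall outside the schedule")
  for (d in c("spatial", "temporal")) {
    ri <- run_index(schedule[[d]]$change_points, n)
    keep <- ri$index > ceiling(ri$run_length / 2)
    col <- if (d == "spatial") "stable_s" else "stable_t"
    # index by trial number, not row position: upstream filters may have
    # dropped rows
    trials[[col]] <- keep[trials$trial]
  }
  trials
}

#' Condition-wise accuracy table
#'
#' Summarizes discrimination accuracy per dimension (spatial/temporal
#' predictability), predictability level (strong = validity 90/10%, weak =
#' 70/30%, unpredictable = 50%) and task relevance (relevant when the
#' current task matches the dimension).  Accuracy is the proportion of
#' responded trials whose response matches the target feature of the
#' performed task; the dimension factor only bins trials by that dimension's
#' validity.  If `stable_s`/`stable_t` columns are present (from
#' [stable_second_half()]), each dimension's cells use only its stable
#' trials.  Empty cells are reported with `n_trials = 0` and `accuracy = NA`,
#' never silently 0.
#'
#' @param trials A `trial_sequence` (filters already applied).
#' @param strong,weak,unpredictable Validity levels defining the three
#'   predictability bins.
#' @return A `condition_table` data frame with columns `dimension`,
#'   `predictability`, `relevance`, `n_trials`, `accuracy`.
#' @export
accuracy_table <- function(trials, strong = c(0.9, 0.1), weak = c(0.7, 0.3),
                           unpredictable = 0.5) {
  correct <- response_correct(trials)
  bins <- list(strong = strong, weak = weak, unpredictable = unpredictable)
  out <- expand.grid(dimension = c("spatial", "temporal"),
                     predictability = names(bins),
                     relevance = c("relevant", "irrelevant"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_trials <- 0L
  out$accuracy <- NA_real_
  for (i in seq_len(nrow(out))) {
    d <- out$dimension[i]
    v <- if (d == "spatial") trials$validity_s else trials$validity_t
    stable_col <- if (d == "spatial") "stable_s" else "stable_t"
    sel <- v %in% bins[[out$predictability[i]]] & !is.na(correct)
    if (out$relevance[i] == "relevant") sel <- sel & trials$task == d
    else sel <- sel & trials$task != d
    if (stable_col %in% names(trials)) sel <- sel & trials[[stable_col]]
    out$n_trials[i] <- sum(sel)
    if (out$n_trials[i] > 0) out$accuracy[i] <- mean(correct[sel])
  }
  class(out) <- c("condition_table", "data.frame")
  out
}

#' Repeated-measures ANOVA on a stack of condition tables
#'
#' Convenience F-test for the predictability-by-relevance design on
#' simulated cohorts: one 3 x 2 repeated-measures ANOVA per dimension, with
#' predictability treated as a parametric (linear) factor.
#'
#' @param tables Named list of `condition_table`s, one per subject.
#' @param dimension `"spatial"` or `"temporal"`.
#' @return The `summary()` of the fitted [stats::aov()] model.
#' @export
condition_anova <- function(tables, dimension = c("spatial", "temporal")) {
  dimension <- match.arg(dimension)
  dat <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    tb <- tb[tb$dimension == dimension, , drop = FALSE]
    tb$subject <- factor(i)
    tb
  }))
  dat$pred_num <- c(strong = 1, weak = 0, unpredictable = -1)[
    dat$predictability]
  dat$relevance <- factor(dat$relevance)
  summary(aov(accuracy ~ pred_num * relevance +
                Error(subject / (pred_num * relevance)), data = dat))
}

#' Extract trial-wise model-based regressors
#'
#' Builds the eight GLM regressors used downstream: the magnitude of the
#' cue-locked validity prediction `|muhat2|` and of the target-locked
#' precision-weighted prediction error `|eps2|`, each split by dimension
#' (spatial/temporal) and task relevance (relevant/irrelevant).  Every trial
#' contributes each dimension's value to exactly one relevance cell; the
#' other cell carries 0 for that trial.  By default each regressor is
#' mean-centred within its supporting trials (the usual parametric-modulator
#' convention, which keeps regressors with disjoint supports uncorrelated);
#' `center = FALSE` returns the raw magnitudes.
#'
#' @param traj_s,traj_t `belief_trajectory` objects for the two dimensions.
#' @param trials The aligned `trial_sequence`.
#' @param signed If `TRUE`, use signed `eps2` instead of magnitudes
#'   (control-analysis variant); predictions stay unsigned.
#' @param center Mean-centre each regressor within its support.
#' @return A `regressor_set` data frame keyed by `trial` with columns
#'   `pred_<dim>_<relevance>` and `pe_<dim>_<relevance>`.
#' @export
extract_regressors <- function(traj_s, traj_t, trials, signed = FALSE,
                               center = TRUE) {
  n <- nrow(trials)
  if (nrow(traj_s) != n || nrow(traj_t) != n)
    stop("trajectories and trials are misaligned")
  cell <- function(values, support) {
    out <- numeric(n)
    out[support] <- if (center) values[support] - mean(values[support])
                    else values[support]
    out
  }
  rel_s <- trials$task == "spatial"
  pe <- function(x) if (signed) x else abs(x)
  out <- data.frame(
    trial = trials$trial,
    pred_spatial_rel = cell(abs(traj_s$muhat2), rel_s),
    pred_spatial_irrel = cell(abs(traj_s$muhat2), !rel_s),
    pred_temporal_rel = cell(abs(traj_t$muhat2), !rel_s),
    pred_temporal_irrel = cell(abs(traj_t$muhat2), rel_s),
    pe_spatial_rel = cell(pe(traj_s$eps2), rel_s),
    pe_spatial_irrel = cell(pe(traj_s$eps2), !rel_s),
    pe_temporal_rel = cell(pe(traj_t$eps2), !rel_s),
    pe_temporal_irrel = cell(pe(traj_t$eps2), rel_s)
  )
  class(out) <- c("regressor_set", "data.frame")
  out
}

#' Pairwise Pearson correlations among regressors
#'
#' @param regs A `regressor_set` (or any data frame; a `trial` column is
#'   dropped).  Constant regressors yield NA rows/columns with a warning.
#' @return The Pearson correlation matrix.
#' @export
regressor_correlations <- function(regs) {
  x <- as.data.frame(regs)
  x$trial <- NULL
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0))
    warning("constant regressor(s): ",
            paste(names(x)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  suppressWarnings(cor(as.matrix(x)))
}

#' Mean absolute off-diagonal correlation
#'
#' Summary statistic for regressor independence: the mean of `|r|` over the
#' upper triangle of a correlation matrix (NA entries dropped).
#'
#' @param r A correlation matrix, or a `regressor_set` (correlations are
#'   computed first).
#' @return A single number in \[0, 1\].
#' @export
mean_abs_correlation <- function(r) {
  if (is.data.frame(r)) r <- regressor_correlations(r)
  mean(abs(r[upper.tri(r)]), na.rm = TRUE)
}
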
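#' Response-model parameters
#'
#' Weights of the relevance-weighted logistic (binary softmax) response
#' model.  On a spatial-task trial the response is driven by the spatial
#' prediction with weight `zeta_s_rel` and the (currently irrelevant)
#' temporal prediction with weight `zeta_t_irrel`; conversely on
#' temporal-task trials.  The task-specific variant fixes both irrelevant
#' weights at exactly 0; the task-general variant estimates them.  All
#' weights are inverse-decision-noise parameters (`zeta >= 0`, estimated in
#' log space during fitting).
#'
#' @param variant `"task_specific"` or `"task_general"`.
#' @param zeta_s_rel,zeta_t_rel Relevant-prediction weights (defaults are the
#'   cohort posterior means, `exp(0.64)` and `exp(0.67)`).
#' @param zeta_s_irrel,zeta_t_irrel Irrelevant-prediction weights
#'   (task-general only; forced to 0 for task-specific).
#' @param literal_sign If `TRUE`, use the literal minus-sign form of the
#'   softmax, under which confident predictions make the congruent response
#'   *less* likely.  The default (`FALSE`) uses the congruent-response
#'   convention; see the methods vignette.
#'
#' @return An object of class `response_params`.
#' @export
response_params <- function(variant = c("task_specific", "task_general"),
                            zeta_s_rel = exp(0.64), zeta_t_rel = exp(0.67),
                            zeta_s_irrel = 0, zeta_t_irrel = 0,
                            literal_sign = FALSE) {
  variant <- match.arg(variant)
  z <- c(zeta_s_rel, zeta_t_rel, zeta_s_irrel, zeta_t_irrel)
  if (any(z < 0)) stop("decision-noise weights zeta must be non-negative")
  if (variant == "task_specific" && any(c(zeta_s_irrel, zeta_t_irrel) != 0))
    stop("the task-specific response model fixes the irrelevant weights at 0")
  structure(list(variant = variant,
                 zeta_s_rel = zeta_s_rel, zeta_t_rel = zeta_t_rel,
                 zeta_s_irrel = zeta_s_irrel, zeta_t_irrel = zeta_t_irrel,
                 literal_sign = isTRUE(literal_sign)),
            class = "response_params")
}

#' Probability of a response under the relevance-weighted logistic model
#'
#' `p(y) = s( zeta_rel * (2 * muhat1_task - 1) * (2y - 1) + zeta_irrel *
#' (2 * muhat1_other - 1) * (2y - 1) )`, where `muhat1_task` is the current
#' task dimension's outcome prediction and `muhat1_other` the other
#' dimension's.  Satisfies `p(y = 1) + p(y = 0) = 1`.
#'
#' @param mu1hat_task,mu1hat_other Outcome predictions in (0, 1) for the
#'   scored (task) dimension and the other dimension; vectors recycle.
#' @param y Response(s) in contingency space, 0 or 1.
#' @param params A [response_params()].
#' @param task `"spatial"` or `"temporal"`: which dimension is scored (and
#'   thus which zeta pair applies); vectorized.
#'
#' @return Response probabilities in (0, 1).
#' @examples
#' pr <- response_params("task_specific", zeta_s_rel = 2, zeta_t_rel = 2)
#' response_probability(0.9, 0.5, 1, pr, "spatial") # s(1.6), about 0.832
#' @export
response_probability <- function(mu1hat_task, mu1hat_other, y, params,
                                 task = "spatial") {
  stopifnot(inherits(params, "response_params"),
            all(y %in% c(0, 1)),
            all(mu1hat_task > 0 & mu1hat_task < 1),
            all(mu1hat_other > 0 & mu1hat_other < 1))
  spatial <- task == "spatial"
  z_rel <- ifelse(spatial, params$zeta_s_rel, params$zeta_t_rel)
  z_irrel <- ifelse(spatial, params$zeta_t_irrel, params$zeta_s_irrel)
  x <- z_rel * (2 * mu1hat_task - 1) + z_irrel * (2 * mu1hat_other - 1)
  sgn <- if (params$literal_sign) -1 else 1
  plogis(sgn * x * (2 * y - 1))
}

#' Log-likelihood of observed responses given belief trajectories
#'
#' Sums the log response probability over all trials with a recorded
#' response; on spatial-task trials the scored response is `y_s` with the
#' spatial prediction as the relevant one, and conversely on temporal-task
#' trials.  Trials without a response contribute zero.
#'
#' @param trials A `trial_sequence` with responses filled.
#' @param traj_s,traj_t `belief_trajectory` objects for the spatial and
#'   temporal dimensions (aligned with `trials`).
#' @param params A [response_params()].
#'
#' @return The summed log-likelihood in nats.
#' @export
response_loglik <- function(trials, traj_s, traj_t, params) {
  stopifnot(inherits(params, "response_params"))
  n <- nrow(trials)
  if (nrow(traj_s) != n || nrow(traj_t) != n)
    stop("trajectory/trial length mismatch")
  y <- scored_response(trials)
  -cpp_response_negll(traj_s$muhat1, traj_t$muhat1, as.numeric(y),
                      trials$task == "spatial",
                      params$zeta_s_rel, params$zeta_t_rel,
                      params$zeta_s_irrel, params$zeta_t_irrel,
                      if (params$literal_sign) -1 else 1)
}
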
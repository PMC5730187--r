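#' Logistic sigmoid
#'
#' `s(x) = 1 / (1 + exp(-x))`, the link between the contingency belief
#' (level 2, unbounded) and the predicted outcome probability (level 1).
#'
#' @param x Numeric vector.
#' @return Values strictly in (0, 1).
#' @examples
#' sigmoid(0) # 0.5
#' @export
sigmoid <- function(x) plogis(x)

#' Observer-model parameters
#'
#' Parameters of the trial-by-trial belief filters.  The hierarchical
#' Gaussian filter (HGF) variants track, per contingency dimension, the
#' outcome prediction (level 1), the cue-validity belief `mu2` with variance
#' `sigma2` (level 2) and, for the 3-level variant, log-volatility `mu3`
#' (level 3).  The constant component of the level-2 learning step is
#' `exp(omega)`; with context-specific learning the active `omega` is
#' `omega_*_rel` on trials where the dimension is task-relevant and
#' `omega_*_irrel` otherwise.  The 2-level variant fixes `kappa = 0` and
#' freezes level 3.  The Rescorla-Wagner (RW) baseline replaces the filter
#' with a fixed-learning-rate value update per dimension.
#'
#' Defaults are the cohort posterior means of the winning 2-level
#' context-specific model (learning rates about -5, prior level-2 variance
#' `exp(0.1)`).
#'
#' @param variant `"HGF3"`, `"HGF2"` or `"RW"`.
#' @param context_specific Logical; if `FALSE`, the `_irrel` learning rates
#'   are tied to their `_rel` counterparts (single `omega` per dimension).
#' @param omega_s_rel,omega_s_irrel Spatial learning-rate constants
#'   (log-variance units) for task-relevant / task-irrelevant trials.
#' @param omega_t_rel,omega_t_irrel Temporal counterparts.
#' @param kappa Coupling of inferred volatility to the level-2 learning step
#'   (must be 0 for HGF2).
#' @param theta Level-3 random-walk variance (HGF3 only; > 0).
#' @param log_sigma2_0_s,log_sigma2_0_t Log prior variance of the level-2
#'   belief per dimension.
#' @param mu2_0,mu3_0,sigma3_0 Initial belief means/variance (level 2 starts
#'   unbiased at 0; level 3 at mean 1, variance 1).
#' @param alpha_s,alpha_t RW learning rates in \[0, 1\] (RW only).
#'
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(variant = c("HGF2", "HGF3", "RW"),
                            context_specific = TRUE,
                            omega_s_rel = -5.13, omega_t_rel = -5.11,
                            omega_s_irrel = -5.17, omega_t_irrel = -5.22,
                            kappa = if (match.arg(variant) == "HGF3") 1 else 0,
                            theta = exp(-6),
                            log_sigma2_0_s = 0.10, log_sigma2_0_t = 0.09,
                            mu2_0 = 0, mu3_0 = 1, sigma3_0 = 1,
                            alpha_s = 0.15, alpha_t = 0.15) {
  variant <- match.arg(variant)
  if (variant == "HGF2" && kappa != 0)
    stop("the 2-level HGF fixes kappa = 0")
  if (theta <= 0) stop("theta must be strictly positive")
  if (sigma3_0 <= 0) stop("sigma3_0 must be strictly positive")
  if (variant == "RW" &&
      (alpha_s < 0 || alpha_s > 1 || alpha_t < 0 || alpha_t > 1))
    stop("RW learning rates must lie in [0, 1]")
  if (!context_specific) {
    omega_s_irrel <- omega_s_rel
    omega_t_irrel <- omega_t_rel
  }
  structure(list(
    variant = variant, context_specific = context_specific,
    omega_s_rel = omega_s_rel, omega_t_rel = omega_t_rel,
    omega_s_irrel = omega_s_irrel, omega_t_irrel = omega_t_irrel,
    kappa = kappa, theta = theta,
    log_sigma2_0_s = log_sigma2_0_s, log_sigma2_0_t = log_sigma2_0_t,
    mu2_0 = mu2_0, mu3_0 = mu3_0, sigma3_0 = sigma3_0,
    alpha_s = alpha_s, alpha_t = alpha_t
  ), class = "observer_params")
}

#' Hierarchical Gaussian Filter over one contingency dimension
#'
#' Sequentially filters the binary outcome series of one dimension.  Per
#' trial: the outcome prediction is `muhat1 = s(mu2)` from the previous
#' belief; the outcome prediction error is `delta1 = u - muhat1`; the
#' predicted level-2 precision is `pihat2 = 1 / (sigma2 + exp(kappa * mu3 +
#' omega))` with the context-appropriate `omega`; the posterior level-2
#' precision is `pi2 = pihat2 + muhat1 * (1 - muhat1)`; the belief update is
#' `delta1 / pi2`, and the precision-weighted prediction error is `eps2 =
#' psi2 * delta1` with `psi2 = 1 / pi2` (unit level-1 prediction precision;
#' see the methods vignette for the convention).  The 3-level variant
#' additionally updates the volatility belief from the level-2 prediction
#' error `delta2`.  Both dimensions are filtered on every trial regardless of
#' the current task: the task only selects which `omega` applies.
#'
#' @param trials A `trial_sequence` (or any data frame with columns `u_s`,
#'   `u_t` and `task`).
#' @param params An [observer_params()] with variant `"HGF2"` or `"HGF3"`.
#' @param dimension `"spatial"` or `"temporal"`.
#'
#' @return A `belief_trajectory` data frame, one row per trial, with the
#'   pre-outcome quantities `muhat1`, `muhat2`, `pihat2` and post-outcome
#'   `delta1`, `mu2`, `sigma2`, `pi2`, `psi2`, `eps2`, `mu3`, `sigma3`,
#'   `delta2`, `eps3`.
#' @examples
#' cfg <- session_config()
#' sch <- generate_validity_schedule(cfg, seed = 1, decorrelate = FALSE)
#' tr <- generate_trials(sch, cfg, seed = 2)
#' traj <- hgf_filter(tr, observer_params("HGF2"), "spatial")
#' head(traj[, c("muhat1", "delta1", "eps2")])
#' @export
hgf_filter <- function(trials, params,
                       dimension = c("spatial", "temporal")) {
  dimension <- match.arg(dimension)
  stopifnot(inherits(params, "observer_params"),
            params$variant %in% c("HGF2", "HGF3"))
  u <- if (dimension == "spatial") trials$u_s else trials$u_t
  if (any(is.na(u)) || !all(u %in% c(0, 1)))
    stop("outcomes must be binary (0/1) with no missing values")
  rel <- trials$task == dimension
  if (dimension == "spatial") {
    om_rel <- params$omega_s_rel; om_irrel <- params$omega_s_irrel
    s2_0 <- exp(params$log_sigma2_0_s)
  } else {
    om_rel <- params$omega_t_rel; om_irrel <- params$omega_t_irrel
    s2_0 <- exp(params$log_sigma2_0_t)
  }
  res <- cpp_hgf_filter(as.numeric(u), rel, params$kappa, om_rel, om_irrel,
                        params$theta, params$mu2_0, s2_0, params$mu3_0,
                        params$sigma3_0, params$variant == "HGF3")
  if (!res$ok)
    stop("belief filter hit a numerical pathology (non-finite state or ",
         "non-positive precision); check the parameter values")
  traj <- data.frame(trial = seq_along(u), res[names(res) != "ok"])
  attr(traj, "dimension") <- dimension
  class(traj) <- c("belief_trajectory", "data.frame")
  traj
}

#' Rescorla-Wagner filter over one contingency dimension
#'
#' Fixed-learning-rate value update `v(k+1) = v(k) + alpha * (u(k) - v(k))`
#' starting from `v(0) = 0.5`; the trial-wise prediction `muhat1(k)` is the
#' pre-outcome value `v(k)`.  No context specificity: the same `alpha`
#' applies on relevant and irrelevant trials.
#'
#' @inheritParams hgf_filter
#' @param params An [observer_params()] with `variant = "RW"`.
#' @return A `belief_trajectory` data frame with columns `trial`, `muhat1`,
#'   `delta1` and `value` (the post-outcome value `v(k+1)`).
#' @export
rw_filter <- function(trials, params,
                      dimension = c("spatial", "temporal")) {
  dimension <- match.arg(dimension)
  stopifnot(inherits(params, "observer_params"), params$variant == "RW")
  alpha <- if (dimension == "spatial") params$alpha_s else params$alpha_t
  if (alpha < 0 || alpha > 1) stop("RW learning rate must lie in [0, 1]")
  u <- if (dimension == "spatial") trials$u_s else trials$u_t
  if (any(is.na(u)) || !all(u %in% c(0, 1)))
    stop("outcomes must be binary (0/1) with no missing values")
  muhat1 <- cpp_rw_muhat1(as.numeric(u), alpha, 0.5)
  delta1 <- u - muhat1
  traj <- data.frame(trial = seq_along(u), muhat1 = muhat1,
                     delta1 = delta1, value = muhat1 + alpha * delta1)
  attr(traj, "dimension") <- dimension
  class(traj) <- c("belief_trajectory", "data.frame")
  traj
}
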
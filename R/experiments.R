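#' Simulate a cohort of agents on a shared schedule
#'
#' Mirrors the experimental design in which one accepted (decorrelated)
#' validity schedule pair is fixed for all participants: each agent gets its
#' own cue/target draws and response noise, but the same underlying validity
#' series.
#'
#' @param n_agents Number of agents.
#' @param observer,responder Generating parameter objects (either a single
#'   object shared by all agents, or a list of length `n_agents`).
#' @param cfg A [session_config()].
#' @param seed Master integer seed; schedule, trials and responses use
#'   derived sub-seeds.
#' @return List with the `schedule` and a list `agents` of simulated
#'   `trial_sequence`s.
#' @export
simulate_cohort <- function(n_agents = 17,
                            observer = observer_params("HGF2"),
                            responder = response_params("task_specific"),
                            cfg = session_config(), seed = 1) {
  schedule <- generate_validity_schedule(cfg, seed = seed)
  get <- function(x, i) if (inherits(x, "observer_params") ||
                            inherits(x, "response_params")) x else x[[i]]
  agents <- lapply(seq_len(n_agents), function(i) {
    tr <- generate_trials(schedule, cfg, seed = seed + 1000L + i)
    simulate_agent(tr, get(observer, i), get(responder, i),
                   seed = seed + 2000L + i)
  })
  list(schedule = schedule, agents = agents)
}

#' Model-recovery experiment
#'
#' Simulates a cohort from the winning model (2-level HGF with
#' context-specific learning rates and the task-specific responder, at the
#' reported cohort posterior-mean parameters), fits every model of the
#' canonical 10-model space to each agent by MAP with Laplace evidence, and
#' runs random-effects Bayesian model selection on the resulting
#' subjects-by-models evidence matrix.
#'
#' @param n_agents Number of simulated agents (default 17).
#' @param seed Master integer seed.
#' @param n_restarts Optimizer restarts per fit.
#' @param models Model list (default: the canonical space).
#' @param observer,responder Generating parameters.
#' @param generating_name Name of the generating model within `models`.
#' @return List with the evidence matrix `log_evidence`, the `bms_result`,
#'   the per-agent fits of the generating model (`fits_generating`), the
#'   simulated `cohort`, and `generating_name`.
#' @export
model_recovery_experiment <- function(n_agents = 17, seed = 1,
                                      n_restarts = 4,
                                      models = enumerate_model_space(),
                                      observer = observer_params("HGF2"),
                                      responder =
                                        response_params("task_specific"),
                                      generating_name =
                                        "HGF2_ctx+task_specific") {
  cohort <- simulate_cohort(n_agents, observer, responder, seed = seed)
  L <- matrix(NA_real_, n_agents, length(models),
              dimnames = list(NULL, names(models)))
  fits_generating <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    sp <- fit_model_space(cohort$agents[[i]], models,
                          n_restarts = n_restarts, seed = seed + i)
    L[i, ] <- sp$log_evidence
    fits_generating[[i]] <- sp$fits[[generating_name]]
  }
  bms <- rfx_bms(L, seed = seed)
  list(log_evidence = L, bms = bms, fits_generating = fits_generating,
       cohort = cohort, generating_name = generating_name)
}

#' Parameter-recovery experiment for the winning model
#'
#' Simulates agents whose transformed parameters are drawn around the cohort
#' posterior means (Gaussian jitter of SD `spread` in estimation space, so
#' agents genuinely differ), refits the generating model to each agent, and
#' reports generating versus recovered values.
#'
#' @param n_agents Number of agents (default 17).
#' @param seed Master integer seed.
#' @param spread SD of the between-agent jitter in transformed space.
#' @param n_restarts Optimizer restarts per fit.
#' @return List with matrices `generating` and `recovered` (agents x
#'   transformed parameters of the winning model) and the model used.
#' @export
parameter_recovery_experiment <- function(n_agents = 17, seed = 1,
                                          spread = 0.5, n_restarts = 4) {
  model <- model_spec("HGF2_ctx", "task_specific")
  centre <- c(log_sigma2_0_s = 0.10, log_sigma2_0_t = 0.09,
              omega_s_rel = -5.13, omega_t_rel = -5.11,
              omega_s_irrel = -5.17, omega_t_irrel = -5.22,
              log_zeta_s_rel = 0.64, log_zeta_t_rel = 0.67)
  centre <- centre[model$priors$param]
  set.seed(seed)
  gen <- matrix(rnorm(n_agents * length(centre), rep(centre, each = n_agents),
                      spread),
                n_agents, length(centre),
                dimnames = list(NULL, names(centre)))
  observers <- lapply(seq_len(n_agents), function(i)
    params_from_theta(gen[i, ], model)$observer)
  responders <- lapply(seq_len(n_agents), function(i)
    params_from_theta(gen[i, ], model)$responder)
  cohort <- simulate_cohort(n_agents, observers, responders, seed = seed)
  rec <- matrix(NA_real_, n_agents, length(centre),
                dimnames = dimnames(gen))
  for (i in seq_len(n_agents)) {
    fit <- fit_map(cohort$agents[[i]], model, n_restarts = n_restarts,
                   seed = seed + i, compute_evidence = FALSE)
    rec[i, ] <- fit$theta
  }
  list(generating = gen, recovered = rec, model = model, cohort = cohort)
}

#' Regressor-independence summary over fitted agents
#'
#' For each fitted agent, rebuilds the winning model's belief trajectories
#' at the MAP parameters, extracts the eight prediction / prediction-error
#' regressors, and averages the mean absolute pairwise correlation across
#' agents.
#'
#' @param fits List of `hgf_fit`s (one per agent).
#' @param agents List of the corresponding `trial_sequence`s.
#' @return List with `mean_abs_r` (scalar), the per-agent values, and the
#'   across-agent mean correlation matrix.
#' @export
regressor_independence <- function(fits, agents) {
  stopifnot(length(fits) == length(agents))
  mats <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    obs <- fits[[i]]$params$observer
    tr <- agents[[i]]
    regs <- extract_regressors(hgf_filter(tr, obs, "spatial"),
                               hgf_filter(tr, obs, "temporal"), tr)
    mats[[i]] <- regressor_correlations(regs)
  }
  per_agent <- vapply(mats, mean_abs_correlation, numeric(1))
  list(mean_abs_r = mean(per_agent), per_agent = per_agent,
       mean_matrix = Reduce(`+`, mats) / length(mats))
}

#' Correlate fitted parameters with behavioural accuracy across agents
#'
#' Simple per-parameter report relating individual differences in model
#' parameters to mean accuracy: one Pearson correlation (with p-value) per
#' transformed parameter across agents.  A deliberately plain alternative
#' to stepwise selection, which is unstable at typical cohort sizes.
#'
#' @param fits List of `hgf_fit`s from the same model, one per agent.
#' @param agents List of the corresponding `trial_sequence`s.
#' @return Data frame with columns `param`, `r`, `p`, `n`.
#' @export
parameter_accuracy_correlations <- function(fits, agents) {
  stopifnot(length(fits) == length(agents), length(fits) >= 3)
  theta <- do.call(rbind, lapply(fits, function(f) f$theta))
  acc <- vapply(agents, function(a)
    mean(response_correct(a), na.rm = TRUE), numeric(1))
  out <- do.call(rbind, lapply(colnames(theta), function(p) {
    ct <- suppressWarnings(cor.test(theta[, p], acc))
    data.frame(param = p, r = unname(ct$estimate), p = ct$p.value,
               n = length(acc))
  }))
  out
}
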
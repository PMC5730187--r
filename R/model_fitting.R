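# Map a transformed-space parameter vector (ordered as in the model's prior
# table) to native observer/response parameter objects.
params_from_theta <- function(theta, model) {
  stopifnot(length(theta) == model$n_params)
  th <- as.list(theta)
  names(th) <- model$priors$param
  obs <- model$observer
  if (obs == "RW") {
    observer <- observer_params("RW",
                                alpha_s = plogis(th$logit_alpha_s),
                                alpha_t = plogis(th$logit_alpha_t))
  } else {
    ctx <- endsWith(obs, "_ctx")
    three <- startsWith(obs, "HGF3")
    observer <- observer_params(
      variant = if (three) "HGF3" else "HGF2",
      context_specific = ctx,
      omega_s_rel = th$omega_s_rel, omega_t_rel = th$omega_t_rel,
      omega_s_irrel = if (ctx) th$omega_s_irrel else th$omega_s_rel,
      omega_t_irrel = if (ctx) th$omega_t_irrel else th$omega_t_rel,
      kappa = if (three) exp(th$log_kappa) else 0,
      theta = if (three) exp(th$log_theta) else exp(-6),
      log_sigma2_0_s = th$log_sigma2_0_s,
      log_sigma2_0_t = th$log_sigma2_0_t)
  }
  responder <- response_params(
    variant = model$responder,
    zeta_s_rel = exp(th$log_zeta_s_rel),
    zeta_t_rel = exp(th$log_zeta_t_rel),
    zeta_s_irrel = if (model$responder == "task_general")
      exp(th$log_zeta_s_irrel) else 0,
    zeta_t_irrel = if (model$responder == "task_general")
      exp(th$log_zeta_t_irrel) else 0)
  list(observer = observer, responder = responder)
}

# Fast negative log-likelihood used inside the optimizer: compiled filters
# plus the compiled response likelihood.  Returns +Inf on numerical
# pathology so the optimizer treats the parameter vector as invalid.
negloglik_theta <- function(theta, model, u_s, u_t, rel_s, rel_t, y,
                            task_spatial) {
  th <- as.list(theta)
  names(th) <- model$priors$param
  obs <- model$observer
  if (obs == "RW") {
    ms <- cpp_rw_muhat1(u_s, plogis(th$logit_alpha_s), 0.5)
    mt <- cpp_rw_muhat1(u_t, plogis(th$logit_alpha_t), 0.5)
  } else {
    ctx <- endsWith(obs, "_ctx")
    three <- startsWith(obs, "HGF3")
    kappa <- if (three) exp(th$log_kappa) else 0
    vtheta <- if (three) exp(th$log_theta) else exp(-6)
    om_s_i <- if (ctx) th$omega_s_irrel else th$omega_s_rel
    om_t_i <- if (ctx) th$omega_t_irrel else th$omega_t_rel
    ms <- cpp_hgf_muhat1(u_s, rel_s, kappa, th$omega_s_rel, om_s_i, vtheta,
                         0, exp(th$log_sigma2_0_s), 1, 1, three)
    if (length(ms) == 1L) return(Inf)
    mt <- cpp_hgf_muhat1(u_t, rel_t, kappa, th$omega_t_rel, om_t_i, vtheta,
                         0, exp(th$log_sigma2_0_t), 1, 1, three)
    if (length(mt) == 1L) return(Inf)
  }
  zg <- model$responder == "task_general"
  cpp_response_negll(ms, mt, y, task_spatial,
                     exp(th$log_zeta_s_rel), exp(th$log_zeta_t_rel),
                     if (zg) exp(th$log_zeta_s_irrel) else 0,
                     if (zg) exp(th$log_zeta_t_irrel) else 0, 1)
}

#' Fit a model to one agent's responses by MAP estimation
#'
#' Maximizes the log-joint (response log-likelihood composed with the
#' observer's filter, plus Gaussian log-priors in transformed space) by
#' quasi-Newton search (BFGS) from `n_restarts` starting points: the prior
#' means, then jittered draws around them.  The best optimum is returned
#' along with a Laplace approximation to the log model evidence.
#'
#' @param trials A `trial_sequence` with responses.
#' @param model A [model_spec()].
#' @param priors Prior table (defaults to the model's own
#'   [default_priors()]).
#' @param n_restarts Number of optimizer starts (>= 1; default 4).
#' @param seed Integer seed controlling the jittered starts (fit is then
#'   fully deterministic).
#' @param compute_evidence If `TRUE` (default), attach the Laplace evidence.
#' @param control Passed to [stats::optim()] (objective tolerance defaults
#'   to `reltol = 1e-8`, `maxit = 500`).
#'
#' @return An object of class `hgf_fit`: MAP parameters in transformed space
#'   (`$theta`) and as parameter objects (`$params`), `$loglik`, `$logprior`,
#'   `$logjoint`, `$evidence`, `$hessian_logdet`, a positive-definiteness
#'   flag `$hessian_pd`, per-restart objective values, and the log-joint
#'   closure `$logjoint_fn`.
#' @export
fit_map <- function(trials, model, priors = model$priors, n_restarts = 4,
                    seed = 1, compute_evidence = TRUE,
                    control = list(reltol = 1e-8, maxit = 500)) {
  stopifnot(inherits(model, "model_spec"), n_restarts >= 1)
  y <- scored_response(trials)
  if (all(is.na(y))) stop("trials contain no responses to fit")
  u_s <- as.numeric(trials$u_s); u_t <- as.numeric(trials$u_t)
  task_spatial <- trials$task == "spatial"
  rel_s <- task_spatial; rel_t <- !task_spatial
  y <- as.numeric(y)
  pm <- priors$mean; ps <- priors$sd
  negjoint <- function(theta) {
    nll <- negloglik_theta(theta, model, u_s, u_t, rel_s, rel_t, y,
                           task_spatial)
    if (!is.finite(nll)) return(1e10)
    nll - sum(dnorm(theta, pm, ps, log = TRUE))
  }
  set.seed(seed)
  starts <- matrix(pm, nrow = n_restarts, ncol = length(pm), byrow = TRUE)
  if (n_restarts > 1) {
    jitter <- matrix(rnorm((n_restarts - 1) * length(pm), 0,
                           rep(ps / 4, each = n_restarts - 1)),
                     n_restarts - 1, length(pm))
    starts[-1, ] <- starts[-1, , drop = FALSE] + jitter
  }
  fits <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    fits[[i]] <- tryCatch(
      optim(starts[i, ], negjoint, method = "BFGS", control = control),
      error = function(e) list(value = Inf, convergence = 1L))
  }
  values <- vapply(fits, function(f) f$value, numeric(1))
  if (!any(is.finite(values) & values < 1e10))
    stop("all optimizer restarts failed to produce a finite log-joint")
  best <- fits[[which.min(values)]]
  theta <- best$par
  names(theta) <- priors$param
  logjoint_fn <- function(th) -negjoint(th)
  ll <- -negloglik_theta(theta, model, u_s, u_t, rel_s, rel_t, y,
                         task_spatial)
  fit <- structure(list(
    model = model, priors = priors, theta = theta,
    params = params_from_theta(theta, model),
    loglik = ll,
    logprior = sum(dnorm(theta, pm, ps, log = TRUE)),
    logjoint = -best$value,
    evidence = NA_real_, hessian_logdet = NA_real_, hessian_pd = NA,
    convergence = best$convergence,
    restart_values = -values,
    n_restarts_used = n_restarts,
    logjoint_fn = logjoint_fn
  ), class = "hgf_fit")
  if (compute_evidence) {
    ev <- laplace_evidence(logjoint_fn, theta, logjoint = fit$logjoint)
    fit$evidence <- ev$evidence
    fit$hessian_logdet <- ev$logdet
    fit$hessian_pd <- ev$pd
  }
  fit
}

#' @export
print.hgf_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MAP fit of %s\n", x$model$name))
  cat(sprintf("  log-lik %.2f, log-joint %.2f, Laplace evidence %.2f\n",
              x$loglik, x$logjoint, x$evidence))
  print(round(x$theta, digits))
  invisible(x)
}

#' Laplace approximation to the log model evidence
#'
#' Approximates `log integral exp(logjoint(theta)) dtheta` by
#' `logjoint(map) + (n/2) log(2 pi) - 0.5 * logdet(-H)`, where `H` is the
#' Hessian of the log-joint at the MAP, computed by central finite
#' differences.  A non-positive-definite curvature is regularized by
#' clamping its eigenvalues (flagged via `pd = FALSE`).
#'
#' @param logjoint_fn Function of the transformed parameter vector returning
#'   the log-joint.
#' @param theta MAP estimate (numeric vector).
#' @param logjoint Optional precomputed value of `logjoint_fn(theta)`.
#'
#' @return List with `evidence` (nats), `logdet` (log-determinant of the
#'   negative Hessian) and `pd` (was the curvature positive definite).
#' @examples
#' # 1-D Gaussian integral: peak L, curvature c -> L + 0.5 * log(2 * pi / c)
#' f <- function(x) 2 - 3 / 2 * (x - 1)^2
#' laplace_evidence(f, 1)$evidence - (2 + 0.5 * log(2 * pi / 3))
#' @export
laplace_evidence <- function(logjoint_fn, theta, logjoint = NULL) {
  if (is.null(logjoint)) logjoint <- logjoint_fn(theta)
  n <- length(theta)
  H <- -pracma::hessian(function(th) logjoint_fn(th), theta)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  pd <- all(ev > 0)
  if (!pd) {
    floor_ev <- max(abs(ev)) * 1e-8
    ev <- pmax(ev, floor_ev)
  }
  logdet <- sum(log(ev))
  list(evidence = logjoint + 0.5 * n * log(2 * pi) - 0.5 * logdet,
       logdet = logdet, pd = pd)
}

#' Fit every model of the canonical space to one agent
#'
#' Convenience wrapper running [fit_map()] for each model in `models` and
#' collecting the Laplace log evidences.
#'
#' @inheritParams fit_map
#' @param models List of [model_spec()]s (default: the canonical 10).
#' @return List with `fits` (named list of `hgf_fit`) and `log_evidence`
#'   (named numeric vector).
#' @export
fit_model_space <- function(trials, models = enumerate_model_space(),
                            n_restarts = 4, seed = 1) {
  fits <- lapply(models, function(m)
    fit_map(trials, m, n_restarts = n_restarts, seed = seed))
  list(fits = fits,
       log_evidence = vapply(fits, function(f) f$evidence, numeric(1)))
}
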
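# Independent plain-R reference implementations used as oracles against the
# package's compiled filters, plus small fixture builders.  These are written
# directly from the update equations and share no code with the package
# internals.

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

# Reference binary HGF over one dimension.  Returns per-trial lists of the
# state variables; deliberately scalar-looped and transparent.
ref_hgf <- function(u, rel, kappa = 0, om_rel = -5, om_irrel = -5,
                    theta = exp(-6), mu2_0 = 0, sigma2_0 = exp(0.1),
                    mu3_0 = 1, sigma3_0 = 1, three_level = FALSE) {
  n <- length(u)
  out <- data.frame(muhat1 = numeric(n), delta1 = numeric(n),
                    muhat2 = numeric(n), mu2 = numeric(n),
                    sigma2 = numeric(n), pihat2 = numeric(n),
                    pi2 = numeric(n), psi2 = numeric(n), eps2 = numeric(n),
                    mu3 = numeric(n), sigma3 = numeric(n),
                    delta2 = numeric(n), eps3 = numeric(n))
  mu2 <- mu2_0; sigma2 <- sigma2_0; mu3 <- mu3_0; sigma3 <- sigma3_0
  for (k in seq_len(n)) {
    om <- if (rel[k]) om_rel else om_irrel
    muhat1 <- ref_sigmoid(mu2)
    delta1 <- u[k] - muhat1
    vhat <- exp(kappa * mu3 + om)
    pihat2 <- 1 / (sigma2 + vhat)
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    psi2 <- 1 / pi2 # unit level-1 prediction precision convention
    mu2_new <- mu2 + psi2 * delta1
    sigma2_new <- max(1 / pi2, 1e-8)
    delta2 <- (sigma2_new + (mu2_new - mu2)^2) / (sigma2 + vhat) - 1
    mu3_new <- mu3; sigma3_new <- sigma3; eps3 <- 0
    if (three_level) {
      pihat3 <- 1 / (sigma3 + theta)
      w2 <- vhat / (sigma2 + vhat)
      pi3 <- pihat3 + 0.5 * kappa^2 * w2 * (w2 + (2 * w2 - 1) * delta2)
      stopifnot(pi3 > 0)
      mu3_new <- mu3 + 0.5 * kappa * (w2 / pi3) * delta2
      sigma3_new <- max(1 / pi3, 1e-8)
      eps3 <- mu3_new - mu3
    }
    out[k, ] <- c(muhat1, delta1, mu2, mu2_new, sigma2_new, pihat2, pi2,
                  psi2, psi2 * delta1, mu3_new, sigma3_new, delta2, eps3)
    mu2 <- mu2_new; sigma2 <- sigma2_new
    mu3 <- mu3_new; sigma3 <- sigma3_new
  }
  out
}

# Reference response log-likelihood: direct per-trial product of logistic
# probabilities.
ref_response_loglik <- function(mu_s, mu_t, y, task_spatial, zs_rel, zt_rel,
                                zs_irrel = 0, zt_irrel = 0) {
  ll <- 0
  for (k in seq_along(y)) {
    if (is.na(y[k])) next
    x <- if (task_spatial[k])
      zs_rel * (2 * mu_s[k] - 1) + zt_irrel * (2 * mu_t[k] - 1)
    else
      zt_rel * (2 * mu_t[k] - 1) + zs_irrel * (2 * mu_s[k] - 1)
    p1 <- ref_sigmoid(x)
    ll <- ll + log(if (y[k] == 1) p1 else 1 - p1)
  }
  ll
}

# Build a bare trial sequence from outcome/task vectors (all same length).
make_trials <- function(u_s, u_t, task, validity_s = NA_real_,
                        validity_t = NA_real_, y_s = NA_integer_,
                        y_t = NA_integer_, rt = NA_real_) {
  n <- length(u_s)
  tr <- data.frame(trial = seq_len(n), block_id = 1L, task = task,
                   cue_pitch = 0L, cue_composition = 0L,
                   u_s = u_s, u_t = u_t,
                   validity_s = validity_s, validity_t = validity_t,
                   y_s = y_s, y_t = y_t, rt = rt,
                   stringsAsFactors = FALSE)
  class(tr) <- c("trial_sequence", "data.frame")
  tr
}

# Build a toy contingency schedule from explicit run-length/validity pairs.
make_schedule <- function(run_lengths_s, validity_s_levels,
                          run_lengths_t = run_lengths_s,
                          validity_t_levels = validity_s_levels) {
  series <- function(len, lev) {
    stopifnot(length(len) == length(lev))
    list(validity = rep(lev, len),
         change_points = if (length(len) > 1)
           cumsum(len[-length(len)]) + 1L else integer(0),
         run_lengths = as.integer(len),
         volatility_mean = rep(NA_integer_, length(len)))
  }
  sp <- series(run_lengths_s, validity_s_levels)
  te <- series(run_lengths_t, validity_t_levels)
  stopifnot(length(sp$validity) == length(te$validity))
  structure(list(spatial = sp, temporal = te,
                 n_trials = length(sp$validity),
                 series_correlation = suppressWarnings(
                   cor(sp$validity, te$validity)),
                 attempts = 1L, seed = NA_integer_),
            class = "contingency_schedule")
}

# A small constant-validity session used by several tests.
constant_session <- function(n_trials, validity_s = 0.9, validity_t = 0.9,
                             seed = 1, n_blocks = 4) {
  stopifnot(n_trials %% n_blocks == 0)
  len <- n_trials / n_blocks
  cfg <- session_config(n_blocks = n_blocks, mean_block_len = len,
                        block_len_range = c(len, len), rng_seed = seed)
  sch <- make_schedule(n_trials, validity_s, n_trials, validity_t)
  generate_trials(sch, cfg, seed = seed)
}

# The model-recovery experiment is expensive enough to share across
# acceptance tests; computed once per session on first use.
recovery_cache <- new.env(parent = emptyenv())
get_recovery_experiment <- function() {
  if (is.null(recovery_cache$mr))
    recovery_cache$mr <- model_recovery_experiment(n_agents = 17, seed = 1)
  recovery_cache$mr
}
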
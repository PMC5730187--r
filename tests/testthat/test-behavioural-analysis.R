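test_that("the RT rule discards only implausibly slow responses", {
  rts <- c(0.4, 0.5, 0.6, 3.0)
  tr <- make_trials(rep(1L, 4), rep(1L, 4), rep("spatial", 4),
                    y_s = rep(1L, 4), rt = rts)
  # cutoff = median + 2 * sd = 0.55 + 2 * 1.25268... = 3.0554 -> keep all
  expect_equal(nrow(filter_trials(tr)), 4L)
  # with enough fast trials the same 3 s response becomes an outlier:
  # median 0.5, sd 0.5458, cutoff 1.5916
  rts2 <- c(rep(0.5, 20), 3.0)
  tr2 <- make_trials(rep(1L, 21), rep(1L, 21), rep("spatial", 21),
                     y_s = rep(1L, 21), rt = rts2)
  expect_equal(filter_trials(tr2)$trial, 1:20)
  # identical RTs: SD 0, cutoff = median, strict inequality keeps ties
  tr$rt <- rep(0.5, 4)
  expect_equal(nrow(filter_trials(tr)), 4L)
  # missing RTs pass through untouched
  tr$rt <- c(NA, 0.5, 0.6, NA)
  expect_equal(nrow(filter_trials(tr)), 4L)
  # empty input stays empty
  expect_equal(nrow(filter_trials(tr[0, ])), 0L)
})

test_that("stable-second-half selection matches brute force", {
  lens <- c(3L, 1L, 10L, 5L, 2L)
  sch <- make_schedule(lens, c(0.9, 0.5, 0.1, 0.7, 0.3),
                       c(6L, 6L, 9L), c(0.3, 0.9, 0.5))
  n <- sum(lens)
  tr <- make_trials(rep(0L, n), rep(0L, n), rep("spatial", n))
  out <- stable_second_half(tr, sch)
  brute <- function(lens) {
    unlist(lapply(lens, function(L) seq_len(L) > ceiling(L / 2)))
  }
  expect_equal(out$stable_s, brute(lens))
  expect_equal(out$stable_t, brute(c(6L, 6L, 9L)))
  # run of length 10 keeps within-run trials 6..10; length 1 keeps none
  expect_equal(which(out$stable_s[5:14]), 6:10)
  expect_false(any(out$stable_s[4]))
})

test_that("RT filter and stability selection commute", {
  cfg <- session_config()
  sch <- generate_validity_schedule(cfg, seed = 31, decorrelate = FALSE)
  tr <- generate_trials(sch, cfg, seed = 32)
  ag <- simulate_agent(tr, observer_params("HGF2"),
                       response_params("task_specific"), seed = 33)
  a <- stable_second_half(filter_trials(ag), sch)
  b <- filter_trials(stable_second_half(ag, sch))
  expect_equal(a, b)
})

test_that("accuracy table covers the design cells with sane values", {
  cfg <- session_config()
  sch <- generate_validity_schedule(cfg, seed = 41, decorrelate = FALSE)
  tr <- generate_trials(sch, cfg, seed = 42)
  # perfect responder: copy the target feature of the scored task
  spatial <- tr$task == "spatial"
  tr$y_s <- ifelse(spatial, tr$u_s, NA)
  tr$y_t <- ifelse(spatial, NA, tr$u_t)
  tab <- accuracy_table(tr)
  expect_s3_class(tab, "condition_table")
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$accuracy[tab$n_trials > 0] == 1))
  # coin-flip responder on a large constant-validity session is at chance
  n <- 2e4
  cfg2 <- session_config(n_blocks = 4, mean_block_len = n / 4,
                         block_len_range = c(n / 4, n / 4))
  tr2 <- generate_trials(make_schedule(n, 0.7, n, 0.3), cfg2, seed = 43)
  ag2 <- simulate_agent(tr2, observer_params("HGF2"),
                        response_params("task_specific", zeta_s_rel = 0,
                                        zeta_t_rel = 0), seed = 44)
  tab2 <- accuracy_table(ag2)
  filled <- tab2[tab2$n_trials > 0, ]
  expect_true(all(abs(filled$accuracy - 0.5) < 0.03))
  # empty cells are flagged with NA, never silently zero
  empty <- tab2[tab2$n_trials == 0, ]
  expect_true(all(is.na(empty$accuracy)))
})

test_that("predictability helps accuracy only in the relevant context", {
  cfg <- session_config()
  sch <- generate_validity_schedule(cfg, seed = 20)
  acc <- list(rel_strong = 0, rel_unpred = 0, irrel_strong = 0,
              irrel_unpred = 0)
  tabs <- list()
  for (s in 1:6) {
    tr <- generate_trials(sch, cfg, seed = 100 + s)
    ag <- simulate_agent(tr, observer_params("HGF2"),
                         response_params("task_specific", zeta_s_rel = 5,
                                         zeta_t_rel = 5), seed = 200 + s)
    ag <- stable_second_half(ag, sch)
    tabs[[s]] <- accuracy_table(ag)
  }
  pool <- do.call(rbind, tabs)
  cell <- function(p, r)
    mean(pool$accuracy[pool$predictability == p & pool$relevance == r],
         na.rm = TRUE)
  rel_effect <- cell("strong", "relevant") - cell("unpredictable", "relevant")
  irrel_effect <- cell("strong", "irrelevant") -
    cell("unpredictable", "irrelevant")
  expect_gt(rel_effect, 0)
  expect_gt(cell("strong", "relevant"), cell("weak", "relevant"))
  # irrelevant-context accuracy is comparatively flat: the predictability
  # effect is much larger in the relevant context
  expect_gt(rel_effect, abs(irrel_effect) + 0.05)
  expect_lt(abs(irrel_effect), 0.1)
  # the repeated-measures ANOVA utility runs on the stacked tables
  an <- condition_anova(tabs, "spatial")
  expect_true(is.list(an))
})

test_that("regressor extraction splits by relevance and centres supports", {
  set.seed(51)
  n <- 200
  u <- rbinom(n, 1, 0.8)
  task <- rep(c("spatial", "temporal"), each = 25, length.out = n)
  tr <- make_trials(u, rev(u), task)
  obs <- observer_params("HGF2")
  ts <- hgf_filter(tr, obs, "spatial")
  tt <- hgf_filter(tr, obs, "temporal")
  regs <- extract_regressors(ts, tt, tr)
  rel <- task == "spatial"
  # disjoint supports per dimension and centring within support
  expect_true(all(regs$pred_spatial_rel[!rel] == 0))
  expect_true(all(regs$pred_spatial_irrel[rel] == 0))
  expect_equal(mean(regs$pred_spatial_rel[rel]), 0, tolerance = 1e-12)
  expect_equal(mean(regs$pe_temporal_rel[!rel]), 0, tolerance = 1e-12)
  # uncentred variant recovers the raw magnitudes on the support
  raw <- extract_regressors(ts, tt, tr, center = FALSE)
  expect_equal(raw$pred_spatial_rel[rel], abs(ts$muhat2[rel]))
  expect_true(all(raw$pe_spatial_rel >= 0))
  # degenerate belief: all-zero level-2 means give an all-zero regressor
  zs <- ts; zs$muhat2 <- 0
  expect_true(all(extract_regressors(zs, tt, tr,
                                     center = FALSE)$pred_spatial_rel == 0))
})

test_that("signed prediction errors flip with the outcome coding", {
  set.seed(52)
  n <- 150
  u <- rbinom(n, 1, 0.75)
  task <- rep(c("spatial", "temporal"), each = 25, length.out = n)
  tr <- make_trials(u, u, task)
  flip <- make_trials(1L - u, 1L - u, task)
  obs <- observer_params("HGF2")
  r1 <- extract_regressors(hgf_filter(tr, obs, "spatial"),
                           hgf_filter(tr, obs, "temporal"), tr,
                           signed = TRUE, center = FALSE)
  r2 <- extract_regressors(hgf_filter(flip, obs, "spatial"),
                           hgf_filter(flip, obs, "temporal"), flip,
                           signed = TRUE, center = FALSE)
  expect_equal(r1$pe_spatial_rel, -r2$pe_spatial_rel, tolerance = 1e-10)
  expect_equal(r1$pe_temporal_irrel, -r2$pe_temporal_irrel,
               tolerance = 1e-10)
})

test_that("regressor correlations behave structurally", {
  set.seed(53)
  x <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  r <- regressor_correlations(x)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r, t(r))
  expect_true(all(abs(r[upper.tri(r)]) < 0.15))
  expect_equal(mean_abs_correlation(r),
               mean(abs(r[upper.tri(r)])))
  x$d <- 1
  expect_warning(r2 <- regressor_correlations(x), "constant")
  expect_true(all(is.na(r2["d", c("a", "b", "c")])))
})

test_that("parameter-accuracy correlations pick up the noise weight", {
  # agents varying only in decision noise: accuracy should correlate with
  # the fitted log zeta
  pr <- parameter_recovery_experiment(n_agents = 12, seed = 9, spread = 0.6)
  fits <- lapply(seq_len(12), function(i)
    fit_map(pr$cohort$agents[[i]], pr$model, n_restarts = 1, seed = i,
            compute_evidence = FALSE))
  rep <- parameter_accuracy_correlations(fits, pr$cohort$agents)
  expect_equal(rep$param, pr$model$priors$param)
  expect_true(all(rep$n == 12))
  expect_gt(rep$r[rep$param == "log_zeta_s_rel"], 0)
})
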
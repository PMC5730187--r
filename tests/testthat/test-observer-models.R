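test_that("sigmoid satisfies its identities", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(1e3), 1)
  x <- seq(-20, 20, length.out = 41)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(sigmoid(c(-30, 30)) > 0 & sigmoid(c(-30, 30)) < 1))
})

test_that("a single HGF step reproduces the hand-computed oracle", {
  # mu2 = 0, sigma2 = 1, kappa = 0, omega = -5, u = 1
  tr <- make_trials(1L, 1L, "spatial")
  p <- observer_params("HGF2", omega_s_rel = -5, omega_s_irrel = -5,
                       log_sigma2_0_s = 0)
  traj <- hgf_filter(tr, p, "spatial")
  pihat2 <- 1 / (1 + exp(-5))
  pi2 <- pihat2 + 0.25
  expect_equal(traj$muhat1, 0.5, tolerance = 1e-12)
  expect_equal(traj$delta1, 0.5, tolerance = 1e-12)
  expect_equal(traj$pihat2, pihat2, tolerance = 1e-12)
  expect_equal(traj$pi2, pi2, tolerance = 1e-12)
  expect_equal(traj$mu2, 0.5 / pi2, tolerance = 1e-12)
  expect_equal(traj$eps2, 0.5 / pi2, tolerance = 1e-12)
})

test_that("compiled filter matches the independent reference trajectory", {
  set.seed(42)
  for (three_level in c(FALSE, TRUE)) {
    for (rep in 1:5) {
      n <- 120
      u <- rbinom(n, 1, runif(1, 0.2, 0.8))
      task <- sample(c("spatial", "temporal"), n, replace = TRUE)
      kappa <- if (three_level) runif(1, 0.3, 1.5) else 0
      om_r <- runif(1, -6, -3); om_i <- runif(1, -6, -3)
      s20 <- exp(runif(1, -1, 1)); theta <- exp(runif(1, -7, -4))
      tr <- make_trials(u, u, task)
      p <- observer_params(if (three_level) "HGF3" else "HGF2",
                           omega_s_rel = om_r, omega_s_irrel = om_i,
                           kappa = kappa, theta = theta,
                           log_sigma2_0_s = log(s20))
      got <- hgf_filter(tr, p, "spatial")
      want <- ref_hgf(u, task == "spatial", kappa, om_r, om_i, theta,
                      0, s20, 1, 1, three_level)
      for (col in names(want))
        expect_equal(got[[col]], want[[col]], tolerance = 1e-12,
                     label = paste(col, "three_level =", three_level))
    }
  }
})

test_that("context-specific filter with equal omegas reduces to nonspecific", {
  set.seed(1)
  u <- rbinom(200, 1, 0.7)
  task <- rep(c("spatial", "temporal"), each = 50, length.out = 200)
  tr <- make_trials(u, u, task)
  ctx <- observer_params("HGF2", context_specific = TRUE,
                         omega_s_rel = -4.5, omega_s_irrel = -4.5)
  non <- observer_params("HGF2", context_specific = FALSE,
                         omega_s_rel = -4.5)
  expect_equal(hgf_filter(tr, ctx, "spatial"),
               hgf_filter(tr, non, "spatial"))
})

test_that("3-level filter with kappa = 0 reproduces the 2-level filter", {
  set.seed(2)
  u <- rbinom(300, 1, 0.6)
  tr <- make_trials(u, u, rep("spatial", 300))
  h3 <- observer_params("HGF3", kappa = 0, theta = 1e-12)
  h2 <- observer_params("HGF2")
  t3 <- hgf_filter(tr, h3, "spatial")
  t2 <- hgf_filter(tr, h2, "spatial")
  for (col in c("muhat1", "delta1", "mu2", "sigma2", "eps2"))
    expect_equal(t3[[col]], t2[[col]], tolerance = 1e-10)
  # level 3 stays at its initial mean when decoupled
  expect_true(all(abs(t3$mu3 - 1) < 1e-12))
})

test_that("under constant validity beliefs converge and surprise declines", {
  set.seed(3)
  u <- rbinom(600, 1, 0.9)
  tr <- make_trials(u, u, rep("spatial", 600))
  traj <- hgf_filter(tr, observer_params("HGF2"), "spatial")
  expect_gt(mean(traj$muhat1[501:600]), 0.75)
  expect_lt(abs(mean(traj$muhat1[501:600]) - 0.9), 0.15)
  # surprise declines from the uninformed start (|delta1| = 0.5 on trial 1)
  # to the post-learning regime
  expect_lt(mean(abs(traj$delta1[101:600])), mean(abs(traj$delta1[1:10])))
  # structural invariants of the trajectory
  expect_true(all(traj$muhat1 > 0 & traj$muhat1 < 1))
  expect_true(all(traj$sigma2 > 0))
  expect_true(all(abs(traj$delta1) <= 1))
})

test_that("higher predicted precision shrinks the weighted prediction error", {
  # same outcome and prediction, tighter level-2 prediction -> smaller |eps2|
  tr <- make_trials(1L, 1L, "spatial")
  p_wide <- observer_params("HGF2", log_sigma2_0_s = log(2))
  p_tight <- observer_params("HGF2", log_sigma2_0_s = log(0.25))
  e_wide <- hgf_filter(tr, p_wide, "spatial")$eps2
  e_tight <- hgf_filter(tr, p_tight, "spatial")$eps2
  expect_lt(abs(e_tight), abs(e_wide))
})

test_that("filtering is deterministic and rejects invalid input", {
  set.seed(4)
  u <- rbinom(100, 1, 0.5)
  tr <- make_trials(u, u, rep("spatial", 100))
  p <- observer_params("HGF2")
  expect_identical(hgf_filter(tr, p, "spatial"),
                   hgf_filter(tr, p, "spatial"))
  bad <- make_trials(c(u[-1], 2L), u, rep("spatial", 100))
  expect_error(hgf_filter(bad, p, "spatial"), "binary")
  expect_error(observer_params("HGF2", kappa = 1), "kappa")
  expect_error(observer_params("HGF3", theta = 0), "theta")
})

test_that("Rescorla-Wagner filter follows its closed-form recursion", {
  u <- c(1L, 0L, 1L, 1L)
  tr <- make_trials(u, u, rep("spatial", 4))
  p <- observer_params("RW", alpha_s = 0.1)
  traj <- rw_filter(tr, p, "spatial")
  expect_equal(traj$muhat1[1], 0.5)
  expect_equal(traj$muhat1[2], 0.55) # 0.5 + 0.1 * (1 - 0.5)
  expect_equal(traj$value, traj$muhat1 + 0.1 * traj$delta1)
  # alpha = 0: frozen at 0.5; alpha = 1: pure tracking
  t0 <- rw_filter(tr, observer_params("RW", alpha_s = 0), "spatial")
  expect_true(all(t0$muhat1 == 0.5))
  t1 <- rw_filter(tr, observer_params("RW", alpha_s = 1), "spatial")
  expect_equal(t1$muhat1[-1], as.numeric(u[-4]))
  expect_error(observer_params("RW", alpha_s = 1.2), "\\[0, 1\\]")
})
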
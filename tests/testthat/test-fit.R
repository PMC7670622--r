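test_that("breakpoint sampling covers the full set and is reproducible", {
  expect_identical(sample_breakpoints(10, 8), 1:8)   # m = n - 2: everything
  expect_identical(sample_breakpoints(10, 0), integer())
  set.seed(5); a <- sample_breakpoints(30, 7)
  set.seed(5); b <- sample_breakpoints(30, 7)
  expect_identical(a, b)
  expect_true(all(diff(a) > 0) && all(a >= 1) && all(a <= 28))
  expect_error(sample_breakpoints(10, 9), "0..8")
})

test_that("breakpoint-count selection requires a 1.92 out-of-sample gain", {
  G <- c(`49` = -1000.0, `99` = -997.0, `149` = -996.5, `198` = -996.4)
  expect_identical(select_breakpoint_count(G), 99L)
  expect_identical(select_breakpoint_count(c(`4` = -10, `9` = -10, `14` = -10)),
                   4L)   # ties keep the simplest model
  expect_identical(select_breakpoint_count(c(`7` = -5)), 7L)
  # advance requires beating EVERY smaller candidate
  G2 <- c(`2` = -100, `4` = -90, `6` = -99)
  expect_identical(select_breakpoint_count(G2), 4L)
  expect_error(select_breakpoint_count(numeric()), "no candidate")
})

test_that("single-epoch fit recovers a constant theta within 5%", {
  set.seed(12)
  truth <- 4.8e-4
  x <- simulate_skyline_sfs(epoch_theta(10, rep(truth, 9)), L = 1e6)
  f <- fit_thetas(x, integer(), inference_config(mu = 1.2e-8))
  expect_identical(f$theta$breakpoints, integer())
  expect_lt(abs(f$theta$theta[1] / truth - 1), 0.05)
})

test_that("greedy search only ever improves the training likelihood", {
  set.seed(13)
  model <- model_presets()$zigzag
  x <- fold_sfs(simulate_coalescent_sfs(model, n = 20, L = 1e6, mu = 1.2e-8))
  f <- fit_thetas(x, 1:18, inference_config(mu = 1.2e-8))
  expect_true(all(diff(f$loglik_path) > 0))
  expect_true(all(f$theta$breakpoints %in% f$candidates))
  expect_equal(f$train_loglik, composite_loglik(
    x, class_probabilities(f$theta, x)), tolerance = 1e-6)
})

test_that("richer candidate sets cannot lower the best achievable fit", {
  set.seed(14)
  x <- fold_sfs(simulate_coalescent_sfs(model_presets()$zigzag,
                                        n = 12, L = 1e6, mu = 1.2e-8))
  ctx <- stairsfs:::fit_context(x, 1e-12)
  l1 <- stairsfs:::fit_grouping(ctx, 5L)$loglik
  l2 <- stairsfs:::fit_grouping(ctx, c(3L, 5L))$loglik
  l3 <- stairsfs:::fit_grouping(ctx, c(3L, 5L, 8L))$loglik
  expect_gte(l2, l1 - 1e-6)
  expect_gte(l3, l2 - 1e-6)
})

test_that("distinct theta groups never exceed the observed class count", {
  set.seed(15)
  x <- fold_sfs(simulate_coalescent_sfs(model_presets()$zigzag,
                                        n = 20, L = 1e7, mu = 1.2e-8))
  cfg <- inference_config(mu = 1.2e-8, greedy_threshold = 0)
  f <- fit_thetas(x, 1:18, cfg)
  n_groups <- length(f$theta$breakpoints) + 1L
  expect_lte(n_groups, 11L)   # 10 folded polymorphic classes + monomorphic
})

test_that("an all-monomorphic training spectrum pins theta at the floor", {
  x <- sfs(c(1000, rep(0, 9)), n = 10)
  f <- fit_thetas(x, integer(), inference_config(mu = 1.2e-8))
  expect_lt(f$theta$theta[1], 1e-11)
})

test_that("evaluating a model on its own training data returns train_loglik", {
  set.seed(16)
  x <- simulate_skyline_sfs(epoch_theta(10, rep(5e-4, 9)), L = 1e5)
  f <- fit_thetas(x, c(2L, 5L), inference_config(mu = 1.2e-8))
  expect_equal(evaluate_model(f, x), f$train_loglik, tolerance = 1e-9)
  y <- sfs(c(100, 1, 1), n = 4, folded = TRUE)
  expect_error(evaluate_model(f, y), "does not match")
})

test_that("a zero-SNP testing spectrum scores l_n * log p_0", {
  set.seed(17)
  x <- simulate_skyline_sfs(epoch_theta(6, rep(5e-4, 5)), L = 1e5)
  f <- fit_thetas(x, integer(), inference_config(mu = 1.2e-8))
  test0 <- sfs(c(250, rep(0, 5)), n = 6)
  p <- class_probabilities(f$theta, test0)
  # multinomial constant vanishes when one class holds all sites
  expect_equal(evaluate_model(f, test0), 250 * log(p$p[1]),
               tolerance = 1e-10)
})

test_that("ensembles are deterministic given the master seed", {
  set.seed(18)
  x <- simulate_skyline_sfs(epoch_theta(10, rep(5e-4, 9)), L = 1e6)
  cfg <- inference_config(B = 4, mu = 1.2e-8, seed = 31)
  e1 <- run_ensemble(x, cfg)
  e2 <- run_ensemble(x, cfg)
  expect_identical(e1$G, e2$G)
  expect_identical(e1$chosen_m, e2$chosen_m)
  expect_identical(lapply(e1$models, function(m) m$theta$theta),
                   lapply(e2$models, function(m) m$theta$theta))
  # B = 1 degenerates to one split + one selection
  e3 <- run_ensemble(x, inference_config(B = 1, mu = 1.2e-8, seed = 31))
  expect_length(e3$models, 1L)
  expect_identical(dim(e3$test_loglik), c(1L, 4L))
})

test_that("a two-epoch expansion is recovered from the ensemble median", {
  # 10-fold ancient-to-recent expansion: recent N = 10,000, ancient N = 1,000,
  # change at the boundary between the theta_6 and theta_5 intervals
  set.seed(19)
  n <- 20
  truth <- epoch_theta(n, c(rep(4.8e-5, 4), rep(4.8e-4, 15)),
                       breakpoints = 4L)
  x <- simulate_skyline_sfs(truth, L = 1e7)
  cfg <- inference_config(B = 20, mu = 1.2e-8, seed = 19)
  ens <- run_ensemble(x, cfg)
  trajs <- lapply(ens$models, function(m)
    ne_trajectory(m$theta, 1.2e-8, b = m$b))
  s <- summarize_ensemble(trajs)
  t_change <- epoch_times(truth)[5]            # T_6, the true change point
  recent <- s$time < t_change / 2
  ancient <- s$time > t_change * 1.3   # the grid ends near the truth's T_2
  expect_lt(abs(median(s$Ne_median[recent]) / 10000 - 1), 0.25)
  expect_lt(abs(median(s$Ne_median[ancient]) / 1000 - 1), 0.25)
  # change time within 2-fold: still near the recent size at t_change / 2,
  # already near the ancient size at 2 * t_change
  at <- function(t) s$Ne_median[which.min(abs(log(s$time) - log(t)))]
  expect_gt(at(t_change / 2), 5000)
  expect_lt(at(t_change * 2), 2000)
})
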
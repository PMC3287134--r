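small_cfg <- function(...) {
  args <- list(sgncmb = c("X", "Y"), predicttime_u = 1,
               optimizemethod = "ragwitz", ragdim = 1:3,
               ragtaurange = c(0.5, 1.5), ragtausteps = 5,
               repPred = 60, trialselect = "no", minnrtrials = 4,
               maxlag = 100, numpermutation = 200, rng_seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(analysis_config, args)
}

test_that("prepare yields a complete embedding spec per ordered pair", {
  d <- quick_coupled_pair(8, 400, seed = 51)
  prep <- prepare(d, small_cfg(), opt_ntrials = 2)
  expect_s3_class(prep, "prepared_dataset")
  expect_equal(nrow(prep$pairs), 1L)
  sp <- prep$specs[[1]]
  expect_true(sp$d >= 1 && sp$tau >= 1 && sp$u == 1L)
  expect_equal(sp$k, 4L)
  expect_length(prep$trials[[1]], 8L)
  expect_error(prepare(d, small_cfg(sgncmb = c("X", "Z"))), "unknown channel")
})

test_that("trial selection follows the range and ACT rules", {
  d <- quick_coupled_pair(12, 400, seed = 52)
  prep <- prepare(d, small_cfg(trialselect = "range", trial_from = 5,
                               trial_to = 10), opt_ntrials = 2)
  expect_equal(prep$trials[[1]], 5:10)
  # an ACT threshold below every trial's ACT leaves too few trials
  expect_error(prepare(d, small_cfg(trialselect = "ACT", actthrvalue = 0)),
               "too few trials")
})

test_that("dimension override bypasses optimisation", {
  d <- quick_coupled_pair(6, 300, seed = 53)
  prep <- prepare(d, small_cfg(dim = 2, tau_samples = 3))
  expect_equal(prep$specs[[1]]$d, 2L)
  expect_equal(prep$specs[[1]]$tau, 3L)
})

test_that("surrogate analysis detects built-in coupling and gates on mixing", {
  d <- quick_coupled_pair(10, 400, coupling = 0.9, lag = 1, seed = 54)
  cfg <- small_cfg(dim = 1, tau_samples = 1, shifttesttype = "TEshift > TE")
  prep <- prepare(d, cfg)
  res <- surrogate_analysis(prep)
  pt <- res$permtest
  expect_equal(nrow(pt), 2L)  # both directions
  xy <- pt[pt$source == "X" & pt$target == "Y", ]
  yx <- pt[pt$source == "Y" & pt$target == "X", ]
  expect_true(xy$significant)
  expect_equal(xy$verdict, "significant interaction")
  expect_false(yx$significant)
  # the shift-test gate: mixing and significance never co-reported
  expect_false(any(pt$verdict == "significant interaction" &
                     pt$mixing_detected))
  expect_equal(nrow(res$te$table), 20L)
})

test_that("end-to-end runs are bitwise deterministic under a fixed seed", {
  d <- quick_coupled_pair(8, 300, seed = 55)
  cfg <- small_cfg(dim = 1, tau_samples = 1)
  r1 <- surrogate_analysis(prepare(d, cfg))
  r2 <- surrogate_analysis(prepare(d, cfg))
  expect_identical(r1$permtest, r2$permtest)
  expect_identical(r1$te$table, r2$te$table)
})

test_that("condition comparison is antisymmetric and null on identical data", {
  da <- quick_coupled_pair(8, 300, coupling = 0.9, seed = 56)
  db <- quick_coupled_pair(8, 300, coupling = 0.0, seed = 57)
  cfg <- small_cfg(dim = 1, tau_samples = 1, permstatstype = "mean")
  pa <- prepare(da, cfg); pb <- prepare(db, cfg)
  ab <- compare_conditions(pa, pb, cfg)
  ba <- compare_conditions(pb, pa, cfg)
  expect_equal(ab$t_obt, -ba$t_obt, tolerance = 1e-12)
  xy <- ab[ab$source == "X" & ab$target == "Y", ]
  expect_true(xy$significant)
  expect_gt(xy$mean_te_a, xy$mean_te_b)
  same <- compare_conditions(pa, pa, cfg)
  expect_true(all(!same$significant))
  expect_true(all(same$p > 0.5))
})

test_that("group pipeline checks design validity and preparation consistency", {
  ar <- ar_sim_config(n_trials = 4, n_samples = 400)
  g <- simulate_group_study(n_subjects = 3, seed = 13, ar = ar)
  cfg <- analysis_config(sgncmb = rbind(c("F3", "T8"), c("T7", "F4")),
                         predicttime_u = 21, dim = 1, tau_samples = 1,
                         trialselect = "no", minnrtrials = 3,
                         maxlag = 100, permstatstype = "depsamplesT",
                         numpermutation = 500, rng_seed = 17)
  preps <- lapply(g$datasets, prepare, cfg = cfg)
  # inconsistent preparation is refused
  cfg2 <- analysis_config(sgncmb = rbind(c("F3", "T8"), c("T7", "F4")),
                          predicttime_u = 22, dim = 1, tau_samples = 1,
                          trialselect = "no", minnrtrials = 3,
                          maxlag = 100, numpermutation = 500)
  mixed <- preps
  mixed[[2]] <- prepare(g$datasets[[2]], cfg2)
  expect_error(group_pipeline(mixed, g$design, cfg),
               "inconsistent preparation")
  # a unit missing from condition 2 breaks the paired design
  bad_design <- group_design(g$design$design[, -4, drop = FALSE])
  expect_error(group_pipeline(preps[-4], bad_design, cfg),
               "each unit exactly once")
})

test_that("group results are invariant to dataset input order", {
  ar <- ar_sim_config(n_trials = 4, n_samples = 300)
  g <- simulate_group_study(n_subjects = 3, seed = 19, ar = ar)
  cfg <- analysis_config(sgncmb = rbind(c("F3", "T8")),
                         predicttime_u = 21, dim = 1, tau_samples = 1,
                         trialselect = "no", minnrtrials = 3,
                         maxlag = 100, permstatstype = "depsamplesT",
                         numpermutation = 500, rng_seed = 23)
  preps <- lapply(g$datasets, prepare, cfg = cfg)
  r1 <- group_pipeline(preps, g$design, cfg)
  ord <- c(4, 2, 6, 1, 5, 3)
  gd2 <- group_design(g$design$design[, ord])
  r2 <- group_pipeline(preps[ord], gd2, cfg)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$t_obt, r2$t_obt, tolerance = 1e-12)
})
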
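test_that("bias, MSE, and relative bias follow their definitions", {
  perfect <- bias_and_mse(rep(2, 10), 2)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$mse, 0)

  expect_equal(bias_and_mse(c(1, 2, 3), 1.5)$bias, 0.5)

  res <- bias_and_mse(c(1, 2, 3), 1)
  expect_equal(res$mse, 5 / 3, tolerance = 1e-12)
  expect_equal(res$mse, res$var_estimate + res$bias^2, tolerance = 1e-12)
  expect_equal(res$relative_bias_pct, 100)

  expect_true(is.na(bias_and_mse(c(-1, 1), 0)$relative_bias_pct))
  expect_error(bias_and_mse(numeric(), 1), "empty")
  expect_error(bias_and_mse(1:3, NA), "finite")
})

test_that("MSE identity holds on every summary of a study run", {
  cfg <- study_config(one_condition_grid(
    path_coefficients(a = 0.39, b = 0.59, d = 0.39, f = 0.39, g = 0.14,
                      h = 0.14), sample_size = 150),
    replications = 30, master_seed = 3)
  res <- run_condition(cfg$grid[[1]], cfg)
  expect_equal(res$mse, res$var_estimate + res$bias^2, tolerance = 1e-12)
  expect_true(all(res$mse >= res$bias^2))
})

test_that("run_condition is deterministic and aggregates per spec", {
  cond <- simulation_condition("c1", path_coefficients(a = 0.39, b = 0.59),
                               200)
  cfg <- study_config(structure(list(cond), class = "condition_grid"),
                      batteries = list(two_confounder = two_confounder_battery()),
                      replications = 25, master_seed = 11,
                      keep_replications = TRUE)
  r1 <- run_condition(cond, cfg)
  r2 <- run_condition(cond, cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 5)
  expect_true(all(r1$R == 25))
  expect_true(all(r1$n_failed == 0))
  reps <- attr(r1, "replications")
  expect_equal(nrow(reps), 25 * 5)
  expect_true(all(is.finite(reps$indirect_hat)))
})

test_that("failed replications are excluded and counted, not fatal", {
  boom <- estimation_spec("regression", label = "boom",
                          estimator = local({
                            calls <- 0L
                            function(dataset, spec, total_hat) {
                              calls <<- calls + 1L
                              if (calls %% 3L == 0L) stop("numerical failure")
                              effect_estimates("boom", "boom", 1, 0.5)
                            }
                          }))
  cond <- simulation_condition("c1", path_coefficients(a = 0.39, b = 0.59), 80)
  cfg <- study_config(structure(list(cond), class = "condition_grid"),
                      batteries = list(b = list(boom)),
                      replications = 9, master_seed = 1)
  res <- suppressMessages(run_condition(cond, cfg))
  expect_equal(res$n_failed, 3)
  expect_equal(res$R, 6)
})

test_that("run_study concatenates conditions and batteries in grid order", {
  grid <- build_condition_grid(a_levels = c(0.14, 0.59), b_levels = 0.59,
                               cprime_levels = 0, dm_levels = 0.14,
                               gx_levels = 0, sample_size = 120)
  cfg <- study_config(grid, replications = 4, master_seed = 2)
  res <- run_study(cfg)
  expect_equal(nrow(res), 2 * (5 + 7))
  expect_identical(unique(res$condition_id),
                   vapply(grid, `[[`, character(1), "id"))
  expect_named(res, c("condition_id", "a", "b", "c_prime", "d", "f", "g", "h",
                      "battery", "method", "spec_label", "truth",
                      "mean_estimate", "bias", "mse", "var_estimate",
                      "relative_bias_pct", "coverage", "R", "n_failed"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_summary(res, path)
  expect_equal(nrow(read.csv(path)), nrow(res))
})

test_that("study loop attaches bootstrap coverage when enabled", {
  cond <- simulation_condition("c1", path_coefficients(a = 0.39, b = 0.59), 100)
  cfg <- study_config(structure(list(cond), class = "condition_grid"),
                      batteries = list(b = list(estimation_spec("regression"))),
                      replications = 8, master_seed = 5, bootstrap = TRUE,
                      n_resamples = 60)
  res <- run_condition(cond, cfg)
  expect_true(res$coverage >= 0 && res$coverage <= 1)
})

test_that("zero-confounding check flags a broken estimator but not sound ones", {
  stub <- estimation_spec("regression", label = "broken",
                          estimator = function(dataset, spec, total_hat) {
                            effect_estimates("broken", "broken",
                                             total_hat = 1.2301, direct_hat = 0)
                          })
  res <- zero_confounding_check(replications = 10, sample_size = 100,
                                batteries = list(b = list(
                                  estimation_spec("seq_g",
                                                  outcome_confounders = c("C1", "C2")),
                                  stub)))
  expect_named(res, c("method", "spec_label", "truth", "mean_estimate",
                      "bias", "relative_bias_pct", "pass"))
  expect_false(res$pass[res$spec_label == "broken"])  # truth + 1 is ~435% off
})

test_that("config validation refuses empty batteries and bad replication counts", {
  grid <- one_condition_grid(path_coefficients(a = 0.39, b = 0.59))
  expect_error(study_config(grid, replications = 0), "replications")
  expect_error(study_config(grid, batteries = list()), "non-empty")
})
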
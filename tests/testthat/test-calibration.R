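test_that("observation tables enforce their invariants", {
  expect_error(observation_table(t = 5, kind = "exact", value = 0.1),
               "at least two")
  expect_error(observation_table(t = c(10, 5), kind = "exact",
                                 value = c(0.1, 0.2)), "strictly increasing")
  expect_error(observation_table(t = c(0, 5), kind = "exact",
                                 value = c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(observation_table(t = c(0, 5), kind = "interval",
                                 lower = c(0.2, 0), upper = c(0.1, 0.05)),
               "lower <= upper")
})

test_that("observation CSV dialect round-trips and converts percentages", {
  obs <- observation_table(t = c(0, 90, 150),
                           kind = c("interval", "exact", "exact"),
                           value = c(NA, 0.08, 0.24),
                           lower = c(0, NA, NA), upper = c(0.05, NA, NA),
                           patient_id = "P1")
  path <- tempfile(fileext = ".csv")
  write_observations(list(P1 = obs), path)
  back <- read_observations(path)[["P1"]]
  expect_equal(back$t, obs$t)
  expect_equal(back$kind, obs$kind)
  expect_equal(back$value, obs$value)
  expect_equal(back$upper, obs$upper)
  raw <- read.csv(path)
  expect_equal(raw$blast_pct_exact[2], 8)  # stored as percent

  # rows are reordered by time on load
  raw2 <- raw[c(3, 1, 2), ]
  path2 <- tempfile(fileext = ".csv")
  write.csv(raw2, path2, row.names = FALSE, na = "")
  expect_equal(read_observations(path2)[["P1"]]$t, obs$t)
})

test_that("RMSE objective follows the exact/interval residual conventions", {
  p <- leuk_m2(0.85, 0.6, 3.0)
  init <- seeded_state(p, 500)
  tt <- c(0, 15, 30, 45)
  obs_exact <- obs_from_trajectory(p, init, tt)

  # curve through every exact point: zero
  expect_lt(objective_rmse(p$leukemic, 500, "model2", obs_exact), 1e-9)

  # model inside every interval: zero
  bf <- obs_exact$value
  obs_iv <- observation_table(t = tt, kind = "interval",
                              lower = pmax(bf - 0.02, 0),
                              upper = pmin(bf + 0.02, 1))
  expect_equal(objective_rmse(p$leukemic, 500, "model2", obs_iv), 0)

  # frozen two-point case: residuals 0.03 and 0.04 give sqrt(mean) = 0.03536
  obs_off <- observation_table(t = tt[3:4], kind = "exact",
                               value = bf[3:4] - c(0.03, 0.04))
  expect_equal(objective_rmse(p$leukemic, 500, "model2", obs_off),
               sqrt((0.03^2 + 0.04^2) / 2), tolerance = 1e-6)

  # scaling all residuals scales the rmse linearly
  obs_off2 <- observation_table(t = tt[3:4], kind = "exact",
                                value = bf[3:4] - c(0.015, 0.02))
  expect_equal(objective_rmse(p$leukemic, 500, "model2", obs_off2),
               objective_rmse(p$leukemic, 500, "model2", obs_off) / 2,
               tolerance = 1e-5)
})

test_that("noiseless trajectories are recovered to far below measurement noise", {
  p <- leuk_m2(0.85, 0.6, 3.0)
  obs <- obs_from_trajectory(p, seeded_state(p, 500), c(0, 10, 20, 30, 40, 55))
  fit <- fit_model("model2", obs, n_starts = 16, seed = 1)
  expect_true(fit$converged)
  expect_lt(fit$rmse, 1e-3)
  # the recovered parameters reproduce the effective growth rate even
  # though (a_l, p_l) are only identified through it
  egr_true <- effective_growth_rate(0.85, 0.6)
  egr_fit <- effective_growth_rate(fit$params$leukemic$a, fit$params$leukemic$p)
  expect_equal(egr_fit, egr_true, tolerance = 0.02)
})

test_that("fits are deterministic given the seed", {
  p <- leuk_m2(0.8, 0.5)
  obs <- obs_from_trajectory(p, seeded_state(p, 1000), c(0, 20, 40, 60))
  f1 <- fit_model("model2", obs, n_starts = 6, seed = 42)
  f2 <- fit_model("model2", obs, n_starts = 6, seed = 42)
  expect_identical(f1$rmse, f2$rmse)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$multistart, f2$multistart)
})

test_that("a fast relapse is explained by the autonomous model only", {
  # 10% marrow blasts within ~25 days of remission from a small residual
  # burden: far beyond what feedback-limited expansion can produce
  p <- leuk_m2(0.95, 1)
  obs <- obs_from_trajectory(p, seeded_state(p, 100), c(0, 10, 18, 25))
  f1 <- fit_model("model1", obs, n_starts = 12, seed = 1)
  f2 <- fit_model("model2", obs, n_starts = 12, seed = 1)
  expect_gt(f1$rmse, 10 * max(f2$rmse, 1e-6))
  expect_identical(select_model(f1, f2)$group, "group2")
})

test_that("model selection applies the relative-RMSE rule with its tie band", {
  mkfit <- function(variant, rmse)
    structure(list(variant = variant, rmse = rmse, converged = TRUE),
              class = "leukdyn_fit")
  # 6% worse: the autonomous model is preferred
  sel <- select_model(mkfit("model1", 0.106), mkfit("model2", 0.100))
  expect_identical(sel$group, "group2")
  expect_false(sel$compatible[["model1"]])
  # 4% worse: inside the band, both compatible
  sel2 <- select_model(mkfit("model1", 0.104), mkfit("model2", 0.100))
  expect_identical(sel2$group, "group1")
  expect_true(all(sel2$compatible))
  # exact tie
  expect_identical(select_model(mkfit("model1", 0.1), mkfit("model2", 0.1))$group,
                   "group1")
  # symmetric: swapping the fits swaps the preference
  selA <- select_model(mkfit("model1", 0.2), mkfit("model2", 0.1))
  selB <- select_model(mkfit("model1", 0.1), mkfit("model2", 0.2))
  expect_identical(selA$preferred, "model2")
  expect_identical(selB$preferred, "model1")
  # RMSEs below measurement resolution are not distinguished
  sel3 <- select_model(mkfit("model1", 3e-4), mkfit("model2", 1e-9))
  expect_identical(sel3$group, "group1")
  # failed fit on either side
  bad <- structure(list(variant = "model1", rmse = NA_real_, converged = FALSE),
                   class = "leukdyn_fit")
  expect_identical(select_model(bad, mkfit("model2", 0.1))$group, "undetermined")
})
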
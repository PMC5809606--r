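test_that("threshold-crossing times come from event detection and match the oracle", {
  # a clone that cannot invade never reaches the threshold
  p_dead <- leuk_m1(0.9, 1)
  expect_identical(time_to_blast_threshold(p_dead, horizon = 2000), Inf)

  # fastest autonomous expansion: crossing time agrees with the
  # independent RK4 oracle to better than 1%
  p <- leuk_m2(1, 1)
  t_pkg <- time_to_blast_threshold(p)
  t_orc <- rk4_crossing_time(p, seeded_state(p), 30, 0.002, 0.1)
  expect_lt(abs(t_pkg - t_orc) / t_orc, 0.01)

  # an already-relapsed state crosses immediately
  init <- seeded_state(p)
  init["l1"] <- init["c1"]
  expect_equal(time_to_blast_threshold(p, init = init), 0)

  expect_error(time_to_blast_threshold(p, threshold = 0), "threshold")
})

test_that("autonomous expansion is faster than cytokine-dependent expansion on a shared grid", {
  grid <- seq(0.94, 1, length.out = 10)
  s1 <- expansion_scan("model1", a_grid = grid)
  s2 <- expansion_scan("model2", a_grid = grid)
  expect_true(all(is.finite(s2$days)))
  both <- is.finite(s1$days)
  expect_true(any(both))
  expect_true(all(s2$days[both] < s1$days[both]))
  # larger self-renewal means earlier crossing on the expanding branch
  expect_true(all(diff(s2$days) <= 0))
  expect_true(all(diff(s1$days[both]) <= 0))
  expect_true(all(s2$days > 0))
})

test_that("expansion scan rejects invalid grids and proliferation rates", {
  expect_error(expansion_scan("model2", a_grid = numeric(0)), "at least one")
  expect_error(expansion_scan("model2", a_grid = c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(expansion_scan("model2", p_l = 1.5), "one division per day")
})

test_that("stimulation experiment handles the no-trigger case and ties", {
  # a dying clone never depletes mature cells
  res <- stimulation_experiment(leuk_m1(0.9, 1), horizon = 1500)
  expect_false(res$triggered)
  expect_identical(res$classification, "not_triggered")

  # exactly matched effective growth rates predict no relevant effect
  hc <- default_healthy_params()
  p_tie <- leuk_m2(0.93, hc$p)
  expect_identical(predict_stimulation_response(p_tie), "neutral")
})

test_that("transient remission under the autonomous model regrows after the protocol", {
  p <- leuk_m2(0.75, 0.6)   # growth rate below the stimulated healthy rate
  res <- stimulation_experiment(p)
  expect_true(res$triggered)
  expect_identical(res$classification, "beneficial")
  l1 <- res$stimulated$l1
  tt <- res$stimulated$t
  expect_gt(l1[which(tt == 90)], l1[which(tt == 30)])  # regrowth
  # and the control branch was never reduced
  expect_gt(res$control$l1[which(tt == 30)], res$stimulated$l1[which(tt == 30)])
})

test_that("stimulation experiments are deterministic", {
  p <- leuk_m1(0.99, 0.8)
  r1 <- stimulation_experiment(p)
  r2 <- stimulation_experiment(p)
  expect_identical(r1$share_change, r2$share_change)
  expect_identical(r1$t_trigger, r2$t_trigger)
})
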
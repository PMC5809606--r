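test_that("feedback signal has the saturating form and is monotone in consumers", {
  expect_equal(feedback_signal(1e-9, 0), 1)
  expect_equal(feedback_signal(1, 1), 0.5)
  expect_equal(feedback_signal(2e-9, 1e9), 1 / 3)
  expect_equal(feedback_signal(1e-9, 5e8, stimulated = TRUE), 1)

  cc <- seq(0, 5e9, length.out = 50)
  s <- feedback_signal(1e-9, cc)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))

  expect_error(feedback_signal(0, 1), "positive")
  expect_error(feedback_signal(-1, 1), "positive")
  expect_error(feedback_signal(1e-9, -1), ">= 0")
})

test_that("effective growth rate reproduces the self-renewal/proliferation trade-off", {
  expect_equal(effective_growth_rate(0.5, 1), 0)
  expect_equal(effective_growth_rate(0.5, 0.123), 0)
  expect_equal(effective_growth_rate(1, 1), 1)
  # slow proliferation with high self-renewal matches fast proliferation
  # with modest self-renewal
  expect_equal(effective_growth_rate(0.9, 0.2), 0.16)
  expect_equal(effective_growth_rate(0.58, 1.0), 0.16)
  expect_error(effective_growth_rate(1.2, 1), "\\[0, 1\\]")
  expect_error(effective_growth_rate(0.8, -1), ">= 0")
})

test_that("right-hand side vanishes at the healthy equilibrium and matches plug-in cases", {
  p <- model_params(lineage_params(0.8, 0.5, 3), dbar = 0)
  eq <- healthy_equilibrium(p)
  expect_lt(max(abs(model_rhs(eq, p)) / pmax(eq, 1)), 1e-12)

  # autonomous leukemia at full self-renewal doubles at its proliferation rate
  p2 <- leuk_m2(1, 1, dbar = 0)
  st <- c(c1 = 1e9, c2 = 5e8, l1 = 2e5, l2 = 0)
  d <- model_rhs(st, p2)
  expect_equal(d[["l1"]], 2e5)

  # invasion sign under the cytokine-dependent model is set by the
  # self-renewal comparison, not the proliferation rate
  for (a_l in c(0.90, 0.96)) {
    for (p_l in c(0.1, 1)) {
      p1 <- leuk_m1(a_l, p_l, dbar = 0)
      st <- healthy_equilibrium(p1)
      st["l1"] <- 1
      d <- model_rhs(st, p1)
      expect_equal(sign(d[["l1"]]), sign(a_l - p1$healthy$a))
    }
  }

  expect_error(model_rhs(c(c1 = -1, c2 = 0, l1 = 0, l2 = 0), p2), "finite and >= 0")
})

test_that("healthy equilibrium closed form is correct and matches the numeric root", {
  p <- model_params(lineage_params(0.8, 0.5, 2.3),
                    healthy = lineage_params(0.87, 0.42, 2.3),
                    k = 1e-9, dbar = 0)
  eq <- healthy_equilibrium(p)
  expect_equal(eq[["c2"]], (2 * 0.87 - 1) / 1e-9)          # 7.4e8 cells/kg
  expect_equal(eq[["c1"]], 2.3 * eq[["c2"]] / 0.42)
  expect_equal(attr(eq, "s"), 1 / (2 * 0.87))
  expect_equal(eq[["l1"]], 0)

  num <- healthy_equilibrium(p, method = "numeric")
  expect_lt(max(abs(num - eq) / pmax(eq, 1)), 1e-8)

  # with crowding the root satisfies the full stationarity conditions
  pc <- model_params(lineage_params(0.93, 0.7, 2.3), dbar = 1e-12)
  eqc <- healthy_equilibrium(pc)
  expect_lt(max(abs(model_rhs(eqc, pc)) / pmax(eqc, 1)), 1e-8)

  expect_error(healthy_equilibrium(model_params(lineage_params(0.9, 1, 1),
                                                healthy = lineage_params(0.5, 1, 1))),
               "exceed 0.5")
})

test_that("blast fraction is the leukemic share of mitotic cells", {
  expect_equal(blast_fraction(c(c1 = 1e9, c2 = 1, l1 = 0, l2 = 0)), 0)
  expect_equal(blast_fraction(c(c1 = 5e8, c2 = 1, l1 = 5e8, l2 = 0)), 0.5)
  expect_equal(blast_fraction(c(c1 = 9e8, c2 = 1, l1 = 1e8, l2 = 0)), 0.1)
  expect_error(blast_fraction(c(c1 = 0, c2 = 1, l1 = 0, l2 = 0)), "empty marrow")
})

test_that("healthy equilibrium persists and sub-threshold clones die out", {
  p <- leuk_m1(0.8, 0.5)
  eq <- healthy_equilibrium(p)
  tr <- simulate_model(p, init = eq, t_end = 1000, times = seq(0, 1000, 50))
  for (v in c("c1", "c2")) {
    expect_lt(max(abs(tr[[v]] - eq[[v]])) / eq[[v]], 1e-6)
  }
  expect_true(all(tr$l1 == 0))

  # cytokine-dependent clone with self-renewal below the healthy level
  # is eliminated
  p_low <- leuk_m1(0.85, 1, dbar = 0)
  tr2 <- simulate_model(p_low, init = seeded_state(p_low), t_end = 500,
                        times = seq(0, 500, 25))
  expect_lt(tr2$l1[nrow(tr2)], 1e-3)
})

test_that("compartments stay non-negative from boundary states", {
  starts <- list(
    c(c1 = 0, c2 = 1e9, l1 = 10, l2 = 0),
    c(c1 = 1e5, c2 = 0, l1 = 0, l2 = 1e8),
    c(c1 = 1e9, c2 = 1e9, l1 = 0, l2 = 0))
  for (variant in c("model1", "model2")) {
    p <- model_params(lineage_params(0.9, 0.8, 3), variant = variant)
    for (st in starts) {
      tr <- simulate_model(p, init = st, t_end = 100)
      expect_true(all(as.matrix(tr[, c("c1", "c2", "l1", "l2")]) >= 0))
    }
  }
})

test_that("only the cytokine-dependent model couples leukemic mature cells to the signal", {
  st <- c(c1 = 1e9, c2 = 5e8, l1 = 1e7, l2 = 0)
  st_l2 <- st
  st_l2["l2"] <- 5e8
  p1 <- leuk_m1(0.9, 0.5)
  p2 <- leuk_m2(0.9, 0.5)
  expect_lt(attr(model_rhs(st_l2, p1), "s"), attr(model_rhs(st, p1), "s"))
  expect_equal(attr(model_rhs(st_l2, p2), "s"), attr(model_rhs(st, p2), "s"))
})

test_that("trajectories expose time, densities, signal and blast fraction", {
  p <- leuk_m2(0.9, 0.8)
  tr <- simulate_model(p, init = seeded_state(p, 100), t_end = 10)
  expect_s3_class(tr, "leukdyn_trajectory")
  expect_named(tr, c("t", "c1", "c2", "l1", "l2", "s", "blast_fraction"))
  expect_true(all(diff(tr$t) > 0))
  expect_equal(tr$blast_fraction, tr$l1 / (tr$c1 + tr$l1))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path)
  expect_equal(back$l1, tr$l1)
  expect_named(back, c("t_days", "c1", "c2", "l1", "l2", "s", "blast_fraction"))
})
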
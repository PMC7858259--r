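test_that("the reward-space sweep traces monotone, once-crossing curves", {
  g <- pd_game(floor = 0)
  sw <- sweep_exploitation(g, grid = 1:12,
                           cutoff_pair = c("Cooperate", "Policy 3"))
  expect_identical(sw$parameter_name, "exploitation_reward")
  expect_equal(nrow(sw$curves), 12)
  coop <- sw$curves[["Cooperate"]]
  pol3 <- sw$curves[["Policy 3"]]
  # anchor at the default temptation reward 5
  expect_equal(coop[sw$grid == 5], log2(23 / 12), tolerance = 1e-12)
  # as exploiting gets more attractive, cooperating gets riskier and the
  # hostile policy safer
  expect_true(all(diff(coop) > 0))
  expect_true(all(diff(pol3) < 0))
  # single crossing: strictly below before temptation 8, equal at 8, above after
  d <- coop - pol3
  expect_true(all(d[sw$grid < 8] < 0))
  expect_lt(abs(d[sw$grid == 8]), 1e-12)
  expect_true(all(d[sw$grid > 8] > 0))
  # the curves meet at temptation 8, both at log2(29/12)
  expect_equal(coop[sw$grid == 8], log2(29 / 12), tolerance = 1e-12)
  expect_equal(pol3[sw$grid == 8], log2(29 / 12), tolerance = 1e-12)
  expect_s3_class(sw$cutoff, "cutoff_estimate")
  expect_equal(sw$cutoff$parameter_value, 8, tolerance = 1e-8)
})

test_that("sweep input contracts are enforced", {
  g <- pd_game()
  expect_error(sweep_exploitation(g, numeric()), "non-empty")
  expect_error(sweep_exploitation(g, c(3, 2)), "strictly increasing")
  one <- sweep_exploitation(g, 5)
  expect_equal(nrow(one$curves), 1)
  expect_null(one$cutoff)
  expect_identical(exploitation_states(g), c("E3,A1", "E3,A2"))
})

test_that("bisection finds the cooperation cut-off at temptation 8", {
  g <- pd_game(floor = 0)
  ct <- find_cutoff(g, "Cooperate", "Policy 3", bracket = c(5, 15))
  expect_equal(ct$parameter_value, 8, tolerance = 1e-8)
  expect_equal(ct$exploit_probability, 8 / 29, tolerance = 1e-8)
  expect_lt(ct$residual, 1e-9)
  expect_identical(ct$policy_pair, c("Cooperate", "Policy 3"))
  # no sign change in the bracket -> informative error
  expect_error(find_cutoff(g, "Cooperate", "Policy 3", bracket = c(1, 6)),
               "widen the bracket")
  # identical posteriors never cross (finite floor keeps both risks finite)
  expect_error(find_cutoff(pd_game(), "Policy 1", "Policy 2",
                           bracket = c(5, 15)),
               "does not change sign")
})

test_that("the probability-space sweep reaches the same cut-off probability", {
  g <- pd_game(floor = 0)
  ct <- find_cutoff(g, "Cooperate", "Policy 3",
                    bracket = c(0.18, 0.34),
                    parameter = "exploitation_probability")
  expect_equal(ct$exploit_probability, ct$parameter_value, tolerance = 1e-12)
  expect_equal(ct$parameter_value, 8 / 29, tolerance = 1e-8)
  sw <- sweep_exploitation(g, seq(0.1, 0.4, by = 0.05),
                           parameter = "exploitation_probability")
  expect_equal(sw$exploit_probability, sw$grid, tolerance = 1e-12)
  expect_error(sweep_exploitation(g, c(0.2, 0.5),
                                  parameter = "exploitation_probability"),
               "infeasible")
})

test_that("agents classify as dove below and hawk above the cut-off", {
  base <- pd_game(floor = 0)
  ct <- find_cutoff(base, "Cooperate", "Policy 3", bracket = c(5, 15))

  # cautious agent: per-state exploitation preference 0.15
  # (temptation t solves t / (13 + 2t) = 0.15)
  dove <- pd_game(floor = 0, temptation = 1.95 / 0.7)
  expect_equal(dove$prior$probs[dove$prior$labels == "E3,A1"], 0.15,
               tolerance = 1e-10)
  cd <- classify_agent(dove, ct)
  expect_identical(cd$class, "dove")
  expect_true(cd$cooperates)
  expect_identical(evaluate_all(dove)$selected, "Cooperate")

  # bold agent: preference 0.35 (temptation 4.55 / 0.3 = 15.17)
  hawk <- pd_game(floor = 0, temptation = 4.55 / 0.3)
  ch <- classify_agent(hawk, ct)
  expect_identical(ch$class, "hawk")
  expect_false(ch$cooperates)
  expect_false(identical(evaluate_all(hawk)$selected, "Cooperate"))

  # exactly at the cut-off: borderline, stress
  edge <- pd_game(floor = 0, temptation = 8)
  ce <- classify_agent(edge, ct)
  expect_identical(ce$class, "borderline")
  expect_true(ce$stress)
  redge <- evaluate_all(edge)
  expect_true(redge$tie)
  expect_setequal(redge$tie_members, c("Cooperate", "Policy 3"))
})

test_that("classification agrees with the engine's selection along the grid", {
  base <- pd_game(floor = 0)
  ct <- find_cutoff(base, "Cooperate", "Policy 3", bracket = c(5, 15))
  for (t in c(1, 3, 5, 7, 7.9, 8.1, 9, 12, 20)) {
    g <- pd_game(floor = 0, temptation = t)
    cl <- classify_agent(g, ct)
    sel <- evaluate_all(g)$selected
    if (cl$class == "dove") expect_identical(sel, "Cooperate")
    if (cl$class == "hawk") expect_false(identical(sel, "Cooperate"))
  }
})

test_that("random prisoner's-dilemma games match the closed-form cut-off", {
  # with friendly reward R, mutual-hostility reward P and sucker 0, the risks
  # of Cooperate and Policy 3 are equal exactly at T* = (4R/3)^(3/2) / sqrt(P)
  # (the total-reward terms cancel), and their difference is globally
  # increasing in the temptation reward, so the crossing is unique
  set.seed(55)
  for (i in 1:20) {
    R <- runif(1, 1, 6)
    P <- runif(1, 0.1, R)
    T0 <- runif(1, R, 2 * R)  # base temptation: maximal, so the
                              # exploitation states are the E3 row
    g <- pd_game(floor = 0, temptation = T0, reward = R, punishment = P,
                 sucker = 0)
    t_star <- (4 * R / 3)^1.5 / sqrt(P)
    ct <- find_cutoff(g, "Cooperate", "Policy 3",
                      bracket = t_star * c(0.5, 2))
    expect_equal(ct$parameter_value, t_star, tolerance = 1e-6)
    expect_lt(ct$residual, 1e-9)
    # monotone region: Policy 3's risk decreases while T < 4R + P
    grid <- seq(R * 1.01, 4 * R + P - 0.01, length.out = 25)
    sw <- sweep_exploitation(g, grid)
    expect_true(all(diff(sw$curves[["Cooperate"]]) > 0))
    expect_true(all(diff(sw$curves[["Policy 3"]]) < 0))
    d <- sw$curves[["Cooperate"]] - sw$curves[["Policy 3"]]
    expect_true(all(diff(d) > 0))  # hence at most one crossing
  }
})
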
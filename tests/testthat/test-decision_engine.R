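test_that("policy risks on the nine-state game match the summation oracle", {
  g <- pd_game(floor = 0)
  expect_equal(evaluate_policy(g, "Cooperate")$risk_bits, log2(23 / 12),
               tolerance = 1e-12)
  expect_equal(evaluate_policy(g, "Policy 3")$risk_bits,
               (2 / 3) * log2(23 / 15) + (1 / 3) * log2(23 / 3),
               tolerance = 1e-12)
  # the sucker states are prior-impossible at floor 0
  expect_identical(evaluate_policy(g, "Policy 1")$risk_bits, Inf)
  o <- oracle_evaluate_game(g)
  for (nm in c("Policy 3", "Cooperate")) {
    expect_equal(evaluate_policy(g, nm)$risk_bits, unname(o[nm]),
                 tolerance = 1e-12)
  }
})

test_that("a policy whose posterior equals the prior has zero risk", {
  sp <- joint_state_space(c("E1", "E2"), c("A1", "A2"))
  g <- game_spec(sp, reward_matrix(rep(1, 4), sp),
                 list(policy_spec("free", "contract")))
  ev <- evaluate_policy(g, "free")
  expect_equal(ev$risk_bits, 0, tolerance = 1e-12)
  expect_equal(-ev$expected_utility_term, ev$entropy_term, tolerance = 1e-12)
})

test_that("the engine selects Cooperate and orders policies as expected", {
  rep6 <- evaluate_all(pd_game(floor = 1e-6))
  df <- as.data.frame(rep6)
  risks <- setNames(df$risk_bits, df$policy)
  expect_identical(rep6$selected, "Cooperate")
  expect_false(rep6$tie)
  expect_lt(risks[["Cooperate"]], risks[["Policy 3"]])
  expect_lt(risks[["Policy 3"]], risks[["Policy 1"]])
  expect_equal(risks[["Policy 1"]], risks[["Policy 2"]], tolerance = 1e-12)
  expect_true(all(is.finite(risks)))
  # PolicyEvaluation internal identity
  expect_equal(df$risk_bits, -df$expected_utility_term - df$entropy_term,
               tolerance = 1e-9)
})

test_that("selection is invariant to policy order and to added policies", {
  g <- pd_game()
  base <- evaluate_all(g)
  set.seed(33)
  for (i in 1:10) {
    g2 <- g
    g2$policies <- g$policies[sample(length(g$policies))]
    r2 <- evaluate_all(g2)
    expect_identical(r2$selected, base$selected)
    expect_identical(r2$tie, base$tie)
  }
  # adding a policy can never raise the minimum risk
  g3 <- g
  g3$policies <- c(g$policies, list(
    policy_spec("Extra", "forced_action", forced_ego_action = "E2")))
  min_risk <- function(r) min(vapply(r$evaluations, `[[`, numeric(1),
                                     "risk_bits"))
  expect_lte(min_risk(evaluate_all(g3)), min_risk(base))
})

test_that("ties are surfaced as stress, never silently broken", {
  sp <- joint_state_space(c("E1", "E2"), c("A1", "A2"))
  g <- game_spec(sp, reward_matrix(c(4, 1, 4, 1), sp), list(
    policy_spec("one", "forced_action", forced_ego_action = "E1"),
    policy_spec("two", "forced_action", forced_ego_action = "E2")))
  r <- evaluate_all(g)  # identical posteriors up to symmetric rewards
  expect_true(r$tie)
  expect_identical(r$selected, NA_character_)
  expect_setequal(r$tie_members, c("one", "two"))
  s <- detect_stress(r)
  expect_true(s$stress)
  expect_match(s$explanation, "one")
  expect_match(s$explanation, "two")

  single <- game_spec(sp, reward_matrix(c(4, 1, 4, 1), sp),
                      list(policy_spec("only", "forced_action",
                                       forced_ego_action = "E1")))
  rs <- evaluate_all(single)
  expect_identical(rs$selected, "only")
  expect_false(detect_stress(rs)$stress)
})

test_that("infinite-risk policies lose unless every policy is infinite", {
  sp <- joint_state_space(c("E1", "E2"), c("A1", "A2"))
  g <- game_spec(sp, reward_matrix(c(1, 0, 0, 0), sp), list(
    policy_spec("hits-zero", "forced_action", forced_ego_action = "E2"),
    policy_spec("safe", "contract", banned_ego_actions = "E2",
                banned_alter_actions = "A2")),
    floor = 0)
  r <- evaluate_all(g)
  expect_identical(r$selected, "safe")
  # degenerate game: all policies infinite -> all tied, stress
  g2 <- game_spec(sp, reward_matrix(c(1, 0, 0, 0), sp), list(
    policy_spec("a", "forced_action", forced_ego_action = "E2"),
    policy_spec("b", "contract", banned_ego_actions = "E1")),
    floor = 0)
  r2 <- evaluate_all(g2)
  expect_true(r2$tie)
  expect_true(detect_stress(r2)$stress)
  expect_setequal(r2$tie_members, c("a", "b"))
})

test_that("higher entropy means lower risk at equal expected utility", {
  # uniform prior: every posterior has the same per-state log-prior, so the
  # expected-utility term is constant and risk differences are pure entropy
  sp <- joint_state_space(c("E1", "E2"), c("A1", "A2"))
  g <- game_spec(sp, reward_matrix(rep(1, 4), sp), list(
    policy_spec("narrow", "forced_action", forced_ego_action = "E1"),
    policy_spec("open", "contract")))
  narrow <- evaluate_policy(g, "narrow")
  open <- evaluate_policy(g, "open")
  expect_equal(narrow$expected_utility_term, open$expected_utility_term,
               tolerance = 1e-12)
  expect_gt(open$entropy_term, narrow$entropy_term)
  expect_lt(open$risk_bits, narrow$risk_bits)
})

test_that("the engine matches brute-force re-evaluation on random games", {
  for (seed in 1:60) {
    g <- generate_random_game(seed,
                              n_ego_actions = 2 + seed %% 3,
                              n_alter_actions = 2 + (seed %/% 3) %% 3,
                              reward_concentration = c(0.5, 1, 4)[1 + seed %% 3])
    got <- evaluate_all(g)
    risks <- vapply(got$evaluations, `[[`, numeric(1), "risk_bits")
    names(risks) <- vapply(got$evaluations, `[[`, character(1), "policy_name")
    want <- oracle_evaluate_game(g)
    expect_equal(risks, want[names(risks)], tolerance = 1e-10)
    if (!got$tie) expect_identical(got$selected, names(which.min(want)))
  }
})
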
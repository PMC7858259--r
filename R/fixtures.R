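# run code under a temporary RNG state so generators are pure in their seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fixture_bundle <- function(game, description, provenance_notes) {
  stopifnot(inherits(game, "game_spec"), nzchar(provenance_notes))
  structure(list(game = game, description = description,
                 provenance_notes = provenance_notes),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture: %s>\n", x$description))
  print(x$game)
  invisible(x)
}

#' The nine-state prisoner's-dilemma game
#'
#' Two agents, Ego and Alter, each with two friendly actions (E1/E2, A1/A2)
#' and one hostile action (E3/A3): nine joint states. Rewards follow the
#' canonical prisoner's-dilemma ordering — temptation 5 on the two
#' exploitation states (E3,A1) and (E3,A2), reward 3 on the four
#' friendly-friendly states, punishment 1 on mutual hostility (E3,A3), and
#' sucker 0 on (E1,A3) and (E2,A3). Linear preference encoding then puts
#' per-state probability 5/23 (about 0.22) on each exploitation state at
#' `floor = 0`. The repertoire holds the three forced-action policies plus
#' "Cooperate", the enforceable contract banning E3 and A3 for both agents.
#'
#' @param floor Probability floor for [encode_preferences()]; the shipped
#'   default `1e-6` keeps the sucker states "close to impossible" rather
#'   than impossible, so Policy 1/2 get large finite risks.
#' @param temptation,reward,punishment,sucker The four payoff levels.
#' @return `pd_fixture()` returns a fixture bundle (game, description,
#'   provenance notes); `pd_game()` returns the [game_spec()] directly.
#' @examples
#' evaluate_all(pd_game())
#' @export
pd_fixture <- function(floor = 1e-6, temptation = 5, reward = 3,
                       punishment = 1, sucker = 0) {
  sp <- joint_state_space(c("E1", "E2", "E3"), c("A1", "A2", "A3"))
  rw <- c(
    "E1,A1" = reward, "E1,A2" = reward, "E1,A3" = sucker,
    "E2,A1" = reward, "E2,A2" = reward, "E2,A3" = sucker,
    "E3,A1" = temptation, "E3,A2" = temptation, "E3,A3" = punishment
  )
  policies <- list(
    policy_spec("Policy 1", "forced_action", forced_ego_action = "E1"),
    policy_spec("Policy 2", "forced_action", forced_ego_action = "E2"),
    policy_spec("Policy 3", "forced_action", forced_ego_action = "E3"),
    policy_spec("Cooperate", "contract",
                banned_ego_actions = "E3", banned_alter_actions = "A3")
  )
  game <- game_spec(sp, reward_matrix(rw, sp), policies, floor = floor)
  fixture_bundle(
    game,
    description = "nine-state two-agent prisoner's-dilemma game",
    provenance_notes = paste(
      "Canonical prisoner's-dilemma payoffs (temptation 5, reward 3,",
      "punishment 1, sucker 0) with linear preference encoding, chosen so",
      "each exploitation state carries prior probability 5/23 (~0.22) at",
      "floor 0. The uniform opponent model and the uniform contract",
      "posterior are modelling choices of this package; the payoff ordering",
      "is the canonical game structure."))
}

#' @rdname pd_fixture
#' @export
pd_game <- function(floor = 1e-6, temptation = 5, reward = 3,
                    punishment = 1, sucker = 0) {
  pd_fixture(floor, temptation, reward, punishment, sucker)$game
}

#' Gaussian goal-state / attainable-state scenario
#'
#' Continuous one-dimensional analogue of the discrete setting: the agent's
#' goal states and a policy's attainable states are each a Gaussian belief,
#' and the policy's risk is their KL divergence. Defaults place the goal at
#' state 3 and the attainable mean at state 5.3; the common standard
#' deviation is configurable (1 by default).
#'
#' @param goal_mean,attainable_mean Means of the two beliefs.
#' @param goal_sd,attainable_sd Standard deviations (> 0).
#' @return List with `goal` and `attainable` [gaussian_belief()]s.
#' @examples
#' sc <- gaussian_scenario()
#' kl_gaussian(sc$attainable, sc$goal)
#' @export
gaussian_scenario <- function(goal_mean = 3, attainable_mean = 5.3,
                              goal_sd = 1, attainable_sd = goal_sd) {
  list(goal = gaussian_belief(goal_mean, goal_sd),
       attainable = gaussian_belief(attainable_mean, attainable_sd))
}

#' Generate a seeded random two-agent game
#'
#' Rewards are drawn i.i.d. from a gamma distribution with shape and rate
#' both equal to `reward_concentration` (mean 1): small concentration gives
#' peaked preferences, large concentration approaches a flat (uniform)
#' prior. The repertoire holds one forced-action policy per ego action plus
#' one contract banning the globally worst ego and alter actions (lowest
#' total reward across their row/column). The same seed always yields the
#' identical game; the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_ego_actions,n_alter_actions Action counts, each >= 2.
#' @param reward_concentration Gamma shape/rate parameter, > 0.
#' @param floor Probability floor for the prior (default `1e-6`).
#' @return A [game_spec()].
#' @export
generate_random_game <- function(seed, n_ego_actions = 3,
                                 n_alter_actions = 3,
                                 reward_concentration = 1,
                                 floor = 1e-6) {
  if (n_ego_actions < 2L || n_alter_actions < 2L) {
    stop("each agent needs at least 2 actions", call. = FALSE)
  }
  if (reward_concentration <= 0) {
    stop("`reward_concentration` must be > 0", call. = FALSE)
  }
  sp <- joint_state_space(paste0("E", seq_len(n_ego_actions)),
                          paste0("A", seq_len(n_alter_actions)))
  vals <- with_seed(seed, stats::rgamma(length(sp$states),
                                        shape = reward_concentration,
                                        rate = reward_concentration))
  rw <- reward_matrix(stats::setNames(vals, sp$states), sp)

  row_tot <- tapply(as.numeric(rw), sp$state_ego, sum)[sp$ego_actions]
  col_tot <- tapply(as.numeric(rw), sp$state_alter, sum)[sp$alter_actions]
  worst_ego <- sp$ego_actions[which.min(row_tot)]
  worst_alter <- sp$alter_actions[which.min(col_tot)]

  policies <- c(
    lapply(sp$ego_actions, function(a) {
      policy_spec(paste0("Force ", a), "forced_action",
                  forced_ego_action = a)
    }),
    list(policy_spec("Contract", "contract",
                     banned_ego_actions = worst_ego,
                     banned_alter_actions = worst_alter))
  )
  game_spec(sp, rw, policies, floor = floor)
}

#' Two games showing both effects of a restrictive rule
#'
#' A restriction that makes states unreachable always costs open options
#' (entropy), but its net effect on risk depends on what it excludes.
#' Fixture `favorable`: the contract bans an action leading to a likely,
#' highly aversive state, the expected-utility gain dominates, and the
#' contract's risk drops below the best unrestricted policy's. Fixture
#' `unfavorable`: the contract bans a moderately desirable, moderately
#' likely state, the utility gain is small, the lost options dominate, and
#' the contract's risk exceeds the unrestricted optimum. Both inequalities
#' are verified at construction time.
#'
#' @param floor Probability floor for both games (default `1e-6`).
#' @return Named list of two fixture bundles, `favorable` and
#'   `unfavorable`.
#' @examples
#' pr <- restriction_pair()
#' evaluate_all(pr$favorable$game)
#' @export
restriction_pair <- function(floor = 1e-6) {
  sp <- joint_state_space(c("E1", "E2"), c("A1", "A2"))
  forced <- list(
    policy_spec("Force E1", "forced_action", forced_ego_action = "E1"),
    policy_spec("Force E2", "forced_action", forced_ego_action = "E2"))
  contract <- policy_spec("Contract", "contract",
                          banned_alter_actions = "A2")

  # A2 leads to the worthless (E1,A2): banning it is a large utility gain
  rw_a <- c("E1,A1" = 10, "E1,A2" = 0, "E2,A1" = 4, "E2,A2" = 4)
  game_a <- game_spec(sp, reward_matrix(rw_a, sp), c(forced, list(contract)),
                      floor = floor)

  # all states similarly valued: banning A2 mostly just closes options
  rw_b <- c("E1,A1" = 5, "E1,A2" = 4, "E2,A1" = 3, "E2,A2" = 4)
  game_b <- game_spec(sp, reward_matrix(rw_b, sp), c(forced, list(contract)),
                      floor = floor)

  check <- function(game, want_lower) {
    risks <- vapply(evaluate_all(game)$evaluations, `[[`, numeric(1),
                    "risk_bits")
    names(risks) <- vapply(game$policies, `[[`, character(1), "name")
    contract_risk <- risks[["Contract"]]
    best_free <- min(risks[setdiff(names(risks), "Contract")])
    ok <- if (want_lower) contract_risk < best_free else
      contract_risk > best_free
    if (!ok) {
      stop("internal error: restriction fixture no longer shows the intended effect",
           call. = FALSE)
    }
  }
  check(game_a, want_lower = TRUE)
  check(game_b, want_lower = FALSE)

  list(
    favorable = fixture_bundle(
      game_a,
      "restriction excludes a likely, highly aversive state",
      paste("Constructed 2x2 game; rewards chosen so the contract's",
            "expected-utility gain outweighs the lost options. Verified at",
            "construction via evaluate_all.")),
    unfavorable = fixture_bundle(
      game_b,
      "restriction excludes a moderately desirable, moderately likely state",
      paste("Constructed 2x2 game with nearly flat rewards; the contract's",
            "small utility gain is outweighed by the lost options. Verified",
            "at construction via evaluate_all."))
  )
}
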
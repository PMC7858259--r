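#' Joint state space of a two-agent game
#'
#' Two agents, Ego and Alter, each commit to one action; the environmental
#' state is the joint outcome. States are the full Cartesian product,
#' row-major with Ego's action as the first coordinate, labelled
#' `"<ego_action>,<alter_action>"`.
#'
#' @param ego_actions Ordered character vector of Ego's action labels.
#' @param alter_actions Ordered character vector of Alter's action labels.
#' @return An object of class `joint_state_space` with fields `ego_actions`,
#'   `alter_actions`, `states` (labels), `state_ego`, `state_alter`
#'   (per-state action coordinates).
#' @examples
#' joint_state_space(c("E1", "E2", "E3"), c("A1", "A2", "A3"))
#' @export
joint_state_space <- function(ego_actions, alter_actions) {
  ego_actions <- as.character(ego_actions)
  alter_actions <- as.character(alter_actions)
  if (length(ego_actions) < 1L || length(alter_actions) < 1L) {
    stop("both agents need at least one action", call. = FALSE)
  }
  if (anyDuplicated(ego_actions) || anyDuplicated(alter_actions)) {
    stop("action labels must be unique within each agent", call. = FALSE)
  }
  if (length(intersect(ego_actions, alter_actions)) > 0L) {
    stop("ego and alter action labels must not overlap", call. = FALSE)
  }
  state_ego <- rep(ego_actions, each = length(alter_actions))
  state_alter <- rep(alter_actions, times = length(ego_actions))
  structure(list(
    ego_actions = ego_actions,
    alter_actions = alter_actions,
    states = paste(state_ego, state_alter, sep = ","),
    state_ego = state_ego,
    state_alter = state_alter
  ), class = "joint_state_space")
}

#' @export
print.joint_state_space <- function(x, ...) {
  cat(sprintf("<joint_state_space %d x %d = %d states>\n",
              length(x$ego_actions), length(x$alter_actions),
              length(x$states)))
  invisible(x)
}

state_label <- function(ego, alter) paste(ego, alter, sep = ",")

#' Reward matrix over joint states
#'
#' Non-negative utilities, one per joint state; at least one must be
#' positive. Kept as a named vector in state order.
#'
#' @param values Named numeric vector (names are joint-state labels) or a
#'   numeric vector in `space$states` order.
#' @param space A [joint_state_space()].
#' @return Named numeric vector of class `reward_matrix`, in state order.
#' @export
reward_matrix <- function(values, space) {
  stopifnot(inherits(space, "joint_state_space"))
  if (!is.null(names(values))) {
    missing <- setdiff(space$states, names(values))
    if (length(missing) > 0L) {
      stop(sprintf("rewards missing for state(s): %s",
                   paste(missing, collapse = "; ")), call. = FALSE)
    }
    extra <- setdiff(names(values), space$states)
    if (length(extra) > 0L) {
      stop(sprintf("rewards name unknown state(s): %s",
                   paste(extra, collapse = "; ")), call. = FALSE)
    }
    values <- values[space$states]
  } else if (length(values) != length(space$states)) {
    stop("unnamed rewards must match the number of joint states",
         call. = FALSE)
  } else {
    names(values) <- space$states
  }
  values <- as.numeric(stats::setNames(as.numeric(values), names(values)))
  names(values) <- space$states
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("rewards must be finite and non-negative", call. = FALSE)
  }
  if (all(values == 0)) {
    stop("at least one reward must be positive", call. = FALSE)
  }
  structure(values, class = "reward_matrix")
}

#' Specify one policy of the repertoire
#'
#' A policy is either a forced own action (`kind = "forced_action"`: Ego
#' commits to one action, Alter remains free) or an enforceable contract
#' (`kind = "contract"`: designated actions become impossible for both
#' agents, e.g. a mutual ban on the hostile action).
#'
#' @param name Policy name (unique within a game).
#' @param kind `"forced_action"` or `"contract"`.
#' @param forced_ego_action For `forced_action`: the single ego action taken.
#' @param banned_ego_actions,banned_alter_actions For `contract`: action
#'   labels excluded for each agent (either may be empty).
#' @return An object of class `policy_spec`.
#' @examples
#' policy_spec("Policy 1", "forced_action", forced_ego_action = "E1")
#' policy_spec("Cooperate", "contract",
#'             banned_ego_actions = "E3", banned_alter_actions = "A3")
#' @export
policy_spec <- function(name, kind = c("forced_action", "contract"),
                        forced_ego_action = NULL,
                        banned_ego_actions = character(),
                        banned_alter_actions = character()) {
  kind <- match.arg(kind)
  name <- as.character(name)[1L]
  if (!nzchar(name)) stop("policy name must be non-empty", call. = FALSE)
  if (kind == "forced_action") {
    if (length(forced_ego_action) != 1L) {
      stop(sprintf("policy '%s': forced_action requires exactly one ego action",
                   name), call. = FALSE)
    }
    forced_ego_action <- as.character(forced_ego_action)
  } else {
    forced_ego_action <- NULL
  }
  structure(list(
    name = name, kind = kind,
    forced_ego_action = forced_ego_action,
    banned_ego_actions = as.character(banned_ego_actions),
    banned_alter_actions = as.character(banned_alter_actions)
  ), class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  if (x$kind == "forced_action") {
    cat(sprintf("<policy '%s': force %s>\n", x$name, x$forced_ego_action))
  } else {
    cat(sprintf("<policy '%s': contract banning ego {%s}, alter {%s}>\n",
                x$name, paste(x$banned_ego_actions, collapse = ","),
                paste(x$banned_alter_actions, collapse = ",")))
  }
  invisible(x)
}

#' Apply an enforceable contract to a state space
#'
#' Returns the joint states that touch no banned action, in original state
#' order. Banning actions makes every joint state containing them impossible
#' for both agents.
#'
#' @param space A [joint_state_space()].
#' @param banned_ego,banned_alter Character vectors of banned action labels
#'   (must be subsets of the respective action sets).
#' @return Character vector of permitted joint-state labels.
#' @examples
#' sp <- joint_state_space(c("E1", "E2", "E3"), c("A1", "A2", "A3"))
#' apply_contract(sp, "E3", "A3")  # the four friendly-friendly states
#' @export
apply_contract <- function(space, banned_ego = character(),
                           banned_alter = character()) {
  stopifnot(inherits(space, "joint_state_space"))
  banned_ego <- as.character(banned_ego)
  banned_alter <- as.character(banned_alter)
  bad_e <- setdiff(banned_ego, space$ego_actions)
  bad_a <- setdiff(banned_alter, space$alter_actions)
  if (length(bad_e) > 0L || length(bad_a) > 0L) {
    stop(sprintf("contract bans unknown action(s): %s",
                 paste(c(bad_e, bad_a), collapse = "; ")), call. = FALSE)
  }
  keep <- !(space$state_ego %in% banned_ego) &
    !(space$state_alter %in% banned_alter)
  if (!any(keep)) {
    stop("contract bans every joint state; at least one must remain permitted",
         call. = FALSE)
  }
  space$states[keep]
}

#' Encode a reward matrix as a prior preference distribution
#'
#' Linear normalization: prior(s) is proportional to
#' `max(reward(s), floor * max(reward))`, normalized to sum to one. The
#' linear map guarantees that raising one state's reward while holding the
#' others fixed monotonically raises that state's preference probability.
#' The floor keeps zero-reward states merely "close to impossible" rather
#' than impossible, so policies reaching them carry large finite risk
#' instead of infinite risk.
#'
#' @param rewards A [reward_matrix()] (or named non-negative vector).
#' @param floor Small probability floor >= 0, as a fraction of the maximal
#'   reward (default 0: zero-reward states get probability exactly 0).
#' @return A [discrete_distribution()] over the joint states.
#' @examples
#' sp <- joint_state_space(c("E1", "E2"), c("A1", "A2"))
#' rw <- reward_matrix(c("E1,A1" = 3, "E1,A2" = 0, "E2,A1" = 5, "E2,A2" = 1), sp)
#' encode_preferences(rw)
#' @export
encode_preferences <- function(rewards, floor = 0) {
  if (!is.numeric(rewards) || is.null(names(rewards))) {
    stop("`rewards` must be a named numeric vector", call. = FALSE)
  }
  if (floor < 0) stop("`floor` must be >= 0", call. = FALSE)
  v <- pmax(as.numeric(rewards), floor * max(rewards))
  if (sum(v) <= 0) {
    stop("all rewards are zero and floor is 0: preferences undefined",
         call. = FALSE)
  }
  discrete_distribution(names(rewards), v / sum(v))
}

#' Assemble a two-agent game
#'
#' Bundles the joint state space, the reward matrix, the preference prior
#' (derived from rewards via [encode_preferences()] unless given
#' explicitly), the policy repertoire, and the opponent model (Ego's belief
#' about Alter's action, uniform by default: Ego does not know Alter's
#' preferences).
#'
#' @param space A [joint_state_space()].
#' @param rewards A [reward_matrix()] over `space`.
#' @param policies List of [policy_spec()] objects, order preserved.
#' @param prior Optional explicit [discrete_distribution()] over
#'   `space$states`; overrides the reward-derived prior.
#' @param opponent_model Optional [discrete_distribution()] over Alter's
#'   actions; default uniform.
#' @param floor Probability floor passed to [encode_preferences()]
#'   (default `1e-6`).
#' @param agent_id Name of the deciding agent (default `"Ego"`).
#' @return An object of class `game_spec`.
#' @export
game_spec <- function(space, rewards, policies, prior = NULL,
                      opponent_model = NULL, floor = 1e-6,
                      agent_id = "Ego") {
  stopifnot(inherits(space, "joint_state_space"))
  rewards <- reward_matrix(rewards, space)
  if (is.null(prior)) {
    prior <- encode_preferences(rewards, floor = floor)
  } else {
    stopifnot(is_discrete_distribution(prior))
    if (!identical(prior$labels, space$states)) {
      stop("explicit prior labels must equal the joint states, in order",
           call. = FALSE)
    }
  }
  if (is.null(opponent_model)) {
    n <- length(space$alter_actions)
    opponent_model <- discrete_distribution(space$alter_actions, rep(1 / n, n))
  } else {
    stopifnot(is_discrete_distribution(opponent_model))
    if (!identical(opponent_model$labels, space$alter_actions)) {
      stop("opponent model labels must equal the alter actions, in order",
           call. = FALSE)
    }
  }
  if (length(policies) < 1L) stop("at least one policy required", call. = FALSE)
  if (inherits(policies, "policy_spec")) policies <- list(policies)
  names <- vapply(policies, function(p) {
    if (!inherits(p, "policy_spec")) {
      stop("`policies` must be a list of policy_spec objects", call. = FALSE)
    }
    p$name
  }, character(1))
  if (anyDuplicated(names)) {
    stop("policy names must be unique", call. = FALSE)
  }
  # validate each policy against the space (forced actions exist, contracts
  # leave at least one permitted state)
  for (p in policies) {
    if (p$kind == "forced_action") {
      if (!p$forced_ego_action %in% space$ego_actions) {
        stop(sprintf("policy '%s' forces unknown ego action '%s'",
                     p$name, p$forced_ego_action), call. = FALSE)
      }
    } else {
      apply_contract(space, p$banned_ego_actions, p$banned_alter_actions)
    }
  }
  structure(list(
    space = space, rewards = rewards, prior = prior,
    policies = policies, opponent_model = opponent_model,
    floor = floor, agent_id = agent_id
  ), class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf("<game_spec '%s': %d states, %d policies>\n", x$agent_id,
              length(x$space$states), length(x$policies)))
  for (p in x$policies) print(p)
  invisible(x)
}

#' Distribution over attainable states under a policy
#'
#' A forced-action policy pins Ego's action and spreads its mass over
#' Alter's actions according to the opponent model (uniform by default, so
#' each joint state in the forced row gets 1/|alter actions|). A contract
#' policy makes banned states impossible and spreads mass uniformly over
#' all permitted joint states (maximum-entropy choice for Ego's own free
#' action under the contract). All other states get probability zero.
#'
#' @param game A [game_spec()].
#' @param policy A [policy_spec()] belonging to the game, or a policy name.
#' @return A [discrete_distribution()] over `game$space$states`.
#' @export
build_policy_posterior <- function(game, policy) {
  stopifnot(inherits(game, "game_spec"))
  policy <- resolve_policy(game, policy)
  sp <- game$space
  probs <- numeric(length(sp$states))
  if (policy$kind == "forced_action") {
    row <- sp$state_ego == policy$forced_ego_action
    probs[row] <- game$opponent_model$probs[
      match(sp$state_alter[row], game$opponent_model$labels)]
  } else {
    permitted <- apply_contract(sp, policy$banned_ego_actions,
                                policy$banned_alter_actions)
    probs[sp$states %in% permitted] <- 1 / length(permitted)
  }
  discrete_distribution(sp$states, probs, renormalize = TRUE)
}

resolve_policy <- function(game, policy) {
  if (inherits(policy, "policy_spec")) {
    names <- vapply(game$policies, `[[`, character(1), "name")
    if (!policy$name %in% names) {
      stop(sprintf("policy '%s' does not belong to this game", policy$name),
           call. = FALSE)
    }
    return(policy)
  }
  names <- vapply(game$policies, `[[`, character(1), "name")
  i <- match(as.character(policy)[1L], names)
  if (is.na(i)) {
    stop(sprintf("no policy named '%s' in this game (have: %s)", policy,
                 paste(names, collapse = ", ")), call. = FALSE)
  }
  game$policies[[i]]
}
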
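#' Read a game specification from a JSON config file
#'
#' The config document has keys: `agents` (object with `ego` and `alter`
#' action-label arrays), `rewards` (object keyed by
#' `"<ego_action>,<alter_action>"`), `policies` (array of objects with
#' `name`, `kind`, and either `action` or `banned_ego`/`banned_alter`),
#' plus optional `prior` (object state -> probability, taken verbatim and
#' overriding the reward-derived prior), `opponent_model` (object
#' alter-action -> probability), `floor`, and `agent_id`. A machine-readable
#' description of the format ships as
#' `system.file("extdata", "game-config-schema.json", package = "klrisk")`.
#'
#' Loading is deterministic, and `load_game(write_game(g, f))` reproduces
#' `g` exactly.
#'
#' @param path Path to a JSON config file, or a pre-parsed list.
#' @return A [game_spec()].
#' @seealso [write_game()]
#' @export
load_game <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) {
      stop(sprintf("game config not found: %s", path), call. = FALSE)
    }
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (is.list(path)) {
    path
  } else {
    stop("`path` must be a file path or a parsed config list", call. = FALSE)
  }

  need <- function(field) {
    if (is.null(cfg[[field]])) {
      stop(sprintf("config field '%s' is required", field), call. = FALSE)
    }
    cfg[[field]]
  }
  agents <- need("agents")
  if (is.null(agents$ego) || is.null(agents$alter)) {
    stop("config field 'agents' must contain 'ego' and 'alter' action lists",
         call. = FALSE)
  }
  space <- joint_state_space(unlist(agents$ego), unlist(agents$alter))

  rw <- need("rewards")
  bad <- setdiff(names(rw), space$states)
  if (length(bad) > 0L) {
    stop(sprintf("config field 'rewards' keys unknown state(s): %s",
                 paste(bad, collapse = "; ")), call. = FALSE)
  }
  rewards <- reward_matrix(unlist(rw), space)

  pols <- need("policies")
  policies <- lapply(seq_along(pols), function(i) {
    p <- pols[[i]]
    at <- sprintf("policies[%d]", i)
    if (is.null(p$name) || is.null(p$kind)) {
      stop(sprintf("config field '%s' needs 'name' and 'kind'", at),
           call. = FALSE)
    }
    if (p$kind == "forced_action") {
      if (is.null(p$action)) {
        stop(sprintf("config field '%s.action' is required for forced_action",
                     at), call. = FALSE)
      }
      if (!p$action %in% space$ego_actions) {
        stop(sprintf("config field '%s.action': unknown ego action '%s'",
                     at, p$action), call. = FALSE)
      }
      policy_spec(p$name, "forced_action", forced_ego_action = p$action)
    } else if (p$kind == "contract") {
      policy_spec(p$name, "contract",
                  banned_ego_actions = unlist(p$banned_ego),
                  banned_alter_actions = unlist(p$banned_alter))
    } else {
      stop(sprintf("config field '%s.kind': must be 'forced_action' or 'contract', got '%s'",
                   at, p$kind), call. = FALSE)
    }
  })

  prior <- NULL
  if (!is.null(cfg$prior)) {
    pv <- unlist(cfg$prior)
    bad <- setdiff(names(pv), space$states)
    if (length(bad) > 0L) {
      stop(sprintf("config field 'prior' keys unknown state(s): %s",
                   paste(bad, collapse = "; ")), call. = FALSE)
    }
    missing <- setdiff(space$states, names(pv))
    if (length(missing) > 0L) {
      stop(sprintf("config field 'prior' missing state(s): %s",
                   paste(missing, collapse = "; ")), call. = FALSE)
    }
    prior <- discrete_distribution(space$states, pv[space$states])
  }

  opp <- NULL
  if (!is.null(cfg$opponent_model)) {
    ov <- unlist(cfg$opponent_model)
    if (!setequal(names(ov), space$alter_actions)) {
      stop("config field 'opponent_model' must assign one probability per alter action",
           call. = FALSE)
    }
    opp <- discrete_distribution(space$alter_actions, ov[space$alter_actions])
  }

  game_spec(space, rewards, policies, prior = prior, opponent_model = opp,
            floor = if (is.null(cfg$floor)) 1e-6 else as.numeric(cfg$floor),
            agent_id = if (is.null(cfg$agent_id)) "Ego" else cfg$agent_id)
}

#' Write a game specification to a JSON config file
#'
#' Inverse of [load_game()]: full numeric precision is kept so that a
#' load/save/load round trip reproduces the game exactly. The prior is
#' always written explicitly (so an edited rewards block cannot silently
#' change it on reload).
#'
#' @param game A [game_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_game <- function(game, path) {
  stopifnot(inherits(game, "game_spec"))
  pol_to_list <- function(p) {
    if (p$kind == "forced_action") {
      list(name = p$name, kind = p$kind, action = p$forced_ego_action)
    } else {
      list(name = p$name, kind = p$kind,
           banned_ego = as.list(p$banned_ego_actions),
           banned_alter = as.list(p$banned_alter_actions))
    }
  }
  cfg <- list(
    agent_id = game$agent_id,
    agents = list(ego = as.list(game$space$ego_actions),
                  alter = as.list(game$space$alter_actions)),
    rewards = as.list(stats::setNames(as.numeric(game$rewards),
                                      names(game$rewards))),
    prior = as.list(stats::setNames(game$prior$probs, game$prior$labels)),
    opponent_model = as.list(stats::setNames(game$opponent_model$probs,
                                             game$opponent_model$labels)),
    policies = lapply(game$policies, pol_to_list),
    floor = game$floor
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
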
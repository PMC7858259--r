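#' Identify the exploitation states of a game
#'
#' The exploitation states are the joint states the deciding agent most
#' prefers: playing the hostile action while receiving a friendly one. By
#' default they are taken as the states carrying the maximal reward, which
#' in a prisoner's-dilemma structure (temptation > reward > punishment >
#' sucker) is exactly that set.
#'
#' @param game A [game_spec()].
#' @return Character vector of joint-state labels.
#' @export
exploitation_states <- function(game) {
  stopifnot(inherits(game, "game_spec"))
  names(game$rewards)[game$rewards == max(game$rewards)]
}

set_exploitation <- function(game, value, parameter, exploit_states) {
  if (parameter == "exploitation_reward") {
    if (value < 0) stop("exploitation reward must be >= 0", call. = FALSE)
    rw <- game$rewards
    rw[exploit_states] <- value
    if (all(rw == 0) && game$floor == 0) {
      stop("grid value makes all rewards zero with floor 0", call. = FALSE)
    }
    game$rewards <- reward_matrix(rw, game$space)
    game$prior <- encode_preferences(game$rewards, floor = game$floor)
  } else {
    # probability-space: set each exploitation state's prior probability to
    # `value` and renormalize the remaining states proportionally
    k <- length(exploit_states)
    if (value < 0 || k * value >= 1) {
      stop(sprintf(
        "per-state exploitation probability %g infeasible for %d states",
        value, k), call. = FALSE)
    }
    p <- game$prior$probs
    idx <- game$prior$labels %in% exploit_states
    rest <- sum(p[!idx])
    if (rest <= 0) {
      stop("all prior mass sits on exploitation states; cannot renormalize",
           call. = FALSE)
    }
    p[idx] <- value
    p[!idx] <- p[!idx] * (1 - k * value) / rest
    game$prior <- discrete_distribution(game$prior$labels, p)
  }
  game
}

#' Sweep the exploitation preference and trace per-policy risk curves
#'
#' Varies the agent's preference for exploiting the other agent and records
#' every policy's KL risk at each grid value. In the default reward-space
#' sweep the exploitation reward is set to each grid value while all other
#' rewards stay constant and the prior is re-derived by
#' [encode_preferences()]; in the probability-space sweep the per-state
#' exploitation probability is set directly and the remaining prior mass is
#' renormalized proportionally.
#'
#' When `cutoff_pair` names two policies, the grid is scanned for a sign
#' change of their risk difference and the crossing is refined by
#' [find_cutoff()] bisection.
#'
#' @param game A [game_spec()].
#' @param grid Strictly increasing numeric vector of parameter values.
#' @param parameter `"exploitation_reward"` (default) or
#'   `"exploitation_probability"`.
#' @param exploit_states Joint-state labels to treat as exploitation states;
#'   default [exploitation_states()] of the base game.
#' @param cutoff_pair Optional character vector of two policy names whose
#'   crossing should be located (e.g. `c("Cooperate", "Policy 3")`).
#' @return An object of class `sweep_result`: `parameter_name`, `grid`,
#'   `curves` (data frame, one risk column per policy), `exploit_probability`
#'   (per-state exploitation prior probability at each grid value), and
#'   `cutoff` (a `cutoff_estimate` or `NULL`).
#' @export
sweep_exploitation <- function(game, grid,
                               parameter = c("exploitation_reward",
                                             "exploitation_probability"),
                               exploit_states = NULL, cutoff_pair = NULL) {
  stopifnot(inherits(game, "game_spec"))
  parameter <- match.arg(parameter)
  grid <- as.numeric(grid)
  if (length(grid) < 1L) stop("grid must be non-empty", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  if (is.null(exploit_states)) exploit_states <- exploitation_states(game)

  pol_names <- vapply(game$policies, `[[`, character(1), "name")
  risks <- matrix(NA_real_, nrow = length(grid), ncol = length(pol_names),
                  dimnames = list(NULL, pol_names))
  exploit_prob <- numeric(length(grid))
  for (i in seq_along(grid)) {
    g <- set_exploitation(game, grid[i], parameter, exploit_states)
    rep_i <- evaluate_all(g)
    risks[i, ] <- vapply(rep_i$evaluations, `[[`, numeric(1), "risk_bits")
    exploit_prob[i] <- g$prior$probs[match(exploit_states[1L],
                                           g$prior$labels)]
  }

  cutoff <- NULL
  if (!is.null(cutoff_pair)) {
    stopifnot(length(cutoff_pair) == 2L, all(cutoff_pair %in% pol_names))
    diff <- risks[, cutoff_pair[1L]] - risks[, cutoff_pair[2L]]
    sgn <- sign(diff)
    cross <- which(sgn[-1L] * sgn[-length(sgn)] <= 0 &
                     is.finite(diff[-1L]) & is.finite(diff[-length(diff)]))
    if (length(cross) > 0L) {
      cutoff <- find_cutoff(game, cutoff_pair[1L], cutoff_pair[2L],
                            bracket = c(grid[cross[1L]], grid[cross[1L] + 1L]),
                            parameter = parameter,
                            exploit_states = exploit_states)
    }
  }

  structure(list(
    parameter_name = parameter,
    grid = grid,
    curves = as.data.frame(cbind(parameter_value = grid, risks)),
    exploit_probability = exploit_prob,
    cutoff = cutoff
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %s over [%g, %g], %d points>\n",
              x$parameter_name, min(x$grid), max(x$grid), length(x$grid)))
  if (!is.null(x$cutoff)) print(x$cutoff)
  invisible(x)
}

#' Locate the cooperation cut-off by bisection
#'
#' Finds the exploitation-preference value at which two policies carry
#' equal risk — the cut-off beyond which cooperation stops being the best
#' policy and at which, exactly, there is no clear best policy. Bisection
#' on the risk difference runs to a parameter tolerance of `tol`; the
#' residual risk difference at the estimate is reported.
#'
#' @inheritParams sweep_exploitation
#' @param policy_a,policy_b Names of the two policies whose risks cross.
#' @param bracket Numeric length-2 interval of parameter values over which
#'   the risk difference changes sign.
#' @param tol Bisection tolerance on the parameter (default `1e-10`).
#' @return An object of class `cutoff_estimate`: `parameter_name`,
#'   `parameter_value`, `exploit_probability` (per-state exploitation prior
#'   probability at the cut-off), `policy_pair`, `residual` (bits).
#' @examples
#' g <- pd_game(floor = 0)
#' find_cutoff(g, "Cooperate", "Policy 3", bracket = c(5, 15))
#' @export
find_cutoff <- function(game, policy_a, policy_b, bracket,
                        parameter = c("exploitation_reward",
                                      "exploitation_probability"),
                        exploit_states = NULL, tol = 1e-10) {
  stopifnot(inherits(game, "game_spec"))
  parameter <- match.arg(parameter)
  if (is.null(exploit_states)) exploit_states <- exploitation_states(game)
  bracket <- as.numeric(bracket)
  stopifnot(length(bracket) == 2L, bracket[1L] < bracket[2L])

  fdiff <- function(v) {
    g <- set_exploitation(game, v, parameter, exploit_states)
    evaluate_policy(g, policy_a)$risk_bits -
      evaluate_policy(g, policy_b)$risk_bits
  }
  flo <- fdiff(bracket[1L])
  fhi <- fdiff(bracket[2L])
  if (!is.finite(flo) || !is.finite(fhi)) {
    stop("risk difference is not finite at the bracket ends", call. = FALSE)
  }
  if (flo == 0 && fhi == 0) {
    stop(sprintf(
      "risk difference between '%s' and '%s' does not change sign over [%g, %g]: the risks are identical at both ends, so there is no unique crossing",
      policy_a, policy_b, bracket[1L], bracket[2L]), call. = FALSE)
  }
  if (flo == 0) {
    root <- bracket[1L]
  } else if (fhi == 0) {
    root <- bracket[2L]
  } else if (flo * fhi > 0) {
    stop(sprintf(
      "risk difference between '%s' and '%s' does not change sign over [%g, %g]; widen the bracket",
      policy_a, policy_b, bracket[1L], bracket[2L]), call. = FALSE)
  } else {
    lo <- bracket[1L]; hi <- bracket[2L]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- fdiff(mid)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    root <- (lo + hi) / 2
  }

  g_star <- set_exploitation(game, root, parameter, exploit_states)
  structure(list(
    parameter_name = parameter,
    parameter_value = root,
    exploit_probability = g_star$prior$probs[match(exploit_states[1L],
                                                   g_star$prior$labels)],
    policy_pair = c(policy_a, policy_b),
    residual = abs(fdiff(root))
  ), class = "cutoff_estimate")
}

#' @export
print.cutoff_estimate <- function(x, ...) {
  cat(sprintf(
    "<cutoff: %s = %.10g (exploit prob %.6f) where '%s' and '%s' tie; residual %.3g bits>\n",
    x$parameter_name, x$parameter_value, x$exploit_probability,
    x$policy_pair[1L], x$policy_pair[2L], x$residual))
  invisible(x)
}

#' Classify an agent as hawk, dove, or borderline
#'
#' A dove-like (cautious) agent has an exploitation preference below the
#' cut-off and cooperates; a hawk-like (bold) agent sits above it and does
#' not. At the cut-off itself the two policies tie, there is no clear best
#' policy, and the classification is borderline — the stress condition.
#' The classification is read off the risk comparison of the cut-off's
#' policy pair at the game's current preferences, so it is always
#' consistent with [evaluate_all()]'s selection.
#'
#' @param game A [game_spec()] at its current exploitation preference.
#' @param cutoff A [find_cutoff()] estimate whose `policy_pair` puts the
#'   cooperative (contract) policy first.
#' @param tie_tol Risk-difference tolerance (bits) for the borderline call.
#' @return List with `class` (`"dove"`, `"hawk"`, or `"borderline"`),
#'   `cooperates` (logical, `NA` for borderline), and `stress` (logical).
#' @export
classify_agent <- function(game, cutoff, tie_tol = 1e-9) {
  stopifnot(inherits(game, "game_spec"), inherits(cutoff, "cutoff_estimate"))
  risk_coop <- evaluate_policy(game, cutoff$policy_pair[1L])$risk_bits
  risk_host <- evaluate_policy(game, cutoff$policy_pair[2L])$risk_bits
  d <- risk_coop - risk_host
  if (is.finite(d) && abs(d) < tie_tol) {
    list(class = "borderline", cooperates = NA, stress = TRUE)
  } else if (d < 0) {
    list(class = "dove", cooperates = TRUE, stress = FALSE)
  } else {
    list(class = "hawk", cooperates = FALSE, stress = FALSE)
  }
}
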
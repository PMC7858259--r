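#' Evaluate one policy's risk against the agent's preferences
#'
#' The risk is the KL divergence (bits) from the policy's attainable-state
#' distribution to the preference prior, together with its decomposition
#' into the expected-utility term and the entropy (exploration) bonus.
#'
#' @param game A [game_spec()].
#' @param policy A [policy_spec()] in the game, or a policy name.
#' @return A list of class `policy_evaluation` with fields `policy_name`,
#'   `risk_bits` (possibly `Inf`), `expected_utility_term`, `entropy_term`.
#' @export
evaluate_policy <- function(game, policy) {
  stopifnot(inherits(game, "game_spec"))
  policy <- resolve_policy(game, policy)
  post <- build_policy_posterior(game, policy)
  d <- decompose_risk(post, game$prior)
  structure(list(
    policy_name = policy$name,
    risk_bits = d$risk,
    expected_utility_term = d$expected_utility_term,
    entropy_term = d$entropy_term
  ), class = "policy_evaluation")
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat(sprintf("<policy '%s': risk %.6f bits (EU %.6f, entropy %.6f)>\n",
              x$policy_name, x$risk_bits, x$expected_utility_term,
              x$entropy_term))
  invisible(x)
}

#' Evaluate every policy and select the risk-minimizing one
#'
#' Ranks all policies by KL risk. The agent selects the policy with minimal
#' risk; when two or more policies sit within `tie_tol` bits of the minimum
#' there is no clear best policy and the report flags a tie instead of
#' breaking it — the tie itself is the decision-level stress condition.
#' Infinite-risk policies appear in the report but are never selected
#' unless every policy is infinite (then all are tied).
#'
#' @param game A [game_spec()].
#' @param tie_tol Absolute risk difference (bits) below which two policies
#'   count as tied. Default `1e-9`.
#' @return A list of class `decision_report`: `evaluations` (in the game's
#'   policy order), `selected` (policy name, or `NA` on a tie), `tie`
#'   (logical), `tie_members` (names of the minimal-risk group).
#' @export
evaluate_all <- function(game, tie_tol = 1e-9) {
  stopifnot(inherits(game, "game_spec"))
  evals <- lapply(game$policies, function(p) evaluate_policy(game, p))
  risks <- vapply(evals, `[[`, numeric(1), "risk_bits")
  names <- vapply(evals, `[[`, character(1), "policy_name")

  finite <- is.finite(risks)
  if (any(finite)) {
    m <- min(risks[finite])
    minimal <- finite & (risks - m) < tie_tol
  } else {
    minimal <- rep(TRUE, length(risks))  # all infinite: all tied
  }
  tie <- sum(minimal) > 1L
  structure(list(
    evaluations = evals,
    selected = if (tie) NA_character_ else names[minimal],
    tie = tie,
    tie_members = names[minimal],
    tie_tol = tie_tol
  ), class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  if (x$tie) {
    cat(sprintf("No clear best policy: %s tied at minimal risk.\n",
                paste(x$tie_members, collapse = ", ")))
  } else {
    cat(sprintf("Selected: %s\n", x$selected))
  }
  invisible(x)
}

#' @export
as.data.frame.decision_report <- function(x, ...) {
  data.frame(
    policy = vapply(x$evaluations, `[[`, character(1), "policy_name"),
    risk_bits = vapply(x$evaluations, `[[`, numeric(1), "risk_bits"),
    expected_utility_term = vapply(x$evaluations, `[[`, numeric(1),
                                   "expected_utility_term"),
    entropy_term = vapply(x$evaluations, `[[`, numeric(1), "entropy_term"),
    selected = vapply(x$evaluations, `[[`, character(1), "policy_name") %in%
      if (x$tie) character() else x$selected,
    stringsAsFactors = FALSE
  )
}

#' Detect the no-clear-best-policy (stress) condition
#'
#' Stress arises when the minimal-risk policies tie: the agent has no clear
#' best policy. Returns the flag plus an explanation naming the tied
#' policies.
#'
#' @param report A [evaluate_all()] report.
#' @return List with `stress` (logical) and `explanation` (character).
#' @examples
#' g <- pd_game()
#' detect_stress(evaluate_all(g))
#' @export
detect_stress <- function(report) {
  stopifnot(inherits(report, "decision_report"))
  if (report$tie) {
    list(stress = TRUE,
         explanation = sprintf(
           "no clear best policy: %s have equal minimal risk",
           paste(report$tie_members, collapse = ", ")))
  } else {
    list(stress = FALSE,
         explanation = sprintf("'%s' is the unique minimal-risk policy",
                               report$selected))
  }
}
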
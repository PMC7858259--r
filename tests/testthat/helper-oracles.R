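# Independent brute-force oracles: plain element-by-element loops, written
# against the mathematical definitions only, never calling package internals.

oracle_entropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

oracle_kl <- function(p, q) {
  d <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] == 0) return(Inf)
      d <- d + p[i] * log2(p[i] / q[i])
    }
  }
  d
}

# numeric integration of the Gaussian KL integrand, in bits
oracle_kl_gaussian <- function(mu_p, sd_p, mu_q, sd_q) {
  f <- function(x) {
    dp <- dnorm(x, mu_p, sd_p)
    ifelse(dp > 0,
           dp * (dnorm(x, mu_p, sd_p, log = TRUE) -
                   dnorm(x, mu_q, sd_q, log = TRUE)) / log(2),
           0)
  }
  lim <- max(abs(mu_p) + 12 * sd_p, abs(mu_q) + 12 * sd_q)
  stats::integrate(f, -lim, lim, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

rand_dist <- function(n, zeros = 0L) {
  p <- stats::rexp(n)
  if (zeros > 0L) p[sample.int(n, zeros)] <- 0
  p / sum(p)
}

# first-principles re-evaluation of a whole game: posteriors rebuilt from
# the policy definitions, risks by the loop oracle
oracle_evaluate_game <- function(game) {
  sp <- game$space
  out <- list()
  for (pol in game$policies) {
    post <- numeric(length(sp$states))
    if (pol$kind == "forced_action") {
      for (i in seq_along(sp$states)) {
        if (sp$state_ego[i] == pol$forced_ego_action) {
          post[i] <- game$opponent_model$probs[
            which(game$opponent_model$labels == sp$state_alter[i])]
        }
      }
    } else {
      ok <- logical(length(sp$states))
      for (i in seq_along(sp$states)) {
        ok[i] <- !(sp$state_ego[i] %in% pol$banned_ego_actions) &&
          !(sp$state_alter[i] %in% pol$banned_alter_actions)
      }
      post[ok] <- 1 / sum(ok)
    }
    post <- post / sum(post)
    out[[pol$name]] <- oracle_kl(post, game$prior$probs)
  }
  unlist(out)
}
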
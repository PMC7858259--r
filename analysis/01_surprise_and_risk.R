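#!/usr/bin/env Rscript
# Surprisal of realized states, and the quadratic growth of policy risk with
# the distance between attainable and goal states.
#
# Writes: results/surprise_by_state.tsv, results/risk_vs_distance.tsv

library(klrisk)
dir.create("results", showWarnings = FALSE)

# An agent whose goal states peak at state 3: discretized Gaussian prior
# over nine states. Surprise is -log2 of the preference assigned to the
# state actually reached -- minimal at the preferred state, growing as the
# realized state drifts away.
states <- 1:9
w <- dnorm(states, mean = 3, sd = 1)
prior <- discrete_distribution(as.character(states), w / sum(w))
surp <- vapply(as.character(states), function(s) surprise(prior, s),
               numeric(1))
tab <- data.frame(state = states,
                  preference = prior$probs,
                  surprise_bits = surp)
write.table(format(tab, digits = 12), "results/surprise_by_state.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Most preferred state: %d (surprise %.3f bits); state 5 costs %.3f bits\n",
            states[which.max(prior$probs)], min(surp), surp[states == 5]))

# Continuous version: goal belief at mean 3, attainable-state belief sweeping
# its mean. With equal spreads the KL risk is (delta mu)^2 / (2 sd^2 ln 2):
# quadratic in the distance.
sc <- gaussian_scenario()
grid <- seq(3, 8, by = 0.1)
risk <- vapply(grid, function(m) {
  kl_gaussian(gaussian_belief(m, sc$attainable$sd), sc$goal)
}, numeric(1))
write.table(format(data.frame(attainable_mean = grid, risk_bits = risk),
                   digits = 12),
            "results/risk_vs_distance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Risk at attainable mean %.1f (sd %.1f): %.4f bits; doubling the distance from the goal multiplies it by %.2f\n",
            sc$attainable$mean, sc$attainable$sd,
            kl_gaussian(sc$attainable, sc$goal),
            kl_gaussian(gaussian_belief(3 + 2 * 2.3, 1), sc$goal) /
              kl_gaussian(sc$attainable, sc$goal)))
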
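#!/usr/bin/env Rscript
# How the preference for exploiting the other agent shifts the policy risks,
# and where cooperation stops: the hawk/dove cut-off.
#
# Writes: results/sweep.tsv, results/sweep_cutoff.json,
#         results/classification.tsv

library(klrisk)

g <- pd_game(floor = 0)

# Sweep the temptation reward while all other rewards stay fixed; the prior
# is re-derived at every grid point. Cooperate gets riskier as exploiting
# grows more attractive, the hostile Policy 3 safer; they cross once.
sw <- run_sweep(g, grid = seq(1, 12, by = 0.25), out_dir = "results",
                cutoff_pair = c("Cooperate", "Policy 3"))
ct <- sw$cutoff
cat(sprintf("Cut-off: temptation reward %.6f, per-state exploitation preference %.4f\n",
            ct$parameter_value, ct$exploit_probability))

# Classify agents by where their exploitation preference sits relative to
# the cut-off: cautious doves below it cooperate, bold hawks above it do
# not, and exactly at it there is no clear best policy (the stress
# condition).
cases <- data.frame(
  label = c("cautious (dove-like)", "shipped default", "at the cut-off",
            "bold (hawk-like)"),
  temptation = c(1.95 / 0.7, 5, ct$parameter_value, 4.55 / 0.3))
cases$exploit_probability <- cases$temptation / (13 + 2 * cases$temptation)
cls <- lapply(cases$temptation, function(t) {
  classify_agent(pd_game(floor = 0, temptation = t), ct)
})
cases$class <- vapply(cls, `[[`, character(1), "class")
cases$cooperates <- vapply(cls, function(x) {
  if (is.na(x$cooperates)) "no clear best policy" else
    if (x$cooperates) "yes" else "no"
}, character(1))
cases$stress <- vapply(cls, `[[`, logical(1), "stress")
write.table(format(cases, digits = 10), "results/classification.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(cases[, c("label", "exploit_probability", "class", "cooperates",
                "stress")], row.names = FALSE)
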
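Package: klrisk
Title: Surprise-Minimization Decision Analysis via Kullback-Leibler Risk
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements policy selection by surprise minimization: the risk of
    a policy is the Kullback-Leibler divergence (in bits) between the
    distribution over states attainable under that policy and the agent's
    prior preferences, and decomposes into an expected-utility term and an
    entropy (exploration) bonus. Provides exact information-theoretic
    primitives for discrete and Gaussian beliefs, a two-agent game model with
    reward-derived preference priors and enforceable-contract policies, a
    decision engine that ranks policies by risk and flags the
    no-clear-best-policy (stress) condition, an exploitation-preference sweep
    that locates the hawk/dove cooperation cut-off by bisection, and seeded
    generators for prisoner's-dilemma-structured games.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
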
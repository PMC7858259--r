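---
title: "Policy selection by surprise minimization: model and design notes"
author: "klrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Policy selection by surprise minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klrisk)
```

## The model

An agent's goals are a probability distribution over states of the world,
the *preference prior* $P(S)$: the more the agent prefers a state, the more
probability it carries. Reaching a state $s$ then surprises the agent by
$-\log_2 P(s)$ bits — zero at a fully expected goal state, unbounded as the
realized state becomes dispreferred.

A policy $\pi$ does not lead to one certain state; it induces a distribution
over *attainable states*, $P(S\mid\pi)$. The **risk** of the policy is the
expected future surprise, measured as the Kullback–Leibler divergence

$$
D_{KL}\big(P(S\mid\pi)\,\|\,P(S)\big)
  \;=\; \sum_s P(s\mid\pi)\,\log_2\frac{P(s\mid\pi)}{P(s)} ,
$$

in bits. A surprise-minimizing agent evaluates every policy in its
repertoire and selects the one with minimal risk (KL control). All reported
quantities in this package are in bits; internal natural-log arithmetic is
converted before anything is returned.

### The decomposition and its sign convention

The risk splits into two interpretable parts:

$$
D_{KL} \;=\; \underbrace{-\sum_s P(s\mid\pi)\log_2 P(s)}_{\text{cross-entropy}
 \;=\; -\,\text{expected utility}} \;-\;
\underbrace{H\!\left[P(S\mid\pi)\right]}_{\text{entropy bonus}} .
$$

The first term is the cross-entropy of the attainable states under the
preference prior; its negative, $\sum_s P(s\mid\pi)\log_2 P(s)$, is the
expected utility of the policy's outcomes. The second is the entropy of the
attainable-state distribution. One sometimes sees the decomposition written
with the entropy *added*; the algebra of the KL definition forces
subtraction, and `decompose_risk()` implements the forced identity
(`risk == -expected_utility_term - entropy_term`, checked to `1e-12` in the
tests). The sign matters conceptually: the entropy term is an *exploration
bonus*. At equal cross-entropy, the policy that keeps more options open has
strictly lower risk, which is why pure expected-utility maximization and
surprise minimization can disagree.

For one-dimensional Gaussian beliefs `kl_gaussian()` uses the closed form;
with equal spreads it reduces to $(\Delta\mu)^2/(2\sigma^2\ln 2)$, so risk
grows quadratically with the distance between the attainable-state mean and
the goal mean. The closed form is checked against numeric integration of
the KL integrand (`stats::integrate`, tolerance `1e-6` bits) in the tests.

## The two-agent game

The social scenario is a one-shot interaction between Ego and Alter. Each
holds three actions — two friendly (E1/E2, A1/A2) and one hostile (E3/A3) —
so the environment has $3 \times 3 = 9$ joint states, ordered row-major
with Ego's action first. Ego's preferences follow the canonical prisoner's
dilemma: temptation $T=5$ for exploiting (hostile Ego, friendly Alter),
reward $R=3$ for mutual friendliness, punishment $P=1$ for mutual
hostility, sucker payoff $S=0$ for being exploited.

```{r}
fx <- pd_fixture()
fx$game
```

### From rewards to preferences

The reward matrix is mapped to the preference prior by **linear
normalization**: $P(s) \propto \max(r_s, \text{floor}\cdot r_{\max})$. Two
considerations fixed this choice over a softmax:

* linearity makes the map scale-free (multiplying all rewards by a constant
  leaves the prior untouched) and strictly monotone — raising one reward
  while holding the others fixed raises exactly that state's probability,
  which is the mechanism the exploitation sweep below relies on;
* with the canonical payoffs it puts $5/23 \approx 0.22$ on each
  exploitation state, a low-to-medium exploitation preference that makes
  the worked example land in the interesting regime.

The `floor` parameter (a fraction of the maximal reward; shipped default
`1e-6`, dimensionless) keeps zero-reward states "close to impossible"
rather than impossible. At `floor = 0` any policy that can reach a
zero-preference state has infinite risk; the infinite value is returned as
a sentinel, ranks last, and never wins selection, but finite floors keep
reports readable.

### Policies and posteriors

A *forced-action* policy pins Ego's action; since Ego does not know Alter's
preferences, the opponent model is uniform by default (configurable), so
the posterior spreads $1/3$ over the forced row. The *Cooperate* policy is
an enforceable contract banning E3 and A3 for both agents: the four
banned-action states become impossible and the posterior is uniform over
the four permitted friendly states. Uniformity over permitted states is the
maximum-entropy choice for how Ego's own action behaves under the contract
— nothing in the scenario distinguishes the permitted states once the
contract is signed, and any other choice would smuggle in a second
preference structure.

```{r}
evaluate_all(fx$game)
```

Cooperate wins: its posterior overlaps the preference prior about as well
as the hostile Policy 3's does (cross-entropies 2.94 vs 2.98 bits), but it
keeps four options open instead of three, and the extra
$\log_2 4 - \log_2 3 \approx 0.415$ bits of entropy bonus decide the
ranking. Policies 1 and 2 reach the near-impossible sucker states and carry
large risks. Selection is invariant to policy order; exact ties are never
broken silently (see below).

## The exploitation sweep and the hawk/dove cut-off

`sweep_exploitation()` varies the temptation reward $T$ while all other
rewards stay constant, re-deriving the prior at each grid value
(reward-space sweep, the default, because the generating mechanism is a
reward change; a probability-space sweep that sets the per-state
exploitation probability directly is provided for plotting against a
probability axis — both locate the same crossing). Cooperate's risk rises
monotonically in $T$ and Policy 3's falls (while $T < 4R + P$), so they
cross at most once; the risk difference is globally increasing in $T$, so
the crossing is unique.

`find_cutoff()` locates the crossing by bisection (parameter tolerance
`1e-10`, chosen so the residual risk difference is far below the `1e-9`
tie tolerance; bisection rather than grid interpolation so the estimate
does not depend on grid density). On the nine-state game the cut-off has a
closed form — the total-reward terms cancel from the equality
$D_{KL}^{\text{Coop}} = D_{KL}^{\text{Policy 3}}$, leaving
$T^\ast = (4R/3)^{3/2}/\sqrt{P} = 8$ at $R=3$, $P=1$, i.e. a per-state
exploitation probability of $8/29 \approx 0.276$. The tests verify the
bisection against this closed form to `1e-8`.

```{r}
g0 <- pd_game(floor = 0)
find_cutoff(g0, "Cooperate", "Policy 3", bracket = c(5, 15))
```

`classify_agent()` reads behavior off the cut-off: a *dove* (exploitation
preference below the cut-off) selects Cooperate, a *hawk* (above) does
not, and exactly at the cut-off the two policies tie — there is no clear
best policy. Ties (risk difference under `1e-9` bits, a float-noise guard
around the conceptual exact equality) are surfaced by `detect_stress()`
rather than broken: the absence of a clear best policy is itself the
decision-level stress condition this analysis is about, so hiding it behind
a tie-break would discard the result.

## Restrictions cut both ways

A contract always costs entropy (options). `restriction_pair()` constructs
two minimal $2\times2$ games verified at build time: in one, the banned
action leads to a likely, highly aversive state, the expected-utility gain
dominates, and the contract beats the best unrestricted policy; in the
other, rewards are nearly flat, the ban mostly closes a moderately
attractive option, and the contract loses. The pair demonstrates that
surprise minimization does not generically favor or disfavor restrictive
rules — the balance of the two decomposition terms decides.

## The synthetic-data generator

`generate_random_game()` provides the randomized test surface: rewards are
i.i.d. Gamma(shape = rate = `reward_concentration`) draws (mean 1), so one
parameter controls preference peakedness — concentration `0.05` gives
near-deterministic preferences, `1e6` a near-uniform prior (total variation
below `0.01` from uniform, tested). Each game carries one forced policy per
ego action plus a contract banning the row- and column-worst actions.
Generators are pure functions of their seed: the same seed yields a
byte-identical serialized game, and the caller's RNG stream is left
untouched.

What the generator emulates: the structure of small one-shot two-agent
games with reward-derived preferences — enough to exercise every code path
(contracts, infinite risks, ties, sweeps) against brute-force re-evaluation.
What it does not emulate: behavioral data of any kind (none exists for this
model), asymmetric information, belief updating about the opponent, or
repeated play. Green tests therefore certify the arithmetic and the
qualitative structure of the worked example, not an empirical claim about
human cooperation.

## Numerical choices

* Distribution normalization tolerance `1e-9` at construction;
  renormalization only on explicit request.
* Zero-probability handling: surprisal and KL return `Inf` as a sentinel
  (never an exception), so infinite-risk policies still rank.
* Tie tolerance `1e-9` bits; bisection tolerance `1e-10` on the parameter.
* Reports print 12 significant digits; game configs are written with 17 so
  a load/save/load round trip is bit-exact.
* Test problem sizes: 1000 random distribution pairs for the information
  identities, 100 parameter draws for the Gaussian integration check, 200
  random games (2–4 actions per side) for brute-force equivalence — sizes
  at which the whole suite runs in well under a minute.

## Known limitations

The worked example's preference prior is a reconstruction from the
canonical prisoner's-dilemma payoffs, not a uniquely determined object:
published illustrations of this scenario show bar heights only graphically,
and quantities that depend on the exact prior (e.g. a cut-off probability
of 0.24 rather than this package's $8/29 \approx 0.276$) are sensitive to
it. What is robust — and what the tests pin down — is the qualitative
structure: cooperation minimal at moderate exploitation preference, a
single crossing, dove below, hawk above, and a stress-inducing tie exactly
at the cut-off. The engine evaluates any `game_spec`, so Alter's decision
can be computed symmetrically by building the mirrored game; the package
does not model belief updating between the agents.
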
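---
title: "Intrinsic-motivation objectives in discrete state spaces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic-motivation objectives in discrete state spaces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imotiv)
```

imotiv implements three information-theoretic objectives that have been
proposed as accounts of *intrinsic motivation* — behaviour driven by the
structure of the agent–environment loop rather than by an external reward
signal — in one coherent discrete-state framework, together with a numerical
audit of the algebraic identities that relate them. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic fixtures do and do not establish.

## The setting

Everything operates on finite categorical objects:

* a **generative model** (`generative_model()`): a likelihood $P(o \mid s)$
  (observations × states, column-stochastic), per-control transition kernels
  $P(s' \mid s, u)$ (stored as an array indexed `[next, current, control]`),
  a prior over the initial hidden state, and a state-independent
  **preference distribution** $P(o)$ over observations;
* an **MDP** (`mdp_spec()`): the fully observed special case, with an
  optional set of *absorbing* states that self-loop under every action;
* **channels** (`channel()`): row-stochastic conditional matrices, the
  object whose capacity defines empowerment.

All entropies and divergences are in nats; `nats_to_bits()` is the single
conversion point. The conventions (likelihood columns are distributions,
transition columns are distributions) are enforced by `validate_model()`,
which reports violations as a tibble rather than failing, so fixtures can be
inspected. $0 \log 0$ is treated as $0$ by explicit masking, never by
epsilon-flooring — this keeps the degenerate closed-form cases (point
masses, deterministic channels) exact to the last bit rather than
approximately right.

## Empowerment

The $n$-step empowerment of a state (or belief) is the channel capacity

$$\mathcal{E} = C\big(P(O_T \mid A_{t:T})\big) = \max_{P(A)} I(A_{t:T}; O_T),$$

the maximum mutual information between the agent's next $n$ actions and the
observation they lead to. It is high where many distinct outcomes are
*reliably reachable*: it scores controllability and variety jointly.
`action_observation_channel()` materialises the channel (one row per action
sequence, lexicographic), and `channel_capacity()` solves the maximisation
by Blahut–Arimoto iteration:

* the iteration starts from the uniform input distribution and applies the
  standard multiplicative update $r_x \propto r_x e^{D_x}$ with
  $D_x = \mathrm{KL}(P(Y\mid x) \,\|\, q)$;
* at every iterate, $\sum_x r_x D_x$ is a lower bound on capacity (it *is*
  the mutual information at $r$) and $\max_x D_x$ an upper bound; iteration
  stops when the gap is below `tol` (default $10^{-9}$ nats, cap 10,000
  iterations). The lower-bound sequence is monotone non-decreasing, which
  the tests assert per iteration.
* Channels whose capacity-achieving input lies on the simplex boundary
  converge slowly in the upper bound; the solver then returns
  `converged = FALSE` with a warning rather than silently stopping. The
  capacity estimate is still accurate to roughly the reported `bound_gap`.

As an independent reference, `capacity_grid_search()` evaluates mutual
information on a regular simplex grid. For channels with two or three input
rows the grid is exhaustive at the requested resolution (default 0.001).
For four rows an exhaustive 0.001 grid would have $\sim 1.7\times 10^8$
points, so the search is exhaustive at 0.01 and then refined on a local
0.001 grid around the coarse optimum; since the mutual information is
concave on the simplex, the refinement brackets the global maximiser. The
grid value is always a feasible lower bound on capacity, which the tests
also assert.

Empowerment is defined over beliefs, with point-mass beliefs (states) the
special case, because the variational setting only ever has beliefs
available. `empowerment_map()` evaluates every state and joins grid
coordinates for plotting (`autoplot()`). Absorbing states score exactly 0:
every action sequence induces the same outcome distribution, so the channel
rows are identical.

## Active inference

`variational_free_energy()` evaluates both printed forms of the variational
free energy — energy minus entropy, and surprise plus divergence — by
independent code paths, where the divergence is
$\mathrm{KL}(Q(s) \,\|\, P(s \mid o))$, the form under which the two routes
are equal and $F \ge -\log P(o)$ holds with equality exactly at the Bayes
posterior (`perceptual_posterior()`).

For planning, `rollout_policy()` pushes the initial belief through an
open-loop control sequence to get the policy-conditioned priors
$Q(s_t \mid \pi)$ and predicted observations $Q(o_t \mid \pi)$, and
`efe_breakdown()` computes, at each controlled timestep, every term of the
expected free energy $G$:

* risk $= \mathrm{KL}(Q(o_t \mid \pi) \,\|\, P(o))$,
* ambiguity $= \mathbb{E}_{Q(s_t \mid \pi)} H[P(o_t \mid s_t)]$,
* expected log-preference (expected utility) and information gain
  $I(s_t; o_t)$,
* the Helmholtz energy/entropy split under the planning model
  $\tilde P(s, o) = P(o)\, Q(s \mid o, \pi)$.

A design point worth stating explicitly: the conditional
$Q(s_t \mid o_t, \pi)$ is computed as the *exact* Bayes inversion of the
rollout predictive. The usual derivation introduces it as an approximation;
with the exact inversion the three decompositions

$$\text{risk} + \text{ambiguity}
  \;=\; -\mathbb{E}[\log P(o)] - \text{information gain}
  \;=\; \text{energy} - \text{state entropy}$$

become identities that the test suite asserts to $10^{-10}$ on random
models, which gives a much sharper correctness surface than an approximate
relation would. With a uniform preference the risk term collapses to
$\log|O|$ minus the predicted-observation entropy and $G$ reduces, up to the
constant $\log |O|$ per step, to negative information gain — so ranking
policies by $G$ is then exactly ranking by epistemic value, which is also
asserted.

`policy_posterior()` is the softmax of $-G$ with the temperature fixed at 1
(scale $G$ for other temperatures; habit priors and precision updating are
out of scope). Zero-preference observations propagate as explicit infinite
risk — never epsilon-floored, because flooring silently distorts the policy
ranking; `policy_posterior()` maps infinite $G$ to zero probability and
errors only if *no* policy is viable. `generalized_free_energy()` evaluates
$\mathbb{E}_{q}[G] - H(q)$, whose exact minimiser over the simplex is the
softmax posterior (log-partition identity); the tests check this against
1,000 random distributions and a resolution-0.01 simplex grid.

## Maximum occupancy

The occupancy reward of a realised trajectory is

$$R(\tau) = -\sum_{t \ge 0} \gamma^t
  \log\!\big[\pi^{\alpha}(a_t \mid s_t)\, P^{\beta}(s_{t+1} \mid s_t, a_t)\big],$$

whose expectation under the policy is a discounted sum of weighted
conditional entropies, $\alpha H(A \mid s_t) + \beta H(S' \mid s_t, a_t)$.
`mop_value()` evaluates a fixed policy by iterating the linear Bellman
equation; `mop_optimize()` finds the optimal stochastic policy by **soft
value iteration**: because the $\alpha$-weighted action entropy makes the
per-state inner maximisation analytic, the optimal policy is Boltzmann in
$Q(s,a) = \beta H(S' \mid s,a) + \gamma \sum_{s'} P(s' \mid s,a) V(s')$ with
temperature $\alpha$, and the value update is the log-partition
$V(s) = \alpha \log \sum_a e^{Q(s,a)/\alpha}$. The source framework defines
the objective but no algorithm; soft value iteration is chosen because it is
exact, deterministic, and a $\gamma$-contraction (the per-sweep sup-norm
changes decay at rate $\le \gamma$, asserted in the tests). The
infinite-horizon sum is truncated by the contraction tolerance (default
$10^{-10}$ nats), not by a step count.

Parameters, with defaults mirroring the reference experiments in the
occupancy literature: $\alpha = 1$ (action-entropy weight, dimensionless),
$\beta = 0$ (state-entropy weight; negative values prefer predictable
transitions and approximate empowerment's controllability preference —
the tests check the monotone trend over $\beta \in \{0, -0.5, -1\}$),
$\gamma = 0.99$ (discount). $\alpha = 0$ is rejected by `mop_optimize()`
(the closed-form improvement needs the entropy term) and allowed in
evaluation only with $\beta \ne 0$.

Absorbing states are pinned to $V = 0$ with a point-mass policy: they model
states with a single effective action and zero path entropy forever. This
is a modelling device — it deliberately ignores the physical point that
death is a high-entropy state for the universe even if it is a zero-entropy
state for the *agent's* action repertoire; the package implements the
device, not the thermodynamic reinterpretation.

## The audit of the "free energy of empowerment"

Treating the action sequence $\pi$ as a latent variable, the empowerment
mutual information $I(\pi; o_T)$ can be rearranged into free-energy-like
forms involving $H(\pi)$, $H(o_T \mid \pi)$, the expected final-observation
energy $\mathbb{E}[-\log P(o_T \mid s_T)]$, $H(s_T \mid \pi)$ and
$I(\pi; s_T)$. Some printed rearrangements of these terms in the literature
are not algebraic identities (e.g. $I = H(\pi) - H(o_T \mid \pi)$ requires
$H(\pi) = H(o_T)$). Rather than hard-code a possibly inconsistent identity,
`empowerment_free_energy_audit()` builds the exact joint
$P(\pi, s_T, o_T)$ under a supplied policy distribution (uniform by
default — the capacity-achieving distribution is a different object) and
*reports the residual of every candidate identity*. The genuinely exact
relations — the standard $I = H(o_T) - H(o_T \mid \pi)$ and the chain rule
$H(o_T \mid \pi) = \mathbb{E}[\text{ambiguity}] + I(s_T; o_T \mid \pi)$ —
are asserted to $10^{-10}$ in the tests; the others are reported, never
asserted.

## Synthetic fixtures: what they emulate and what they do not

No external data is used anywhere; two generators produce every test input.

`make_gridworld()` builds the standard benchmark environment of this
literature: a $w \times h$ grid with actions up/down/left/right/stay,
wall-blocked moves collapsing onto stay, optional slip (the agent moves in
a uniformly random cardinal direction instead), absorbing cells, and an
identity-plus-uniform-noise observation model. Two deliberate consequences
of these choices: interior cells of a noiseless grid have exactly five
distinct one-step outcomes (so depth-1 empowerment is exactly $\log 5$, a
closed-form anchor), and blocked-move-collapse makes the uniform-policy
random walk doubly stochastic, so its stationary distribution is exactly
uniform (anchoring the long-run visit-entropy check at $\log(wh)$).

`make_random_model()` draws every conditional from a symmetric Dirichlet
with a given concentration, seeded and reproducible. Concentration 1 (the
default) is uniform on the simplex — a neutral choice that exercises the
identities on unstructured models; large concentrations approach uniform
conditionals and small ones give sparse, spiky models, and the tests cover
the trend.

These fixtures establish that the *algebra and the solvers* are correct.
They do not establish anything about real behavioural or neural data: the
environments are small, fully enumerable, stationary, and (in the
comparison) fully observed, and the generative models are sampled from a
convenient prior rather than fit to anything. In particular, on a noiseless
deterministic gridworld with uniform preferences all policies have equal
expected free energy (the epistemic term has nothing to gain), so the
active-inference agent in the comparison behaves like the uniform agent
there — a faithful property of the objective in that regime, not a bug.

## The agent comparison

`run_comparison()` runs four agents on a shared environment — uniform
random; empowerment-greedy (one-step argmax of expected next-state
empowerment at a configurable depth, default 2, ties to the lowest action
index); active inference (receding-horizon EFE with the model's preference,
default depth 2); and MOP-optimal — and reports per (agent, seed): long-run
state-visit entropy, the fraction of steps spent in absorbing states, and
the mean per-step action entropy. All randomness flows through the per-run
seed, and identical seeds give identical reports. The headline qualitative
phenomenon — agents with lookahead objectives avoid the absorbing state
that a random walk falls into — is asserted as a seeded statistical test
(lower absorbing frequency than uniform in at least 9 of 10 seeds) and
recomputed by `scripts/acceptance.R`.

Problem sizes used in the shipped checks (chosen to keep everything exactly
enumerable): joints up to $6 \times 6$; generative models with 2–4 states
and observations and 2–3 controls at planning depths 1–3; gridworlds up to
$5 \times 5$ with 10,000-step simulations over 10 seeds; Monte-Carlo policy
evaluation with 10,000 vectorised episodes of 250 steps.

## Known limitations

* Exhaustive policy enumeration is exponential; `enumerate_policies()`
  refuses beyond a configurable cap (default $10^5$) rather than stalling.
* Continuous state spaces, multi-interval (generalised) empowerment,
  capacity under input costs, learned model parameters, habit priors and
  precision/temperature machinery are out of scope.
* The Blahut–Arimoto upper bound converges slowly for boundary-supported
  optima (see above); raise `max_iter` or relax `tol` if the warning
  appears and the default bound gap matters for your use.
* `mop_optimize()` requires $\alpha > 0$; plain (hard) value iteration for
  $\alpha = 0$ is deliberately not provided.
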
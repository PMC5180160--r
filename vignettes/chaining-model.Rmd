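---
title: "The chaining model: methods, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chaining model: methods, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainsim)
```

## The model and its assumptions

chainsim simulates an agent that learns sequences of behaviour through
conditioned reinforcement. The environment is a finite state space with a
stochastic transition kernel: in state $S$ the agent chooses a behaviour
$B$ from the state's repertoire, the environment draws a successor $S'$,
and the agent collects the primary reinforcement value $u_{S'}$ of the
state it enters. Primary values are fixed properties of states —
positive for biologically rewarding outcomes, small and negative for
neutral conditions (the time and energy a state costs).

The agent maintains state–behaviour values $v_{S \to B}$ and conditioned
state values $w_S$, both keyed by *observation* labels so that
perceptually aliased states share entries. Choice is softmax,
$P(B) \propto e^{\beta_{S,B} v_{S \to B}}$, and after each transition

$$\Delta v_{S\to B} = \alpha_v\,(u_{S'} + w_{S'} - v_{S\to B}), \qquad
  \Delta w_{S} = \alpha_w\,(u_{S'} + w_{S'} - w_{S}),$$

with both targets computed from the same pre-update snapshot (the two
updates are order-independent by construction; the model itself never
fixes an order). The prediction error
$d_v = u_{S'} + w_{S'} - v_{S\to B}$ drives learning and may additionally
modulate choice: a modulation rule replaces a behaviour's exploration
parameter by $\beta_0 - d_v$, using the $d_v$ of the immediately
preceding transition of the *same attempt* and the plain baseline
$\beta_0$ at an attempt's first step. We use the most recent prediction
error rather than an average; nothing in the model's logic requires
smoothing, and the most-recent convention keeps the modulation a pure
function of the last experience.

Assumptions worth making explicit:

- no discounting and no eligibility traces — value propagates strictly
  one step per experience;
- the agent observes the current observation label perfectly; aliasing is
  the only perceptual limitation modelled;
- learning rates are clamped to $[0, 1]$ (values above 1 are rejected:
  they overshoot the target and need not converge);
- terminal observations have $w \equiv 0$, permanently.

## Attempts are episodes

An *attempt* is the trajectory segment between two successive visits to
the task's designated initial state; entering a terminal state also
closes an attempt. The attempt is also the learning episode: on an
attempt-closing transition the update targets use $w = 0$ in place of the
entered state's conditioned value, while the entered state's $u$ is still
collected. Two reasons:

1. Without discounting, bootstrapping value across episode boundaries
   makes $w$ estimate an unbounded cross-episode return. In
   reset-on-mistake tasks this drags the start state's value far below
   any one-episode return (the expected cost of *all future* mistakes),
   which in turn makes mistakes look cheap — their target inherits the
   same sunk value — and measurably distorts asymptotic choice.
2. With attempt-episodes, every learned value has a clean interpretation:
   $w_S$ estimates the value collectible *within the current attempt*
   after leaving $S$, and the exact oracle for that quantity is well
   defined (below).

What counts as "returning to the initial state" is a property of the
task, set by `task_spec(attempt_closure = ...)`:

- `"return"` (default): every transition into the start state closes the
  attempt, including self-transitions. This is right for tasks whose
  mistakes are described as sending the animal back to the start to try
  again — there each choice at the start is its own attempt, which is
  exactly what makes an $l$-step chain cost $\sim m^l$ attempts of chance
  search.
- `"arrival"`: only transitions from a *different* state close the
  attempt. This is right for tasks where a failed action leaves the
  animal in place, still engaged: remaining at the start is one
  continuous visit, not a new attempt. The nut-cracking preset uses this
  mode.

The automatic reset after a terminal state is not a transition and is
never learned from.

## The oracle and its two horizons

`policy_evaluation()` solves the Bellman consistency condition
$w^*_S = \sum_{S'} P_{S,S'}(u_{S'} + w^*_{S'})$ exactly (direct linear
solve on the non-terminal states, residual $\le 10^{-10}$, with iterative
sweeps at $10^{-8}$ as a fallback for ill-conditioned systems), after
checking that the policy is *proper* — a terminal is reached with
probability 1 from everywhere, tested via the spectral radius of the
sub-stochastic non-terminal transition matrix; improper policies are
rejected with the recurrent trap states named. `optimal_values()` runs
value iteration to the same residual and returns the greedy policy.

Two horizons are offered. `horizon = "task"` evaluates the kernel as
given: episodes end only at terminal states, matching Monte-Carlo
rollouts that run until termination (`policy_rollouts()`, which freezes a
policy by encoding it as $\beta = 1$, $v = \log p$ with zero learning
rates). `horizon = "attempt"` additionally ends the episode on
attempt-closing transitions into the start state (per the task's closure
mode); this is the quantity the learning agent estimates, and it is what
`softmax_equilibrium()` uses to predict the learner's asymptote by
alternating exact evaluation with the softmax rule. For aliased
observations the observation-level value fed to the softmax is the
visitation-weighted average of member-state values (expected visits per
episode from the entry distribution), because a shared table entry
converges to a visitation mixture. Aliasing can break the contraction of
this iteration; non-convergence is then reported as data (the iteration
trace), not as an error, and is a real prediction — reverse-cue
discriminations genuinely oscillate.

`compare_to_oracle()` compares learned tables against oracle values only
over entries visited at least `min_visits` times, with aliased entries
compared against the visit-weighted mixture.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `alpha_v`, `alpha_w` | learning rates (unitless, $[0,1]$) | 0.1 | fast enough to converge in $10^3$ attempts on small tasks; presets override with their stated values |
| `beta` | exploration–exploitation (units of 1/value) | 1 (presets: 2–5) | $\beta = 0$ is uniform choice; choice odds scale as $e^{\beta \Delta v}$ |
| initial $v, w$ | innate response tendencies | 0 | uniform initial choice; presets with innate biases override sparsely |
| `max_steps` | per-attempt step cap | 10,000 | guards self-perpetuating loops; hitting it flags the attempt rather than erroring |
| criterion | "task learned" | reward in ≥ 75% of the trailing 20 attempts | sits between the 70–80% criteria conventional in animal sequence-learning experiments |

One interaction deserves emphasis: with the trailing-window criterion, a
chain task is only *learnable* if the asymptotic softmax policy completes
the chain often enough, which requires $e^{\beta\,\Delta v}$ to dominate
the $m-1$ wrong behaviours at every stage. With the attempt-episode
semantics the asymptotic gap at a chain state is essentially the full
downstream value $w$ (mistakes bootstrap 0), so the default $\beta = 5$
makes the criterion comfortably attainable; learning time is then
dominated by the initial chance search.

## Presets: printed values and reconstructions

Each preset records in its `provenance` which parameters are stated in
the literature it models and which are this package's reconstructions.

- **self_control** — $c = 0.2$, $b_1 = 1$, $b_2 = 5$,
  $\alpha = 0.1$, $\beta = 2$. The third action, "leave", returns to the
  initial state and closes the attempt; under attempt-episode semantics
  its value converges to $-c$, so waiting wins decisively once the
  intermediate state has acquired conditioned value.
- **nut_cracking** — six stages, 40 behaviours per state (5 functional,
  35 irrelevant, kept explicit so the 2.5% initial selection probability
  per behaviour emerges from uniformity), steal entry 0.01 directly to
  the open-nut state, mistakes staying in place with probability 0.75
  (else back to start), strike success 0.75, $\alpha = 0.05$,
  $\beta = 5$. Primary values are **not** printed in the source
  literature; the defaults here are $u = +5$ for the eaten state and
  $-0.2$ elsewhere. Attempt closure is `"arrival"`. See "Known
  limitations" for the consequences.
- **raccoon** — printed: $b = 2$, $c = 0.2$, $\alpha = 0.25$,
  $\beta = 1$ except $\beta = 3$ for keeping the token, initial $v = 5$
  on the two initially dominant actions. The task graph itself
  (pick-up/do-nothing; deposit/keep/drop) is a reconstruction.
- **generic_misbehaviour** — topology and magnitudes are reconstructions
  (flagged): the useless behaviour costs $c_2$ per choice, loops without
  affecting reachability, and carries an elevated $\beta$.
- **cronin_(nondiagnostic|distinct|reverse)** — $b = 1$, $c = 0.2$ (the
  no-food outcome also costs $-c$), $\alpha_v = 0.1$, $\alpha_w = 0.05$,
  $\beta = 5$. The reverse variant aliases the two blue and the two
  yellow states into shared observations (7 true states, 5
  observations).

## The random-task generator

`random_task()` builds layered tasks: every behaviour sends most of its
probability mass to the next layer, the last layer is terminal, and an
optional minority share forms reset edges to the entry layer. Episode
finiteness therefore holds *by construction* under any policy, rather
than by post-hoc spectral testing. The generator emulates the structural
features the agent and oracle must handle — stochastic branching, mixed
reward magnitudes, reset edges, multiple entry states — but deliberately
not: aliasing (tested via the hand-built presets), non-layered recurrent
structure, or adversarial reward placement. Passing the property suite
on these tasks shows the *mechanics* (updates, bookkeeping, Bellman
consistency, seed determinism) are right; it does not by itself certify
behaviour on pathological environments.

## Numerical choices

- Softmax scores are shifted by their maximum before exponentiation;
  distributions remain normalized for $|\beta v|$ up to $10^4$.
- The compiled and pure-R engines consume the identical RNG stream (one
  uniform per stochastic entry draw, one per behaviour choice, one per
  stochastic kernel edge) and mirror accumulation order, including
  extended-precision summation, so they are bit-identical on any seed —
  each is a full cross-check of the other in the test suite.
- Kernel rows must sum to 1 within $10^{-9}$; the last cumulative entry
  is forced to 1 so a uniform draw can never fall off the end.
- Behaviour ties in value iteration resolve to the first-listed
  behaviour (repertoires are ordered).
- Degenerate inputs: zero attempts return an empty result with the full
  parameter echo; all-zero choice distributions are an error; a
  max-steps overflow flags the attempt in its trace.
- Replicate seeds are derived from one master seed by
  `sample.int(.Machine$integer.max - 1L, n)` and recorded per replicate.
- Test and acceptance problem sizes (e.g. 20 replicates of the
  $l{=}4,m{=}10$ chain; 30 nut-cracking replicates of up to 20,000
  attempts; 100 random tasks with 2,000 rollouts each) were chosen so the
  full suite completes in a few minutes on one core while keeping
  Monte-Carlo error well inside the asserted tolerances; statistical
  checks over many simultaneous comparisons use 4 standard errors to
  control the family-wise error rate.

## Known limitations

- **Nut-cracking timescale.** With the unprinted primary values defaulted
  as above, the package's measured proficiency onset (median first
  attempt whose trailing-50 reward proportion exceeds 0.5; computed by
  the acceptance checks) is in the several-thousand-attempt range —
  slower than the roughly 1,500 attempts reported for the original
  simulation of this scenario. The discrepancy is driven by middle-stage
  discovery: before any learning, reaching the hammer-in-hand stage
  requires consecutive low-probability advances, and temporarily negative
  conditioned values suppress correct choices by odds $\sim e^{-\beta c}$
  per stage. The onset is sensitive to the value scale and to mistake
  semantics; the configurations explored (costs 0.05–0.2, flat vs.
  optimistic equal initial values, both attempt-closure modes) all land
  above the reported figure, so the reconstruction is flagged rather than
  asserted.
- **Reverse-cue peak preference.** The preference for the unrewarded key
  is self-limiting: as it grows, the valuable delay cue is observed
  mostly on the unrewarded path and its conditioned value falls. The
  model therefore predicts a peak trailing-100 choice proportion around
  0.8 and oscillation, not a sustained 0.9; the equilibrium iteration
  reports the corresponding non-convergence.
- The learner has no mechanism for state inference, stimulus
  generalization, or memory of more than the current observation; the
  sequence-memory extension (keying $w$ by pairs of successive states) is
  out of scope.
- `softmax_equilibrium()` is a fixed-point predictor, not a proof of
  convergence of the stochastic learner; agreement is established
  empirically in the tests at small learning rates.
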
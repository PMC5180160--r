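# chainsim

Simulation of behaviour-sequence learning through conditioned
reinforcement ("chaining"), for researchers in animal learning,
behavioural ecology and comparative cognition who want to ask *what plain
associative learning can and cannot learn* — tool use, self-control,
misbehaviour, delayed-cue discriminations — and on what timescale.

## The model

An animal moves through a finite set of environmental states. Each state
`S` carries a genetically fixed primary reinforcement value `u_S` (positive
for food, small and negative for neutral conditions). The agent maintains
two learned tables, keyed by *observations* (several true states may alias
to one observation):

- `v[S→B]` — the estimated total value of choosing behaviour `B` in `S`;
- `w[S]` — the conditioned reinforcement value of `S` itself, i.e. the
  learned value of a state that predicts reward.

Behaviour is chosen by a softmax compatible with the matching law,

    P(S→B) ∝ exp(β · v[S→B]),

and after a transition `S →B→ S'` both tables move toward the realized
value of the state entered,

    Δv[S→B] = α_v (u[S'] + w[S'] − v[S→B])
    Δw[S]   = α_w (u[S'] + w[S'] − w[S])

with the prediction error `d_v = u[S'] + w[S'] − v[S→B]`. Because `w`
enters the update target, value propagates backwards along behaviour
chains: the model performs an approximate, incremental form of dynamic
programming, and its asymptote can be certified against an exact Bellman
solver included here. Without the `w` term (`chaining = FALSE`) the model
reduces to the classic delta rule, which optimises single choices but not
sequences.

Learning is episodic: an *attempt* is the trajectory segment between two
successive visits to a task's initial state (entering a terminal state
also closes it), and update targets bootstrap from zero at attempt
boundaries.

## What's in the package

- `task_spec()`, `validate_task()` — finite stochastic task environments
  with entry distributions, terminal states and perceptual aliasing.
- `agent_config()` — learning rates, exploration parameters (per-pair
  `beta` maps and prediction-error modulation rules model genetic
  predispositions), initial values.
- `run_simulation()` / `run_attempt()` — the agent–environment loop
  (compiled engine plus a bit-identical pure-R reference), with tidy
  `tidy()`, `glance()`, `autoplot()` accessors.
- `policy_evaluation()`, `optimal_values()`, `softmax_equilibrium()`,
  `compare_to_oracle()`, `policy_rollouts()` — the exact
  dynamic-programming oracle.
- `chain_task()` and `build_preset()` — classic scenarios: behaviour
  chains, self-control, chimpanzee nut cracking, raccoon token
  "misbehaviour", and delayed-cue key discriminations with aliased delay
  stimuli.
- `attempts_to_learn()`, `learning_time_study()`,
  `formula_learning_time()`, `backward_chaining_protocol()`,
  `forward_chaining_protocol()` — learning-time scaling under entry/exit
  patterns and trainer protocols.
- `random_task()` / `random_policy()` — seeded generators of provably
  terminating tasks for property testing.
- `read_task_spec()` / `write_task_spec()` / `write_outputs()` and a
  `chainsim` command-line script (`inst/exec/`) for file-based workflows.

## Worked example

A two-step behaviour chain: two states before the reward, two behaviours
each, the wrong one resetting to the start; reward `b = 1`, step cost
`c = 0.2`.

```r
library(chainsim)

b <- chain_task(l = 2, m = 2, b = 1, c = 0.2)
sim <- run_simulation(b, n_attempts = 2000, seed = 1, record = "attempts")
glance(sim)
#>   n_attempts n_steps reward_rate final_reward_rate total_u capped_attempts  seed
#> 1       2000    3973       0.982              0.98   1562.               0     1
```

The agent completes the sequence in 98% of its final attempts. The exact
oracle says what was learnable: under the optimal policy the expected
future reward is `w*(0) = 0.8` and `w*(1) = 1.0` (one step from the
reward is worth `b`; two steps costs one extra `−c`), and the softmax
equilibrium at `β = 5` predicts the learner's asymptote:

```r
optimal_values(b)$w_star
#>   0   1   2
#> 0.8 1.0 0.0
softmax_equilibrium(b)$values$w_star
#>      0      1      2
#> 0.7903 0.9970 0.0000
```

The learned table agrees: `v[0→B1] = 0.800` versus `v[0→B2] = −0.188`,
giving a 99.3% probability of the correct first behaviour. The same
machinery quantifies *hard* problems: with `l = 4` steps from a
repertoire of `m = 10`, `formula_learning_time("start", 1, 10, 4)` is
10,000 attempts — the reward must initially be found by chance — while
backward or forward chaining (`learning_time_study()`) cuts growth from
exponential to linear in `l`.

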
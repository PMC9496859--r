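---
title: "A hippocampus-striatum agent with memory replay: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hippocampus-striatum agent with memory replay: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replaynav)
```

## The problem

A navigating animal (or robot) must find a hidden reward in an environment
where the reward signal reaches it only at the goal.  Temporal-difference
learners propagate that signal backwards one step per real experience, so in
a large arena most of the state space never feels the reward at all — the
signal *attenuates*.  This package implements a brain-inspired answer:
a hippocampal place-cell map whose value function is trained almost entirely
*offline*, by replaying remembered trajectories, including "virtual"
trajectories the agent never actually walked.

The task family is a discrete Morris water maze: a 20x20 grid with an
invisible platform (goal), eight compass movements plus a stay action,
80% action reliability (the other 20% deviates to a compass-adjacent
direction), reward +100 at the platform, -10 per ordinary step and -100 for
bumping an obstacle or the arena boundary (an *amplified* variant uses
+1000/-500/-10).  `make_maze()` builds the open arena, block-obstacle and
U-trap variants, and a seeded recursive-division corridor maze.

## The model

**Place-cell layer.**  Each cell $i$ holds a state-channel weight vector
$W_{S,i}$ (5 components: position $x, y$ in grid-cell units, heading
$\cos\theta, \sin\theta$ of the last executed action, and the occupied
fraction of the radius-1 lidar scan) and a memory-channel weight $W_{M,i}$.
Its firing rate for a joint input $(S, M)$ is a channel-gated Gaussian

$$v_i = \exp\!\left(-\,\frac{\big(s_t\,\lVert S - W_{S,i}\rVert +
   m_t\,\lvert M - W_{M,i}\rvert\big)^2}{2\sigma_{pc}^2}\right),$$

with gains $s_t = 0.6$, $m_t = 0.4$ and field width $\sigma_{pc} = 0.7$
(grid-cell units).  Positions enter in raw cell units: with these gains a
cell's field has a radius of about 1.4 cells at the striatal filter
threshold, i.e. the layer is an actual place code.  (Normalising positions
to $[0,1]$ makes every cell fire near 1 everywhere and collapses the map to
a single unit; likewise a literal per-dimension normaliser of the distance
flattens the kernel beyond usefulness, so the gains act on the raw channel
distances.)

Learning is competitive: the winning (most active) cell moves its weights
toward the input by $\delta = 0.5$; when no cell fires above the
recruitment threshold a new cell is recruited exactly at the input.  The
recruitment threshold defaults to the filter threshold $\theta = 0.5$
("novel" = no cell passes the filter).  A much lower threshold cannot work
as a recruitment rule: because trajectories are continuous and the winner
migrates toward the agent, the winning activation essentially never falls
below a tiny constant after the first recruit, and the pool would stay at
one cell.

**Striatal action selection.**  A binary filter $F_i = [v_i > \theta]$
selects the active cells; the state-action value is their mean
$Q(s,a) = \sum_i q_i(a) F_i / \sum_i F_i$.  Selection is
$\varepsilon$-greedy ($\varepsilon = 0.1$) over the eight movements with
three provisions that together make the policy workable at all stages of
learning:

* **Cold start / momentum.**  While the *incumbent direction* (the action
  just executed) is still unvalued, the agent turns to a random action with
  probability $P = 0.5$ and otherwise keeps moving in its current
  direction.  An obstacle bump clears the incumbent (there is nothing to
  "continue").  This persistent walk is the exploration engine before any
  reward information exists — essential in corridor mazes.
* **A reward-free prior.**  An action the map has never valued enters the
  greedy comparison at $R_{step}/(1-\gamma) = -100$, the value of walking
  forever without finding reward.  Known routes (whose value always
  exceeds $-100$) are therefore preferred over ignorance, while regions
  whose values have drained to the prior release the agent instead of
  trapping it.
* **An information margin.**  The map only guides the greedy choice where
  its best promise exceeds the prior by at least one step's cost;
  beyond that margin — which coincides with the $\gamma = 0.9$ discount
  horizon — the explorer takes over.

**Episode memory.**  Each episode is recorded as a trajectory sequence of
(state, executed action, reward) triples plus the winning place cell of
every step.  A sequence is classified *high* if it reached the platform and
*low* if the episode failed (cumulative reward below -3000 or 500 steps).
Classified sequences go into a bounded FIFO memory vault
(20 high / 50 low / 50 virtual by default).  Only the final 64 triples of a
sequence are stored: beyond the discount horizon a prefix carries no
recoverable reward signal, and bounding the stored length keeps every
sequence fully replayable within the consolidation budget.

**Virtual paths.**  After episodes, stored low and high sequences are
intersected on shared place cells.  The splice point maximises the low
prefix (ties: longest remaining high suffix, then lowest cell id), and the
virtual sequence is the low prefix up to the intersection followed by the
high suffix after it — a path the agent never walked that nevertheless ends
in the goal reward.  The splice triple's action is redirected onto the high
branch and its reward reset to the step penalty so the result is a
coherent, grid-valid trajectory; the complementary combination (high prefix
+ low suffix) is never built, because it cannot reach the reward.  Virtual
sequences are deduplicated by their visited-cell sequence, and each
(low, high) pair is evaluated once, at most 30 pairs per consolidation
round.

**Replay consolidation.**  After every episode the agent replays its high
and virtual sequences (newest first, up to 1000 replayed triples per round)
through the standard Q-learning update, re-presenting the stored state
vectors with the memory channel driven at 1 and gating the update by the
striatal filter.  Forward (chronological) passes move the reward signal one
step backward per pass, so repeated replay reproduces the effect of a
$\lambda = 1$ eligibility trace without any trace parameter — on a
deterministic corridor of $n$ steps, $n$ passes at $\alpha = 1$ give the
discounted closed form exactly (this is verified to $10^{-9}$ in the test
suite).  The replay bootstrap uses the same reward-free prior for unvalued
continuations, so propagation starts pessimistically from below and rises
as goal information arrives.  Two numerical guards matter: a triple whose
next replayed state activates no cell above the filter is skipped (its
bootstrap is undefined after competitive drift), and sequences classified
low never contribute an update.

**Live learning is a refresh, not a writer.**  By default (`live_td =
"refresh"`), the on-line TD update only re-calibrates state-action pairs
that replay has already written; unexplored actions keep the zero value
that drives cold-start exploration.  Without this, stale replay values
(written by long-evicted sequences) freeze into spurious attractors;
with full on-line writing, penalties immediately fill the arena with
negative values and the momentum explorer never runs.  `live_td = "full"`
turns the agent into a plain filtered on-line Q-learner; with disjoint
single-cell place fields (a lattice pool, `position_only` encoding,
$\theta = 0.7$, replay off) that agent is *bit-for-bit identical* to
tabular Q-learning — trajectory for trajectory and value for value —
which the test suite checks on a seeded 5x5 maze.

An optional forgetting clock (`replay_schedule(forget_after = )`) erases
the action values of cells replay has not reactivated for a given number of
rounds.  It is off by default: in these arenas it measurably erases useful
obstacle knowledge faster than it removes stale values.

## Baselines

* `qlearn`: tabular Q-learning over grid cells with replacing eligibility
  traces, $\lambda = 1$, and no trace cutting on exploratory actions
  ($\alpha = 0.3$, $\gamma = 0.9$, $\varepsilon = 0.1$).  Non-cutting
  traces at $\lambda = 1$ are deliberately kept: they reproduce the
  characteristic instability of this baseline.
* `qlearn_random_er`: tabular Q-learning whose every update comes from a
  uniform random batch (32) sampled from a ring buffer (10,000) of single
  transitions, one batch per environment step.  With a buffer of size 1
  this degenerates to on-policy Q-learning.

## Study conditions and problem sizes

The comparative experiment trains all three agents on the amplified-reward
open maze for 800 episodes per run across 10 seeds.  The stabilization
statistic is the mean of the last 16 sums of 10 consecutive episode
returns — a block total over ten navigations, the natural scale for a
solved maze whose single-episode return is bounded by the goal reward.  The relocated-platform experiment (standard
rewards, start and platform moved to opposite corners) trains fresh agents
and evaluates a frozen-exploration (epsilon = 0) 30-episode block every 20
training episodes; the learning speed is the first checkpoint at which the
evaluation reaches 90% goal arrival.  The corridor-maze experiment uses a
deeper exploration budget (step cap 2000, failure threshold -25000):
a 500-step persistent walk diffuses roughly 20 cells, less than the
start-goal distance of the corridor maze, so the budget scales with task
difficulty.  All runs are deterministic given their seed: a single RNG
stream drives action selection, action perturbation and evaluation in a
documented draw order.

## What the synthetic environments do and do not show

The grid mazes reproduce the structure of the task family — hidden goal,
stochastic actuation, sparse positive reward, obstacle geometry — but not
continuous kinematics, realistic lidar beam models, visual input, or
any 3-D physics.  Results here demonstrate the mechanism (replay-driven
signal propagation, virtual-path construction, junction-concentrated
reactivation); they do not certify performance on physical robots.
Two observed limitations are worth stating plainly.  First, with the
prescribed replay intensity our uniform random-ER baseline is very strong
on a 400-state task — it converges essentially to the noise-optimal
policy — so the replay agent's stabilized reward does not exceed that baseline
here, even where its absolute level is healthy.
Second, in the corridor maze the agent finds and consolidates routes but
per-seed navigation remains intermittent; the junction-reactivation
signature is nevertheless statistically robust.

## A worked example

```{r example, eval = FALSE}
library(replaynav)

maze <- make_maze("open", reward_scheme = "amplified")
run <- run_experiment(maze, agent = "replay", episodes = 800, seed = 1)
run
#> <experiment_result> agent replay, 800 episodes (seed 1)
#>   success rate (last 100 episodes): 1.00
#>   stabilized average reward: 7648.12

maps <- signal_maps(run)
plot_signal_map(maps, maze)
```
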
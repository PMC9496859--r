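# replaynav

Hippocampal memory-replay agents for grid-world spatial navigation.

`replaynav` simulates a hippocampus–striatum model of spatial cognition in
which a competitive place-cell network forms a cognitive map and a
**memory-replay mechanism** trains it: navigation episodes are stored as
trajectory sequences in a bounded memory vault, failed and successful
trajectories are spliced at shared place cells into never-traversed
**virtual paths**, and reward-associated sequences are replayed offline
through temporal-difference updates so that the reward signal propagates
along whole trajectories — the effect of a λ = 1 eligibility trace with no
trace parameter to tune.  The package is for computational-neuroscience and
reinforcement-learning researchers who want a complete, deterministic,
desk-scale implementation of replay-based navigation with matched
reinforcement-learning baselines.

## The model in brief

* **Place cells** fire as channel-gated Gaussians over a joint input
  (5-dimensional state `S`, 1-dimensional memory-replay channel `M`):
  `v_i = exp(−(s_t‖S−W_S,i‖ + m_t|M−W_M,i|)² / 2σ_pc²)`,
  learned by winner-take-all plasticity with novelty recruitment.
* **Striatum**: a binary filter `F_i = [v_i > θ]` selects active cells; the
  value of action `a` is the filtered mean of their per-cell action values
  (`Q(s,a) = Σ q_i(a)F_i / Σ F_i`); selection is ε-greedy with a
  cold-start momentum policy driven by unvalued state–direction pairs.
* **Memory vault**: episodes classified high (goal reached) or low
  (penalty threshold / step cap) in bounded FIFO stores; low × high pairs
  are spliced at the shared place cell that maximises the low prefix into
  goal-reaching virtual sequences (`Φ* = Φ_Ls1 Φ_Hs2`).
* **Replay**: after every episode, high and virtual sequences are replayed
  (newest first) through the standard Q-learning update
  `Q(s_j,a_j) ← Q(s_j,a_j) + α[R + γ·max_a′ Q(s_{j+1},a′) − Q(s_j,a_j)]`,
  gated by the striatal filter, with the memory channel driven at 1.
* **Environments**: 20×20 Morris-water-maze grids (open arena, block
  obstacles, U-shaped trap, recursive-division corridor maze), 9 actions
  (8 compass + stay), 80% action reliability, rewards −100/+100/−10
  (standard) or −500/+1000/−10 (amplified).
* **Baselines**: plain tabular Q(λ = 1) with replacing traces, and tabular
  Q-learning with uniform-random single-transition experience replay
  (buffer 10,000, batch 32 per step).

## A worked example

```r
library(replaynav)

maze <- make_maze("open", reward_scheme = "amplified")
run  <- run_experiment(maze, agent = "replay", episodes = 800, seed = 1)
run
#> <experiment_result> agent replay, 800 episodes (seed 1)
#>   success rate (last 100 episodes): 1.00
#>   stabilized average reward: 7648.12
```

The stabilized average is the mean of the last 16 sums of 10-episode
return blocks: roughly, a block of ten solved navigations at ~23 steps each
earns `10 × (1000 − 10·(steps−1)) ≈ 7600` under the amplified scheme.
Compare the three agents on shared seeds:

```r
cmp <- compare_agents(maze, seeds = 1:10, episodes = 800)
cmp
#> <agent_comparison> stabilized average reward (mean over seeds)
#>   memory-replay agent : 7632.50
#>   random-ER Q-learning: 7910.75
#>   plain Q-learning    : 5600.06
#>   replay vs random-ER : -3.517%
```

Signal-propagation and reactivation ring maps of a trained agent
(ring radius = position-signal strength, ring width = reactivation count):

```r
maps <- signal_maps(run)
plot_signal_map(maps, maze)
```

Lower-level module surfaces are exported too: `maze_step()`,
`lidar_scan()`, `encode_state()`, `activate()`, `observe()`,
`find_intersections()`, `select_intersection()`, `construct_virtual()`,
`refresh_virtual()`, `replay_sequence()`, `consolidate()`,
`cell_filter()`, `state_action_value()`, `select_action()`, `td_update()`,
plus YAML maze files, plain-text maze art, JSON-lines vault serialization
and a CSV cognitive-map dump.  A command-line entry point wrapping
`run_experiment()`/`compare_agents()` is installed at
`inst/cli/replaynav.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "replaynav.R", package = "replaynav"))')" \
  run --agent replay --env open --episodes 300 --seed 1 --reward amplified --out out/
```

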
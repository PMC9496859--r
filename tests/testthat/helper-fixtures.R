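# Shared fixtures: tiny mazes, deterministic trace recording and an
# independent value-iteration oracle for chain MDPs.

open_maze5 <- function(reward_scheme = "standard") {
  grid_maze(5L, 5L, start = c(0L, 0L), goal = c(4L, 4L),
            reward_scheme = reward_scheme)
}

# 1 x n corridor, start west end, goal east end, deterministic actions
corridor_maze <- function(n, reward_scheme = "standard") {
  grid_maze(as.integer(n), 1L, start = c(0L, 0L), goal = c(n - 1L, 0L),
            reward_scheme = reward_scheme, p_intended = 1)
}

# closed-form start-state value of a deterministic corridor with n steps:
# gamma^(n-1) * R_goal + sum_{k=0}^{n-2} gamma^k * R_step
corridor_closed_form <- function(n_steps, r_goal, r_step, gamma) {
  gamma^(n_steps - 1) * r_goal +
    if (n_steps > 1) sum(gamma^(0:(n_steps - 2))) * r_step else 0
}

# independent value-iteration oracle on the deterministic chain MDP
corridor_value_iteration <- function(n_steps, r_goal, r_step, gamma,
                                     tol = 1e-14) {
  v <- numeric(n_steps + 1)          # v[n_steps+1] = terminal
  repeat {
    v_new <- v
    for (j in seq_len(n_steps)) {
      r <- if (j == n_steps) r_goal else r_step
      v_new[j] <- r + gamma * v[j + 1]
    }
    if (max(abs(v_new - v)) < tol) break
    v <- v_new
  }
  v
}

# replay agent configured for exact single-cell place fields on a lattice
lattice_setup <- function(world, live_td = "full") {
  list(net = network_config(recruit_threshold = 0, position_only = TRUE),
       pol = policy_config(theta = 0.7, cold_start = FALSE, live_td = live_td),
       pool = seed_lattice_cells(world))
}

# record a forced path (deterministic maze) against a lattice pool
record_trace <- function(world, actions, net = NULL, pool = NULL) {
  if (is.null(net)) net <- network_config(recruit_threshold = 0,
                                          position_only = TRUE)
  if (is.null(pool)) pool <- seed_lattice_cells(world)
  ag <- replay_agent(network = net, pool = pool, consolidate = FALSE)
  trace_episode(ag, world, actions)
}
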
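#' Hippocampus-striatum replay agent
#'
#' Bundles the place-cell pool, the memory vault and all configurations into
#' one stateful agent.  [run_episode()] advances it by one navigation
#' episode; consolidation (virtual-path construction plus sequence replay)
#' runs after every episode end.
#'
#' @param network a [network_config()].
#' @param policy a [policy_config()].
#' @param schedule a [replay_schedule()].
#' @param capacity_high,capacity_low,capacity_virtual vault capacities.
#' @param fail_threshold cumulative-reward failure threshold.
#' @param step_cap per-episode step cap.
#' @param consolidate run consolidation after each episode.
#' @param pool optional preset `place_cell_pool` (default empty).
#' @return list of class `replay_agent`.
#' @export
replay_agent <- function(network = network_config(),
                         policy = policy_config(),
                         schedule = replay_schedule(),
                         capacity_high = 20L, capacity_low = 50L,
                         capacity_virtual = 50L,
                         fail_threshold = -3000, step_cap = 500L,
                         consolidate = TRUE, pool = place_cell_pool()) {
  structure(list(network = network, policy = policy, schedule = schedule,
                 pool = pool,
                 vault = memory_vault(capacity_high, capacity_low,
                                      capacity_virtual),
                 fail_threshold = fail_threshold,
                 step_cap = as.integer(step_cap),
                 consolidate = consolidate),
            class = "replay_agent")
}

#' @export
print.replay_agent <- function(x, ...) {
  cat(sprintf("<replay_agent> %d place cells; vault high %d / low %d / virtual %d\n",
              nrow(x$pool$W_S), length(x$vault$high), length(x$vault$low),
              length(x$vault$virtual)))
  invisible(x)
}

#' Run one navigation episode
#'
#' Loops observe -> select -> step -> gated TD update from the maze start
#' until the goal, the penalty threshold or the step cap; classifies and
#' stores the recorded sequence; then (by default) runs one consolidation
#' round.
#'
#' @param agent a [replay_agent()].
#' @param world a `grid_maze`.
#' @return list with the updated `agent`, the recorded `sequence` and
#'   `stats` (`return`, `steps`, `success`).
#' @export
run_episode <- function(agent, world) {
  stopifnot(inherits(agent, "replay_agent"), inherits(world, "grid_maze"))
  out <- .cpp_run_episode(unclass(agent$pool), unclass(world),
                          unclass(agent$network), unclass(agent$policy),
                          agent$fail_threshold, agent$step_cap, TRUE)
  agent$pool <- structure(out$pool[c("W_S", "W_M", "q_values",
                                     "reactivations", "last_reactivated",
                                     "saturated_events")],
                          class = "place_cell_pool")
  seq <- as_sequence(out$sequence)
  agent$vault <- vault_store(agent$vault, seq)
  if (agent$consolidate) {
    cons <- consolidate(agent$pool, agent$vault, agent$schedule,
                        agent$network, agent$policy,
                        r_step = reward_of(world, "step"))
    agent$pool <- cons$pool
    agent$vault <- cons$vault
  }
  list(agent = agent, sequence = seq,
       stats = list(return = out$return, steps = out$steps,
                    success = out$success))
}

#' Record a forced-action trajectory
#'
#' Drives the agent's hippocampal machinery along a prescribed intended
#' action sequence (no value learning, no action selection) and returns the
#' recorded `trajectory_sequence`.  Useful for building bespoke two-path
#' fixtures; run it on a maze with `p_intended = 1` for fully deterministic
#' paths.
#'
#' @param agent a [replay_agent()].
#' @param world a `grid_maze`.
#' @param actions integer vector of intended actions (0..8).
#' @return list with the updated `agent` and the recorded `sequence`.
#' @export
trace_episode <- function(agent, world, actions) {
  out <- .cpp_trace_episode(unclass(agent$pool), unclass(world),
                            unclass(agent$network), as.integer(actions), TRUE)
  agent$pool <- structure(out$pool[c("W_S", "W_M", "q_values",
                                     "reactivations", "last_reactivated",
                                     "saturated_events")],
                          class = "place_cell_pool")
  list(agent = agent, sequence = as_sequence(out$sequence))
}
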
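#' Train an agent on a maze and record per-episode metrics
#'
#' Runs `episodes` sequential navigation episodes with one RNG stream per
#' run (seeded by `seed`), so a repeated call reproduces the run exactly.
#' The replay agent consolidates after every episode; the two baselines are
#' tabular Q-learners over the grid cells.
#'
#' @param world a `grid_maze`.
#' @param agent `"replay"` (hippocampus-striatum agent with memory replay),
#'   `"qlearn"` (plain tabular Q-learning with replacing eligibility traces,
#'   lambda = 1 by default) or `"qlearn_random_er"` (tabular Q-learning with
#'   a uniform-random single-transition replay buffer).
#' @param episodes number of training episodes.
#' @param seed RNG seed for the run.
#' @param network,policy,schedule agent configurations.
#' @param capacity_high,capacity_low,capacity_virtual vault capacities
#'   (replay agent).
#' @param fail_threshold,step_cap episode termination rules (all agents).
#' @param lambda eligibility-trace decay of the plain baseline.
#' @param buffer_size,batch_size replay-buffer parameters of the random-ER
#'   baseline.
#' @param consolidate run replay consolidation (replay agent only).
#' @param eval_every if positive, run a frozen-exploration evaluation block
#'   every `eval_every` training episodes.
#' @param eval_episodes episodes per evaluation block.
#' @param window,n_windows stabilization windowing: the stabilized average is
#'   the mean of the last `n_windows` sums of `window` consecutive episode
#'   returns.
#' @param keep_paths also return per-episode trajectories.
#' @param pool preset `place_cell_pool` for the replay agent (default
#'   empty; a lattice pool from [seed_lattice_cells()] gives the tabular
#'   reduction).
#' @return list of class `experiment_result`: per-episode `returns`,
#'   `steps`, `success`, the stabilization summary, the trained value
#'   container (`pool`+`vault` or `Q`), and the evaluation curve.
#' @export
run_experiment <- function(world,
                           agent = c("replay", "qlearn", "qlearn_random_er"),
                           episodes = 800L, seed = 1L,
                           network = network_config(),
                           policy = policy_config(),
                           schedule = replay_schedule(),
                           capacity_high = 20L, capacity_low = 50L,
                           capacity_virtual = 50L,
                           fail_threshold = -3000, step_cap = 500L,
                           lambda = 1, buffer_size = 10000L,
                           batch_size = 32L, consolidate = TRUE,
                           eval_every = 0L, eval_episodes = 30L,
                           window = 10L, n_windows = 16L,
                           keep_paths = FALSE, pool = place_cell_pool()) {
  agent <- match.arg(agent)
  stopifnot(inherits(world, "grid_maze"))
  set.seed(as.integer(seed))
  if (agent == "replay") {
    raw <- .cpp_run_replay_experiment(
      unclass(world), unclass(network), unclass(policy), unclass(schedule),
      vault_unclass(memory_vault(capacity_high, capacity_low,
                                 capacity_virtual)),
      unclass(pool),
      as.integer(episodes), fail_threshold, as.integer(step_cap),
      consolidate, as.integer(eval_every), as.integer(eval_episodes),
      keep_paths)
    value <- list(
      pool = structure(raw$pool[c("W_S", "W_M", "q_values", "reactivations",
                                  "last_reactivated", "saturated_events")],
                       class = "place_cell_pool"),
      vault = vault_reclass(raw$vault))
  } else {
    baseline_policy <- policy
    baseline_policy$cold_start <- FALSE
    raw <- .cpp_run_tabular_experiment(
      unclass(world), unclass(baseline_policy), as.integer(episodes),
      fail_threshold, as.integer(step_cap),
      if (agent == "qlearn") lambda else 0,
      agent == "qlearn_random_er", as.integer(buffer_size),
      as.integer(batch_size), as.integer(eval_every),
      as.integer(eval_episodes), keep_paths)
    value <- list(Q = raw$Q)
  }
  stab <- stabilization_summary(raw$returns, window = window,
                                n_windows = n_windows)
  res <- list(agent = agent, seed = as.integer(seed),
              episodes = as.integer(episodes),
              returns = raw$returns, steps = raw$steps,
              success = raw$success,
              window_values = stab$window_values,
              stabilized_average = stab$stabilized_average,
              eval_episode = raw$eval_episode,
              eval_success = raw$eval_success,
              value = value, world = world)
  if (keep_paths) res$paths <- lapply(raw$paths, as_sequence)
  structure(res, class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> agent %s, %d episodes (seed %d)\n",
              x$agent, x$episodes, x$seed))
  cat(sprintf("  success rate (last 100 episodes): %.2f\n",
              mean(tail(x$success, 100))))
  cat(sprintf("  stabilized average reward: %.2f\n", x$stabilized_average))
  invisible(x)
}

#' Stabilization-period summary of an episode-return series
#'
#' Splits the tail of the return series into `n_windows` consecutive blocks
#' of `window` episodes, sums the returns inside each block and averages the
#' block totals.  When fewer than `n_windows` full blocks are available the
#' summary uses the blocks that exist and flags the shortfall.
#'
#' @param returns numeric vector of per-episode returns.
#' @param window episodes per block.
#' @param n_windows number of trailing blocks.
#' @return list with `window_values` and their mean `stabilized_average`.
#' @export
stabilization_summary <- function(returns, window = 10L, n_windows = 16L) {
  nb <- min(n_windows, length(returns) %/% window)
  if (nb < 1) return(list(window_values = numeric(), stabilized_average = NA_real_))
  if (nb < n_windows)
    message(sprintf("only %d of %d stabilization windows available", nb, n_windows))
  tail_returns <- tail(returns, nb * window)
  wv <- vapply(seq_len(nb), function(i)
    sum(tail_returns[((i - 1) * window + 1):(i * window)]), numeric(1))
  list(window_values = wv, stabilized_average = mean(wv))
}

#' Compare the replay agent with the two reinforcement-learning baselines
#'
#' Trains all three agents on the same maze across shared seeds and reports
#' the per-seed stabilized average rewards plus the relative improvement of
#' the replay agent over random experience replay.
#'
#' @param world a `grid_maze` (typically the amplified-reward open maze).
#' @param seeds integer vector of run seeds.
#' @param episodes training episodes per run.
#' @param ... passed to [run_experiment()].
#' @return list of class `agent_comparison` with `per_seed` (data frame) and
#'   `summary` (named means and the relative improvement in percent).
#' @export
compare_agents <- function(world, seeds = 1:10, episodes = 800L, ...) {
  agents <- c("replay", "qlearn_random_er", "qlearn")
  per_seed <- do.call(rbind, lapply(seeds, function(s) {
    vals <- vapply(agents, function(a)
      run_experiment(world, agent = a, episodes = episodes,
                     seed = s, ...)$stabilized_average, numeric(1))
    data.frame(seed = s, replay = vals[1], random_er = vals[2],
               qlearn = vals[3])
  }))
  means <- colMeans(per_seed[, c("replay", "random_er", "qlearn")])
  structure(list(
    per_seed = per_seed,
    summary = c(means,
                improvement_pct = 100 * (means[["replay"]] /
                                           means[["random_er"]] - 1))),
    class = "agent_comparison")
}

#' @export
print.agent_comparison <- function(x, ...) {
  cat("<agent_comparison> stabilized average reward (mean over seeds)\n")
  cat(sprintf("  memory-replay agent : %.2f\n", x$summary[["replay"]]))
  cat(sprintf("  random-ER Q-learning: %.2f\n", x$summary[["random_er"]]))
  cat(sprintf("  plain Q-learning    : %.2f\n", x$summary[["qlearn"]]))
  cat(sprintf("  replay vs random-ER : %+.3f%%\n",
              x$summary[["improvement_pct"]]))
  invisible(x)
}

#' Signal-strength and reactivation maps of a trained replay agent
#'
#' Per free grid cell: `strength` is the maximum filtered action value at
#' that cell, normalized to [0, 1] by the map maximum; `reactivations` sums
#' the reactivation counts of the place cells whose field centre falls on
#' the cell.
#'
#' @param result an `experiment_result` from a replay run (or a list with
#'   `pool`).
#' @param world the `grid_maze` (defaults to the result's).
#' @param network,policy configurations used for probing.
#' @return list with matrices `strength` and `reactivations`
#'   (`width x height`, NA on obstacles).
#' @export
signal_maps <- function(result, world = NULL, network = network_config(),
                        policy = policy_config()) {
  pool <- if (inherits(result, "experiment_result")) result$value$pool
          else result$pool
  if (is.null(world)) world <- result$world
  .cpp_signal_maps(unclass(pool), unclass(world), unclass(network),
                   unclass(policy))
}

#' Draw a signal-propagation ring map
#'
#' Rings are drawn per free cell with radius proportional to the signal
#' strength and line width proportional to the reactivation count, the
#' rendering used to visualise how reward information has propagated through
#' the cognitive map.
#'
#' @param maps output of [signal_maps()].
#' @param world the `grid_maze`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_signal_map <- function(maps, world, ...) {
  graphics::plot(NA, xlim = c(-1, world$width), ylim = c(-1, world$height),
                 asp = 1, xlab = "x", ylab = "y", ...)
  if (nrow(world$obstacles) > 0)
    graphics::rect(world$obstacles[, 1] - 0.5, world$obstacles[, 2] - 0.5,
                   world$obstacles[, 1] + 0.5, world$obstacles[, 2] + 0.5,
                   col = "grey30", border = NA)
  rmax <- max(maps$reactivations, na.rm = TRUE)
  for (x in 0:(world$width - 1))
    for (y in 0:(world$height - 1)) {
      s <- maps$strength[x + 1, y + 1]
      if (is.na(s) || s <= 0) next
      r <- maps$reactivations[x + 1, y + 1]
      graphics::symbols(x, y, circles = 0.45 * s, inches = FALSE, add = TRUE,
                        fg = "darkgreen",
                        lwd = 0.5 + 3 * (if (rmax > 0) r / rmax else 0))
    }
  graphics::points(world$start[1], world$start[2], pch = 16, col = "red")
  graphics::points(world$goal[1], world$goal[2], pch = 15, col = "blue")
  invisible(maps)
}

#' Episodes needed to solve a task reliably
#'
#' Trains an agent with periodic frozen-exploration evaluation blocks and
#' reports the first training-episode count at which the evaluation success
#' rate reaches `threshold`.
#'
#' @param world a `grid_maze`.
#' @param agent agent type as in [run_experiment()].
#' @param seeds seeds to repeat over.
#' @param max_episodes training budget per seed.
#' @param eval_every,eval_episodes evaluation cadence and block size.
#' @param threshold required evaluation success rate.
#' @param ... passed to [run_experiment()].
#' @return data frame with `seed` and `episodes_to_criterion` (NA when the
#'   budget was exhausted first).
#' @export
learning_speed <- function(world, agent = "replay", seeds = 1:10,
                           max_episodes = 1000L, eval_every = 20L,
                           eval_episodes = 30L, threshold = 0.9, ...) {
  rows <- lapply(seeds, function(s) {
    r <- run_experiment(world, agent = agent, episodes = max_episodes,
                        seed = s, eval_every = eval_every,
                        eval_episodes = eval_episodes, ...)
    hit <- which(r$eval_success >= threshold)
    data.frame(seed = s,
               episodes_to_criterion =
                 if (length(hit) == 0) NA_integer_
                 else r$eval_episode[hit[1]])
  })
  do.call(rbind, rows)
}
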
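#' Replay/consolidation schedule
#'
#' Consolidation first refreshes the virtual store (bounded by `p_runs` pair
#' evaluations) and then replays every high-reward and virtual sequence up
#' to `passes_per_sequence` times, with the total number of replayed triples
#' capped by `niter`.
#'
#' @param passes_per_sequence replays of each eligible sequence per round;
#'   `0` means automatic (length of the longest stored sequence, capped at
#'   50), which guarantees full reward propagation along any stored
#'   corridor.
#' @param rounds consolidation rounds per call.
#' @param niter total replayed-triple budget per round.
#' @param p_runs virtual-construction pair budget per round.
#' @param forget_after rounds without replay reactivation after which a
#'   cell's accumulated action values are erased (0 disables forgetting).
#'   Memories that are not repeatedly stimulated fade; stale value islands
#'   that replay no longer visits return to the cold-start explorer.
#' @return list of class `replay_schedule`.
#' @export
replay_schedule <- function(passes_per_sequence = 0L, rounds = 1L,
                            niter = 1000L, p_runs = 30L,
                            forget_after = 0L) {
  stopifnot(passes_per_sequence >= 0, rounds >= 1, niter >= 1, p_runs >= 1,
            forget_after >= 0)
  structure(list(passes_per_sequence = as.integer(passes_per_sequence),
                 rounds = as.integer(rounds), niter = as.integer(niter),
                 p_runs = as.integer(p_runs),
                 forget_after = as.integer(forget_after)),
            class = "replay_schedule")
}

#' Replay one reward-associated sequence through the cognitive map
#'
#' Re-presents the stored state vectors with the memory channel driven at 1
#' and applies the standard Q-learning update to the action values of every
#' cell passing the striatal filter at the replayed state; the terminal
#' triple bootstraps from 0.  Reactivation counts of the gated cells are
#' incremented.  Only `high` and `virtual` sequences are eligible.
#'
#' @param pool a `place_cell_pool`.
#' @param seq a `trajectory_sequence` with outcome `high` or `virtual`.
#' @param net a [network_config()].
#' @param policy a [policy_config()] (supplies `alpha`, `gamma`, `theta`).
#' @param r_step ordinary step reward (sets the unvalued-action prior
#'   `r_step / (1 - gamma)` of the bootstrap).
#' @return the updated pool.
#' @export
replay_sequence <- function(pool, seq, net = network_config(),
                            policy = policy_config(), r_step = -10) {
  if (!seq$outcome %in% c("high", "virtual"))
    stop("only reward-associated (high/virtual) sequences are replayed")
  out <- .cpp_replay_sequence(unclass(pool), unclass(seq), unclass(net),
                              unclass(policy), r_step)
  structure(out$pool[c("W_S", "W_M", "q_values", "reactivations",
                       "last_reactivated", "saturated_events")], class = "place_cell_pool")
}

#' One consolidation round: virtual-path refresh plus sequence replay
#'
#' @param pool a `place_cell_pool`.
#' @param vault a `memory_vault`.
#' @param schedule a [replay_schedule()].
#' @param net a [network_config()].
#' @param policy a [policy_config()].
#' @param r_step ordinary step reward of the active scheme.
#' @param round consolidation round index (drives the forgetting clock).
#' @return list with the updated `pool` and `vault`.
#' @export
consolidate <- function(pool, vault, schedule = replay_schedule(),
                        net = network_config(), policy = policy_config(),
                        r_step = -10, round = 0L) {
  out <- .cpp_consolidate(unclass(pool), vault_unclass(vault),
                          unclass(schedule), unclass(net), unclass(policy),
                          r_step, as.integer(round))
  list(pool = structure(out$pool[c("W_S", "W_M", "q_values", "reactivations",
                                   "last_reactivated", "saturated_events")],
                        class = "place_cell_pool"),
       vault = vault_reclass(out$vault))
}
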
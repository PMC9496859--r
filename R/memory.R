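#' Trajectory sequences
#'
#' One episode is recorded as an ordered list of state-action-reward triples
#' together with the winning place cell of each step.  A sequence is
#' classified `high` when its final step reached the goal, `low` when the
#' episode failed (penalty threshold or step cap), and `virtual` when it was
#' spliced from a low-reward prefix and a high-reward suffix by
#' [construct_virtual()].
#'
#' @param x,y integer vectors of visited cells (one entry per triple).
#' @param action executed action indices.
#' @param cell_id winning place-cell ids, recorded as 0-based pool indices
#'   (replay re-fires these cells, so a sequence is only meaningful against
#'   the pool it was recorded with).
#' @param reward per-step rewards.
#' @param state_vec numeric matrix (steps x 5) of encoded state vectors.
#' @param outcome `"high"`, `"low"` or `"virtual"`.
#' @return list of class `trajectory_sequence`.
#' @export
trajectory_sequence <- function(x, y, action, cell_id, reward,
                                state_vec = matrix(0, length(x), 5),
                                outcome = c("low", "high", "virtual")) {
  outcome <- match.arg(outcome)
  n <- length(x)
  stopifnot(length(y) == n, length(action) == n, length(cell_id) == n,
            length(reward) == n, nrow(state_vec) == n)
  if (n > 1) {
    dx <- abs(diff(x)); dy <- abs(diff(y))
    if (any(pmax(dx, dy) > 1))
      stop("consecutive states must be grid-adjacent or identical")
  }
  structure(list(x = as.integer(x), y = as.integer(y),
                 action = as.integer(action), cell_id = as.integer(cell_id),
                 reward = as.numeric(reward), state_vec = state_vec,
                 outcome = outcome, total_reward = sum(reward), serial = 0),
            class = "trajectory_sequence")
}

as_sequence <- function(l) {
  l$state_vec <- matrix(as.numeric(l$state_vec), ncol = 5)
  structure(l[c("x", "y", "action", "cell_id", "reward", "state_vec",
                "outcome", "total_reward", "serial")],
            class = "trajectory_sequence")
}

#' @export
print.trajectory_sequence <- function(x, ...) {
  cat(sprintf("<trajectory_sequence> %d triples, outcome %s, total reward %.1f\n",
              length(x$x), x$outcome, x$total_reward))
  invisible(x)
}

#' @export
length.trajectory_sequence <- function(x) length(x$x)

#' Reward-based episode classification
#'
#' `high` iff the final step reached the goal; `low` iff the episode was
#' terminated by the cumulative-penalty threshold or the step cap.
#'
#' @param seq a completed `trajectory_sequence`.
#' @param world the `grid_maze` the episode ran in.
#' @param fail_threshold cumulative-reward failure threshold.
#' @param step_cap episode step cap.
#' @export
classify_episode <- function(seq, world, fail_threshold = -3000,
                             step_cap = 500L) {
  n <- length(seq$x)
  if (n == 0) stop("empty sequence cannot be classified")
  if (seq$reward[n] == reward_of(world, "goal")) return("high")
  if (seq$total_reward <= fail_threshold || n >= step_cap) return("low")
  stop("episode is not terminated: neither goal, penalty threshold nor step cap")
}

#' Triples-only view of a stored sequence
#'
#' The sub-sequence read by downstream replay operations: the
#' state-action-reward triples with the place-cell/memory bookkeeping
#' stripped.
#'
#' @param seq a `trajectory_sequence`.
#' @return data frame with columns `x`, `y`, `action`, `reward`.
#' @export
sequence_triples <- function(seq) {
  data.frame(x = seq$x, y = seq$y, action = seq$action, reward = seq$reward)
}

#' Bounded memory vault of classified sequences
#'
#' Three FIFO stores: goal-reaching (`high`), failed (`low`) and spliced
#' (`virtual`) sequences; on overflow the oldest member of a store is
#' evicted.
#'
#' @param capacity_high,capacity_low,capacity_virtual store capacities.
#' @param max_stored_length stored-tail cap: only the final
#'   `max_stored_length` triples of a sequence are kept (0 = unbounded).
#'   Beyond the discount horizon a trajectory prefix carries no recoverable
#'   reward signal, and bounded sequences stay fully replayable within the
#'   consolidation budget.
#' @return list of class `memory_vault`.
#' @export
memory_vault <- function(capacity_high = 20L, capacity_low = 50L,
                         capacity_virtual = 50L, max_stored_length = 64L) {
  structure(list(high = list(), low = list(), virtual = list(),
                 capacity_high = as.integer(capacity_high),
                 capacity_low = as.integer(capacity_low),
                 capacity_virtual = as.integer(capacity_virtual),
                 max_stored_length = as.integer(max_stored_length),
                 serial = 0, tried = matrix(numeric(), ncol = 2)),
            class = "memory_vault")
}

#' @export
print.memory_vault <- function(x, ...) {
  cat(sprintf("<memory_vault> high %d/%d, low %d/%d, virtual %d/%d\n",
              length(x$high), x$capacity_high, length(x$low), x$capacity_low,
              length(x$virtual), x$capacity_virtual))
  invisible(x)
}

#' Store a classified sequence in the vault
#'
#' @param vault a `memory_vault`.
#' @param seq a classified `trajectory_sequence`.
#' @export
vault_store <- function(vault, seq) {
  stopifnot(inherits(vault, "memory_vault"),
            inherits(seq, "trajectory_sequence"))
  slot <- seq$outcome
  if (slot == "virtual") {
    key <- paste(seq$cell_id, collapse = ",")
    keys <- vapply(vault$virtual, function(s) paste(s$cell_id, collapse = ","), "")
    if (key %in% keys) return(vault)
  }
  vault$serial <- vault$serial + 1
  seq$serial <- vault$serial
  ml <- vault$max_stored_length
  n <- length(seq$x)
  if (ml > 0 && n > ml) {
    keep <- (n - ml + 1):n
    seq$x <- seq$x[keep]; seq$y <- seq$y[keep]
    seq$action <- seq$action[keep]; seq$cell_id <- seq$cell_id[keep]
    seq$reward <- seq$reward[keep]
    seq$state_vec <- seq$state_vec[keep, , drop = FALSE]
  }
  cap <- vault[[paste0("capacity_", slot)]]
  lst <- c(vault[[slot]], list(seq))
  if (length(lst) > cap) lst <- lst[(length(lst) - cap + 1):length(lst)]
  vault[[slot]] <- lst
  vault
}

#' Intersection place cells of a low- and a high-reward sequence
#'
#' For every place cell occurring in both sequences, returns the LAST index
#' at which it occurs in the low sequence and the FIRST index in the high
#' sequence (1-based).
#'
#' @param low,high `trajectory_sequence`s.
#' @return data frame with columns `cell_id`, `low_index`, `high_index`;
#'   zero rows when the cell sets are disjoint.
#' @export
find_intersections <- function(low, high) {
  stopifnot(length(low$cell_id) > 0, length(high$cell_id) > 0)
  r <- .cpp_find_intersections(low$cell_id, high$cell_id)
  data.frame(cell_id = r$cell_id, low_index = r$low_index + 1L,
             high_index = r$high_index + 1L)
}

#' Choose the splice point among candidate intersections
#'
#' Maximizes the low-sequence prefix; ties break to the longest remaining
#' high-sequence suffix, then to the lowest cell id.
#'
#' @param intersections data frame from [find_intersections()].
#' @return single row of `intersections`.
#' @export
select_intersection <- function(intersections) {
  if (nrow(intersections) == 0) stop("no intersection: no virtual path")
  k <- .cpp_select_intersection(intersections$cell_id,
                                intersections$low_index - 1L,
                                intersections$high_index - 1L)
  intersections[k, ]
}

#' Splice a virtual goal-reaching trajectory
#'
#' Concatenates the low-reward prefix up to the chosen intersection with the
#' high-reward suffix after it.  The splice triple's action is redirected
#' onto the high branch and its reward reset to the ordinary step penalty,
#' so the virtual sequence is a grid-valid path ending in the goal reward.
#' The complementary combination (high prefix + low suffix) is never built.
#'
#' @param low,high source `trajectory_sequence`s.
#' @param intersection single-row data frame (`cell_id`, `low_index`,
#'   `high_index`).
#' @param r_step ordinary step reward of the active scheme.
#' @return a `trajectory_sequence` with outcome `"virtual"`, or `NULL` when
#'   the splice would create non-adjacent consecutive states.
#' @export
construct_virtual <- function(low, high, intersection, r_step = -10) {
  out <- .cpp_construct_virtual(unclass(low), unclass(high),
                                intersection$low_index - 1L,
                                intersection$high_index - 1L, r_step)
  if (!out$ok) return(NULL)
  as_sequence(out$sequence)
}

#' Rebuild the virtual store from stored low x high pairs
#'
#' Evaluates up to `pair_budget` not-yet-tried (low, high) pairs, newest
#' first; each crossing pair contributes at most one virtual sequence,
#' deduplicated by its visited-cell-id sequence.
#'
#' @param vault a `memory_vault`.
#' @param r_step ordinary step reward.
#' @param pair_budget maximum pair evaluations for this call.
#' @return the updated vault (attribute `constructed` gives the number of new
#'   virtual sequences).
#' @export
refresh_virtual <- function(vault, r_step = -10, pair_budget = 30L) {
  out <- .cpp_refresh_virtual(vault_unclass(vault), r_step, pair_budget)
  v <- vault_reclass(out$vault)
  attr(v, "constructed") <- out$constructed
  v
}

vault_unclass <- function(vault) {
  v <- unclass(vault)
  v$high <- lapply(v$high, unclass)
  v$low <- lapply(v$low, unclass)
  v$virtual <- lapply(v$virtual, unclass)
  v
}

vault_reclass <- function(v) {
  v$high <- lapply(v$high, as_sequence)
  v$low <- lapply(v$low, as_sequence)
  v$virtual <- lapply(v$virtual, as_sequence)
  structure(v[c("high", "low", "virtual", "capacity_high", "capacity_low",
                "capacity_virtual", "max_stored_length", "serial", "tried")],
            class = "memory_vault")
}

#' Serialize a vault as JSON lines
#'
#' One sequence per line (triples, cell ids, outcome, total reward); a file
#' read back restores the stored sequences exactly.
#'
#' @param vault a `memory_vault`.
#' @param path file path.
#' @export
write_vault_jsonl <- function(vault, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (slot in c("high", "low", "virtual"))
    for (s in vault[[slot]])
      writeLines(jsonlite::toJSON(unclass(s), digits = NA, auto_unbox = FALSE,
                                  matrix = "rowmajor"), con)
  invisible(path)
}

#' @rdname write_vault_jsonl
#' @param capacities passed to [memory_vault()] for the restored vault.
#' @export
read_vault_jsonl <- function(path, capacities = c(20L, 50L, 50L)) {
  vault <- memory_vault(capacities[1], capacities[2], capacities[3])
  for (line in readLines(path)) {
    j <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    seq <- trajectory_sequence(j$x, j$y, j$action, j$cell_id, j$reward,
                               state_vec = matrix(as.numeric(j$state_vec),
                                                  ncol = 5),
                               outcome = j$outcome)
    vault <- vault_store(vault, seq)
  }
  vault
}
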
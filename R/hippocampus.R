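#' Place-cell network configuration
#'
#' The hippocampal layer is a pool of Gaussian-tuned units over a joint
#' input: a 5-dimensional environmental state channel and a 1-dimensional
#' memory-replay channel.  A cell's firing rate is
#' \deqn{v_i = \exp\!\left(-\frac{(s_t\,\lVert S - W_{S,i}\rVert +
#'   m_t\,\lvert M - W_{M,i}\rvert)^2}{2\sigma_{pc}^2}\right)}
#' with channel gains \eqn{s_t, m_t} and place-field width \eqn{\sigma_{pc}}
#' in grid-cell units.  Learning is competitive: the maximally active cell
#' moves its weights toward the input by rate \eqn{\delta}; when no cell
#' fires above `recruit_threshold` a new cell is recruited at the input.
#'
#' @param sigma_pc place-field width, in grid-cell units.
#' @param delta winner-take-all learning rate.
#' @param s_gate,m_gate gains of the state and memory channels.
#' @param a,b declared channel dimensions (5 and 1).
#' @param recruit_threshold winning activation below which a new cell is
#'   recruited.
#' @param recruit_floor activation below which a state counts as wholly
#'   unfamiliar (diagnostic only).
#' @param max_cells pool capacity; recruitment stops at the cap.
#' @param position_only if `TRUE` the encoder zeroes the heading and
#'   occupancy components, making place fields purely positional (used for
#'   the tabular-reduction analysis).
#' @return list of class `network_config`.
#' @export
network_config <- function(sigma_pc = 0.7, delta = 0.5, s_gate = 0.6,
                           m_gate = 0.4, a = 5L, b = 1L,
                           recruit_threshold = 0.5, recruit_floor = 0.0065,
                           max_cells = 2000L, position_only = FALSE) {
  stopifnot(sigma_pc > 0, sigma_pc < 1, delta > 0, delta <= 1,
            s_gate > 0, s_gate < 1, m_gate > 0, m_gate < 1,
            a == 5L, b == 1L, recruit_threshold >= 0, max_cells >= 1)
  structure(list(sigma_pc = sigma_pc, delta = delta, s_gate = s_gate,
                 m_gate = m_gate, a = as.integer(a), b = as.integer(b),
                 recruit_threshold = recruit_threshold,
                 recruit_floor = recruit_floor,
                 max_cells = as.integer(max_cells),
                 position_only = position_only),
            class = "network_config")
}

#' Create an (empty or preset) place-cell pool
#'
#' @param W_S numeric matrix (cells x 5) of state-channel weights.
#' @param W_M numeric vector of memory-channel weights.
#' @param q_values numeric matrix (cells x 9) of per-action values.
#' @param reactivations integer vector of reactivation counts.
#' @param last_reactivated integer vector: consolidation round at which each
#'   cell was last reactivated (-1 = never; drives the forgetting clock).
#' @return list of class `place_cell_pool`.
#' @export
place_cell_pool <- function(W_S = matrix(numeric(), ncol = 5),
                            W_M = numeric(),
                            q_values = matrix(0, nrow = nrow(W_S), ncol = 9),
                            reactivations = integer(nrow(W_S)),
                            last_reactivated = rep(-1L, nrow(W_S))) {
  stopifnot(ncol(W_S) == 5, nrow(W_S) == length(W_M),
            nrow(q_values) == nrow(W_S), ncol(q_values) == 9,
            length(reactivations) == nrow(W_S),
            length(last_reactivated) == nrow(W_S))
  structure(list(W_S = W_S, W_M = as.numeric(W_M), q_values = q_values,
                 reactivations = as.integer(reactivations),
                 last_reactivated = as.integer(last_reactivated),
                 saturated_events = 0L),
            class = "place_cell_pool")
}

#' @export
print.place_cell_pool <- function(x, ...) {
  cat(sprintf("<place_cell_pool> %d cells, %d total reactivations\n",
              nrow(x$W_S), sum(x$reactivations)))
  invisible(x)
}

n_cells <- function(pool) nrow(pool$W_S)

#' Encode an agent state as the 5-dimensional network input
#'
#' Components: position `x` and `y` in grid-cell units, heading direction
#' `cos(theta)` and `sin(theta)` of the last executed action (the stay action
#' maps to angle 0), and the occupied fraction of the radius-1 lidar scan.
#'
#' @param world a `grid_maze`.
#' @param state length-2 cell `(x, y)`.
#' @param heading action index 0..8 of the last executed action (8 = stay).
#' @param position_only zero out heading/occupancy components.
#' @export
encode_state <- function(world, state, heading = 8L, position_only = FALSE) {
  v <- .cpp_encode(unclass(world), state[1], state[2], as.integer(heading),
                   position_only)
  names(v) <- c("x", "y", "cos_heading", "sin_heading", "occupied_frac")
  v
}

#' Firing rates of all cells for a joint input
#'
#' @param pool a `place_cell_pool` with at least one cell.
#' @param S_in numeric length-5 state input.
#' @param M_in memory-channel scalar (0 live navigation, 1 replay).
#' @param cfg a [network_config()].
#' @export
activate <- function(pool, S_in, M_in = 0, cfg = network_config()) {
  if (n_cells(pool) == 0) stop("empty pool: recruitment required")
  .cpp_activate(unclass(pool), as.numeric(S_in), M_in, unclass(cfg))
}

#' Winner-take-all cell for a firing-rate vector
#'
#' Ties break to the lowest cell index.
#' @param v firing-rate vector.
#' @return 1-based index of the winning cell.
#' @export
winner_cell <- function(v) {
  stopifnot(length(v) > 0)
  which.max(v)
}

#' Move the winning cell's weights toward the input
#'
#' @param pool a `place_cell_pool`.
#' @param cell 1-based winning cell index.
#' @param S_in,M_in the joint input.
#' @param cfg a [network_config()].
#' @export
update_weights <- function(pool, cell, S_in, M_in, cfg = network_config()) {
  pool$W_S[cell, ] <- pool$W_S[cell, ] + cfg$delta * (S_in - pool$W_S[cell, ])
  pool$W_M[cell] <- pool$W_M[cell] + cfg$delta * (M_in - pool$W_M[cell])
  pool
}

#' Present an input to the network: activate, recruit or adapt
#'
#' Computes all firing rates; if the pool is empty or the winning activation
#' is below `cfg$recruit_threshold` (and the pool is under `max_cells`) a new
#' cell is recruited exactly at the input; otherwise the winner's weights are
#' moved toward the input.  At capacity with a sub-threshold winner the
#' winner is updated anyway and a warning is raised.
#'
#' @inheritParams activate
#' @param learn apply weight plasticity (`FALSE` = probe only).
#' @return list with the updated `pool`, `rates`, `winner` (1-based) and
#'   `recruited`.
#' @export
observe <- function(pool, S_in, M_in = 0, cfg = network_config(),
                    learn = TRUE) {
  out <- .cpp_observe(unclass(pool), as.numeric(S_in), M_in, unclass(cfg),
                      learn)
  sat <- out$pool$saturated_events
  out$pool <- structure(out$pool[c("W_S", "W_M", "q_values", "reactivations",
                                   "last_reactivated", "saturated_events")],
                        class = "place_cell_pool")
  if (sat > 0)
    warning("pool at max_cells with sub-threshold winner; winner updated anyway")
  out
}

#' Seed a lattice pool with one positional cell per free grid cell
#'
#' Gives every free cell its own place cell (heading/occupancy zeroed),
#' producing disjoint single-cell place fields when the filter threshold
#' exceeds the activation of an orthogonal neighbour.
#'
#' @param world a `grid_maze`.
#' @return a `place_cell_pool` plus an index map as attribute `cell_of`
#'   (matrix `width x height`, NA on obstacles).
#' @export
seed_lattice_cells <- function(world) {
  free <- free_cells(world$width, world$height, world$obstacles)
  W <- cbind(free[, 1], free[, 2], 0, 0, 0)
  pool <- place_cell_pool(W_S = W, W_M = numeric(nrow(W)))
  idx <- matrix(NA_integer_, world$width, world$height)
  idx[cbind(free[, 1] + 1, free[, 2] + 1)] <- seq_len(nrow(free))
  attr(pool, "cell_of") <- idx
  pool
}

#' Dump or restore the cognitive map
#'
#' Writes one CSV row per place cell (id, state/memory weights, the nine
#' action values, reactivation bookkeeping) with doubles printed at 17
#' significant digits, so reading the file back restores the pool
#' bit-exactly.
#'
#' @param pool a `place_cell_pool`.
#' @param path file path.
#' @export
write_cognitive_map <- function(pool, path) {
  n <- nrow(pool$W_S)
  num <- function(x) sprintf("%.17g", x)
  df <- data.frame(cell = seq_len(n))
  for (k in 1:5) df[[paste0("ws", k)]] <- num(pool$W_S[, k])
  df$wm <- num(pool$W_M)
  for (a in 1:9) df[[paste0("q", a - 1)]] <- num(pool$q_values[, a])
  df$reactivations <- pool$reactivations
  df$last_reactivated <- pool$last_reactivated
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cognitive_map
#' @export
read_cognitive_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  place_cell_pool(
    W_S = matrix(as.numeric(unlist(df[paste0("ws", 1:5)])), ncol = 5),
    W_M = as.numeric(df$wm),
    q_values = matrix(as.numeric(unlist(df[paste0("q", 0:8)])), ncol = 9),
    reactivations = as.integer(df$reactivations),
    last_reactivated = as.integer(df$last_reactivated))
}
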
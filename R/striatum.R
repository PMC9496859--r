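#' Striatal action-selection configuration
#'
#' The striatum layer selects among the eight compass movements (plus stay)
#' from the filtered place-cell value function.  While the filtered value
#' function is still identically zero (cold start) the agent picks a random
#' action with probability `p_random` and otherwise keeps its current
#' direction; once values are non-zero it is epsilon-greedy over the eight
#' movements, with exploration drawing uniformly over all nine actions.
#'
#' @param epsilon exploration rate of the epsilon-greedy policy.
#' @param p_random cold-start random-action probability.
#' @param theta place-cell filter threshold (strict inequality).
#' @param alpha TD learning rate.
#' @param gamma discount factor.
#' @param cold_start enable the cold-start branch (disabled for the plain
#'   tabular baselines).
#' @param live_td live temporal-difference mode.  `"refresh"` (default)
#'   lets live experience re-calibrate state-action pairs the replay-written
#'   map has already valued, while unexplored actions keep the zero value
#'   that drives cold-start exploration; `"off"` learns through replay
#'   alone; `"full"` is a plain filtered on-line Q-learner (used for the
#'   tabular-reduction analysis).
#' @return list of class `policy_config`.
#' @export
policy_config <- function(epsilon = 0.1, p_random = 0.5, theta = 0.5,
                          alpha = 0.3, gamma = 0.9, cold_start = TRUE,
                          live_td = c("refresh", "off", "full")) {
  live_td <- match.arg(live_td)
  stopifnot(epsilon >= 0, epsilon <= 1, p_random > 0, p_random < 1,
            theta > 0, theta < 1, alpha > 0, alpha <= 1, gamma > 0, gamma < 1)
  structure(list(epsilon = epsilon, p_random = p_random, theta = theta,
                 alpha = alpha, gamma = gamma, cold_start = cold_start,
                 live_td = live_td),
            class = "policy_config")
}

#' Binary place-cell filter
#'
#' @param v firing-rate vector.
#' @param theta threshold; a cell passes iff `v > theta` (strict).
#' @return integer 0/1 vector.
#' @export
cell_filter <- function(v, theta = 0.5) as.integer(v > theta)

#' Filtered state-action value
#'
#' Mean of the q-values of the filter-active cells for one action.
#'
#' @param pool a `place_cell_pool`.
#' @param F binary filter vector from [cell_filter()].
#' @param action action index 0..8.
#' @export
state_action_value <- function(pool, F, action) {
  active <- which(F == 1)
  if (length(active) == 0) stop("no active cell: state-action value undefined")
  mean(pool$q_values[active, action + 1])
}

#' Select an action from the filtered value function
#'
#' @param pool a `place_cell_pool`.
#' @param F binary filter vector (all zero = no active cell).
#' @param policy a [policy_config()].
#' @param last_action last executed action index, or `-1` at episode start.
#' @param r_step ordinary step reward (sets the unvalued-action prior
#'   `r_step / (1 - gamma)` of the guided greedy choice).
#' @return action index 0..8.
#' @export
select_action <- function(pool, F, policy = policy_config(),
                          last_action = -1L, r_step = -10) {
  active <- which(F == 1)
  qv <- if (length(active) == 0) numeric(9)
        else colMeans(pool$q_values[active, , drop = FALSE])
  .cpp_select_action(qv, length(active) > 0, unclass(policy),
                     as.integer(last_action), r_step)
}

#' Gated temporal-difference update
#'
#' Computes the TD error from the filtered value function and moves the
#' q-value of the taken action for every filter-active cell; cells outside
#' the filter are untouched.  A terminal transition bootstraps from 0.
#'
#' @param pool a `place_cell_pool`.
#' @param F_t filter at the current state.
#' @param action taken action index 0..8.
#' @param reward received reward.
#' @param F_next filter at the next state (ignored when `terminal`).
#' @param policy a [policy_config()].
#' @param terminal whether the transition ended the episode at the goal.
#' @return the updated pool (unchanged, with a warning, when no cell is
#'   active at the current state).
#' @export
td_update <- function(pool, F_t, action, reward, F_next,
                      policy = policy_config(), terminal = FALSE) {
  active <- which(F_t == 1)
  if (length(active) == 0) {
    warning("no active cell at current state: TD update skipped")
    return(pool)
  }
  q_t <- mean(pool$q_values[active, action + 1])
  target_next <- 0
  if (!terminal) {
    nxt <- which(F_next == 1)
    if (length(nxt) > 0)
      target_next <- max(colMeans(pool$q_values[nxt, , drop = FALSE]))
  }
  delta <- reward + policy$gamma * target_next - q_t
  pool$q_values[active, action + 1] <-
    pool$q_values[active, action + 1] + policy$alpha * delta
  pool
}
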
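test_that("only reward-associated sequences are eligible for replay", {
  m <- corridor_maze(4)
  tr <- record_trace(m, rep(2L, 3))
  low <- tr$sequence; low$outcome <- "low"
  expect_error(replay_sequence(tr$agent$pool, low), "high/virtual")
})

test_that("a single goal triple replayed with alpha = 1 writes the goal reward", {
  m <- corridor_maze(2)
  tr <- record_trace(m, 2L)
  pol <- policy_config(alpha = 1, theta = 0.7)
  net <- network_config(recruit_threshold = 0, position_only = TRUE)
  pool <- replay_sequence(tr$agent$pool, tr$sequence, net, pol)
  cell <- tr$sequence$cell_id[1] + 1L   # 0-based id of the start cell
  expect_equal(pool$q_values[cell, 3], 100)   # action E
})

test_that("one forward pass propagates the goal only one step back", {
  m <- corridor_maze(4)
  tr <- record_trace(m, rep(2L, 3))
  pol <- policy_config(alpha = 1, theta = 0.7)
  net <- network_config(recruit_threshold = 0, position_only = TRUE)
  pool <- replay_sequence(tr$agent$pool, tr$sequence, net, pol)
  ids <- tr$sequence$cell_id + 1L
  # penultimate state's value reflects the goal...
  expect_equal(pool$q_values[ids[3], 3], 100)
  # ...but the start state's does not yet carry any goal information
  expect_lt(pool$q_values[ids[1], 3], 0)
})

test_that("n forward passes reproduce the lambda = 1 closed form", {
  for (n_cells in c(3, 6, 10)) {
    m <- corridor_maze(n_cells)
    n_steps <- n_cells - 1
    tr <- record_trace(m, rep(2L, n_steps))
    pol <- policy_config(alpha = 1, theta = 0.7)
    net <- network_config(recruit_threshold = 0, position_only = TRUE)
    pool <- tr$agent$pool
    for (k in seq_len(n_steps)) pool <- replay_sequence(pool, tr$sequence, net, pol)
    got <- pool$q_values[tr$sequence$cell_id[1] + 1L, 3]
    closed <- corridor_closed_form(n_steps, 100, -10, 0.9)
    oracle <- corridor_value_iteration(n_steps, 100, -10, 0.9)[1]
    expect_equal(closed, oracle, tolerance = 1e-12)
    expect_equal(got, closed, tolerance = 1e-9)
  }
})

test_that("cells outside the replay filter are untouched and gated cells count", {
  m <- corridor_maze(5)
  tr <- record_trace(m, rep(2L, 4))
  pol <- policy_config(alpha = 0.3, theta = 0.7)
  net <- network_config(recruit_threshold = 0, position_only = TRUE)
  pool0 <- tr$agent$pool
  pool <- replay_sequence(pool0, tr$sequence, net, pol)
  on_path <- tr$sequence$cell_id + 1L
  off_path <- setdiff(seq_len(nrow(pool$W_S)), on_path)
  expect_identical(pool$q_values[off_path, ], pool0$q_values[off_path, ])
  expect_identical(pool$reactivations[off_path], pool0$reactivations[off_path])
  # one pass with single-cell fields gates exactly one cell per triple
  expect_equal(sum(pool$reactivations), length(tr$sequence$x))
  # three more passes: conservation of gated replay events
  for (k in 1:3) pool <- replay_sequence(pool, tr$sequence, net, pol)
  expect_equal(sum(pool$reactivations), 4L * length(tr$sequence$x))
})

test_that("consolidation replays nothing from an empty or low-only vault", {
  m <- corridor_maze(5)
  tr <- record_trace(m, rep(2L, 4))
  net <- network_config(recruit_threshold = 0, position_only = TRUE)
  pol <- policy_config(theta = 0.7)
  out <- consolidate(tr$agent$pool, memory_vault(), net = net, policy = pol)
  expect_identical(out$pool$q_values, tr$agent$pool$q_values)
  low <- tr$sequence; low$outcome <- "low"
  v <- vault_store(memory_vault(), low)
  out2 <- consolidate(tr$agent$pool, v, net = net, policy = pol)
  expect_identical(out2$pool$q_values, tr$agent$pool$q_values)
  expect_equal(sum(out2$pool$reactivations), 0L)
})

test_that("consolidating one stored corridor reaches the value-iteration fixed point", {
  m <- corridor_maze(6)
  tr <- record_trace(m, rep(2L, 5))
  net <- network_config(recruit_threshold = 0, position_only = TRUE)
  pol <- policy_config(alpha = 1, theta = 0.7)
  v <- vault_store(memory_vault(), tr$sequence)
  out <- consolidate(tr$agent$pool, v,
                     schedule = replay_schedule(passes_per_sequence = 5L),
                     net = net, policy = pol)
  oracle <- corridor_value_iteration(5, 100, -10, 0.9)
  for (j in 1:5)
    expect_equal(out$pool$q_values[tr$sequence$cell_id[j] + 1L, 3],
                 oracle[j], tolerance = 1e-9)
})

test_that("replaying a virtual sequence raises values along its low prefix", {
  m <- grid_maze(7L, 7L, start = c(0L, 3L), goal = c(6L, 3L), p_intended = 1)
  tr <- record_trace(m, rep(2L, 6))
  m2 <- m; m2$start <- c(0L, 0L)
  tr2 <- record_trace(m2, c(1L, 1L, 1L, 0L, 0L), pool = tr$agent$pool)
  low <- tr2$sequence; low$outcome <- "low"
  pick <- select_intersection(find_intersections(low, tr$sequence))
  vs <- construct_virtual(low, tr$sequence, pick, r_step = -10)
  net <- network_config(recruit_threshold = 0, position_only = TRUE)
  pol <- policy_config(alpha = 1, theta = 0.7)
  pool <- tr$agent$pool
  prefix_cells <- low$cell_id[seq_len(pick$low_index - 1)] + 1L
  expect_true(all(pool$q_values[prefix_cells, ] == 0))
  for (k in seq_len(length(vs$x))) pool <- replay_sequence(pool, vs, net, pol)
  # the prefix cells never saw the goal live, yet now carry goal information
  vals <- apply(pool$q_values[prefix_cells, , drop = FALSE], 1, max)
  expect_true(all(vals > -100))
  expect_true(any(pool$q_values[prefix_cells, ] != 0))
})

test_that("forgetting erases values of cells replay no longer reactivates", {
  m <- corridor_maze(5)
  tr <- record_trace(m, rep(2L, 4))
  net <- network_config(recruit_threshold = 0, position_only = TRUE)
  pol <- policy_config(alpha = 1, theta = 0.7)
  v <- vault_store(memory_vault(), tr$sequence)
  sched <- replay_schedule(passes_per_sequence = 2L, forget_after = 5L)
  out <- consolidate(tr$agent$pool, v, sched, net, pol, round = 1L)
  expect_true(any(out$pool$q_values != 0))
  # far in the future, with the vault emptied, the trace is forgotten
  out2 <- consolidate(out$pool, memory_vault(), sched, net, pol, round = 50L)
  expect_true(all(out2$pool$q_values == 0))
})
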
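test_that("the state encoder exposes position, heading and local occupancy", {
  m <- make_maze("open")
  expect_equal(unname(encode_state(m, c(0, 0), 8L)), c(0, 0, 1, 0, 5 / 8))
  expect_equal(unname(encode_state(m, c(10, 10), 0L)), c(10, 10, 0, 1, 0))
  # injective in the position components
  cells <- expand.grid(x = 0:19, y = 0:19)
  keys <- apply(cells, 1, function(s)
    paste(encode_state(m, s, 8L)[1:2], collapse = "_"))
  expect_equal(anyDuplicated(keys), 0L)
  # position-only mode zeroes the non-positional channels
  expect_equal(unname(encode_state(m, c(3, 4), 0L, position_only = TRUE)),
               c(3, 4, 0, 0, 0))
})

test_that("activation is a channel-gated Gaussian of the joint distance", {
  pool <- place_cell_pool(W_S = rbind(c(2, 2, 0, 0, 0)), W_M = 0)
  cfg <- network_config()
  # zero distance fires at 1
  expect_equal(activate(pool, c(2, 2, 0, 0, 0), 0, cfg), 1)
  # unit state distance, matched memory channel: direct evaluation of the
  # kernel exp(-(s_gate * 1)^2 / (2 sigma^2))
  expect_equal(activate(pool, c(3, 2, 0, 0, 0), 0, cfg),
               exp(-(0.6 * 1)^2 / (2 * 0.7^2)))
  # memory channel term adds m_gate * |dM|
  expect_equal(activate(pool, c(2, 2, 0, 0, 0), 1, cfg),
               exp(-(0.4 * 1)^2 / (2 * 0.7^2)))
  # strictly decreasing in state distance, always in (0, 1]
  d <- seq(0, 10, by = 0.5)
  v <- vapply(d, function(k) activate(pool, c(2 + k, 2, 0, 0, 0), 0, cfg),
              numeric(1))
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 1))
})

test_that("winner-take-all picks the maximum with lowest-index ties", {
  expect_equal(winner_cell(c(0.2, 0.9, 0.1)), 2L)
  expect_equal(winner_cell(c(0.5, 0.5)), 1L)
  expect_equal(winner_cell(0.3), 1L)
})

test_that("weight updates contract toward the input by (1 - delta)", {
  pool <- place_cell_pool(W_S = rbind(rep(0, 5)), W_M = 0)
  S <- c(1, 0, 0, 0, 0)
  full <- update_weights(pool, 1, S, 1, network_config(delta = 1))
  expect_equal(unname(full$W_S[1, ]), S)
  expect_equal(full$W_M[1], 1)
  half <- update_weights(pool, 1, S, 0, network_config(delta = 0.5))
  expect_equal(unname(half$W_S[1, ]), c(0.5, 0, 0, 0, 0))
  # contraction property over random inputs
  set.seed(3)
  for (i in 1:10) {
    W0 <- rnorm(5); S1 <- rnorm(5); delta <- runif(1)
    p <- place_cell_pool(W_S = rbind(W0), W_M = 0)
    p1 <- update_weights(p, 1, S1, 0, network_config(delta = delta))
    expect_equal(sqrt(sum((p1$W_S[1, ] - S1)^2)),
                 (1 - delta) * sqrt(sum((W0 - S1)^2)))
  }
})

test_that("observe recruits on novelty and otherwise adapts the winner", {
  cfg <- network_config()
  o <- observe(place_cell_pool(), c(1, 1, 0, 0, 0), 0, cfg)
  expect_equal(nrow(o$pool$W_S), 1L)
  expect_true(o$recruited)
  expect_equal(o$rates, 1)
  # repeated presentation of one input: no growth, weights converge
  pool <- o$pool
  for (i in 1:20) {
    o <- observe(pool, c(1, 1, 0, 0, 0), 0, cfg)
    pool <- o$pool
  }
  expect_equal(nrow(pool$W_S), 1L)
  expect_equal(unname(pool$W_S[1, ]), c(1, 1, 0, 0, 0))
  # a distant input recruits a second cell
  o <- observe(pool, c(10, 10, 0, 0, 0), 0, cfg)
  expect_true(o$recruited)
  expect_equal(nrow(o$pool$W_S), 2L)
})

test_that("a full grid sweep self-organizes a bounded covering map", {
  m <- make_maze("open")
  cfg <- network_config()
  pool <- place_cell_pool()
  for (y in 0:19) for (x in 0:19) {
    o <- observe(pool, encode_state(m, c(x, y), 8L), 0, cfg)
    pool <- o$pool
  }
  expect_lte(nrow(pool$W_S), 400L)
  # every grid cell now has a winner above the recruitment threshold
  for (y in seq(0, 19, by = 3)) for (x in seq(0, 19, by = 3)) {
    v <- activate(pool, encode_state(m, c(x, y), 8L), 0, cfg)
    expect_gt(max(v), cfg$recruit_threshold)
  }
})

test_that("recruitment respects max_cells and warns at saturation", {
  cfg <- network_config(max_cells = 3L)
  pool <- place_cell_pool()
  for (x in c(0, 10, 20)) {
    o <- observe(pool, c(x, 0, 0, 0, 0), 0, cfg)
    pool <- o$pool
  }
  expect_equal(nrow(pool$W_S), 3L)
  expect_warning(observe(pool, c(30, 0, 0, 0, 0), 0, cfg), "max_cells")
})

test_that("the cognitive-map dump restores the pool bit-exactly", {
  set.seed(11)
  pool <- place_cell_pool(W_S = matrix(rnorm(15), 3, 5), W_M = runif(3),
                          q_values = matrix(rnorm(27), 3, 9),
                          reactivations = c(5L, 0L, 2L),
                          last_reactivated = c(3L, -1L, 9L))
  f <- tempfile(fileext = ".json")
  write_cognitive_map(pool, f)
  pool2 <- read_cognitive_map(f)
  expect_identical(pool2$W_S, unname(pool$W_S))
  expect_identical(pool2$W_M, pool$W_M)
  expect_identical(pool2$q_values, unname(pool$q_values))
  expect_identical(pool2$reactivations, pool$reactivations)
  expect_identical(pool2$last_reactivated, pool$last_reactivated)
})
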
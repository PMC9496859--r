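test_that("stay is deterministic and earns the step penalty", {
  m <- make_maze("open")
  set.seed(1)
  for (i in 1:20) {
    o <- maze_step(m, c(5, 5), 8)
    expect_identical(o$next_state, c(5L, 5L))
    expect_identical(o$executed_action, 8L)
    expect_equal(o$reward, -10)
  }
})

test_that("intended action executes 80% of the time, deviations are compass-adjacent", {
  m <- make_maze("open")
  set.seed(42)
  executed <- replicate(10000, maze_step(m, c(10, 10), 0)$executed_action)
  expect_true(all(executed %in% c(0L, 1L, 7L)))
  p_hat <- mean(executed == 0L)
  expect_gte(p_hat, 0.79)
  expect_lte(p_hat, 0.81)
  # binomial test against p = 0.8 not rejected at alpha = 0.01
  expect_gt(binom.test(sum(executed == 0L), 10000, p = 0.8)$p.value, 0.01)
  # the two deviations are split evenly
  expect_gt(binom.test(sum(executed == 1L),
                       sum(executed != 0L), p = 0.5)$p.value, 0.01)
})

test_that("obstacle and boundary hits keep the position and cost the penalty", {
  m <- grid_maze(6L, 6L, obstacles = cbind(3L, 2L), start = c(0L, 0L),
                 goal = c(5L, 5L), p_intended = 1)
  o <- maze_step(m, c(2, 2), 2)  # east into the obstacle
  expect_identical(o$next_state, c(2L, 2L))
  expect_true(o$hit_obstacle)
  expect_equal(o$reward, -100)
  o <- maze_step(m, c(0, 0), 4)  # south off-grid
  expect_identical(o$next_state, c(0L, 0L))
  expect_true(o$hit_obstacle)
  expect_equal(o$reward, -100)
})

test_that("reward constants follow the active scheme", {
  expect_equal(unname(reward_values("standard")), c(-100, 100, -10))
  expect_equal(unname(reward_values("amplified")), c(-500, 1000, -10))
  m <- make_maze("open", reward_scheme = "amplified")
  expect_equal(reward_of(m, "goal"), 1000)
  expect_equal(reward_of(m, "obstacle"), -500)
  expect_equal(reward_of(m, "step"), -10)
})

test_that("lidar reports radius-1 occupancy in compass order", {
  m <- make_maze("open")
  expect_equal(unname(lidar_scan(m, c(10, 10))), rep(0L, 8))
  # corner: N, NE, E free; SE, S, SW, W, NW off-grid
  expect_equal(sum(lidar_scan(m, c(0, 0))), 5L)
  mo <- grid_maze(7L, 7L, obstacles = cbind(4L, 3L), start = c(0L, 0L),
                  goal = c(6L, 6L))
  sc <- lidar_scan(mo, c(3, 3))
  expect_equal(unname(sc[c("N", "NE", "SE", "S", "SW", "W", "NW")]), rep(0L, 7))
  expect_equal(unname(sc["E"]), 1L)
})

test_that("every maze kind is solvable over many seeds", {
  for (kind in c("open", "blocks", "u_shape", "complex"))
    for (s in 1:25)
      expect_gte(bfs_distance(make_maze(kind, seed = s)), 0)
})

test_that("maze construction enforces the validity invariants", {
  expect_error(grid_maze(5L, 5L, start = c(5L, 0L), goal = c(1L, 1L)),
               "inside the grid")
  expect_error(grid_maze(5L, 5L, obstacles = cbind(1L, 1L),
                         start = c(1L, 1L), goal = c(4L, 4L)), "obstacle")
  wall <- cbind(2L, 0L:4L)  # full wall splits the arena
  expect_error(grid_maze(5L, 5L, obstacles = wall, start = c(0L, 0L),
                         goal = c(4L, 4L)), "reachable")
})

test_that("the open maze is empty and the complex maze starts at (2,2)", {
  expect_equal(nrow(make_maze("open")$obstacles), 0L)
  for (s in 1:5)
    expect_identical(make_maze("complex", seed = s)$start, c(2L, 2L))
})

test_that("removing the U obstacle strictly shortens the start-goal path", {
  mu <- make_maze("u_shape")
  mo <- grid_maze(20L, 20L, start = mu$start, goal = mu$goal)
  expect_gt(bfs_distance(mu), bfs_distance(mo))
})

test_that("trajectories never enter obstacles and only emit scheme rewards", {
  m <- make_maze("blocks", reward_scheme = "standard")
  r <- run_experiment(m, "replay", episodes = 30, seed = 5, keep_paths = TRUE,
                      window = 10, n_windows = 3)
  blocked <- paste(m$obstacles[, 1], m$obstacles[, 2])
  for (p in r$paths) {
    expect_false(any(paste(p$x, p$y) %in% blocked))
    expect_true(all(p$reward %in% c(-100, 100, -10)))
  }
})

test_that("maze YAML spec files round-trip exactly", {
  m <- make_maze("u_shape", reward_scheme = "amplified")
  f <- tempfile(fileext = ".yaml")
  write_maze_yaml(m, f)
  m2 <- read_maze_yaml(f)
  expect_equal(m2$width, m$width)
  expect_equal(m2$start, m$start)
  expect_equal(m2$goal, m$goal)
  expect_equal(m2$reward_scheme, m$reward_scheme)
  expect_setequal(paste(m2$obstacles[, 1], m2$obstacles[, 2]),
                  paste(m$obstacles[, 1], m$obstacles[, 2]))
})

test_that("plain-text maze art imports with the top row as highest y", {
  m <- maze_from_text(c("G..",
                        "##.",
                        "S.."))
  expect_identical(m$start, c(0L, 0L))
  expect_identical(m$goal, c(0L, 2L))
  expect_true(is_blocked(m, 0, 1))
  expect_true(is_blocked(m, 1, 1))
  expect_false(is_blocked(m, 2, 1))
  expect_gte(bfs_distance(m), 0)
})

test_that("junction classification follows 4-neighbour degree", {
  m <- maze_from_text(c("S....",
                        ".###.",
                        ".#G#.",
                        ".#.#.",
                        "....."))
  jm <- junction_map(m)
  corner <- jm[jm$x == 0 & jm$y == 4, ]
  expect_equal(corner$class, "corridor")    # degree 2
  side <- jm[jm$x == 2 & jm$y == 4, ]
  expect_equal(side$class, "corridor")      # wall below: degree 2
  inner <- jm[jm$x == 2 & jm$y == 2, ]      # goal pocket: only south open
  expect_equal(inner$class, "dead_end")
})

test_that("the shipped U-trap art fixture loads as a solvable maze", {
  f <- system.file("extdata", "u_trap.txt", package = "replaynav")
  m <- maze_from_text(readLines(f))
  expect_identical(m$goal, c(4L, 3L))
  expect_equal(bfs_distance(m), 4)
  # the goal pocket opens toward the start
  expect_true(is_blocked(m, 7, 3))
  expect_false(is_blocked(m, 1, 3))
})
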
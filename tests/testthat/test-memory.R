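test_that("episodes classify by goal arrival or accumulated failure", {
  m <- open_maze5()
  high <- trajectory_sequence(x = c(3, 4), y = c(4, 4), action = c(2, 2),
                              cell_id = c(1, 2), reward = c(-10, 100))
  expect_equal(classify_episode(high, m), "high")
  low <- trajectory_sequence(x = rep(c(1, 2), 150), y = rep(0, 300),
                             action = rep(c(2, 6), 150), cell_id = rep(1, 300),
                             reward = rep(-10, 300))
  expect_equal(classify_episode(low, m), "low")
  mid <- trajectory_sequence(x = c(1, 2), y = c(0, 0), action = c(2, 2),
                             cell_id = c(1, 2), reward = c(-10, -10))
  expect_error(classify_episode(mid, m), "not terminated")
  empty <- low; empty$x <- integer(0)
  expect_error(classify_episode(empty, m), "empty")
})

test_that("sequences reject non-adjacent consecutive states", {
  expect_error(trajectory_sequence(x = c(0, 3), y = c(0, 0), action = c(2, 2),
                                   cell_id = c(1, 2), reward = c(-10, -10)),
               "adjacent")
})

test_that("the vault stores FIFO within capacity and strips bookkeeping on read", {
  v <- memory_vault(capacity_high = 2L, capacity_low = 3L)
  mk <- function(i, outcome = "low")
    trajectory_sequence(x = i, y = 0, action = 2, cell_id = i,
                        reward = -10, outcome = outcome)
  for (i in 1:5) v <- vault_store(v, mk(i))
  expect_length(v$low, 3L)
  expect_equal(vapply(v$low, function(s) s$x, integer(1)), 3:5)  # oldest gone
  tri <- sequence_triples(v$low[[1]])
  expect_named(tri, c("x", "y", "action", "reward"))
  v <- vault_store(v, mk(9, "high"))
  expect_length(v$high, 1L)
})

test_that("stored sequences keep only the max_stored_length tail", {
  v <- memory_vault(max_stored_length = 10L)
  long <- trajectory_sequence(x = 0:29, y = rep(0, 30), action = rep(2, 30),
                              cell_id = 1:30, reward = rep(-10, 30))
  v <- vault_store(v, long)
  expect_length(v$low[[1]]$x, 10L)
  expect_equal(v$low[[1]]$x, 20:29)
})

test_that("intersections pair the last low index with the first high index", {
  mk <- function(ids) trajectory_sequence(x = seq_along(ids), y = rep(1, length(ids)),
                                          action = rep(2, length(ids)),
                                          cell_id = ids,
                                          reward = rep(-10, length(ids)))
  # identical single-cell sequences
  i1 <- find_intersections(mk(7), mk(7))
  expect_equal(i1, data.frame(cell_id = 7L, low_index = 1L, high_index = 1L))
  # disjoint
  expect_equal(nrow(find_intersections(mk(c(1, 2)), mk(c(3, 4)))), 0L)
  # repeated cell in the low sequence: last occurrence wins
  i3 <- find_intersections(mk(c(1, 2, 3, 2)), mk(c(5, 2, 6)))
  expect_equal(i3, data.frame(cell_id = 2L, low_index = 4L, high_index = 2L))
  # brute-force cross-check on random id sequences
  set.seed(21)
  for (rep in 1:20) {
    lo <- sample(1:8, 12, replace = TRUE)
    hi <- sample(1:8, 9, replace = TRUE)
    got <- find_intersections(mk(lo), mk(hi))
    ids <- sort(intersect(lo, hi))
    expect_setequal(got$cell_id, ids)
    for (id in ids) {
      expect_equal(got$low_index[got$cell_id == id], max(which(lo == id)))
      expect_equal(got$high_index[got$cell_id == id], min(which(hi == id)))
    }
  }
})

test_that("splice selection maximizes the low prefix with stated tie-breaks", {
  cand <- data.frame(cell_id = c(4L, 9L, 1L), low_index = c(2L, 7L, 4L),
                     high_index = c(1L, 5L, 2L))
  expect_equal(select_intersection(cand)$cell_id, 9L)
  tie <- data.frame(cell_id = c(4L, 9L), low_index = c(5L, 5L),
                    high_index = c(8L, 2L))      # longer high suffix wins
  expect_equal(select_intersection(tie)$cell_id, 9L)
  tie2 <- data.frame(cell_id = c(9L, 4L), low_index = c(5L, 5L),
                     high_index = c(2L, 2L))     # lowest cell id wins
  expect_equal(select_intersection(tie2)$cell_id, 4L)
  expect_error(select_intersection(cand[0, ]), "no intersection")
})

test_that("virtual paths splice a low prefix onto the goal-reaching suffix", {
  m <- grid_maze(7L, 7L, start = c(0L, 3L), goal = c(6L, 3L), p_intended = 1)
  # high path: straight east along y = 3, recorded on a lattice pool
  tr <- record_trace(m, rep(2L, 6))
  high <- tr$sequence
  expect_equal(high$outcome, "high")
  # low path: north-east to (3,3) (crossing the high path), then north away
  m2 <- m; m2$start <- c(0L, 0L)
  tr2 <- record_trace(m2, c(1L, 1L, 1L, 0L, 0L), pool = tr$agent$pool)
  low <- tr2$sequence
  low$outcome <- "low"
  inter <- find_intersections(low, high)
  expect_gt(nrow(inter), 0)
  pick <- select_intersection(inter)
  vs <- construct_virtual(low, high, pick, r_step = -10)
  expect_equal(vs$outcome, "virtual")
  # ends at the goal reward and is grid-valid
  expect_equal(tail(vs$reward, 1), 100)
  expect_true(all(pmax(abs(diff(vs$x)), abs(diff(vs$y))) <= 1))
  # splice cell appears exactly once
  expect_equal(sum(vs$cell_id == pick$cell_id), 1L)
  # triple count at the junction: low prefix + high suffix
  expect_length(vs$x, pick$low_index + (length(high$x) - pick$high_index))
})

test_that("degenerate splice of a sequence with itself reproduces it", {
  m <- corridor_maze(5)
  tr <- record_trace(m, rep(2L, 4))
  high <- tr$sequence
  low <- high; low$outcome <- "low"
  inter <- find_intersections(low, high)
  pick <- select_intersection(inter)
  vs <- construct_virtual(low, high, pick, r_step = -10)
  expect_equal(vs$x, high$x)
  expect_equal(vs$y, high$y)
  expect_equal(tail(vs$reward, 1), 100)
})

test_that("refresh constructs each crossing pair once and deduplicates", {
  m <- grid_maze(7L, 7L, start = c(0L, 3L), goal = c(6L, 3L), p_intended = 1)
  tr <- record_trace(m, rep(2L, 6))
  m2 <- m; m2$start <- c(0L, 0L)
  tr2 <- record_trace(m2, c(1L, 1L, 1L, 0L, 0L), pool = tr$agent$pool)
  low <- tr2$sequence; low$outcome <- "low"
  v <- memory_vault()
  # no high stored: nothing happens
  v1 <- refresh_virtual(vault_store(v, low))
  expect_length(v1$virtual, 0L)
  v <- vault_store(vault_store(v, low), tr$sequence)
  v2 <- refresh_virtual(v)
  expect_length(v2$virtual, 1L)
  expect_equal(attr(v2, "constructed"), 1L)
  # calling again neither re-tries the pair nor duplicates the result
  v3 <- refresh_virtual(v2)
  expect_length(v3$virtual, 1L)
  expect_equal(attr(v3, "constructed"), 0L)
  # no vault member is a high prefix that fails to reach the goal
  for (s in c(v3$virtual, v3$high))
    expect_equal(tail(s$reward, 1), 100)
})

test_that("vault JSON-lines serialization round-trips the stored sequences", {
  m <- corridor_maze(6)
  tr <- record_trace(m, rep(2L, 5))
  v <- vault_store(memory_vault(), tr$sequence)
  f <- tempfile(fileext = ".jsonl")
  write_vault_jsonl(v, f)
  v2 <- read_vault_jsonl(f)
  expect_length(v2$high, 1L)
  s1 <- v$high[[1]]; s2 <- v2$high[[1]]
  expect_identical(s2$x, s1$x)
  expect_identical(s2$action, s1$action)
  expect_identical(s2$reward, s1$reward)
  expect_identical(unname(s2$state_vec), unname(s1$state_vec))
  expect_identical(s2$outcome, s1$outcome)
})
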
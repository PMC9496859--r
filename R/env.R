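#' Grid-world water-maze environments
#'
#' A `grid_maze` is a discrete 2-D arena with impassable obstacle cells, a
#' start cell and a hidden goal ("survival platform").  Coordinates are
#' 0-based `(x, y)` with `x` rightward and `y` upward.  The agent moves in the
#' eight compass directions or stays put; an intended movement is executed
#' with probability `p_intended` (0.8 by default) and otherwise deviates to
#' one of the two compass-adjacent directions with equal probability.  Moves
#' into an obstacle or off the grid leave the position unchanged and incur
#' the obstacle penalty.
#'
#' @param width,height arena size in cells.
#' @param obstacles integer matrix with columns `x`, `y` (0-based), possibly
#'   zero rows.
#' @param start,goal length-2 integer vectors `(x, y)`.
#' @param reward_scheme `"standard"` (-100 obstacle / +100 goal / -10 step) or
#'   `"amplified"` (-500 / +1000 / -10).
#' @param p_intended probability that the intended movement is executed.
#' @param rng_seed seed recorded with the maze (informational).
#' @return an object of class `grid_maze`.
#' @export
grid_maze <- function(width = 20L, height = 20L,
                      obstacles = matrix(integer(), ncol = 2),
                      start = c(2L, 2L), goal = c(17L, 17L),
                      reward_scheme = c("standard", "amplified"),
                      p_intended = 0.8, rng_seed = NA_integer_) {
  reward_scheme <- match.arg(reward_scheme)
  obstacles <- matrix(as.integer(obstacles), ncol = 2)
  stopifnot(width >= 2, height >= 1, length(start) == 2, length(goal) == 2,
            p_intended > 0, p_intended <= 1)
  world <- structure(list(
    width = as.integer(width), height = as.integer(height),
    obstacles = obstacles,
    start = as.integer(start), goal = as.integer(goal),
    reward_scheme = reward_scheme,
    rewards = reward_values(reward_scheme),
    p_intended = p_intended,
    rng_seed = rng_seed), class = "grid_maze")
  in_grid <- function(p) all(p >= 0) && p[1] < width && p[2] < height
  if (!in_grid(start) || !in_grid(goal))
    stop("start and goal must lie inside the grid")
  key <- paste(obstacles[, 1], obstacles[, 2])
  if (paste(start[1], start[2]) %in% key || paste(goal[1], goal[2]) %in% key)
    stop("start and goal must not be obstacle cells")
  if (bfs_distance(world, start, goal) < 0)
    stop("goal is not reachable from start")
  world
}

#' @export
print.grid_maze <- function(x, ...) {
  cat(sprintf("<grid_maze> %dx%d, %d obstacle cells, start (%d,%d), goal (%d,%d), %s rewards\n",
              x$width, x$height, nrow(x$obstacles), x$start[1], x$start[2],
              x$goal[1], x$goal[2], x$reward_scheme))
  invisible(x)
}

#' Reward constants of a scheme
#'
#' @param scheme `"standard"` or `"amplified"`.
#' @return named numeric vector `c(obstacle, goal, step)`.
#' @export
reward_values <- function(scheme = c("standard", "amplified")) {
  scheme <- match.arg(scheme)
  if (scheme == "standard") c(obstacle = -100, goal = 100, step = -10)
  else c(obstacle = -500, goal = 1000, step = -10)
}

#' Reward for an outcome context
#'
#' @param world a `grid_maze`.
#' @param context one of `"obstacle"`, `"goal"`, `"step"`.
#' @export
reward_of <- function(world, context = c("step", "obstacle", "goal")) {
  context <- match.arg(context)
  unname(world$rewards[switch(context, obstacle = 1L, goal = 2L, step = 3L)])
}

#' Execute one (stochastic) environment step
#'
#' @param world a `grid_maze`.
#' @param state length-2 integer `(x, y)`, in-grid and not an obstacle.
#' @param action action index 0..8 (0=N, 1=NE, 2=E, 3=SE, 4=S, 5=SW, 6=W,
#'   7=NW, 8=stay).
#' @return list with `next_state`, `reward`, `hit_obstacle`, `reached_goal`,
#'   `executed_action`.
#' @export
maze_step <- function(world, state, action) {
  stopifnot(inherits(world, "grid_maze"))
  if (action < 0 || action > 8) stop("action index must be in 0..8")
  if (is_blocked(world, state[1], state[2]))
    stop("state must be a free in-grid cell")
  .cpp_step(unclass(world), state[1], state[2], as.integer(action))
}

#' Radius-1 lidar occupancy scan
#'
#' Returns occupancy of the 8 neighbouring cells in compass order
#' (N, NE, E, SE, S, SW, W, NW); off-grid counts as occupied.
#'
#' @inheritParams maze_step
#' @export
lidar_scan <- function(world, state) {
  stopifnot(inherits(world, "grid_maze"))
  v <- .cpp_lidar(unclass(world), state[1], state[2])
  names(v) <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  v
}

is_blocked <- function(world, x, y) {
  if (x < 0 || y < 0 || x >= world$width || y >= world$height) return(TRUE)
  nrow(world$obstacles) > 0 &&
    any(world$obstacles[, 1] == x & world$obstacles[, 2] == y)
}

#' Breadth-first-search distance between two free cells
#'
#' 8-connected BFS over free cells; `-1` if unreachable.
#' @param world a `grid_maze`.
#' @param from,to length-2 integer cells.
#' @export
bfs_distance <- function(world, from = world$start, to = world$goal) {
  .cpp_bfs_distance(unclass(world), as.integer(from), as.integer(to))
}

#' Build one of the water-maze task environments
#'
#' `open` is the bare 20x20 Morris-water-maze arena; `blocks` places
#' rectangular obstacles between start and goal; `u_shape` places a U-shaped
#' trap whose opening faces the start; `complex` is a seeded
#' recursive-division corridor maze with start at (2,2) and the goal in the
#' upper-right region.  All mazes are checked for solvability; the complex
#' generator retries with a perturbed seed a bounded number of times.
#'
#' @param kind maze family.
#' @param seed integer seed for the generator (`complex` only).
#' @param reward_scheme passed to [grid_maze()].
#' @param p_intended passed to [grid_maze()].
#' @return a `grid_maze`.
#' @export
make_maze <- function(kind = c("open", "blocks", "u_shape", "complex"),
                      seed = 1L, reward_scheme = "standard",
                      p_intended = 0.8) {
  kind <- match.arg(kind)
  ob <- switch(kind,
    open = matrix(integer(), ncol = 2),
    blocks = rbind(rect_cells(6, 5, 8, 9), rect_cells(11, 11, 13, 15)),
    u_shape = u_obstacle(),
    complex = NULL)
  if (kind != "complex") {
    w <- grid_maze(20L, 20L, obstacles = ob,
                   start = if (kind == "u_shape") c(2L, 10L) else c(2L, 2L),
                   goal = if (kind == "u_shape") c(17L, 10L) else c(17L, 17L),
                   reward_scheme = reward_scheme, p_intended = p_intended,
                   rng_seed = seed)
    w$kind <- kind
    return(w)
  }
  for (try in 0:19) {
    ob <- division_maze(20L, 20L, seed + try)
    free <- setdiff_cells(20L, 20L, ob)
    start <- c(2L, 2L)
    ob <- ob[!(ob[, 1] %in% 1:3 & ob[, 2] %in% 1:3), , drop = FALSE]
    goal <- nearest_free(free_cells(20L, 20L, ob), c(17L, 17L))
    w <- tryCatch(
      grid_maze(20L, 20L, obstacles = ob, start = start, goal = goal,
                reward_scheme = reward_scheme, p_intended = p_intended,
                rng_seed = seed + try),
      error = function(e) NULL)
    if (!is.null(w)) { w$kind <- "complex"; return(w) }
  }
  stop("failed to generate a solvable complex maze")
}

rect_cells <- function(x0, y0, x1, y1) {
  as.matrix(expand.grid(x = x0:x1, y = y0:y1))
}

u_obstacle <- function() {
  # opening faces the start on the left: walls right/top/bottom; tall
  # enough that skirting around it costs strictly more than the direct line
  rbind(rect_cells(12, 4, 12, 16),   # back wall
        rect_cells(7, 16, 12, 16),   # top arm
        rect_cells(7, 4, 12, 4))     # bottom arm
}

free_cells <- function(width, height, obstacles) {
  all <- as.matrix(expand.grid(x = 0:(width - 1), y = 0:(height - 1)))
  if (nrow(obstacles) == 0) return(all)
  key <- paste(all[, 1], all[, 2]) %in% paste(obstacles[, 1], obstacles[, 2])
  all[!key, , drop = FALSE]
}

setdiff_cells <- free_cells

nearest_free <- function(free, target) {
  d <- pmax(abs(free[, 1] - target[1]), abs(free[, 2] - target[2]))
  as.integer(free[which.min(d), ])
}

# seeded recursive-division corridor maze; returns obstacle matrix
division_maze <- function(width, height, seed) {
  rng <- local_rng(seed)
  obst <- matrix(FALSE, nrow = width, ncol = height)
  divide <- function(x0, y0, x1, y1) {
    wdt <- x1 - x0 + 1; hgt <- y1 - y0 + 1
    if (wdt < 5 && hgt < 5) return()
    vertical <- if (wdt > hgt) TRUE else if (hgt > wdt) FALSE else rng() < 0.5
    if (vertical && wdt >= 5) {
      wx <- x0 + 2 + floor(rng() * (wdt - 4))
      gap <- y0 + floor(rng() * hgt)
      for (y in y0:y1) if (y != gap) obst[wx + 1, y + 1] <<- TRUE
      divide(x0, y0, wx - 1, y1); divide(wx + 1, y0, x1, y1)
    } else if (!vertical && hgt >= 5) {
      wy <- y0 + 2 + floor(rng() * (hgt - 4))
      gap <- x0 + floor(rng() * wdt)
      for (x in x0:x1) if (x != gap) obst[x + 1, wy + 1] <<- TRUE
      divide(x0, y0, x1, wy - 1); divide(x0, wy + 1, x1, y1)
    }
  }
  divide(0L, 0L, width - 1L, height - 1L)
  which(obst, arr.ind = TRUE) - 1L
}

# small linear-congruential stream so maze generation does not disturb
# the global RNG used by the simulation
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- state + 2147483646
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

#' Move start and goal of a maze
#'
#' Used for the relocated-platform experiments: the arena and reward scheme
#' are kept, start and platform are moved (and checked again for validity).
#'
#' @param world a `grid_maze`.
#' @param start,goal new cells.
#' @export
maze_relocate <- function(world, start = c(17L, 2L), goal = c(2L, 17L)) {
  grid_maze(world$width, world$height, obstacles = world$obstacles,
            start = start, goal = goal, reward_scheme = world$reward_scheme,
            p_intended = world$p_intended, rng_seed = world$rng_seed)
}

#' Read or write a maze spec as YAML
#'
#' The YAML holds width, height, the obstacle cell list, start, goal and the
#' reward scheme; a written file read back reproduces the maze exactly.
#'
#' @param world a `grid_maze`.
#' @param path file path.
#' @export
write_maze_yaml <- function(world, path) {
  yaml::write_yaml(list(
    width = world$width, height = world$height,
    obstacles = apply(world$obstacles, 1, function(r) as.list(as.integer(r)),
                      simplify = FALSE),
    start = as.list(world$start), goal = as.list(world$goal),
    reward_scheme = world$reward_scheme,
    p_intended = world$p_intended), path)
  invisible(path)
}

#' @rdname write_maze_yaml
#' @export
read_maze_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ob <- if (length(y$obstacles) == 0) matrix(integer(), ncol = 2)
        else do.call(rbind, lapply(y$obstacles, unlist))
  grid_maze(y$width, y$height, obstacles = ob,
            start = unlist(y$start), goal = unlist(y$goal),
            reward_scheme = y$reward_scheme, p_intended = y$p_intended)
}

#' Import a maze from plain-text art
#'
#' Rows of `#` (obstacle), `.` (free), `S` (start) and `G` (goal); the first
#' text row is the top of the maze (largest `y`).
#'
#' @param text character vector of rows, or a single string with newlines.
#' @param reward_scheme,p_intended passed to [grid_maze()].
#' @export
maze_from_text <- function(text, reward_scheme = "standard", p_intended = 0.8) {
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n")[[1]]
  text <- text[nzchar(trimws(text))]
  rows <- lapply(text, function(r) strsplit(trimws(r), "")[[1]])
  height <- length(rows); width <- length(rows[[1]])
  ob <- NULL; start <- goal <- NULL
  for (i in seq_len(height)) {
    y <- height - i
    for (x in seq_len(width) - 1) {
      ch <- rows[[i]][x + 1]
      if (ch == "#") ob <- rbind(ob, c(x, y))
      else if (ch == "S") start <- c(x, y)
      else if (ch == "G") goal <- c(x, y)
    }
  }
  if (is.null(ob)) ob <- matrix(integer(), ncol = 2)
  grid_maze(width, height, obstacles = ob, start = start, goal = goal,
            reward_scheme = reward_scheme, p_intended = p_intended)
}

#' Classify free cells of a maze as junctions, corridors or dead ends
#'
#' Degree is counted in the 4-neighbour free-cell adjacency graph: degree
#' >= 3 is a junction, exactly 2 a corridor, <= 1 a dead end.
#'
#' @param world a `grid_maze`.
#' @return data frame with columns `x`, `y`, `degree`, `class`.
#' @export
junction_map <- function(world) {
  free <- free_cells(world$width, world$height, world$obstacles)
  deg <- vapply(seq_len(nrow(free)), function(i) {
    x <- free[i, 1]; y <- free[i, 2]
    sum(!is_blocked(world, x + 1, y), !is_blocked(world, x - 1, y),
        !is_blocked(world, x, y + 1), !is_blocked(world, x, y - 1))
  }, integer(1))
  data.frame(x = free[, 1], y = free[, 2], degree = deg,
             class = ifelse(deg >= 3, "junction",
                            ifelse(deg == 2, "corridor", "dead_end")))
}
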
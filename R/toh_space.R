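# Tower of Hanoi state space: 4 disks (1 = smallest .. 4 = largest), 3 pegs.
# A state assigns each disk to a peg; stacking order on a peg is implied by
# size, so there are exactly 3^4 = 81 legal states. A legal move transfers
# the smallest disk of one peg onto a peg whose smallest disk is larger (or
# which is empty).

.toh_cache <- new.env(parent = emptyenv())

#' All legal Tower of Hanoi states
#'
#' @return 81 x 4 integer matrix; row `s` gives the peg (1--3) of disks 1--4
#'   (smallest to largest) for state id `s`.
#' @export
toh_states <- function() {
  if (is.null(.toh_cache$states)) {
    .toh_cache$states <- as.matrix(expand.grid(disk1 = 1:3, disk2 = 1:3,
                                               disk3 = 1:3, disk4 = 1:3))
  }
  .toh_cache$states
}

#' State id for a disk-to-peg assignment
#'
#' @param pegs integer vector of length 4: peg (1--3) of each disk, smallest
#'   first.
#' @return integer state id in 1..81.
#' @export
toh_state_id <- function(pegs) {
  stopifnot(length(pegs) == 4L, all(pegs %in% 1:3))
  as.integer(1L + sum((pegs - 1L) * 3L^(0:3)))
}

#' Legal successor states
#'
#' @param id state id (1..81).
#' @return integer vector of state ids reachable in one legal move.
#' @export
toh_neighbors <- function(id) {
  pegs <- toh_states()[id, ]
  out <- integer(0)
  for (from in 1:3) {
    disks_on <- which(pegs == from)
    if (!length(disks_on)) next
    top <- min(disks_on)              # smallest disk on `from` is movable
    for (to in setdiff(1:3, from)) {
      disks_to <- which(pegs == to)
      if (!length(disks_to) || min(disks_to) > top) {
        np <- pegs
        np[top] <- to
        out <- c(out, toh_state_id(np))
      }
    }
  }
  out
}

toh_adjacency <- function() {
  if (is.null(.toh_cache$adj)) {
    .toh_cache$adj <- lapply(1:81, toh_neighbors)
  }
  .toh_cache$adj
}

# breadth-first shortest-path distances from one state to all 81
toh_bfs <- function(from) {
  adj <- toh_adjacency()
  dist <- rep(NA_integer_, 81L)
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

toh_distance_matrix <- function() {
  if (is.null(.toh_cache$dist)) {
    .toh_cache$dist <- vapply(1:81, toh_bfs, integer(81))
  }
  .toh_cache$dist
}

#' Minimum number of moves between two Tower of Hanoi states
#'
#' Breadth-first search over the 81-state legal-move graph (cached all-pairs
#' distances). The graph is connected, so a distance always exists; the full
#' left-peg to right-peg transfer takes the classic 2^4 - 1 = 15 moves.
#'
#' @param a,b state ids (1..81) or length-4 peg vectors.
#' @return integer shortest-path distance.
#' @export
toh_min_distance <- function(a, b) {
  if (length(a) == 4L) a <- toh_state_id(a)
  if (length(b) == 4L) b <- toh_state_id(b)
  toh_distance_matrix()[a, b]
}

#' Generate a Tower of Hanoi problem set
#'
#' Reproduces the task design: three practice problems (one one-step, two
#' two-step) followed by 16 experimental problems, two at each minimum step
#' count from 3 to 10. Initial/target state pairs are sampled uniformly
#' among all pairs at the required breadth-first distance, excluding pairs
#' whose target coincides with a practice target; every problem's step count
#' is verified against [toh_min_distance()].
#'
#' @param seed integer seed; the same seed always yields the same set.
#' @return data.frame with columns `phase` (`practice`/`experimental`),
#'   `trial_index`, `required_steps`, `initial_id`, `target_id`, and the peg
#'   strings `initial`, `target` (e.g. `"1123"`, pegs of disks smallest to
#'   largest).
#' @export
generate_toh_problem_set <- function(seed) {
  D <- toh_distance_matrix()
  with_seed(seed, toh_problem_set_impl(D))
}

toh_problem_set_impl <- function(D) {
  sample_pair <- function(steps, exclude_targets = integer(0)) {
    idx <- which(D == steps, arr.ind = TRUE)
    idx <- idx[!(idx[, 2] %in% exclude_targets), , drop = FALSE]
    idx[sample.int(nrow(idx), 1L), ]
  }
  peg_string <- function(id) paste(toh_states()[id, ], collapse = "")

  rows <- list()
  practice_targets <- integer(0)
  for (i in seq_along(c(1, 2, 2))) {
    steps <- c(1, 2, 2)[i]
    pr <- sample_pair(steps)
    practice_targets <- c(practice_targets, pr[2])
    rows[[length(rows) + 1L]] <- data.frame(
      phase = "practice", trial_index = i, required_steps = steps,
      initial_id = pr[1], target_id = pr[2])
  }
  ti <- 0L
  for (steps in 3:10) {
    for (rep in 1:2) {
      ti <- ti + 1L
      pr <- sample_pair(steps, exclude_targets = practice_targets)
      rows[[length(rows) + 1L]] <- data.frame(
        phase = "experimental", trial_index = ti, required_steps = steps,
        initial_id = pr[1], target_id = pr[2])
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(all(D[cbind(out$initial_id, out$target_id)] == out$required_steps))
  out$initial <- vapply(out$initial_id, peg_string, "")
  out$target <- vapply(out$target_id, peg_string, "")
  out
}
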
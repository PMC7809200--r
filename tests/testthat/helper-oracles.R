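# Independent oracles used to validate the package's numerics. These are
# deliberately naive implementations that share no code with the package.

# classical Gram-Schmidt orthonormalization of (1, x, x^2, x^3), returning
# the age columns only (without the constant), each centered and unit-norm
gram_schmidt_poly <- function(x, degree) {
  V <- cbind(1, outer(x, seq_len(degree), `^`))
  Q <- matrix(0, nrow(V), ncol(V))
  for (j in seq_len(ncol(V))) {
    v <- V[, j]
    if (j > 1) for (k in 1:(j - 1)) v <- v - sum(Q[, k] * V[, j]) * Q[, k]
    Q[, j] <- v / sqrt(sum(v^2))
  }
  Q[, -1, drop = FALSE]
}

# explicit normal-equations least squares: solve (X'X) b = X'y
ols_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# residual maker: (I - X (X'X)^-1 X') y
hat_matrix_residuals <- function(X, y) {
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  drop((diag(nrow(X)) - H) %*% y)
}

# iterative-deepening depth-first search over Tower of Hanoi moves,
# independent of the package's BFS and adjacency cache
id_dfs_toh <- function(a, b, max_depth = 16L) {
  pegs_a <- lifespanEF::toh_states()[a, ]
  target <- lifespanEF::toh_states()[b, ]
  moves_from <- function(pegs) {
    out <- list()
    for (from in 1:3) {
      on_from <- which(pegs == from)
      if (!length(on_from)) next
      top <- min(on_from)
      for (to in setdiff(1:3, from)) {
        on_to <- which(pegs == to)
        if (!length(on_to) || min(on_to) > top) {
          np <- pegs; np[top] <- to
          out[[length(out) + 1L]] <- np
        }
      }
    }
    out
  }
  encode <- function(pegs) 1L + sum((pegs - 1L) * 3L^(0:3))
  # depth-limited search with a transposition table: revisiting a state with
  # no more remaining depth than before cannot find a new solution, so the
  # prune is sound and the search stays exhaustive
  best_remaining <- rep(-1L, 81L)
  dls <- function(pegs, depth) {
    if (all(pegs == target)) return(TRUE)
    if (depth == 0L) return(FALSE)
    id <- encode(pegs)
    if (best_remaining[id] >= depth) return(FALSE)
    best_remaining[id] <<- depth
    for (np in moves_from(pegs)) if (dls(np, depth - 1L)) return(TRUE)
    FALSE
  }
  for (d in 0:max_depth) {
    best_remaining[] <- -1L
    if (dls(pegs_a, d)) return(d)
  }
  NA_integer_
}

# build a simple trial table for RT-task tests
make_trials <- function(rt_ms, condition = "congruent", accurate = TRUE,
                        participant_id = "p1", ...) {
  n <- length(rt_ms)
  data.frame(participant_id = rep_len(participant_id, n), rt_ms = rt_ms,
             condition = rep_len(condition, n),
             accurate = rep_len(accurate, n), ...,
             stringsAsFactors = FALSE)
}
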
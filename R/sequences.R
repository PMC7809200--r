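# Task trial-sequence generators reproducing the experimental designs.

STROOP_COLOR_WORDS <- c("RED", "GREEN", "BLUE", "YELLOW")
STROOP_COLORS <- c("red", "green", "blue", "yellow")
STROOP_FILLERS <- c("TAX", "CHIEF", "MEET", "PLENTY")
OSPAN_POOL <- c("F", "H", "J", "K", "L", "N", "P", "Q", "R", "S", "T", "Y")

#' Generate a pseudo-randomised Stroop trial sequence
#'
#' 20 practice trials (10 filler, 10 congruent) followed by 150 experimental
#' trials (50 congruent, 50 incongruent, 50 filler) in pseudo-random order
#' under the priming-avoidance constraints: the same colour word, the same
#' printed colour, and hence the same word/colour combination never appear on
#' two consecutive trials. Congruent trials print a colour word in its own
#' colour, incongruent trials in a different colour, filler trials use
#' length/frequency-matched non-colour words.
#'
#' @param seed integer seed (same seed, same sequence).
#' @param max_restarts how many times to restart the constraint-satisfaction
#'   pass before retrying with a derived seed and finally failing.
#' @return data.frame with columns `phase`, `trial_index`, `condition`,
#'   `word`, `print_color`.
#' @export
generate_stroop_sequence <- function(seed, max_restarts = 100L) {
  with_seed(seed, {
    prac <- stroop_fill_block(sample(rep(c("filler", "congruent"), c(10, 10))),
                              max_restarts)
    expr <- stroop_fill_block(
      sample(rep(c("congruent", "incongruent", "filler"), each = 50)),
      max_restarts)
    rbind(
      data.frame(phase = "practice", trial_index = seq_len(nrow(prac)), prac),
      data.frame(phase = "experimental", trial_index = seq_len(nrow(expr)), expr))
  })
}

# assign words/colours to an ordered condition vector under the adjacency
# constraints; restarts the greedy pass when it paints itself into a corner
stroop_fill_block <- function(conditions, max_restarts) {
  for (attempt in seq_len(max_restarts)) {
    res <- stroop_try_fill(conditions)
    if (!is.null(res)) return(res)
  }
  stop("could not satisfy Stroop adjacency constraints; increase max_restarts",
       call. = FALSE)
}

.stroop_candidates <- local({
  cong <- data.frame(w = STROOP_COLOR_WORDS, c = STROOP_COLORS,
                     stringsAsFactors = FALSE)
  inc <- expand.grid(w = STROOP_COLOR_WORDS, c = STROOP_COLORS,
                     stringsAsFactors = FALSE)
  inc <- inc[tolower(inc$w) != inc$c, ]
  fill <- expand.grid(w = STROOP_FILLERS, c = STROOP_COLORS,
                      stringsAsFactors = FALSE)
  list(congruent = cong, incongruent = inc, filler = fill)
})

stroop_try_fill <- function(conditions) {
  n <- length(conditions)
  word <- character(n)
  col <- character(n)
  for (i in seq_len(n)) {
    prev_w <- if (i > 1) word[i - 1] else ""
    prev_c <- if (i > 1) col[i - 1] else ""
    cand <- .stroop_candidates[[conditions[i]]]
    ok <- which(cand$w != prev_w & cand$c != prev_c)
    if (!length(ok)) return(NULL)
    pick <- ok[sample.int(length(ok), 1L)]
    word[i] <- cand$w[pick]
    col[i] <- cand$c[pick]
  }
  data.frame(condition = conditions, word = word, print_color = col,
             stringsAsFactors = FALSE)
}

#' Generate an alternating-runs task-switching trial sequence
#'
#' Single-task phase: 16 practice + 32 experimental trials in each of a
#' shape block and a colour block. Mixed-task phase: 16 practice trials and
#' four blocks of 32 experimental trials. Stimuli (circle/triangle in
#' blue/yellow) rotate clockwise through the screen quadrants starting
#' upper-left (UL, UR, LR, LL); in mixed blocks the top quadrants require
#' the shape judgement and the bottom quadrants the colour judgement, so
#' UR->LR and LL->UL transitions are switch trials and UL->UR and LR->LL are
#' non-switch trials, alternating predictably. Block-initial mixed trials
#' have no preceding task and carry `condition = NA`. The same coloured
#' shape never appears on consecutive trials.
#'
#' @param seed integer seed.
#' @return data.frame with columns `phase` (`single_shape`, `single_color`,
#'   `mixed`), `block`, `trial_index`, `practice` (logical), `quadrant`,
#'   `condition` (`single`, `nonswitch`, `switch`, or `NA`), `shape`,
#'   `color`.
#' @export
generate_switching_sequence <- function(seed) {
  with_seed(seed, {
    quadrants <- c("UL", "UR", "LR", "LL")
    draw_stimuli <- function(n) {
      combos <- expand.grid(shape = c("circle", "triangle"),
                            color = c("blue", "yellow"),
                            stringsAsFactors = FALSE)
      idx <- integer(n)
      idx[1] <- sample.int(4L, 1L)
      for (i in seq_len(n)[-1]) {
        idx[i] <- sample(setdiff(1:4, idx[i - 1]), 1L)
      }
      combos[idx, , drop = FALSE]
    }
    make_block <- function(phase, block, n, practice) {
      quad <- quadrants[(seq_len(n) - 1L) %% 4L + 1L]
      cond <- if (phase == "mixed") {
        c(NA, ifelse(quad[-1] %in% c("UR", "LL"), "nonswitch", "switch"))
      } else rep("single", n)
      st <- draw_stimuli(n)
      data.frame(phase = phase, block = block, trial_index = seq_len(n),
                 practice = practice, quadrant = quad, condition = cond,
                 shape = st$shape, color = st$color,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(
      make_block("single_shape", 1L, 16L, TRUE),
      make_block("single_shape", 2L, 32L, FALSE),
      make_block("single_color", 3L, 16L, TRUE),
      make_block("single_color", 4L, 32L, FALSE),
      make_block("mixed", 5L, 16L, TRUE),
      make_block("mixed", 6L, 32L, FALSE),
      make_block("mixed", 7L, 32L, FALSE),
      make_block("mixed", 8L, 32L, FALSE),
      make_block("mixed", 9L, 32L, FALSE))
    rownames(out) <- NULL
    out
  })
}

#' Generate an operation-span trial design
#'
#' Three trials at each span length 2--7 in randomised order (18 trials,
#' 81 letters, 81 maths problems); letters are drawn without replacement
#' within a trial from the 12-letter pool F H J K L N P Q R S T Y.
#'
#' @param seed integer seed.
#' @return data.frame with columns `trial_index`, `span`, `presented`
#'   (letter string).
#' @export
generate_ospan_design <- function(seed) {
  with_seed(seed, {
    spans <- sample(rep(2:7, each = 3))
    letters_str <- vapply(spans, function(s) {
      paste(sample(OSPAN_POOL, s), collapse = "")
    }, "")
    data.frame(trial_index = seq_along(spans), span = spans,
               presented = letters_str, stringsAsFactors = FALSE)
  })
}

#' Check the Stroop adjacency constraints of a sequence
#'
#' Independent validation that no two consecutive trials share a word or a
#' printed colour and that condition labels are consistent with the
#' word/colour pairing.
#'
#' @param seq_df output of [generate_stroop_sequence()] (one phase).
#' @return TRUE invisibly; stops with a diagnostic otherwise.
#' @export
validate_stroop_sequence <- function(seq_df) {
  n <- nrow(seq_df)
  if (n > 1) {
    same_word <- seq_df$word[-1] == seq_df$word[-n]
    same_col <- seq_df$print_color[-1] == seq_df$print_color[-n]
    if (any(same_word)) stop("consecutive trials share a word")
    if (any(same_col)) stop("consecutive trials share a printed colour")
  }
  cong <- seq_df$condition == "congruent"
  incg <- seq_df$condition == "incongruent"
  fill <- seq_df$condition == "filler"
  stopifnot(all(tolower(seq_df$word[cong]) == seq_df$print_color[cong]),
            all(tolower(seq_df$word[incg]) != seq_df$print_color[incg]),
            all(seq_df$word[incg] %in% STROOP_COLOR_WORDS),
            all(seq_df$word[fill] %in% STROOP_FILLERS))
  invisible(TRUE)
}
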
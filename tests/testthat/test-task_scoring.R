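test_that("RT trimming keeps constant-RT trials and drops fast responses", {
  all_equal <- make_trials(rep(500, 10))
  expect_equal(nrow(filter_rt_trials(all_equal)), 10)

  with_fast <- make_trials(c(rep(500, 10), 150))
  kept <- filter_rt_trials(with_fast)
  expect_equal(nrow(kept), 10)
  expect_false(150 %in% kept$rt_ms)

  # inaccurate and timed-out trials never survive
  tr <- make_trials(c(500, 510, 520), accurate = c(TRUE, FALSE, TRUE),
                    timed_out = c(FALSE, FALSE, TRUE))
  expect_equal(suppressWarnings(filter_rt_trials(tr))$rt_ms, 500)
})

test_that("RT trimming excludes exactly the trials outside the one-pass SD band", {
  # 99 trials at 500 plus one high outlier; with a single outlier the sample
  # SD of the full set is offset/sqrt(101), so the outlier sits ~10 SDs out
  # while every 500 sits ~0.1 SDs out -- only the outlier crosses 2.5 SDs
  rt <- c(rep(500, 99), 550)
  m <- mean(rt); s <- sd(rt)
  expect_gt(abs(rt[100] - m), 2.5 * s)  # oracle: direct mean/SD computation
  expect_true(all(abs(rt[1:99] - m) <= 2.5 * s))
  kept <- filter_rt_trials(make_trials(rt))
  expect_equal(nrow(kept), 99)
  expect_true(all(kept$rt_ms == 500))

  # contract property on random sets: every retained trial is accurate,
  # > 200 ms, and within 2.5 SDs of the pre-exclusion mean
  set.seed(41)
  for (rep_i in 1:20) {
    rt <- exp(rnorm(60, 6.6, 0.4)) + 100
    acc <- runif(60) < 0.9
    tr <- make_trials(rt, accurate = acc)
    eligible <- acc & rt > 200
    m <- mean(rt[eligible]); s <- sd(rt[eligible])
    kept <- filter_rt_trials(tr)
    expect_true(all(kept$accurate))
    expect_true(all(kept$rt_ms > 200))
    expect_true(all(abs(kept$rt_ms - m) <= 2.5 * s + 1e-12))
    expect_equal(nrow(kept), sum(eligible & abs(rt - m) <= 2.5 * s))
  }
})

test_that("RT trimming with fewer than two eligible trials warns and skips the band", {
  tr <- make_trials(c(500, 150, 180), accurate = c(TRUE, TRUE, TRUE))
  expect_warning(kept <- filter_rt_trials(tr), "fewer than 2")
  expect_equal(kept$rt_ms, 500)
  expect_equal(nrow(filter_rt_trials(make_trials(numeric(0)))), 0)
})

test_that("Stroop congruency effect follows the reversed log-difference definition", {
  same <- make_trials(rep(600, 20), condition = rep(c("congruent", "incongruent"), 10))
  expect_equal(stroop_congruency_effect(same), 0)

  # hand arithmetic on log scale: incongruent {7.0, 7.2}, congruent {6.8, 7.0}
  tr <- make_trials(exp(c(7.0, 7.2, 6.8, 7.0)),
                    condition = c("incongruent", "incongruent",
                                  "congruent", "congruent"))
  expect_equal(stroop_congruency_effect(tr), -0.2)
  # untransformed variant negates the raw-ms difference
  expect_equal(stroop_congruency_effect(tr, log_transform = FALSE),
               -(mean(exp(c(7.0, 7.2))) - mean(exp(c(6.8, 7.0)))))

  # missing condition -> missing score
  expect_true(is.na(stroop_congruency_effect(
    make_trials(c(500, 520), condition = "congruent"))))

  # reverse scoring: slowing the incongruent trials strictly lowers the score
  set.seed(7)
  tr2 <- make_trials(exp(rnorm(40, 6.8, 0.2)),
                     condition = rep(c("congruent", "incongruent"), each = 20))
  s0 <- stroop_congruency_effect(tr2)
  tr2$rt_ms[tr2$condition == "incongruent"] <-
    tr2$rt_ms[tr2$condition == "incongruent"] * 1.1
  expect_lt(stroop_congruency_effect(tr2), s0)

  # invariant to trial order within condition
  expect_equal(stroop_congruency_effect(tr2[sample(nrow(tr2)), ]),
               stroop_congruency_effect(tr2))
})

test_that("switching costs are reversed differences of condition log-RT means", {
  const <- function(cond, n) make_trials(rep(700, n), condition = cond)
  res <- switching_costs(const("single", 10),
                         const(rep(c("switch", "nonswitch"), 10), 20))
  expect_equal(res$switch_cost, 0)
  expect_equal(res$mixing_cost, 0)

  # group-mean arithmetic: single 6.42, nonswitch 6.88, switch 7.21
  single <- make_trials(exp(c(6.40, 6.44)), condition = "single")
  mixed <- make_trials(exp(c(6.86, 6.90, 7.20, 7.22)),
                       condition = c("nonswitch", "nonswitch", "switch", "switch"))
  res <- switching_costs(single, mixed)
  expect_equal(res$switch_cost, -0.33)
  expect_equal(res$mixing_cost, -0.46)

  # an empty condition makes the dependent costs missing
  res2 <- switching_costs(single, mixed[mixed$condition == "switch", ])
  expect_true(is.na(res2$switch_cost))
  expect_true(is.na(res2$mixing_cost))
  res3 <- switching_costs(single[0, ], mixed)
  expect_false(is.na(res3$switch_cost))
  expect_true(is.na(res3$mixing_cost))

  # block-initial mixed trials are excluded from both condition means
  mixed_b <- make_trials(exp(c(9.0, 6.88, 7.21, 6.88, 7.21)),
                         condition = c("nonswitch", "nonswitch", "switch",
                                       "nonswitch", "switch"),
                         block = c(1, 1, 1, 2, 2),
                         trial_index = c(1, 2, 3, 1, 2))
  # the 9.0 first-of-block trial must not contaminate the nonswitch mean:
  # trial_index 1 of each block is dropped, leaving nonswitch {6.88},
  # switch {7.21, 7.21}  (block 2's first trial is also dropped)
  res4 <- switching_costs(single, mixed_b)
  expect_equal(res4$switch_cost, -(7.21 - 6.88), tolerance = 1e-12)
})

test_that("operation-span scoring counts perfect sets and correct positions", {
  tr <- data.frame(span = c(2, 3, 4),
                   presented = c("FK", "JLN", "PQRS"),
                   recalled = c("FK", "JLN", "PTRS"))
  s <- ospan_scores(tr)
  expect_equal(s$absolute, 5L)
  expect_equal(s$partial, 8L)

  # the full design recalled perfectly: 18 trials, spans 2..7 three times
  design <- generate_ospan_design(1)
  perfect <- data.frame(span = design$span, presented = design$presented,
                        recalled = design$presented)
  s2 <- ospan_scores(perfect)
  expect_equal(s2$absolute, 81L)
  expect_equal(s2$partial, 81L)

  # all-blank recall scores nothing
  blanks <- data.frame(span = c(2, 3), presented = c("FK", "JLN"),
                       recalled = c("--", "---"))
  expect_equal(ospan_scores(blanks), list(absolute = 0L, partial = 0L))

  # extra recalled entries beyond the span contribute nothing, and a
  # length mismatch voids perfection even when all presented positions match
  over <- data.frame(span = 2, presented = "FK", recalled = "FKL")
  s3 <- ospan_scores(over)
  expect_equal(s3$absolute, 0L)
  expect_equal(s3$partial, 2L)

  # property: partial >= absolute share of letters on random inputs
  set.seed(11)
  pool <- c("F","H","J","K","L","N","P","Q","R","S","T","Y")
  for (i in 1:25) {
    sp <- sample(2:7, 6, replace = TRUE)
    pres <- vapply(sp, function(s) paste(sample(pool, s), collapse = ""), "")
    rec <- vapply(pres, function(p) {
      ch <- strsplit(p, "")[[1]]
      flip <- runif(length(ch)) < 0.3
      ch[flip] <- sample(c(pool, "-"), sum(flip), replace = TRUE)
      paste(ch, collapse = "")
    }, "")
    s <- ospan_scores(data.frame(span = sp, presented = pres, recalled = rec))
    expect_gte(s$partial, s$absolute)
  }
})

test_that("Tower of Hanoi absolute score sums perfectly completed step counts", {
  expect_equal(toh_absolute_score(
    data.frame(required_steps = 5, perfect = TRUE)), 5L)
  expect_equal(toh_absolute_score(
    data.frame(required_steps = c(3, 7), perfect = c(FALSE, FALSE))), 0L)
  # the standard 16-trial design solved perfectly reaches 2*(3+...+10) = 104
  probs <- generate_toh_problem_set(3)
  ex <- probs[probs$phase == "experimental", ]
  ex$perfect <- TRUE
  expect_equal(toh_absolute_score(ex), 104L)
})

test_that("SES index sums the three component codes within range", {
  expect_equal(ses_index(1, 1, 1), 3L)
  expect_equal(ses_index(6, 7, 7), 20L)
  expect_equal(ses_index(3, 4, 5), 12L)
  expect_true(is.na(ses_index(NA, 4, 5)))
  expect_error(ses_index(7, 1, 1), "education")
  expect_error(ses_index(2, 8, 1), "income")
  expect_error(ses_index(2, 3, 0), "occupation")
})

test_that("reliability matches the covariance formula and the standardized identity", {
  # identical items are perfectly consistent
  x <- matrix(rep(rnorm(10), 4), ncol = 4)
  r <- reliability(x)
  expect_equal(r$cronbach_alpha, 1)
  expect_equal(r$avg_inter_item_r, 1)

  # standardized path reproduces k*r/(1+(k-1)*r)
  expect_equal(standardized_alpha(16, 0.20), 0.80)

  # toy 4 x 3 matrix against hand covariance arithmetic
  toy <- matrix(c(1, 2, 3, 4,
                  2, 2, 4, 5,
                  1, 3, 3, 6), ncol = 3)
  k <- 3
  alpha_hand <- k / (k - 1) *
    (1 - sum(apply(toy, 2, var)) / var(rowSums(toy)))
  expect_equal(reliability(toy)$cronbach_alpha, alpha_hand)

  # zero total variance is undefined
  z <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2), ncol = 2)
  z[, 2] <- 3 - z[, 1]   # rows all sum to 3
  expect_true(is.na(reliability(z)$cronbach_alpha))

  # exchangeable equal-variance items: standardized alpha from (k, rbar)
  # agrees with the matrix computation within sampling error
  set.seed(5)
  n <- 400; k <- 8
  common <- rnorm(n)
  items <- sapply(1:k, function(j) common + rnorm(n, sd = 1.5))
  rel <- reliability(items, standardized = TRUE)
  expect_equal(rel$cronbach_alpha,
               standardized_alpha(k, rel$avg_inter_item_r))
  expect_equal(reliability(items)$cronbach_alpha, rel$cronbach_alpha,
               tolerance = 0.02)
})
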
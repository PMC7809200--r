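#' Socio-economic status index
#'
#' Sums three ordinal household codes -- education (1--6), household income
#' (1--7) and occupational class (1--7) -- into a single SES index ranging
#' from 3 (lowest) to 20 (highest). Any missing component makes the index
#' missing for that person.
#'
#' @param education_code integer vector in 1..6.
#' @param income_code integer vector in 1..7.
#' @param occupation_code integer vector in 1..7.
#' @return Integer vector of SES indices in `[3, 20]`, `NA` where any
#'   component is missing.
#' @examples
#' ses_index(6, 7, 7)   # 20, the ceiling of the scale
#' ses_index(3, 4, 5)   # 12
#' @export
ses_index <- function(education_code, income_code, occupation_code) {
  check_code <- function(x, lo, hi, what) {
    bad <- !is.na(x) & (x < lo | x > hi | x != round(x))
    if (any(bad)) {
      stop(sprintf("%s code out of range [%d, %d]: %s",
                   what, lo, hi, paste(unique(x[bad]), collapse = ", ")),
           call. = FALSE)
    }
  }
  check_code(education_code, 1L, 6L, "education")
  check_code(income_code, 1L, 7L, "income")
  check_code(occupation_code, 1L, 7L, "occupation")
  as.integer(education_code + income_code + occupation_code)
}

#' Trim reaction-time trials
#'
#' Retains accurate, non-timed-out responses made more than `min_rt_ms` after
#' stimulus onset and lying within `sd_mult` standard deviations of the
#' participant's overall trial mean. The mean and SD are computed once, per
#' participant and task, over the accurate > `min_rt_ms` trials pooled across
#' conditions (raw-millisecond scale, single pass; no iterative re-trimming).
#'
#' @param trials data.frame with columns `rt_ms` (positive, milliseconds) and
#'   `accurate` (logical); optional `timed_out` (logical) and `participant_id`
#'   (trimming statistics are computed within participant when present).
#' @param min_rt_ms lower response-time bound in milliseconds (default 200).
#' @param sd_mult SD multiplier for the outlier band (default 2.5).
#' @param on_log if `TRUE`, the mean/SD band is computed on log response
#'   times instead of raw milliseconds (the default raw scale is the
#'   convention used throughout the package).
#' @return The retained rows of `trials`. If a participant has fewer than two
#'   eligible trials the SD is undefined; their eligible trials are kept
#'   without SD trimming and a warning is emitted.
#' @export
filter_rt_trials <- function(trials, min_rt_ms = 200, sd_mult = 2.5,
                             on_log = FALSE) {
  if (nrow(trials) == 0L) return(trials)
  stopifnot(all(c("rt_ms", "accurate") %in% names(trials)))
  timed_out <- if ("timed_out" %in% names(trials)) {
    trials$timed_out %in% TRUE
  } else rep(FALSE, nrow(trials))
  eligible <- trials$accurate %in% TRUE & !timed_out &
    !is.na(trials$rt_ms) & trials$rt_ms > min_rt_ms

  grp <- if ("participant_id" %in% names(trials)) {
    as.character(trials$participant_id)
  } else rep("all", nrow(trials))

  x <- if (on_log) log(trials$rt_ms) else trials$rt_ms
  xe <- x[eligible]
  ge <- grp[eligible]
  m <- tapply(xe, ge, mean)
  s <- tapply(xe, ge, stats::sd)
  cnt <- tapply(xe, ge, length)
  if (any(cnt < 2L)) {
    warning(sprintf(
      "fewer than 2 eligible trials for %d participant(s); SD trimming skipped there",
      sum(cnt < 2L)), call. = FALSE)
  }

  keep <- eligible
  idx <- match(grp, names(m))
  has_sd <- !is.na(s[idx]) & s[idx] > 0
  band <- abs(x - m[idx]) <= sd_mult * s[idx]
  keep <- keep & (!has_sd | band)
  trials[keep, , drop = FALSE]
}

#' Stroop congruency effect (reverse scored)
#'
#' Mean log response time on incongruent trials minus mean log response time
#' on congruent trials, negated so that a higher score indicates better
#' inhibitory control. Trials should already have passed
#' [filter_rt_trials()]. With `log_transform = FALSE` the difference is taken
#' on raw milliseconds (still negated), which supports the untransformed
#' sensitivity analysis.
#'
#' @param trials data.frame of one participant's Stroop trials with columns
#'   `condition` (`"congruent"`, `"incongruent"`, `"filler"`) and `rt_ms`.
#' @param log_transform log-transform each trial RT before averaging?
#' @return A single numeric score, `NA` if either condition is absent.
#' @export
stroop_congruency_effect <- function(trials, log_transform = TRUE) {
  rt_inc <- trials$rt_ms[trials$condition == "incongruent"]
  rt_con <- trials$rt_ms[trials$condition == "congruent"]
  if (length(rt_inc) == 0L || length(rt_con) == 0L) return(NA_real_)
  if (log_transform) {
    rt_inc <- log(rt_inc)
    rt_con <- log(rt_con)
  }
  -(mean(rt_inc) - mean(rt_con))
}

#' Switch and mixing costs (reverse scored)
#'
#' The switch cost is the mean (log) RT on switch trials minus non-switch
#' trials within mixed blocks; the mixing cost is the mean non-switch (mixed)
#' RT minus the mean single-task RT. Both are negated so that higher scores
#' indicate better cognitive flexibility. Block-initial mixed trials have no
#' preceding task, so they are excluded from both condition means: rows whose
#' `condition` is `NA` are dropped, and when `block` and `trial_index`
#' columns are present the first trial of each mixed block is dropped as
#' well.
#'
#' @param single_trials data.frame of filtered single-task trials (`rt_ms`).
#' @param mixed_trials data.frame of filtered mixed-block trials with
#'   `condition` in `"switch"`/`"nonswitch"` (`NA` for block-initial trials)
#'   and `rt_ms`; optional `block`, `trial_index`.
#' @param log_transform log-transform trial RTs before averaging?
#' @return list with numeric `switch_cost` and `mixing_cost`; a cost is `NA`
#'   when any condition mean it needs is unavailable.
#' @export
switching_costs <- function(single_trials, mixed_trials, log_transform = TRUE) {
  mixed_trials <- drop_block_initial(mixed_trials)
  tr <- function(x) if (log_transform) log(x) else x
  m_single <- if (nrow(single_trials)) mean(tr(single_trials$rt_ms)) else NA_real_
  m_ns <- cond_mean(mixed_trials, "nonswitch", tr)
  m_sw <- cond_mean(mixed_trials, "switch", tr)
  list(switch_cost = -(m_sw - m_ns),
       mixing_cost = -(m_ns - m_single))
}

cond_mean <- function(trials, cond, tr) {
  x <- trials$rt_ms[!is.na(trials$condition) & trials$condition == cond]
  if (length(x) == 0L) NA_real_ else mean(tr(x))
}

drop_block_initial <- function(mixed_trials) {
  if (!nrow(mixed_trials)) return(mixed_trials)
  if (all(c("block", "trial_index") %in% names(mixed_trials))) {
    grp <- if ("participant_id" %in% names(mixed_trials)) {
      interaction(mixed_trials$participant_id, mixed_trials$block, drop = TRUE)
    } else factor(mixed_trials$block)
    first <- stats::ave(mixed_trials$trial_index, grp, FUN = min)
    mixed_trials <- mixed_trials[mixed_trials$trial_index != first, , drop = FALSE]
  }
  mixed_trials[!is.na(mixed_trials$condition), , drop = FALSE]
}

#' Operation-span absolute and partial scores
#'
#' The absolute score sums the span lengths of trials whose letter sequence
#' was recalled perfectly (strict positional match, no missing or extra
#' entries). The partial score counts, across all trials, letters recalled in
#' their correct serial position. Blank recall markers (`"-"`) occupy a
#' position and never match, and recalled positions beyond the presented span
#' contribute nothing, so `partial >= absolute` always holds.
#'
#' @param trials data.frame of one participant's span trials with columns
#'   `span` (integer), `presented` and `recalled` (letter strings, e.g.
#'   `"FKQ"`, with `-` marking a blank recall slot).
#' @return list with integer `absolute` and `partial` scores.
#' @export
ospan_scores <- function(trials) {
  if (!nrow(trials)) return(list(absolute = 0L, partial = 0L))
  pres <- strsplit(as.character(trials$presented), "", fixed = TRUE)
  rec <- strsplit(as.character(trials$recalled), "", fixed = TRUE)
  hits <- mapply(function(p, r) {
    k <- min(length(p), length(r))
    if (k == 0L) return(0L)
    sum(p[seq_len(k)] == r[seq_len(k)] & r[seq_len(k)] != "-")
  }, pres, rec)
  perfect <- mapply(function(p, r) length(p) == length(r) && all(p == r),
                    pres, rec)
  list(absolute = as.integer(sum(trials$span[perfect])),
       partial = as.integer(sum(hits)))
}

#' Tower of Hanoi absolute score
#'
#' Sums the required step counts of trials completed perfectly: a trial that
#' needed 5 moves and was solved in exactly 5 legal moves contributes 5
#' points. The standard 16-trial design (two trials at each of 3--10 steps)
#' has a ceiling of 104.
#'
#' @param trials data.frame with columns `required_steps` (integer) and
#'   `perfect` (logical).
#' @return Integer score.
#' @export
toh_absolute_score <- function(trials) {
  if (!nrow(trials)) return(0L)
  as.integer(sum(trials$required_steps[trials$perfect %in% TRUE]))
}

#' Internal consistency (Cronbach's alpha)
#'
#' Raw alpha is `k/(k-1) * (1 - sum(item variances)/variance(total))`;
#' standardized alpha is `k*rbar / (1 + (k-1)*rbar)` where `rbar` is the mean
#' of the `k(k-1)/2` pairwise Pearson item correlations. Rows with any
#' missing item are dropped (listwise deletion).
#'
#' @param item_matrix numeric matrix or data.frame, participants x items.
#' @param standardized report the standardized (correlation-based) alpha
#'   instead of the covariance-based raw alpha?
#' @return list of class `"ef_reliability"`: `cronbach_alpha`,
#'   `avg_inter_item_r`, `n_items`, `n_obs`, `standardized`. Alpha is `NA`
#'   when the total score has zero variance.
#' @examples
#' # 16 exchangeable items with average inter-item correlation 0.20 give
#' # a standardized alpha of 0.80
#' standardized_alpha(16, 0.20)
#' @export
reliability <- function(item_matrix, standardized = FALSE) {
  x <- as.matrix(item_matrix)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  if (k < 2L || nrow(x) < 3L) {
    stop("reliability() needs at least 2 items and 3 complete rows", call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(x))
  rbar <- mean(R[upper.tri(R)], na.rm = TRUE)
  total_var <- stats::var(rowSums(x))
  alpha_raw <- if (is.na(total_var) || total_var <= 0) {
    NA_real_
  } else {
    k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
  }
  alpha <- if (standardized) standardized_alpha(k, rbar) else alpha_raw
  structure(list(cronbach_alpha = alpha, avg_inter_item_r = rbar,
                 n_items = k, n_obs = nrow(x), standardized = standardized),
            class = "ef_reliability")
}

#' Standardized Cronbach's alpha from item count and mean correlation
#'
#' @param n_items number of items `k`.
#' @param avg_r average pairwise inter-item Pearson correlation.
#' @return `k*avg_r / (1 + (k-1)*avg_r)`.
#' @export
standardized_alpha <- function(n_items, avg_r) {
  n_items * avg_r / (1 + (n_items - 1) * avg_r)
}

#' @export
print.ef_reliability <- function(x, ...) {
  cat(sprintf("Cronbach's alpha (%s): %.3f  (k = %d items, mean r = %.3f, n = %d)\n",
              if (x$standardized) "standardized" else "raw",
              x$cronbach_alpha, x$n_items, x$avg_inter_item_r, x$n_obs))
  invisible(x)
}

#' Score a full cohort of trial tables
#'
#' Applies response-time trimming and the per-task scoring rules to
#' trial-level tables for every participant, producing one row of derived
#' executive-function measures per participant. A participant with no rows in
#' a task table receives `NA` for that task's score(s); the SES index is
#' `NA` when any of its three component codes is missing.
#'
#' @param participants data.frame with `participant_id`, `age_years`, `fsiq`,
#'   and either `ses_index` or the three component code columns
#'   `education_code`, `income_code`, `occupation_code` (optional `viq`,
#'   `piq` are carried through).
#' @param stroop Stroop trial table (`participant_id`, `condition`, `rt_ms`,
#'   `accurate`; practice rows, if present, flagged by `phase == "practice"`).
#' @param switching task-switching trial table (`participant_id`, `phase` in
#'   `single_shape`/`single_color`/`mixed`, `block`, `trial_index`,
#'   `condition`, `rt_ms`, `accurate`, `timed_out`).
#' @param ospan operation-span table (`participant_id`, `span`, `presented`,
#'   `recalled`).
#' @param toh Tower of Hanoi table (`participant_id`, `required_steps`,
#'   `perfect`).
#' @param log_transform log-transform RTs before computing the Stroop effect
#'   and switching costs (the primary analysis); `FALSE` reproduces the
#'   untransformed sensitivity analysis.
#' @return data.frame with one row per participant: ids, age, IQ, SES and the
#'   five executive-function scores (`stroop_effect`, `ospan_absolute`,
#'   `ospan_partial`, `switch_cost`, `mixing_cost`, `toh_score`).
#' @export
score_cohort <- function(participants, stroop = NULL, switching = NULL,
                         ospan = NULL, toh = NULL, log_transform = TRUE) {
  ids <- as.character(participants$participant_id)
  out <- data.frame(participant_id = ids,
                    age_years = participants$age_years,
                    stringsAsFactors = FALSE)
  for (col in c("fsiq", "viq", "piq")) {
    if (col %in% names(participants)) out[[col]] <- participants[[col]]
  }
  out$ses_index <- if ("ses_index" %in% names(participants)) {
    participants$ses_index
  } else if (all(c("education_code", "income_code", "occupation_code") %in%
                 names(participants))) {
    ses_index(participants$education_code, participants$income_code,
              participants$occupation_code)
  } else NA_integer_

  drop_practice <- function(df) {
    if (!is.null(df) && "phase" %in% names(df)) {
      df[df$phase != "practice", , drop = FALSE]
    } else df
  }

  out$stroop_effect <- NA_real_
  if (!is.null(stroop) && nrow(stroop)) {
    st <- filter_rt_trials(drop_practice(stroop))
    sc <- per_participant(st, ids, function(d) stroop_congruency_effect(d, log_transform))
    out$stroop_effect <- sc
  }

  out$ospan_absolute <- NA_integer_
  out$ospan_partial <- NA_integer_
  if (!is.null(ospan) && nrow(ospan)) {
    sp <- split(seq_len(nrow(ospan)), as.character(ospan$participant_id))
    for (id in names(sp)) {
      i <- match(id, ids)
      if (is.na(i)) next
      s <- ospan_scores(ospan[sp[[id]], , drop = FALSE])
      out$ospan_absolute[i] <- s$absolute
      out$ospan_partial[i] <- s$partial
    }
  }

  out$switch_cost <- NA_real_
  out$mixing_cost <- NA_real_
  if (!is.null(switching) && nrow(switching)) {
    sw <- drop_practice(switching)
    single <- filter_rt_trials(sw[startsWith(as.character(sw$phase), "single"), , drop = FALSE])
    mixed <- filter_rt_trials(sw[sw$phase == "mixed", , drop = FALSE])
    sp_single <- split(seq_len(nrow(single)), as.character(single$participant_id))
    sp_mixed <- split(seq_len(nrow(mixed)), as.character(mixed$participant_id))
    empty <- single[0, , drop = FALSE]
    for (id in unique(as.character(sw$participant_id))) {
      i <- match(id, ids)
      if (is.na(i)) next
      s_rows <- sp_single[[id]]
      m_rows <- sp_mixed[[id]]
      costs <- switching_costs(
        if (is.null(s_rows)) empty else single[s_rows, , drop = FALSE],
        if (is.null(m_rows)) mixed[0, , drop = FALSE] else mixed[m_rows, , drop = FALSE],
        log_transform = log_transform)
      out$switch_cost[i] <- costs$switch_cost
      out$mixing_cost[i] <- costs$mixing_cost
    }
  }

  out$toh_score <- NA_integer_
  if (!is.null(toh) && nrow(toh)) {
    sp <- split(seq_len(nrow(toh)), as.character(toh$participant_id))
    for (id in names(sp)) {
      i <- match(id, ids)
      if (is.na(i)) next
      out$toh_score[i] <- toh_absolute_score(toh[sp[[id]], , drop = FALSE])
    }
  }
  out
}

# apply f per participant over a trial table, aligned to the id vector
per_participant <- function(trials, ids, f) {
  res <- rep(NA_real_, length(ids))
  if (is.null(trials) || !nrow(trials)) return(res)
  sp <- split(seq_len(nrow(trials)), as.character(trials$participant_id))
  for (id in names(sp)) {
    i <- match(id, ids)
    if (!is.na(i)) res[i] <- f(trials[sp[[id]], , drop = FALSE])
  }
  res
}
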
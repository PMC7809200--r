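#' Specification of a synthetic lifespan cohort
#'
#' Collects every parameter of the generative model: sample size and
#' five-band age mixture, per-band IQ distributions, SES component code
#' distributions, per-measure age trajectories (polynomial coefficients on
#' age rescaled to `[0, 1]` so coefficients are portable across age ranges),
#' general slowing of baseline log response times, person- and trial-level
#' noise, logistic success models for the span and planning tasks, and
#' per-task missingness. The defaults emulate the study conditions: 350
#' participants in bands of 62/60/76/74/78, baseline single-task log RT
#' rising linearly with age within the observed 6.27--6.59 band-mean range,
#' a quadratic inhibition trajectory peaking near age 35, a quadratic
#' working-memory trajectory peaking near age 30, opposite-signed linear
#' trajectories for switch and mixing costs, and a cubic planning trajectory
#' (rise to 30, decline to 70, slight late recovery), with effect sizes at
#' the magnitudes of the reported standardized betas.
#'
#' @param n_participants cohort size.
#' @param age_distribution `"bands"` (default, the study's five-band mixture)
#'   or `"uniform"` over the age range.
#' @param trajectories named list; each element a list with `degree` (1--3),
#'   `coefs` (polynomial coefficients, increasing degree, on rescaled age
#'   `u = (age - 10)/76`, latent-scale units), `person_sd`, `iq_load`.
#'   Latent scales: log-ms for `stroop`, `switch`, `mixing`; logit units for
#'   `ospan`, `toh`.
#' @param missingness named per-task probabilities that a participant's task
#'   is entirely absent.
#' @param ... overrides for the remaining elements (see the function body
#'   for names and defaults).
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 350,
                        age_distribution = c("bands", "uniform"),
                        trajectories = NULL,
                        missingness = c(stroop = 3 / 350, ospan = 16 / 350,
                                        switching = 17 / 350, toh = 2 / 350),
                        ...) {
  spec <- list(
    n_participants = n_participants,
    age_range = c(10, 86),
    age_distribution = match.arg(age_distribution),
    band_breaks = c(10, 18, 30, 50, 65, 87),
    band_weights = c(62, 60, 76, 74, 78),
    # per-band full-scale/verbal/performance IQ means and SDs
    iq_model = list(
      fsiq = list(mean = c(107.35, 107.45, 104.70, 110.18, 120.65),
                  sd = c(11.07, 10.75, 9.81, 11.83, 10.43)),
      viq = list(mean = c(105.74, 108.13, 103.05, 109.86, 120.14),
                 sd = c(10.07, 11.06, 9.82, 11.50, 11.52)),
      piq = list(mean = c(107.27, 104.70, 105.45, 110.18, 120.66),
                 sd = c(13.47, 12.18, 11.57, 13.12, 11.30)),
      ref_mean = 110, ref_sd = 12),
    ses_model = list(
      education = c(0.02, 0.10, 0.18, 0.26, 0.26, 0.18),
      income = c(0.08, 0.13, 0.14, 0.15, 0.17, 0.17, 0.16),
      occupation = c(0.04, 0.12, 0.02, 0.03, 0.23, 0.38, 0.18)),
    # baseline log RT (general slowing), intercept + slope on rescaled age u
    slowing = list(stroop_base = c(6.70, 0.35), switching_base = c(6.28, 0.30)),
    trial_sd = c(stroop = 0.15, switching = 0.20),
    accuracy = c(stroop = 0.97, switching = 0.95, condition_penalty = 0.02),
    # logistic models: intercept, per-unit load slope, on the latent
    ospan_model = list(intercept = 2.6, span_slope = 0.35),
    toh_model = list(intercept = 1.5, step_slope = 0.38),
    trajectories = list(
      stroop = list(degree = 2, coefs = c(-0.159, 0.145, -0.220),
                    person_sd = 0.065, iq_load = 0.016),
      ospan = list(degree = 2, coefs = c(-0.219, 1.620, -3.000),
                   person_sd = 0.70, iq_load = 0.35),
      switch = list(degree = 1, coefs = c(-0.400, 0.120),
                    person_sd = 0.130, iq_load = 0.005),
      mixing = list(degree = 1, coefs = c(-0.380, -0.180),
                    person_sd = 0.190, iq_load = 0.005),
      toh = list(degree = 3, coefs = c(-0.636, 8.239, -18.033, 10.075),
                 person_sd = 0.70, iq_load = 0.40)),
    missingness = missingness)
  if (!is.null(trajectories)) {
    spec$trajectories[names(trajectories)] <- trajectories
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown)) {
    stop("unknown cohort_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec[names(dots)] <- dots
  structure(spec, class = "cohort_spec")
}

# draw demographic + latent person-level variables for a cohort
draw_participants <- function(spec, seed) {
  with_seed(seed, {
    n <- spec$n_participants
    if (spec$age_distribution == "uniform") {
      age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
      band <- findInterval(age, spec$band_breaks[-length(spec$band_breaks)])
    } else {
      band <- sample.int(5L, n, replace = TRUE,
                         prob = spec$band_weights / sum(spec$band_weights))
      lo <- spec$band_breaks[band]
      hi <- pmin(spec$band_breaks[band + 1], spec$age_range[2] + 1)
      age <- stats::runif(n, lo, hi - 0.001)
    }
    iq <- spec$iq_model
    fsiq <- stats::rnorm(n, iq$fsiq$mean[band], iq$fsiq$sd[band])
    viq <- stats::rnorm(n, iq$viq$mean[band], iq$viq$sd[band])
    piq <- stats::rnorm(n, iq$piq$mean[band], iq$piq$sd[band])
    ses <- spec$ses_model
    educ <- sample.int(6L, n, replace = TRUE, prob = ses$education)
    inc <- sample.int(7L, n, replace = TRUE, prob = ses$income)
    occ <- sample.int(7L, n, replace = TRUE, prob = ses$occupation)

    u <- (age - spec$age_range[1]) / diff(spec$age_range)
    z_iq <- (fsiq - iq$ref_mean) / iq$ref_sd
    latents <- lapply(spec$trajectories, function(tr) {
      polyval_inc(tr$coefs, u) + tr$iq_load * z_iq +
        stats::rnorm(n, 0, tr$person_sd)
    })
    miss <- lapply(spec$missingness, function(p) stats::runif(n) < p)

    list(
      participants = data.frame(
        participant_id = sprintf("P%04d", seq_len(n)),
        age_years = round(age, 2), band = band,
        fsiq = round(fsiq, 1), viq = round(viq, 1), piq = round(piq, 1),
        education_code = educ, income_code = inc, occupation_code = occ,
        stringsAsFactors = FALSE),
      u = u, latents = latents, missing = miss)
  })
}

#' Simulate derived scores directly from the latent model
#'
#' Fast path for statistical experiments (model-selection recovery, power
#' and type-I-error studies): draws the same demographic and latent
#' person-level variables as the trial-level simulator, then produces the
#' derived scores directly -- response-time scores get a Gaussian sampling
#' error matching the trial counts of the designs, while span recall and
#' Tower of Hanoi outcomes are drawn from the same per-trial binomial models
#' the trial-level path uses.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return data.frame in the shape of [score_cohort()] output.
#' @export
simulate_scores <- function(spec, seed) {
  pp <- draw_participants(spec, seed)
  with_seed(derive_seed(seed, 1L), {
    n <- spec$n_participants
    lat <- pp$latents
    # sampling SD of a difference of condition log-RT means under the designs
    tsd <- spec$trial_sd
    se_stroop <- tsd[["stroop"]] * sqrt(1 / 47 + 1 / 47)
    se_switch <- tsd[["switching"]] * sqrt(1 / 60 + 1 / 60)
    se_mixing <- tsd[["switching"]] * sqrt(1 / 60 + 1 / 62)

    scores <- data.frame(
      participant_id = pp$participants$participant_id,
      age_years = pp$participants$age_years,
      fsiq = pp$participants$fsiq, viq = pp$participants$viq,
      piq = pp$participants$piq,
      ses_index = ses_index(pp$participants$education_code,
                            pp$participants$income_code,
                            pp$participants$occupation_code),
      stroop_effect = lat$stroop + stats::rnorm(n, 0, se_stroop),
      ospan_absolute = NA_integer_, ospan_partial = NA_integer_,
      switch_cost = lat$switch + stats::rnorm(n, 0, se_switch),
      mixing_cost = lat$mixing + stats::rnorm(n, 0, se_mixing),
      toh_score = NA_integer_, stringsAsFactors = FALSE)

    om <- spec$ospan_model
    absolute <- partial <- integer(n)
    for (s in 2:7) {
      p <- stats::plogis(om$intercept - om$span_slope * (s - 2) + lat$ospan)
      for (r in 1:3) {
        k <- stats::rbinom(n, s, p)
        partial <- partial + k
        absolute <- absolute + s * (k == s)
      }
    }
    scores$ospan_absolute <- absolute
    scores$ospan_partial <- partial

    tm <- spec$toh_model
    toh <- integer(n)
    for (s in 3:10) {
      p <- stats::plogis(tm$intercept - tm$step_slope * (s - 3) + lat$toh)
      toh <- toh + s * (stats::rbinom(n, 2, p))
    }
    scores$toh_score <- toh

    scores$stroop_effect[pp$missing$stroop] <- NA
    scores$ospan_absolute[pp$missing$ospan] <- NA
    scores$ospan_partial[pp$missing$ospan] <- NA
    scores$switch_cost[pp$missing$switching] <- NA
    scores$mixing_cost[pp$missing$switching] <- NA
    scores$toh_score[pp$missing$toh] <- NA
    scores
  })
}

#' Simulate a full trial-level cohort
#'
#' Generates, for every participant, the complete trial-level records of the
#' four task designs: pseudo-randomised Stroop sequences with log-normal
#' response times (incongruent trials shifted by the participant's latent
#' interference), alternating-runs switching blocks with additive switch and
#' mixing shifts on top of an age-dependent baseline, operation-span recall
#' with per-letter correct-in-position probabilities logistic in working
#' memory and span, and Tower of Hanoi trials with per-trial success
#' logistic in planning ability and required steps. Per-task missingness
#' removes whole participants from a task, as in attrition.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer master seed; all task substreams derive from it.
#' @param fresh_design if `TRUE` (default) every participant receives their
#'   own pseudo-randomised trial sequences; if `FALSE` one design per task
#'   is shared by the cohort, which is much faster and statistically
#'   equivalent for condition-mean scoring.
#' @return list with `participants`, trial tables `stroop`, `switching`,
#'   `ospan`, `toh`, and `truth` (the latent person-level variables, for
#'   parameter-recovery studies).
#' @export
simulate_cohort <- function(spec, seed, fresh_design = TRUE) {
  pp <- draw_participants(spec, seed)
  n <- spec$n_participants
  ids <- pp$participants$participant_id
  u <- pp$u
  lat <- pp$latents

  stroop <- with_seed(derive_seed(seed, 2L), {
    keep <- which(!pp$missing$stroop)
    designs <- if (fresh_design) {
      lapply(keep, function(i) generate_stroop_sequence(
        derive_seed(seed, 1000L + i)))
    } else {
      rep(list(generate_stroop_sequence(derive_seed(seed, 1000L))),
          length(keep))
    }
    designs <- lapply(designs, function(d) d[d$phase == "experimental", ])
    nt <- vapply(designs, nrow, 0L)
    d <- do.call(rbind, designs)
    pid <- rep(keep, nt)
    mu <- polyval_inc(spec$slowing$stroop_base, u[pid]) +
      (d$condition == "incongruent") * (-lat$stroop[pid])
    rt <- exp(mu + stats::rnorm(nrow(d), 0, spec$trial_sd[["stroop"]]))
    acc_p <- spec$accuracy[["stroop"]] -
      spec$accuracy[["condition_penalty"]] * (d$condition == "incongruent")
    data.frame(participant_id = ids[pid], trial_index = d$trial_index,
               condition = d$condition, word = d$word,
               print_color = d$print_color, rt_ms = round(rt, 1),
               accurate = stats::runif(nrow(d)) < acc_p,
               stringsAsFactors = FALSE)
  })

  switching <- with_seed(derive_seed(seed, 3L), {
    keep <- which(!pp$missing$switching)
    designs <- if (fresh_design) {
      lapply(keep, function(i) generate_switching_sequence(
        derive_seed(seed, 2000L + i)))
    } else {
      rep(list(generate_switching_sequence(derive_seed(seed, 2000L))),
          length(keep))
    }
    designs <- lapply(designs, function(d) d[!d$practice, ])
    nt <- vapply(designs, nrow, 0L)
    d <- do.call(rbind, designs)
    pid <- rep(keep, nt)
    base <- polyval_inc(spec$slowing$switching_base, u[pid])
    nonswitch_mu <- base - lat$mixing[pid]
    mu <- ifelse(d$phase != "mixed", base,
                 ifelse(is.na(d$condition) | d$condition == "nonswitch",
                        nonswitch_mu, nonswitch_mu - lat$switch[pid]))
    rt <- exp(mu + stats::rnorm(nrow(d), 0, spec$trial_sd[["switching"]]))
    timed_out <- rt >= 5000
    rt[timed_out] <- 5000
    acc_p <- spec$accuracy[["switching"]] -
      spec$accuracy[["condition_penalty"]] *
        (!is.na(d$condition) & d$condition == "switch")
    data.frame(participant_id = ids[pid], phase = d$phase, block = d$block,
               trial_index = d$trial_index, quadrant = d$quadrant,
               condition = d$condition, rt_ms = round(rt, 1),
               accurate = stats::runif(nrow(d)) < acc_p,
               timed_out = timed_out, stringsAsFactors = FALSE)
  })

  ospan <- with_seed(derive_seed(seed, 4L), {
    keep <- which(!pp$missing$ospan)
    om <- spec$ospan_model
    designs <- if (fresh_design) {
      lapply(keep, function(i) generate_ospan_design(
        derive_seed(seed, 3000L + i)))
    } else {
      rep(list(generate_ospan_design(derive_seed(seed, 3000L))), length(keep))
    }
    nt <- vapply(designs, nrow, 0L)
    d <- do.call(rbind, designs)
    pid <- rep(keep, nt)
    # per-letter correct-in-position draws, vectorized over the whole cohort
    letters_all <- strsplit(d$presented, "", fixed = TRUE)
    trial_of_letter <- rep(seq_len(nrow(d)), d$span)
    p_letter <- stats::plogis(om$intercept - om$span_slope * (d$span - 2) +
                              lat$ospan[pid])[trial_of_letter]
    letter_vec <- unlist(letters_all)
    hit <- stats::runif(length(letter_vec)) < p_letter
    out_vec <- letter_vec
    miss_idx <- which(!hit)
    if (length(miss_idx)) {
      blank <- stats::runif(length(miss_idx)) >= 2 / 3
      out_vec[miss_idx[blank]] <- "-"
      wrong <- miss_idx[!blank]
      # a wrong letter differs from the presented one in that position
      repl <- OSPAN_POOL[sample.int(12L, length(wrong), replace = TRUE)]
      clash <- repl == letter_vec[wrong]
      while (any(clash)) {
        repl[clash] <- OSPAN_POOL[sample.int(12L, sum(clash), replace = TRUE)]
        clash <- repl == letter_vec[wrong]
      }
      out_vec[wrong] <- repl
    }
    rec <- vapply(split(out_vec, trial_of_letter), paste, "", collapse = "")
    # maths accuracy summary, generated at or above the 85% criterion
    math_total <- d$span
    math_correct <- stats::rbinom(nrow(d), math_total, 0.93)
    low <- math_correct < ceiling(0.85 * math_total)
    math_correct[low] <- ceiling(0.85 * math_total[low])
    data.frame(participant_id = ids[pid], trial_index = d$trial_index,
               span = d$span, presented = d$presented,
               recalled = unname(rec[as.character(seq_len(nrow(d)))]),
               math_correct = math_correct, math_total = math_total,
               stringsAsFactors = FALSE)
  })

  toh <- with_seed(derive_seed(seed, 5L), {
    keep <- which(!pp$missing$toh)
    tm <- spec$toh_model
    designs <- if (fresh_design) {
      lapply(keep, function(i) generate_toh_problem_set(
        derive_seed(seed, 4000L + i)))
    } else {
      rep(list(generate_toh_problem_set(derive_seed(seed, 4000L))),
          length(keep))
    }
    designs <- lapply(designs, function(d) d[d$phase == "experimental", ])
    nt <- vapply(designs, nrow, 0L)
    d <- do.call(rbind, designs)
    pid <- rep(keep, nt)
    p <- stats::plogis(tm$intercept - tm$step_slope * (d$required_steps - 3) +
                       lat$toh[pid])
    perfect <- stats::runif(nrow(d)) < p
    errors <- ifelse(perfect, 0L, 1L + stats::rbinom(nrow(d), 3, 0.4))
    data.frame(participant_id = ids[pid], trial_index = d$trial_index,
               required_steps = d$required_steps, initial = d$initial,
               target = d$target, perfect = perfect, error_moves = errors,
               stringsAsFactors = FALSE)
  })

  list(participants = pp$participants, stroop = stroop, switching = switching,
       ospan = ospan, toh = toh,
       truth = list(u = u, latents = lat, missing = pp$missing, spec = spec,
                    seed = seed))
}

#' Simulate one participant's trial-level records
#'
#' Convenience wrapper around [simulate_cohort()] for a single participant.
#'
#' @param spec a [cohort_spec()] (its `n_participants` is ignored).
#' @param participant_seed integer seed for this participant.
#' @return the [simulate_cohort()] list, with one participant.
#' @export
simulate_participant <- function(spec, participant_seed) {
  spec$n_participants <- 1L
  spec$missingness[] <- 0
  simulate_cohort(spec, participant_seed)
}
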
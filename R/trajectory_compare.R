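#' Test whether two measures share a developmental trajectory
#'
#' Stacks two executive-function measures (each z-scored within its own
#' sample) into one dataset, rebuilds the shared-degree orthogonal age
#' polynomial on the stacked age vector, and compares (i) the model with only
#' the shared age terms against (ii) the model adding a group indicator and
#' group-by-age-term interactions, via a nested ANOVA. A significant
#' F-change means the two age trajectories differ in shape.
#'
#' Both measures must previously have been assigned the same best-fitting
#' polynomial degree; measures whose selected degrees differ already have
#' demonstrably different trajectories and are refused (a classed error of
#' condition `"ef_degree_mismatch"`), not given a numeric result.
#'
#' Participants contributing both measures appear once per measure and the
#' stacked observations are treated as independent; this ignores the
#' within-person correlation and is a documented limitation of the approach.
#'
#' @param measure_a,measure_b data.frames with columns `age_years` and
#'   `score` (rows with missing values dropped).
#' @param degree_a polynomial degree selected for measure A.
#' @param degree_b polynomial degree selected for measure B (default: same
#'   as `degree_a`).
#' @param labels optional length-2 character vector naming the measures.
#' @return Object of class `"ef_traj_comparison"`: `rss_delta`, `f_change`
#'   (statistic, df1, df2), `p`, `verdict` (`"different"` iff p < 0.05),
#'   the two model RSS values and the stacked sample size.
#' @export
compare_trajectories <- function(measure_a, measure_b, degree_a,
                                 degree_b = degree_a,
                                 labels = c("A", "B")) {
  if (degree_a != degree_b) {
    stop(structure(class = c("ef_degree_mismatch", "error", "condition"),
                   list(message = sprintf(
      paste0("measures '%s' (degree %d) and '%s' (degree %d) were selected ",
             "with different polynomial degrees; their age trajectories ",
             "already differ in form and are not directly comparable"),
      labels[1], degree_a, labels[2], degree_b), call = NULL)))
  }
  degree <- degree_a
  a <- measure_a[stats::complete.cases(measure_a[c("age_years", "score")]), ]
  b <- measure_b[stats::complete.cases(measure_b[c("age_years", "score")]), ]
  z <- c(scale(a$score)[, 1], scale(b$score)[, 1])
  ages <- c(a$age_years, b$age_years)
  grp <- factor(rep(1:2, c(nrow(a), nrow(b))))

  basis <- build_orthopoly(ages, degree)
  P <- basis$columns
  X1 <- cbind(1, P)
  g <- as.numeric(grp == levels(grp)[2])
  X2 <- cbind(X1, g, P * g)
  r1 <- qr.resid(qr(X1), z)
  r2 <- qr.resid(qr(X2), z)
  rss1 <- sum(r1^2)
  rss2 <- sum(r2^2)
  n <- length(z)
  df1 <- ncol(X2) - ncol(X1)
  df2 <- n - ncol(X2)
  f_stat <- (rss1 - rss2) / df1 / (rss2 / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  structure(list(measure_a = labels[1], measure_b = labels[2],
                 degree = degree, n = n,
                 rss_simple = rss1, rss_interaction = rss2,
                 rss_delta = rss1 - rss2,
                 f_change = list(statistic = f_stat, df1 = df1, df2 = df2),
                 p = p,
                 verdict = if (p < 0.05) "different" else "not_different"),
            class = "ef_traj_comparison")
}

#' @export
print.ef_traj_comparison <- function(x, ...) {
  cat(sprintf(
    "Trajectory comparison %s vs %s (shared degree %d, n = %d)\n",
    x$measure_a, x$measure_b, x$degree, x$n))
  cat(sprintf("  RSS delta = %.3f, F(%d, %d) = %.3f, p = %.3f -> %s\n",
              x$rss_delta, x$f_change$df1, x$f_change$df2,
              x$f_change$statistic, x$p, x$verdict))
  invisible(x)
}
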
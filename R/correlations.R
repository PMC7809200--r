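#' Raw and age-adjusted correlations among executive-function measures
#'
#' Pairwise-complete Pearson correlations among the five derived measures,
#' plus partial correlations controlling for age: each measure is first
#' residualized on its own best-fitting orthogonal age polynomial (degree
#' from the model-selection step), and the residuals are then correlated.
#' Two-sided p-values use `df = n - 2` for the raw correlations and
#' `df = n - 2 - q` for the partial correlations, where `q` is the larger of
#' the two measures' partialled age-term counts.
#'
#' @param scores data.frame as returned by [score_cohort()] (needs
#'   `age_years` and the measure columns).
#' @param degrees named integer vector giving each measure's selected
#'   polynomial degree, e.g. `c(stroop_effect = 2, ...)`.
#' @param measures character vector of measure columns to correlate.
#' @return Object of class `"ef_cormat"`: `measures`, matrices `r`, `p`,
#'   `n`, `partial_r`, `partial_p`, `partial_n` and the `degrees` used.
#' @export
ef_correlations <- function(scores, degrees,
                            measures = c("stroop_effect", "ospan_partial",
                                         "switch_cost", "mixing_cost",
                                         "toh_score")) {
  stopifnot(all(measures %in% names(scores)),
            all(measures %in% names(degrees)))
  k <- length(measures)
  m <- function() matrix(NA_real_, k, k, dimnames = list(measures, measures))
  r <- m(); p <- m(); nn <- m(); pr <- m(); pp <- m(); pn <- m()
  diag(r) <- 1; diag(pr) <- 1

  # age-residualized version of each measure, aligned to the score rows
  resid_cols <- lapply(measures, function(ms) {
    y <- scores[[ms]]
    ok <- !is.na(y) & !is.na(scores$age_years)
    out <- rep(NA_real_, nrow(scores))
    if (sum(ok) >= degrees[[ms]] + 2) {
      basis <- build_orthopoly(scores$age_years[ok], degrees[[ms]])
      out[ok] <- residualize(y[ok], basis$columns)
    }
    out
  })
  names(resid_cols) <- measures

  corr_cell <- function(x, y, extra_df = 0L) {
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L + extra_df) return(c(NA_real_, NA_real_, n))
    rv <- stats::cor(x[ok], y[ok])
    df <- n - 2L - extra_df
    tv <- rv * sqrt(df) / sqrt(1 - rv^2)
    c(rv, 2 * stats::pt(abs(tv), df, lower.tail = FALSE), n)
  }

  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      raw <- corr_cell(scores[[measures[i]]], scores[[measures[j]]])
      r[i, j] <- r[j, i] <- raw[1]
      p[i, j] <- p[j, i] <- raw[2]
      nn[i, j] <- nn[j, i] <- raw[3]
      q <- max(degrees[[measures[i]]], degrees[[measures[j]]])
      part <- corr_cell(resid_cols[[i]], resid_cols[[j]], extra_df = q)
      pr[i, j] <- pr[j, i] <- part[1]
      pp[i, j] <- pp[j, i] <- part[2]
      pn[i, j] <- pn[j, i] <- part[3]
    }
  }
  structure(list(measures = measures, r = r, p = p, n = nn,
                 partial_r = pr, partial_p = pp, partial_n = pn,
                 degrees = degrees[measures]),
            class = "ef_cormat")
}

sig_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Format a correlation matrix in report style
#'
#' Lower-triangle table with the raw Pearson correlation, significance
#' stars (*p < .05, **p < .01, ***p < .001) and the age-adjusted partial
#' correlation in parentheses.
#'
#' @param x an `"ef_cormat"`.
#' @return character matrix.
#' @export
format_cormat <- function(x) {
  k <- length(x$measures)
  out <- matrix("", k, k, dimnames = list(x$measures, x$measures))
  diag(out) <- "-"
  for (i in 2:k) {
    for (j in 1:(i - 1)) {
      out[i, j] <- sprintf("%.2f%s (%.2f%s)",
                           x$r[i, j], sig_stars(x$p[i, j]),
                           x$partial_r[i, j], sig_stars(x$partial_p[i, j]))
    }
  }
  out
}

#' @export
print.ef_cormat <- function(x, ...) {
  cat("Pearson correlations (age-adjusted partial correlations in parentheses)\n")
  print(format_cormat(x), quote = FALSE)
  cat("*p < .05, **p < .01, ***p < .001\n")
  invisible(x)
}
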
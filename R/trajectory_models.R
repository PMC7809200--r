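#' Sample-anchored orthonormal polynomial age basis
#'
#' Builds degree-1..3 orthogonal polynomial columns of age on the analysis
#' sample: each column sums to zero, the columns are pairwise orthogonal with
#' unit norm, and column `j` is a degree-`j` polynomial of age. The
#' recurrence constants are stored so the same polynomials can be evaluated
#' at arbitrary new ages (e.g. for plotting fitted trajectories on a fine
#' grid).
#'
#' @param ages numeric vector of ages (years).
#' @param degree integer 1--3.
#' @return Object of class `"ortho_poly_basis"` with elements `anchor_ages`,
#'   `degree`, `columns` (n x degree matrix) and `coefs` (recurrence
#'   constants for off-sample evaluation).
#' @export
build_orthopoly <- function(ages, degree) {
  stopifnot(degree %in% 1:3)
  if (length(unique(ages)) < degree + 1L) {
    stop(sprintf("need at least %d distinct ages for a degree-%d basis",
                 degree + 1L, degree), call. = FALSE)
  }
  P <- stats::poly(ages, degree = degree)
  structure(list(anchor_ages = ages, degree = degree,
                 columns = matrix(as.numeric(P), ncol = degree,
                                  dimnames = list(NULL, paste0("age", 1:degree))),
                 coefs = attr(P, "coefs")),
            class = "ortho_poly_basis")
}

#' Evaluate an orthogonal polynomial basis at new ages
#'
#' @param basis an [build_orthopoly()] object.
#' @param new_ages ages at which to evaluate the stored polynomials.
#' @return matrix `length(new_ages)` x `degree`.
#' @export
eval_orthopoly <- function(basis, new_ages) {
  stopifnot(inherits(basis, "ortho_poly_basis"))
  P <- stats::poly(new_ages, degree = basis$degree, coefs = basis$coefs)
  matrix(as.numeric(P), ncol = basis$degree,
         dimnames = list(NULL, paste0("age", seq_len(basis$degree))))
}

#' Fit an age-trajectory regression
#'
#' Ordinary least squares of an executive-function measure on orthogonal
#' polynomial age terms (degree 1--3) plus optional covariate columns
#' (typically full-scale IQ and the SES index). Rows with any missing value
#' are dropped (model-wise complete cases). Reported alongside the raw
#' coefficients are standardized betas (every predictor and the outcome
#' scaled to unit SD), the overall F test, the Gaussian log-likelihood
#' `-n/2 (log 2*pi + log(rss/n) + 1)`, and AIC/BIC with
#' `k = (number of coefficients) + 1` counting the residual variance.
#'
#' @param outcome numeric outcome vector.
#' @param ages numeric age vector, same length.
#' @param covariates optional numeric matrix/data.frame of covariate columns.
#' @param degree polynomial degree 1--3.
#' @return Object of class `"ef_fit"`: coefficients, standardized betas,
#'   `r_squared`, `f_overall` (statistic, df1, df2, p), `rss`, `loglik`,
#'   `aic`, `bic`, `k_params`, `n`, the basis, and the data actually used.
#' @export
fit_trajectory <- function(outcome, ages, covariates = NULL, degree) {
  cov_m <- prepare_covariates(covariates, length(outcome))
  keep <- stats::complete.cases(outcome, ages, cov_m)
  y <- outcome[keep]
  a <- ages[keep]
  cv <- if (is.null(cov_m)) NULL else cov_m[keep, , drop = FALSE]
  n <- length(y)

  basis <- build_orthopoly(a, degree)
  X <- cbind(`(Intercept)` = 1, basis$columns, cv)
  k_coef <- ncol(X)
  if (n <= k_coef) stop("not enough complete rows for the requested model", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < k_coef) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k_coef]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrX, y)
  fitted <- drop(X %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  df1 <- k_coef - 1L
  df2 <- n - k_coef
  f_stat <- (tss - rss) / df1 / (rss / df2)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k_params <- k_coef + 1L
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  beta_std <- coefs[-1] * sds / stats::sd(y)

  structure(list(
    degree = degree, n = n, k_coef = k_coef, k_params = k_params,
    coefficients = coefs, beta_std = beta_std,
    r_squared = r2,
    f_overall = list(statistic = f_stat, df1 = df1, df2 = df2,
                     p = stats::pf(f_stat, df1, df2, lower.tail = FALSE)),
    rss = rss, loglik = loglik,
    aic = 2 * k_params - 2 * loglik,
    bic = k_params * log(n) - 2 * loglik,
    basis = basis, fitted = fitted, residuals = res,
    covariate_means = if (is.null(cv)) NULL else colMeans(cv),
    covariate_names = if (is.null(cv)) NULL else colnames(cv),
    outcome = y, ages = a
  ), class = "ef_fit")
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  m <- as.matrix(covariates)
  if (ncol(m) == 0L) return(NULL)
  stopifnot(nrow(m) == n)
  if (is.null(colnames(m))) colnames(m) <- paste0("cov", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  m
}

#' @export
print.ef_fit <- function(x, ...) {
  cat(sprintf("Age-trajectory fit, degree %d (n = %d)\n", x$degree, x$n))
  cat(sprintf("  R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n", x$r_squared,
              x$f_overall$df1, x$f_overall$df2, x$f_overall$statistic,
              x$f_overall$p))
  cat(sprintf("  RSS = %.2f, logLik = %.2f, AIC = %.2f, BIC = %.2f (k = %d)\n",
              x$rss, x$loglik, x$aic, x$bic, x$k_params))
  cat("  standardized betas:\n")
  print(round(x$beta_std, 3))
  invisible(x)
}

#' Compare two nested trajectory fits
#'
#' Computes the change-F test, the likelihood-ratio chi-square, and the
#' AIC/BIC differences for two fits of the same outcome rows where the
#' simpler model's age terms are a subset of the complex model's.
#'
#' @param simple,complex `"ef_fit"` objects on identical rows, with
#'   `complex$degree > simple$degree`.
#' @return list of class `"ef_model_comparison"`: `f_change` (statistic,
#'   df1, df2, p), `lr_chisq` (statistic, df, p), `delta_aic`, `delta_bic`
#'   (complex minus simple).
#' @export
compare_nested <- function(simple, complex) {
  stopifnot(inherits(simple, "ef_fit"), inherits(complex, "ef_fit"))
  if (simple$n != complex$n) {
    stop("models were fit on different numbers of rows", call. = FALSE)
  }
  if (complex$degree <= simple$degree) {
    stop("`complex` must have higher polynomial degree than `simple`", call. = FALSE)
  }
  dk <- complex$k_coef - simple$k_coef
  df2 <- complex$n - complex$k_coef
  f_stat <- (simple$rss - complex$rss) / dk / (complex$rss / df2)
  lr <- max(0, 2 * (complex$loglik - simple$loglik))
  structure(list(
    f_change = list(statistic = f_stat, df1 = dk, df2 = df2,
                    p = stats::pf(f_stat, dk, df2, lower.tail = FALSE)),
    lr_chisq = list(statistic = lr, df = dk,
                    p = stats::pchisq(lr, dk, lower.tail = FALSE)),
    delta_aic = complex$aic - simple$aic,
    delta_bic = complex$bic - simple$bic,
    degrees = c(simple = simple$degree, complex = complex$degree)
  ), class = "ef_model_comparison")
}

#' Select the best-fitting polynomial degree
#'
#' Fits degree-1, -2 and -3 trajectories on the same model-wise complete rows
#' and chooses among them by a hierarchical majority vote over four
#' goodness-of-fit indices per nested comparison: the change-F p-value and
#' likelihood-ratio p-value (each favouring the complex model when < 0.05),
#' and AIC and BIC (each favouring the model with the lower value). Degree 1
#' is compared with degree 2 first; the winner is then compared with degree
#' 3. A 2--2 tie goes to the simpler model (parsimony).
#'
#' @inheritParams fit_trajectory
#' @return Object of class `"ef_selection"`: `chosen_degree`, the three
#'   `fits`, the `comparisons`, a `votes` table and an `audit_trail`
#'   character vector reproducing the decision.
#' @export
select_best_model <- function(outcome, ages, covariates = NULL) {
  cov_m <- prepare_covariates(covariates, length(outcome))
  keep <- stats::complete.cases(outcome, ages, cov_m)
  y <- outcome[keep]
  a <- ages[keep]
  cv <- if (is.null(cov_m)) NULL else cov_m[keep, , drop = FALSE]

  fits <- lapply(1:3, function(d) fit_trajectory(y, a, cv, degree = d))
  names(fits) <- paste0("degree", 1:3)

  votes <- list()
  audit <- character()
  vote_one <- function(simple, complex) {
    cmp <- compare_nested(simple, complex)
    v <- c(f_change_p = unname(cmp$f_change$p < 0.05),
           lr_p = unname(cmp$lr_chisq$p < 0.05),
           aic = unname(cmp$delta_aic < 0),
           bic = unname(cmp$delta_bic < 0))
    list(cmp = cmp, votes = v, complex_wins = sum(v) >= 3L)
  }

  current <- 1L
  comparisons <- list()
  s12 <- vote_one(fits[[current]], fits[[2L]])
  comparisons[["1v2"]] <- s12$cmp
  votes[["1v2"]] <- s12$votes
  audit <- c(audit, sprintf(
    "degree 1 vs 2: %d/4 indices favour the quadratic -> keep degree %d",
    sum(s12$votes), if (s12$complex_wins) 2L else 1L))
  if (s12$complex_wins) current <- 2L

  sx3 <- vote_one(fits[[current]], fits[[3L]])
  comparisons[[paste0(current, "v3")]] <- sx3$cmp
  votes[[paste0(current, "v3")]] <- sx3$votes
  audit <- c(audit, sprintf(
    "degree %d vs 3: %d/4 indices favour the cubic -> keep degree %d",
    current, sum(sx3$votes), if (sx3$complex_wins) 3L else current))
  if (sx3$complex_wins) current <- 3L

  structure(list(chosen_degree = current, fits = fits,
                 comparisons = comparisons, votes = votes,
                 audit_trail = audit, n = fits[[1]]$n),
            class = "ef_selection")
}

#' @export
print.ef_selection <- function(x, ...) {
  cat(sprintf("Best-fitting age polynomial: degree %d (n = %d)\n",
              x$chosen_degree, x$n))
  for (line in x$audit_trail) cat(" ", line, "\n")
  invisible(x)
}

#' Residualize an outcome on a predictor matrix
#'
#' Ordinary least-squares residuals of `outcome` on `predictors` plus an
#' intercept. The residuals sum to zero and are orthogonal to every
#' predictor column. Used both for covariate adjustment of trajectory plots
#' (IQ/SES removed) and for age adjustment in the partial correlations.
#'
#' @param outcome numeric vector (no missing values).
#' @param predictors numeric matrix/data.frame, full column rank.
#' @return numeric vector of residuals.
#' @export
residualize <- function(outcome, predictors) {
  X <- cbind(1, as.matrix(predictors))
  storage.mode(X) <- "double"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("predictor matrix is rank deficient", call. = FALSE)
  drop(qr.resid(qrX, outcome))
}

#' Predicted trajectory curve at new ages
#'
#' Evaluates a fitted trajectory at arbitrary ages with covariates held at
#' their sample means (or at supplied values). With no covariates in the
#' fit, evaluating at the anchor ages reproduces the in-sample fitted values
#' exactly.
#'
#' @param fit an `"ef_fit"`.
#' @param new_ages ages at which to evaluate; ages outside the anchor range
#'   trigger an extrapolation warning.
#' @param covariate_values optional named vector fixing each covariate;
#'   defaults to the sample means.
#' @return numeric vector of predicted outcome values.
#' @export
predict_curve <- function(fit, new_ages, covariate_values = NULL) {
  stopifnot(inherits(fit, "ef_fit"))
  rng <- range(fit$basis$anchor_ages)
  if (any(new_ages < rng[1] | new_ages > rng[2])) {
    warning("predicting outside the anchor age range (extrapolation)", call. = FALSE)
  }
  Z <- eval_orthopoly(fit$basis, new_ages)
  b <- fit$coefficients
  pred <- b[1] + drop(Z %*% b[1 + seq_len(fit$degree)])
  if (!is.null(fit$covariate_names)) {
    cv <- fit$covariate_means
    if (!is.null(covariate_values)) {
      if (is.null(names(covariate_values)) &&
          length(covariate_values) == length(cv)) {
        cv[] <- covariate_values
      } else {
        cv[names(covariate_values)] <- covariate_values
      }
    }
    pred <- pred + sum(b[fit$covariate_names] * cv)
  }
  pred
}
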
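# Covariate-adjusted differential analysis: z-standardization, per-feature
# linear models y ~ DD + sex + BACS + BAI + outcome, pairwise outcome-group
# contrasts with Benjamini-Hochberg correction, and the cohort covariate
# comparison tests (ANOVA / chi-square).

#' Z-standardize a numeric vector
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @return Vector with mean 0 and sample SD 1.
#' @export
standardize <- function(values) {
  if (sum(is.finite(values)) < 2) stop("need at least 2 finite values")
  s <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (values - mean(values, na.rm = TRUE)) / s
}

#' Fit the covariate-adjusted model for one feature
#'
#' Ordinary least squares of a (standardized) feature on depression diagnosis,
#' sex, cognition, anxiety, and the 3-level outcome, with the remitted group
#' as the reference level (all reported contrasts are relative to remitted).
#' Sex is coded female = 0, male = 1.
#'
#' @param y Numeric response, one value per participant (standardize first
#'   with [standardize()] to obtain effect sizes in SD units).
#' @param covariates Data frame with columns `DD` (0/1), `sex`
#'   (factor female/male or 0/1), `BACS`, `BAI`, `outcome` (factor with levels
#'   among converted/remitted/maintained).
#' @return The fitted `lm` object.
#' @export
fit_feature_model <- function(y, covariates) {
  req <- c("DD", "sex", "BACS", "BAI", "outcome")
  missing_cols <- setdiff(req, names(covariates))
  if (length(missing_cols)) stop("missing covariate columns: ", paste(missing_cols, collapse = ", "))
  df <- covariates[req]
  df$outcome <- stats::relevel(factor(df$outcome), ref = "remitted")
  if (is.factor(df$sex) || is.character(df$sex)) {
    df$sex <- as.integer(df$sex == "male")
  }
  df$y <- y
  keep <- stats::complete.cases(df)
  if (sum(!keep) > 0) message(sum(!keep), " row(s) dropped by listwise deletion")
  df <- df[keep, , drop = FALSE]
  if (nlevels(droplevels(df$outcome)) < 2) stop("outcome must have at least 2 observed levels")
  n_par <- 5 + nlevels(droplevels(df$outcome)) - 1
  if (nrow(df) <= n_par) stop("n must exceed the number of model parameters (", n_par, ")")
  fit <- stats::lm(y ~ DD + sex + BACS + BAI + outcome, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ", paste(bad, collapse = ", "))
  }
  fit
}

#' Pairwise outcome-group contrasts from a fitted feature model
#'
#' Builds the three pairwise contrasts (converted - remitted, maintained -
#' remitted, converted - maintained) as linear combinations of the model
#' coefficients, with standard errors propagated through the coefficient
#' covariance matrix and t tests on the residual degrees of freedom.
#'
#' @param fit An `lm` from [fit_feature_model()].
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `contrast`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `t`, `p`.
#' @export
outcome_contrasts <- function(fit, level = 0.95) {
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  need <- c("outcomeconverted", "outcomemaintained")
  if (!all(need %in% names(beta))) {
    stop("fit must contain both outcome dummies (reference = remitted)")
  }
  L <- matrix(0, nrow = 3, ncol = length(beta),
              dimnames = list(c("converted-remitted", "maintained-remitted",
                                "converted-maintained"), names(beta)))
  L["converted-remitted", "outcomeconverted"] <- 1
  L["maintained-remitted", "outcomemaintained"] <- 1
  L["converted-maintained", c("outcomeconverted", "outcomemaintained")] <- c(1, -1)
  est <- drop(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  df <- stats::df.residual(fit)
  tval <- est / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  crit <- stats::qt(1 - (1 - level) / 2, df)
  data.frame(contrast = rownames(L), estimate = est, se = se,
             ci_low = est - crit * se, ci_high = est + crit * se,
             t = tval, p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. `family_size` allows adjusting a subset of p-values
#' against a larger family (the default family in this pipeline is the set of
#' features within one family - 4 linguistic or 5 acoustic - within each
#' contrast).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param family_size Total number of tests in the family (default
#'   `length(pvalues)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvalues, family_size = length(pvalues)) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (family_size < length(pvalues)) stop("family_size must be >= length(pvalues)")
  stats::p.adjust(pvalues, method = "BH", n = family_size)
}

#' Differential analysis of a feature family
#'
#' Standardizes each feature, fits the covariate-adjusted model, extracts the
#' three pairwise outcome contrasts, and applies Benjamini-Hochberg correction
#' across the features of the family within each contrast (the default
#' family mode, which reproduces the printed adjusted values; alternative
#' modes pool across contrasts or globally).
#'
#' @param feature_table Data frame containing the feature columns and the
#'   covariate columns `DD`, `sex`, `BACS`, `BAI`, `outcome`.
#' @param features Character vector of feature column names forming one
#'   family.
#' @param family Label stored in the output (for example `"linguistic"`).
#' @param fdr_mode `"within_contrast"` (default), `"within_feature"`, or
#'   `"global"`.
#' @return Data frame with one row per feature x contrast: `family`,
#'   `feature`, `contrast`, `estimate`, `se`, `ci_low`, `ci_high`, `t`, `p`,
#'   `p_adj`.
#' @export
differential_analysis <- function(feature_table, features, family = "features",
                                  fdr_mode = c("within_contrast", "within_feature", "global")) {
  fdr_mode <- match.arg(fdr_mode)
  missing_cols <- setdiff(features, names(feature_table))
  if (length(missing_cols)) stop("feature columns not found: ", paste(missing_cols, collapse = ", "))
  rows <- lapply(features, function(f) {
    fit <- fit_feature_model(standardize(feature_table[[f]]), feature_table)
    cbind(family = family, feature = f, outcome_contrasts(fit),
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- switch(fdr_mode,
    within_contrast = stats::ave(res$p, res$contrast, FUN = bh_adjust),
    within_feature = stats::ave(res$p, res$feature, FUN = bh_adjust),
    global = bh_adjust(res$p)
  )
  res
}

#' One-way ANOVA from per-group summary statistics
#'
#' Computes the classical one-way ANOVA F test from group sizes, means, and
#' SDs alone - algebraically identical to the raw-data ANOVA - so printed
#' summary tables can be re-tested without the raw values.
#'
#' @param n Integer vector of group sizes.
#' @param means Group means.
#' @param sds Group sample SDs.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(n, means, sds) {
  stopifnot(length(n) == length(means), length(n) == length(sds))
  if (length(n) < 2 || any(n < 2)) stop("need at least 2 groups with at least 2 members each")
  N <- sum(n)
  k <- length(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, df1 = k - 1, df2 = N - k,
       p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

#' Cohort covariate comparison tests
#'
#' One-way ANOVA across outcome groups for each continuous covariate and a
#' Pearson chi-square test (no continuity correction) for each categorical
#' covariate, mirroring the usual cohort demographics table.
#'
#' @param cohort Data frame with an `outcome` column.
#' @param continuous Character vector of continuous covariate columns.
#' @param categorical Character vector of categorical covariate columns.
#' @return Data frame with columns `covariate`, `test`, `statistic`, `p`.
#' @export
cohort_covariate_tests <- function(cohort,
                                   continuous = c("BACS", "BAI"),
                                   categorical = c("sex", "DD")) {
  grp <- factor(cohort$outcome)
  if (nlevels(droplevels(grp)) < 2 || any(table(droplevels(grp)) < 2)) {
    stop("need at least 2 groups with at least 2 members each")
  }
  rows <- list()
  for (v in continuous) {
    a <- stats::anova(stats::lm(cohort[[v]] ~ grp))
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = v, test = "anova", statistic = a$`F value`[1], p = a$`Pr(>F)`[1],
      stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    tab <- table(cohort[[v]], grp)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (any(dim(tab) < 2)) stop("degenerate contingency table for '", v, "'")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = v, test = "chi-square", statistic = unname(ct$statistic),
      p = ct$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pearson chi-square test p-value from a contingency table
#'
#' Convenience wrapper (no continuity correction) for recomputing printed
#' contingency-table tests.
#'
#' @param counts Matrix of counts (categories x groups).
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_from_counts <- function(counts) {
  ct <- suppressWarnings(stats::chisq.test(as.matrix(counts), correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}
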
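#' Covariate-adjusted two-group comparison (ANCOVA)
#'
#' Models a continuous outcome on the binary group plus covariates
#' (age, sex and intracranial volume by default) with a linear model and
#' reports the group term's partial F test — the covariate-adjusted
#' analogue of the one-way ANOVA. Incomplete rows are dropped listwise
#' and the n actually used is reported.
#'
#' @param table Cohort data.frame.
#' @param outcome Name of a continuous outcome column.
#' @param group Name of a binary (0/1) group column.
#' @param covariates Character vector of covariate columns; may be
#'   empty, in which case the test reduces to a plain one-way ANOVA.
#' @return A one-row `data.frame` (a "stat result"): `comparison`,
#'   `effect` (adjusted group-mean difference, group 1 minus group 0),
#'   `statistic` (F), `p_raw`, `p_adjusted` (NA until a correction is
#'   applied), `n`, `family`.
#' @export
adjusted_group_compare <- function(table, outcome, group,
                                   covariates = c("age", "sex", "icv")) {
  cols <- c(outcome, group, covariates)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- table[stats::complete.cases(table[cols]), cols, drop = FALSE]
  if (!all(d[[group]] %in% c(0, 1))) stop(group, " must be binary 0/1")
  if (min(table(factor(d[[group]], levels = c(0, 1)))) < 2L)
    stop("need >= 2 subjects per group")
  if (stats::sd(d[[outcome]]) == 0) stop("constant outcome")
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f1 <- stats::as.formula(paste(outcome, "~", rhs0, "+", group))
  f0 <- stats::as.formula(paste(outcome, "~", rhs0))
  fit1 <- stats::lm(f1, data = d)
  fit0 <- stats::lm(f0, data = d)
  a <- stats::anova(fit0, fit1)
  Fv <- a$F[2]
  p <- a$`Pr(>F)`[2]
  if (is.na(Fv)) { Fv <- 0; p <- 1 }   # group adds nothing (zero extra SS)
  data.frame(comparison = paste0(group, " -> ", outcome),
             effect = unname(stats::coef(fit1)[group]),
             statistic = Fv, p_raw = p, p_adjusted = NA_real_,
             n = nrow(d), family = NA_character_,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted Spearman rank correlation
#'
#' Rank-transforms both variables (midranks for ties), regresses the
#' configured covariates out of each rank vector, and reports the
#' Pearson correlation of the residuals — a partial Spearman
#' correlation. With no covariates this is exactly the classical
#' Spearman coefficient. The p value uses the t approximation with
#' n - 2 - k degrees of freedom (k covariates).
#'
#' @param table Cohort data.frame.
#' @param x,y Names of continuous/ordinal columns.
#' @param covariates Covariate column names; may be empty.
#' @return One-row stat-result `data.frame` with `effect` = partial
#'   Spearman r.
#' @export
rank_correlation <- function(table, x, y,
                             covariates = c("age", "sex", "icv")) {
  cols <- c(x, y, covariates)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- table[stats::complete.cases(table[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < 4L) stop("need >= 4 complete rows")
  rx <- rank(d[[x]]); ry <- rank(d[[y]])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant variable after listwise deletion")
  k <- length(covariates)
  if (k) {
    # covariates are rank-transformed too, so the partialing is linear on
    # the rank scale throughout
    X <- apply(as.matrix(d[covariates]), 2, rank)
    rx <- stats::lm.fit(cbind(1, X), rx)$residuals
    ry <- stats::lm.fit(cbind(1, X), ry)$residuals
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(comparison = paste0(x, " ~ ", y),
             effect = r, statistic = tstat, p_raw = p,
             p_adjusted = NA_real_, n = n, family = NA_character_,
             stringsAsFactors = FALSE)
}

#' Chi-square test of association for two binary variables
#'
#' Pearson chi-square on the 2x2 contingency table, without Yates
#' continuity correction by default.
#'
#' @param table Cohort data.frame.
#' @param a,b Names of binary columns.
#' @param correct Apply the continuity correction (default FALSE).
#' @return One-row stat-result `data.frame`; `effect` is the difference
#'   in proportions of `b` between the two levels of `a`.
#' @export
chi_square <- function(table, a, b, correct = FALSE) {
  missing_cols <- setdiff(c(a, b), names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- table[stats::complete.cases(table[c(a, b)]), c(a, b)]
  ct <- base::table(factor(d[[a]], levels = c(0, 1)),
                    factor(d[[b]], levels = c(0, 1)))
  if (any(rowSums(ct) == 0) || any(colSums(ct) == 0))
    stop("degenerate margin in 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(ct, correct = correct))
  pr <- ct[, 2] / rowSums(ct)
  data.frame(comparison = paste0(a, " x ", b),
             effect = unname(pr[2] - pr[1]),
             statistic = unname(ht$statistic), p_raw = ht$p.value,
             p_adjusted = NA_real_, n = nrow(d), family = NA_character_,
             stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies each raw p value by the family size m and caps at 1;
#' order is preserved and the map is monotone.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @param m Family size; defaults to `length(pvals)`.
#' @return Adjusted p values, same order as the input.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  pmin(1, pvals * m)
}

#' Intraclass correlation for rater consistency
#'
#' Two-way mixed-effects, absolute-agreement, single-rater ICC
#' (ICC(A,1)): the statistic for intra-observer consistency of repeated
#' measurements. Computed from the two-way ANOVA mean squares
#' (subjects x raters).
#'
#' @param measure1,measure2 Equal-length numeric vectors (>= 3) of the
#'   two measurement sessions.
#' @return ICC in `[-1, 1]`.
#' @export
icc_consistency <- function(measure1, measure2) {
  if (length(measure1) != length(measure2)) stop("unequal lengths")
  n <- length(measure1)
  if (n < 3L) stop("need >= 3 paired measurements")
  Y <- cbind(measure1, measure2)
  k <- 2L
  grand <- mean(Y)
  if (sum((Y - grand)^2) == 0) stop("zero total variance")
  msr <- k * sum((rowMeans(Y) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(Y) - grand)^2) / (k - 1)
  sse <- sum((Y - grand)^2) - k * sum((rowMeans(Y) - grand)^2) -
    n * sum((colMeans(Y) - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

.rf_cols <- c("hypertension", "diabetes", "hyperlipidemia", "smoking")
.diam_cols <- c("ica", "ba", "aca", "mca", "pca")
.rf_outcomes <- c("dm_median", "vti_median", "vl_median", "lsa_count")
.diam_outcomes <- c("lsa_count", "dm_mean", "dm_median", "vti_mean",
                    "vti_median", "vl_mean", "vl_median")

#' Run the full cohort analysis grid
#'
#' Executes the standard comparison grid: every vascular risk factor
#' against the median morphometry summaries and LSA count via
#' covariate-adjusted ANCOVA, and every major-artery diameter against
#' count and mean/median summaries via partial Spearman correlation.
#' Bonferroni correction is applied within each of the two families and
#' the family label is recorded with every result.
#'
#' @param table Cohort data.frame with demographics (`age`, `sex`,
#'   `icv`), binary risk factors, artery diameters and per-subject
#'   morphometry summary columns.
#' @param covariates Adjustment covariates for both families.
#' @return data.frame of stat results, one row per comparison, with
#'   `p_adjusted` filled in.
#' @export
run_full_analysis <- function(table, covariates = c("age", "sex", "icv")) {
  required <- c(covariates, .rf_cols, .diam_cols, .rf_outcomes, .diam_outcomes)
  missing_cols <- setdiff(unique(required), names(table))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  rf <- do.call(rbind, lapply(.rf_cols, function(g)
    do.call(rbind, lapply(.rf_outcomes, function(oc)
      adjusted_group_compare(table, oc, g, covariates)))))
  rf$family <- "risk_factor_anova"
  rf$p_adjusted <- bonferroni(rf$p_raw)
  dm <- do.call(rbind, lapply(.diam_cols, function(a)
    do.call(rbind, lapply(.diam_outcomes, function(oc)
      rank_correlation(table, a, oc, covariates)))))
  dm$family <- "diameter_spearman"
  dm$p_adjusted <- bonferroni(dm$p_raw)
  out <- rbind(rf, dm)
  rownames(out) <- NULL
  out
}
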
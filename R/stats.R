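# Cohort-level inference: univariate group tests with normality-driven
# test selection, summary-from-table t-tests, stepwise-AIC logistic models
# (morphology-only versus joint) and random-forest Gini importance.

#' Univariate group comparisons with automatic test selection
#'
#' Continuous features: Shapiro-Wilk in each group at `shapiro_alpha`; if
#' both groups are compatible with normality, a pooled-variance two-sided
#' Student t-test (Welch behind `welch = TRUE`), otherwise a two-sided
#' Mann-Whitney-Wilcoxon test (normal approximation with tie correction
#' for n > 20, exact otherwise). Categorical features: chi-squared on the
#' contingency table, without continuity correction unless
#' `yates = TRUE`. Summaries follow the reporting convention: mean +/- SD
#' for normal, median (min-max) otherwise, count (%) for categorical.
#'
#' @param cohort data.frame with a two-level `group_col` and feature
#'   columns
#' @param features character vector of feature columns (default: all
#'   except `subject_id` and the group column)
#' @param group_col group column name
#' @param alpha significance level flagging candidate risk factors
#' @param shapiro_alpha level of the per-group normality gate
#' @param welch use Welch instead of pooled-variance t
#' @param yates apply the continuity correction to chi-squared
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (default "none", matching per-test alpha)
#' @return data.frame of class `laa_test_results`: feature, type,
#'   test_used, statistic, p_value, per-group summaries, significant
#' @export
univariate_tests <- function(cohort, features = NULL, group_col = "group",
                             alpha = 0.05, shapiro_alpha = 0.05,
                             welch = FALSE, yates = FALSE,
                             p_adjust = "none") {
  cohort <- validate_cohort_table(as.data.frame(cohort), group_col)
  g <- cohort[[group_col]]
  if (is.null(features)) {
    features <- setdiff(names(cohort), c("subject_id", group_col))
  }
  rows <- lapply(features, function(fe) {
    x <- cohort[[fe]]
    if (is.numeric(x)) {
      x1 <- x[g == levels(g)[1] & !is.na(x)]
      x2 <- x[g == levels(g)[2] & !is.na(x)]
      if (length(x1) < 3 || length(x2) < 3) {
        return(NULL)
      }
      if (sd(x1) == 0 && sd(x2) == 0) {
        warning("constant feature skipped: ", fe, call. = FALSE)
        return(NULL)
      }
      normal <- sd(x1) > 0 && sd(x2) > 0 &&
        shapiro.test(x1)$p.value > shapiro_alpha &&
        shapiro.test(x2)$p.value > shapiro_alpha
      if (normal) {
        tt <- t.test(x1, x2, var.equal = !welch)
        data.frame(feature = fe, type = "continuous-normal",
                   test_used = if (welch) "welch_t" else "student_t",
                   statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   summary_1 = sprintf("%.2f ± %.2f", mean(x1), sd(x1)),
                   summary_2 = sprintf("%.2f ± %.2f", mean(x2), sd(x2)))
      } else {
        n <- length(x1) + length(x2)
        wt <- suppressWarnings(
          wilcox.test(x1, x2, exact = n <= 20 && !any(duplicated(c(x1, x2)))))
        data.frame(feature = fe, type = "continuous-nonnormal",
                   test_used = "mann_whitney",
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value,
                   summary_1 = sprintf("%.2f (%.2f-%.2f)", median(x1),
                                       min(x1), max(x1)),
                   summary_2 = sprintf("%.2f (%.2f-%.2f)", median(x2),
                                       min(x2), max(x2)))
      }
    } else {
      tab <- table(factor(x), g)
      if (nrow(tab) < 2) {
        warning("constant feature skipped: ", fe, call. = FALSE)
        return(NULL)
      }
      ct <- suppressWarnings(chisq.test(tab, correct = yates))
      pct <- function(col) paste(sprintf("%d (%.1f%%)", tab[, col],
                                         100 * tab[, col] / sum(tab[, col])),
                                 collapse = ", ")
      data.frame(feature = fe, type = "categorical",
                 test_used = "chi_squared",
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 summary_1 = pct(1), summary_2 = pct(2))
    }
  })
  out <- do.call(rbind, rows)
  out$p_value <- p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  class(out) <- c("laa_test_results", "data.frame")
  attr(out, "group_levels") <- levels(g)
  out
}

#' Pooled-variance two-sided t-test from summary statistics
#'
#' For checking printed group rows (mean +/- SD with group sizes) without
#' subject-level data.
#'
#' @param mean1,sd1,n1 first group summary
#' @param mean2,sd2,n2 second group summary
#' @return named vector `c(t, df, p)`
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Stepwise-AIC logistic regression
#'
#' Binomial-logit model of the binary group label on the candidate
#' features; bidirectional stepwise search minimising AIC, starting from
#' the full candidate model.
#'
#' @param cohort data.frame with `group_col` and the candidates, no
#'   missing values among them
#' @param candidate_features character vector of feature columns
#' @param group_col group column (two levels; second level is the event)
#' @param direction passed to [stats::step()] (default "both")
#' @return list of class `laa_model_report`: `selected`, `coefficients`,
#'   `aic`, `model`, `separation` flag
#' @export
stepwise_logistic <- function(cohort, candidate_features,
                              group_col = "group", direction = "both") {
  cohort <- validate_cohort_table(as.data.frame(cohort), group_col)
  dat <- cohort[, c(group_col, candidate_features), drop = FALSE]
  if (!all(complete.cases(dat))) {
    stop("missing values among candidate features", call. = FALSE)
  }
  dat$.y <- as.integer(dat[[group_col]] == levels(dat[[group_col]])[2])
  rhs <- paste(sprintf("`%s`", candidate_features), collapse = " + ")
  full <- suppressWarnings(
    glm(as.formula(paste(".y ~", rhs)), family = binomial(), data = dat))
  scope <- list(lower = .y ~ 1, upper = stats::formula(full))
  fit <- suppressWarnings(step(full, scope = scope, direction = direction,
                               trace = 0))
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) &&
    max(abs(coef(fit)[-1]), 0) > 15
  selected <- setdiff(all.vars(stats::formula(fit)), ".y")
  structure(list(selected = selected, coefficients = coef(fit),
                 aic = AIC(fit), model = fit, separation = separation,
                 direction = direction),
            class = "laa_model_report")
}

#' @export
print.laa_model_report <- function(x, ...) {
  cat("stepwise logistic model: AIC", round(x$aic, 2), "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected,
                                                   collapse = ", ") else
    "(intercept only)", "\n")
  if (isTRUE(x$separation)) {
    cat("  WARNING: quasi-separation; coefficients not interpretable\n")
  }
  if (!is.null(x$rf_accuracy)) {
    cat("  random forest OOB accuracy:", round(x$rf_accuracy, 3), "\n")
  }
  invisible(x)
}

#' Morphology-only versus joint morpho-haemodynamic model comparison
#'
#' Fits a stepwise logistic model on the morphological candidates alone
#' and on morphological plus haemodynamic candidates, on the same
#' subjects, and reports both AICs and their difference. Features listed
#' in both blocks are de-duplicated with a warning.
#'
#' @param cohort cohort table
#' @param morph_features,haemo_features candidate feature names
#' @param group_col group column
#' @return list of class `laa_joint_comparison`: `morph`, `joint`
#'   (both `laa_model_report`s), `aic_morph`, `aic_joint`, `delta_aic`
#' @export
joint_model_comparison <- function(cohort, morph_features, haemo_features,
                                   group_col = "group") {
  dup <- intersect(morph_features, haemo_features)
  if (length(dup)) {
    warning("features in both blocks de-duplicated: ",
            paste(dup, collapse = ", "), call. = FALSE)
    haemo_features <- setdiff(haemo_features, morph_features)
  }
  dat <- as.data.frame(cohort)
  need <- c(morph_features, haemo_features)
  keep <- complete.cases(dat[, need, drop = FALSE])
  if (!all(keep)) {
    stop("subject sets differ between feature blocks (missing values)",
         call. = FALSE)
  }
  m1 <- stepwise_logistic(dat, morph_features, group_col)
  m2 <- stepwise_logistic(dat, c(morph_features, haemo_features), group_col)
  structure(list(morph = m1, joint = m2, aic_morph = m1$aic,
                 aic_joint = m2$aic, delta_aic = m2$aic - m1$aic),
            class = "laa_joint_comparison")
}

#' @export
print.laa_joint_comparison <- function(x, ...) {
  cat(sprintf("AIC morphology-only %.2f vs joint %.2f (delta %.2f)\n",
              x$aic_morph, x$aic_joint, x$delta_aic))
  invisible(x)
}

#' Random-forest classification with Gini importance
#'
#' Classification forest on the binary group label with the study's
#' hyperparameters (500 trees, 4 variables sampled per split, at most 90
#' terminal nodes). Importance is the mean decrease in Gini impurity;
#' accuracy is out-of-bag.
#'
#' @param cohort cohort table
#' @param features feature columns (character features are converted to
#'   factors)
#' @param group_col group column
#' @param ntree,mtry,maxnodes forest hyperparameters
#' @param seed integer seed for the forest's bootstrap
#' @return list of class `laa_model_report` with `rf_importances`
#'   (named, decreasing), `rf_accuracy` (OOB), `model`
#' @export
random_forest_importance <- function(cohort, features, group_col = "group",
                                     ntree = 500L, mtry = 4L,
                                     maxnodes = 90L, seed = 1L) {
  cohort <- validate_cohort_table(as.data.frame(cohort), group_col)
  if (nrow(cohort) < 10) stop("need at least 10 subjects", call. = FALSE)
  dat <- cohort[, features, drop = FALSE]
  for (j in seq_along(dat)) {
    if (is.character(dat[[j]])) dat[[j]] <- factor(dat[[j]])
  }
  y <- cohort[[group_col]]
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = dat, y = y, ntree = ntree, mtry = min(mtry, ncol(dat)),
    maxnodes = min(maxnodes, nrow(dat)))
  imp <- sort(rf$importance[, "MeanDecreaseGini"], decreasing = TRUE)
  acc <- 1 - unname(rf$err.rate[ntree, "OOB"])
  structure(list(rf_importances = imp, rf_accuracy = acc, model = rf,
                 selected = names(imp), aic = NA_real_,
                 coefficients = NULL),
            class = "laa_model_report")
}
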
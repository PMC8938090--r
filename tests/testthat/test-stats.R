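# Univariate test selection, summary t-tests, stepwise-AIC logistic
# modelling and the random forest.

make_cohort_df <- function(n1 = 38, n2 = 33, shift = 0, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", 1:(n1 + n2)),
    group = rep(c("control", "case"), c(n1, n2)),
    gauss = c(rnorm(n1), rnorm(n2, mean = shift)),
    skewed = exp(c(rnorm(n1), rnorm(n2, mean = shift))),
    cat = sample(c("yes", "no"), n1 + n2, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("test selection follows the per-group normality gate", {
  res <- univariate_tests(make_cohort_df(seed = 5))
  expect_s3_class(res, "laa_test_results")
  expect_equal(res$test_used[res$feature == "gauss"], "student_t")
  expect_equal(res$test_used[res$feature == "skewed"], "mann_whitney")
  expect_equal(res$test_used[res$feature == "cat"], "chi_squared")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # summary style matches the reporting convention
  expect_match(res$summary_1[res$feature == "gauss"], "±")
  expect_match(res$summary_1[res$feature == "skewed"], "\\(")
})

test_that("identical groups give p = 1 for the rank test", {
  x <- rnorm(30)
  df <- data.frame(group = rep(c("a", "b"), each = 30),
                   v = c(x, x))
  res <- univariate_tests(df, features = "v")
  expect_equal(res$p_value, 1, tolerance = 1e-9)
})

test_that("constant features are skipped with a warning", {
  df <- make_cohort_df()
  df$flat <- 1
  expect_warning(res <- univariate_tests(df), "constant feature")
  expect_false("flat" %in% res$feature)
})

test_that("chi-squared matches the hand-computed 2x2 oracle", {
  # counts 11/27 vs 19/14; uncorrected X^2 = 5.933, p = 0.0149
  df <- data.frame(
    group = rep(c("g1", "g2"), c(38, 33)),
    sex = c(rep(c("f", "m"), c(11, 27)), rep(c("f", "m"), c(19, 14))))
  res <- univariate_tests(df, features = "sex")
  expect_equal(unname(res$statistic), 5.9326, tolerance = 1e-3)
  expect_equal(res$p_value, 0.01486, tolerance = 1e-3)
  res_y <- univariate_tests(df, features = "sex", yates = TRUE)
  expect_equal(res_y$p_value, 0.02818, tolerance = 1e-3)
})

test_that("summary t-test reproduces printed cohort rows", {
  eq <- t_test_from_summary(5, 1, 20, 5, 1, 20)
  expect_equal(unname(eq["t"]), 0)
  expect_equal(unname(eq["p"]), 1)
  # weight row: 86.4 +/- 15.9 (n 38) vs 78.5 +/- 16.6 (n 33) -> p 0.045
  w <- t_test_from_summary(86.4, 15.9, 38, 78.5, 16.6, 33)
  expect_equal(round(unname(w["p"]), 3), 0.045)
  # maximum ostium diameter row -> p < 0.001, t ~ -4.01, df 69
  d <- t_test_from_summary(25.77, 4.40, 38, 30.20, 4.90, 33)
  expect_lt(unname(d["p"]), 0.001)
  expect_equal(unname(d["df"]), 69)
  expect_equal(unname(d["t"]), -4.014, tolerance = 1e-3)
})

test_that("type-I error of both continuous branches is near nominal", {
  set.seed(202)
  n_rep <- 2000
  rej_t <- 0; rej_w <- 0
  for (r in seq_len(n_rep)) {
    x1 <- rnorm(38); x2 <- rnorm(33)
    p_t <- t.test(x1, x2, var.equal = TRUE)$p.value
    p_w <- suppressWarnings(wilcox.test(x1, x2, exact = FALSE)$p.value)
    rej_t <- rej_t + (p_t < 0.05)
    rej_w <- rej_w + (p_w < 0.05)
  }
  expect_lt(abs(rej_t / n_rep - 0.05), 0.015)
  expect_lt(abs(rej_w / n_rep - 0.05), 0.015)
})

test_that("power at the printed ostium-diameter effect size is ~0.97", {
  set.seed(303)
  n_rep <- 2000
  rej <- 0
  for (r in seq_len(n_rep)) {
    x1 <- rnorm(38); x2 <- rnorm(33, mean = 0.95)
    rej <- rej + (t.test(x1, x2, var.equal = TRUE)$p.value < 0.05)
  }
  expect_equal(rej / n_rep, 0.97, tolerance = 0.02)
})

test_that("intercept-only logistic AIC matches the closed form", {
  df <- data.frame(group = rep(c("a", "b"), each = 15),
                   noise = rnorm(30))
  rep_ <- stepwise_logistic(df, "noise")
  # balanced intercept-only: -2 * 30 * ln(1/2) + 2
  expect_equal(rep_$aic, -2 * 30 * log(0.5) + 2, tolerance = 1e-6)
  expect_length(rep_$selected, 0)
})

test_that("stepwise keeps a strong true effect and drops pure noise", {
  set.seed(99)
  hits <- 0; n_rep <- 60
  for (r in seq_len(n_rep)) {
    n <- 200
    y <- rep(0:1, each = n / 2)
    df <- data.frame(group = ifelse(y == 1, "case", "control"),
                     true_f = y * 1.5 + rnorm(n),
                     n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                     n4 = rnorm(n), n5 = rnorm(n))
    rep_ <- stepwise_logistic(df, c("true_f", paste0("n", 1:5)))
    hits <- hits + ("true_f" %in% rep_$selected)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("all-noise candidates usually collapse to the intercept", {
  set.seed(17)
  n_int <- 0; n_rep <- 40
  for (r in seq_len(n_rep)) {
    df <- data.frame(group = rep(c("a", "b"), each = 25),
                     n1 = rnorm(50), n2 = rnorm(50), n3 = rnorm(50))
    rep_ <- stepwise_logistic(df, c("n1", "n2", "n3"))
    n_int <- n_int + (length(rep_$selected) == 0)
  }
  expect_gt(n_int / n_rep, 0.5)
  # and stepwise never ends above the intercept-only AIC
  df <- data.frame(group = rep(c("a", "b"), each = 25),
                   n1 = rnorm(50), n2 = rnorm(50))
  rep_ <- stepwise_logistic(df, c("n1", "n2"))
  aic0 <- -2 * 50 * log(0.5) + 2
  expect_lte(rep_$aic, aic0 + 1e-8)
})

test_that("joint comparison reports both AICs and de-duplicates", {
  set.seed(31)
  n <- 120
  y <- rep(0:1, each = n / 2)
  df <- data.frame(group = ifelse(y == 1, "case", "control"),
                   m1 = y + rnorm(n), m2 = rnorm(n),
                   h1 = y * 1.2 + rnorm(n), h2 = rnorm(n))
  expect_warning(
    cmp <- joint_model_comparison(df, c("m1", "m2"), c("m1", "h1", "h2")),
    "de-duplicated")
  expect_s3_class(cmp, "laa_joint_comparison")
  expect_equal(cmp$delta_aic, cmp$aic_joint - cmp$aic_morph)
  expect_lt(cmp$aic_joint, cmp$aic_morph)  # h1 carries real signal
})

test_that("noise-only haemodynamic block yields no large spurious gain", {
  set.seed(41)
  deltas <- replicate(25, {
    n <- 100
    y <- rep(0:1, each = n / 2)
    df <- data.frame(group = ifelse(y == 1, "case", "control"),
                     m1 = y * 0.8 + rnorm(n),
                     h1 = rnorm(n), h2 = rnorm(n), h3 = rnorm(n))
    suppressWarnings(
      joint_model_comparison(df, "m1", c("h1", "h2", "h3"))$delta_aic)
  })
  expect_gt(mean(deltas), -2)
})

test_that("random forest ranks the informative feature first, repeatably", {
  set.seed(55)
  n <- 300
  y <- rep(c("control", "case"), each = n / 2)
  df <- data.frame(group = y,
                   signal = (y == "case") * 1 + rnorm(n, sd = 0.6))
  for (k in 1:9) df[[paste0("noise", k)]] <- rnorm(n)
  feats <- c("signal", paste0("noise", 1:9))
  rep1 <- random_forest_importance(df, feats, seed = 7)
  rep2 <- random_forest_importance(df, feats, seed = 7)
  expect_equal(names(rep1$rf_importances)[1], "signal")
  expect_identical(rep1$rf_importances, rep2$rf_importances)
  expect_identical(rep1$rf_accuracy, rep2$rf_accuracy)
  expect_gt(rep1$rf_accuracy, 0.6)
})

test_that("all-noise forest has chance-level OOB accuracy", {
  set.seed(66)
  acc <- replicate(15, {
    n <- 200
    df <- data.frame(group = rep(c("a", "b"), each = n / 2),
                     n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                     n4 = rnorm(n))
    random_forest_importance(df, paste0("n", 1:4),
                             seed = sample.int(1e6, 1))$rf_accuracy
  })
  expect_gt(mean(acc), 0.40)
  expect_lt(mean(acc), 0.60)
})
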
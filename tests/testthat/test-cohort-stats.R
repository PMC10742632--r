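test_that("group comparison routes to ANOVA and matches the sum-of-squares oracle", {
  df <- tibble::tibble(
    y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    g = rep(c("a", "b", "c"), each = 3)
  )
  cmp <- compare_groups(df, y, g)
  expect_identical(cmp$test, "ANOVA")
  # textbook oracle: SSB/(k-1) over SSW/(N-k)
  grand <- mean(df$y)
  ssb <- sum(tapply(df$y, df$g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(df$y, df$g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(f_oracle, 3)
  expect_equal(cmp$statistic, f_oracle)
  expect_equal(cmp$p_value, pf(3, 2, 6, lower.tail = FALSE))
})

test_that("identical groups give F = 0, p = 1 and Bonferroni pairs capped at 1", {
  df <- tibble::tibble(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  cmp <- compare_groups(df, y, g)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  pw <- tidy(cmp)
  expect_identical(nrow(pw), 3L)
  expect_true(all(pw$p_bonferroni <= 1))
  expect_true(all(pw$p_bonferroni >= pw$p_unadjusted))
})

test_that("categorical variables route to chi-squared", {
  df <- tibble::tibble(
    v = rep(c("yes", "no"), c(10, 10)),
    g = rep(c("a", "b"), c(10, 10))
  )
  cmp <- compare_groups(df, v, g)
  expect_identical(cmp$test, "chi-squared")
  expect_lt(cmp$p_value, 0.001)
  expect_error(compare_groups(tibble::tibble(y = 1:5, g = "a"), y, g),
               "2 non-empty groups")
  expect_error(compare_groups(tibble::tibble(y = 1:3, g = c("a", "a", "b")), y, g),
               "at least 2 observations")
})

test_that("skewed data routes to the rank-based tests", {
  set.seed(31)
  df <- tibble::tibble(
    y = exp(rnorm(120, sd = 1.5)),
    g = rep(c("a", "b", "c"), each = 40)
  )
  cmp <- compare_groups(df, y, g)
  expect_identical(cmp$test, "Kruskal-Wallis")
  df2 <- df[df$g != "c", ]
  cmp2 <- compare_groups(df2, y, g)
  expect_identical(cmp2$test, "Mann-Whitney")
})

test_that("correlation matches the covariance-formula oracle and handles ranks", {
  df <- tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5))
  r_oracle <- sum((df$x - 3) * (df$y - 3)) /
    sqrt(sum((df$x - 3)^2) * sum((df$y - 3)^2))
  expect_equal(r_oracle, 0.8)
  got <- correlate(df, x, y, force_method = "pearson")
  expect_equal(got$estimate, r_oracle)

  lin <- tibble::tibble(x = seq(-3, 3, length.out = 20))
  lin$y <- 2 * lin$x + 1
  expect_equal(correlate(lin, x, y)$estimate, 1)

  rev <- tibble::tibble(x = c(1, 5, 20, 400), y = c(400, 20, 5, 1))
  expect_equal(correlate(rev, x, y, force_method = "spearman")$estimate, -1)

  expect_error(correlate(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               "undefined correlation")
})

test_that("odds ratios reproduce the clinical panel from raw counts", {
  # deficient vs insufficient myocardial overload; published to 2 decimals
  or1 <- odds_ratio_2x2(23, 84, 3, 93)
  expect_lt(abs(or1$or_value - 8.49), 0.01)
  expect_lt(abs(or1$ci_low - 2.46), 0.01)
  expect_lt(abs(or1$ci_high - 29.29), 0.01)
  # hepatic overload vs inadequate vitamin D
  or2 <- odds_ratio_2x2(122, 81, 23, 52)
  expect_lt(abs(or2$or_value - 3.41), 0.01)
  expect_lt(abs(or2$ci_low - 1.93), 0.01)
  expect_lt(abs(or2$ci_high - 5.99), 0.01)
  # symmetry
  or3 <- odds_ratio_2x2(5, 5, 5, 5)
  expect_equal(or3$or_value, 1)
  expect_lt(or3$ci_low, 1); expect_gt(or3$ci_high, 1)
  expect_error(odds_ratio_2x2(5, 0, 3, 4), "undefined OR")
  expect_gt(odds_ratio_2x2(5, 0, 3, 4, correction = TRUE)$or_value, 1)
})

test_that("Woolf OR equals the single-predictor logistic MLE", {
  tab <- c(a = 122, b = 81, c = 23, d = 52)
  or <- odds_ratio_2x2(tab[1], tab[2], tab[3], tab[4])
  # independent oracle: logistic maximum likelihood on expanded data
  df <- data.frame(
    exposed = rep(c(1, 1, 0, 0), tab),
    outcome = rep(c(1, 0, 1, 0), tab)
  )
  fit <- glm(outcome ~ exposed, family = binomial(), data = df)
  expect_equal(or$or_value, unname(exp(coef(fit)["exposed"])), tolerance = 1e-6)
  expect_equal(or$log_se, unname(sqrt(vcov(fit)["exposed", "exposed"])),
               tolerance = 1e-6)
})

test_that("OR transposition and swap invariances hold", {
  set.seed(12)
  for (i in 1:10) {
    cts <- sample(1:60, 4)
    or <- odds_ratio_2x2(cts[1], cts[2], cts[3], cts[4])
    # swapping exposure rows inverts the OR
    or_sw <- odds_ratio_2x2(cts[3], cts[4], cts[1], cts[2])
    expect_equal(or_sw$or_value, 1 / or$or_value, tolerance = 1e-12)
    # log-CI width invariant under outcome/exposure transpose
    or_t <- odds_ratio_2x2(cts[1], cts[3], cts[2], cts[4])
    expect_equal(log(or_t$ci_high) - log(or_t$ci_low),
                 log(or$ci_high) - log(or$ci_low), tolerance = 1e-12)
  }
})

test_that("a perfect single predictor is retained with beta 1 and VIF 1", {
  df <- tibble::tibble(y = rnorm(50))
  df$x <- df$y
  rep <- suppressWarnings(stepwise_t2star_model(df, "y", "x"))
  expect_identical(rep$retained_set, "x")
  expect_equal(rep$retained$beta, 1, tolerance = 1e-10)
  expect_equal(rep$retained$vif, 1)
})

test_that("every retained variable satisfies the removal criterion given the others", {
  cc <- make_test_cohort(seed = 17)
  cc$female <- as.numeric(cc$sex == "F")
  cand <- c("female", "age", "hemoglobin", "ferritin", "vitamin_d", "pth",
            "lic", "pancreas_t2star")
  rep <- stepwise_t2star_model(cc, "heart_t2star", cand)
  expect_gt(length(rep$retained_set), 0)
  expect_true(all(rep$retained$p_value <= 0.10))
  # retained variables passed the univariate screen
  uni <- rep$univariate
  expect_true(all(uni$uni_p[uni$term %in% rep$retained_set] < 0.05))
  # collinearity diagnostics are consistent
  expect_equal(rep$retained$tolerance, 1 / rep$retained$vif)
})

test_that("stepwise matches the all-subsets BIC oracle on designed effects", {
  all_subsets_bic <- function(df, outcome, cands) {
    best <- NULL; best_bic <- Inf
    for (m in 0:(2^length(cands) - 1)) {
      sel <- cands[bitwAnd(m, 2^(seq_along(cands) - 1)) > 0]
      f <- if (length(sel)) reformulate(sel, outcome)
           else as.formula(paste(outcome, "~ 1"))
      b <- BIC(lm(f, data = df))
      if (b < best_bic) { best_bic <- b; best <- sel }
    }
    sort(best)
  }
  betas <- c(0.35, 0.30, 0.25, 0, 0, 0, 0)
  sd_e <- sqrt(1 - sum(betas^2))
  for (s in c(1002, 1003, 1004, 1010, 1020)) {
    set.seed(s)
    X <- matrix(rnorm(278 * 7), 278)
    df <- as.data.frame(X)
    names(df) <- paste0("x", 1:7)
    df$y <- as.vector(X %*% betas + rnorm(278, 0, sd_e))
    st <- sort(stepwise_t2star_model(df, "y", paste0("x", 1:7))$retained_set)
    expect_identical(st, all_subsets_bic(df, "y", paste0("x", 1:7)))
    expect_identical(st, c("x1", "x2", "x3"))
  }
})

test_that("singular designs are rejected with the offending variable named", {
  set.seed(44)
  df <- tibble::tibble(y = rnorm(60), x1 = rnorm(60))
  df$x2 <- df$x1
  expect_error(stepwise_t2star_model(df, "y", c("x1", "x2")), "collinear.*x2")
})

test_that("ROC cutoff and operating point match the exhaustive-sweep oracle", {
  df <- tibble::tibble(score = 1:10,
                       mio = as.integer(1:10 %in% c(1, 2, 3, 4, 6)))
  roc <- roc_youden(df, score, mio, direction = "low")
  # exhaustive enumeration of candidate cutoffs (low score calls the event)
  sweep <- lapply(sort(unique(df$score)), function(c) {
    sens <- mean(df$score[df$mio == 1] <= c)
    spec <- mean(df$score[df$mio == 0] > c)
    list(c = c, sens = sens, spec = spec, j = sens + spec - 1)
  })
  jmax <- max(vapply(sweep, `[[`, numeric(1), "j"))
  best <- Filter(function(s) s$j == jmax, sweep)
  best <- best[[which.max(vapply(best, `[[`, numeric(1), "sens"))]]
  expect_equal(roc$optimal_cutoff, best$c)
  expect_equal(roc$sensitivity, 100 * best$sens)
  expect_equal(roc$specificity, 100 * best$spec)
  expect_equal(roc$optimal_cutoff, 6)   # frozen from the oracle
})

test_that("AUC equals the normalized concordant-pair count", {
  set.seed(9)
  for (i in 1:5) {
    s <- sample(1:8, 40, replace = TRUE)   # plenty of ties
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    df <- tibble::tibble(s = s, y = y)
    roc <- roc_youden(df, s, y, direction = "high")
    pos <- s[y == 1]; neg <- s[y == 0]
    conc <- 0
    for (p in pos) for (q in neg) conc <- conc + (p > q) + 0.5 * (p == q)
    expect_equal(roc$auc, conc / (length(pos) * length(neg)))
    # complement symmetry with tie handling
    df$ms <- -df$s
    roc_m <- roc_youden(df, ms, y, direction = "high")
    expect_equal(roc$auc + roc_m$auc, 1)
  }
})

test_that("perfect separation yields AUC 1 and J 1", {
  df <- tibble::tibble(s = c(1:5, 11:15), y = rep(c(0, 1), each = 5))
  roc <- roc_youden(df, s, y, direction = "high")
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity, 100)
  expect_equal(roc$specificity, 100)
  expect_error(roc_youden(tibble::tibble(s = 1:4, y = 1), s, y), "both outcome classes")
})

test_that("AUC and DeLong CI agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  cc <- make_test_cohort(seed = 23)
  roc <- roc_youden(cc, vitamin_d, myocardial_overload, direction = "low")
  ref <- pROC::roc(cc$myocardial_overload, cc$vitamin_d, direction = ">",
                   quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(roc$auc_ci_low, ci[1], tolerance = 1e-6)
  expect_equal(roc$auc_ci_high, ci[3], tolerance = 1e-6)
})
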
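normality_p <- function(x) {
  # Lilliefors-corrected Kolmogorov-Smirnov; small samples lack the power to
  # reject, so they fall through to the parametric route.
  x <- x[is.finite(x)]
  if (length(x) < 5 || stats::sd(x) == 0) return(1)
  tryCatch(nortest::lillie.test(x)$p.value, error = function(e) 1)
}

#' Compare a variable across patient groups
#'
#' Routes the comparison the way clinical cohort analyses do: a
#' Kolmogorov-Smirnov (Lilliefors) normality check on the within-group
#' residuals sends normally distributed variables to the independent-sample
#' t-test (2 groups) or one-way ANOVA (3+), and non-normal variables to the
#' Mann-Whitney rank-sum test or Kruskal-Wallis test. Categorical variables
#' are compared with the chi-squared test. Pairwise post hoc p-values are
#' Bonferroni-multiplied (capped at 1).
#'
#' @param data A data frame.
#' @param value Column with the variable to compare (tidy-eval).
#' @param group Column with group labels (tidy-eval).
#' @param normality_alpha Significance level of the normality check.
#' @return An object of class `group_comparison`; `glance()` gives the
#'   omnibus test and `tidy()` the Bonferroni pairwise table.
#' @export
compare_groups <- function(data, value, group, normality_alpha = 0.05) {
  stopifnot(is.data.frame(data))
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- factor(g[keep])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs at least 2 observations", call. = FALSE)

  categorical <- is.factor(v) || is.character(v) || is.logical(v)
  if (categorical) {
    tab <- table(v, g)
    ct <- suppressWarnings(stats::chisq.test(tab))
    res <- list(test = "chi-squared", statistic = unname(ct$statistic),
                p_value = ct$p.value, normal = NA)
  } else {
    resid <- v - stats::ave(v, g)
    normal <- normality_p(resid) > normality_alpha
    two <- nlevels(g) == 2
    if (normal && two) {
      tt <- stats::t.test(v ~ g, var.equal = TRUE)
      res <- list(test = "t-test", statistic = unname(tt$statistic),
                  p_value = tt$p.value, normal = TRUE)
    } else if (normal) {
      fit <- stats::aov(v ~ g)
      s <- summary(fit)[[1]]
      res <- list(test = "ANOVA", statistic = s[["F value"]][1],
                  p_value = s[["Pr(>F)"]][1], normal = TRUE)
    } else if (two) {
      wt <- suppressWarnings(stats::wilcox.test(v ~ g))
      res <- list(test = "Mann-Whitney", statistic = unname(wt$statistic),
                  p_value = wt$p.value, normal = FALSE)
    } else {
      kt <- stats::kruskal.test(v, g)
      res <- list(test = "Kruskal-Wallis", statistic = unname(kt$statistic),
                  p_value = kt$p.value, normal = FALSE)
    }
  }

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  k <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    sel <- g %in% pr
    if (categorical) {
      p <- suppressWarnings(stats::chisq.test(table(v[sel], droplevels(g[sel]))))$p.value
    } else if (isTRUE(res$normal)) {
      p <- stats::t.test(v[sel] ~ droplevels(g[sel]), var.equal = TRUE)$p.value
    } else {
      p <- suppressWarnings(stats::wilcox.test(v[sel] ~ droplevels(g[sel])))$p.value
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   p_unadjusted = p, p_bonferroni = min(1, p * k))
  })

  structure(c(res, list(pairwise = pairwise, groups = levels(g),
                        n = as.integer(table(g)))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  invisible(x)
}

#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic,
                 p_value = x$p_value, normal = x$normal,
                 n_groups = length(x$groups))
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' Correlation with normality-based method choice
#'
#' Pearson's correlation when both variables pass the Lilliefors normality
#' check, Spearman's rank correlation otherwise; either can be forced.
#'
#' @param data A data frame.
#' @param x,y Columns to correlate (tidy-eval).
#' @param force_method Optional `"pearson"` or `"spearman"`.
#' @param normality_alpha Significance level of the normality check.
#' @return A one-row tibble: `method`, `estimate`, `p_value`, `n`.
#' @export
correlate <- function(data, x, y, force_method = NULL, normality_alpha = 0.05) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  method <- if (!is.null(force_method)) {
    match.arg(force_method, c("pearson", "spearman"))
  } else if (normality_p(xv) > normality_alpha && normality_p(yv) > normality_alpha) {
    "pearson"
  } else {
    "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = method, exact = FALSE))
  tibble::tibble(method = method, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(xv))
}

#' Odds ratio of a 2x2 contingency table
#'
#' Crude odds ratio `(a*d)/(b*c)` for an exposure-by-outcome table laid out
#' as `(a, b; c, d)` = (exposed with outcome, exposed without; unexposed
#' with, unexposed without), with the Woolf log-scale confidence interval
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. For a single binary
#' predictor this equals the logistic-regression Wald estimate. Zero cells
#' make the OR undefined; with `correction = TRUE` the Haldane-Anscombe 0.5
#' is added to every cell instead.
#'
#' @param a,b,c,d Non-negative integer counts. `a` may also be a 2x2 matrix.
#' @param conf_level Confidence level (default 0.95).
#' @param correction Apply the 0.5 continuity correction when a cell is zero.
#' @return A one-row tibble: `or_value`, `ci_low`, `ci_high`, `log_se`,
#'   `p_value` (Wald).
#' @examples
#' odds_ratio_2x2(23, 84, 3, 93)
#' @export
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           conf_level = 0.95, correction = FALSE) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- unname(c(a, b, c, d))
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  if (any(cells == 0)) {
    if (!correction) stop("undefined OR: zero cell (set correction = TRUE)", call. = FALSE)
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  log_se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    or_value = or,
    ci_low = exp(log(or) - z * log_se),
    ci_high = exp(log(or) + z * log_se),
    log_se = log_se,
    p_value = 2 * stats::pnorm(-abs(log(or) / log_se))
  )
}

uni_fit <- function(zd, outcome, term) {
  s <- summary(stats::lm(stats::reformulate(term, outcome), data = zd))
  co <- stats::coef(s)
  if (nrow(co) < 2) return(c(beta = NA_real_, p = NA_real_))
  c(beta = co[2, 1], p = co[2, 4])
}

#' Univariate screen plus forward stepwise regression
#'
#' Identifies determinants of a continuous outcome (typically global heart
#' T2*) the way clinical multivariable analyses are run: every candidate is
#' first screened in a univariate linear regression; candidates with
#' univariate `p < 0.05` enter a forward stepwise selection (entry at
#' `p <= p_enter`, removal at `p > p_remove`). All variables are z-scored
#' first so the reported betas are standardized. Collinearity of the final
#' model is summarised by variance inflation factors (flagged above 5) and
#' tolerances (flagged below 0.20).
#'
#' @param data Cohort data frame.
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param p_enter,p_remove Stepwise entry and removal p-value thresholds.
#' @param screen_alpha Univariate significance required to enter the pool.
#' @return An object of class `stepwise_report`; `tidy()` merges the
#'   univariate and multivariate columns, `glance()` gives the model F test.
#' @export
stepwise_t2star_model <- function(data, outcome, candidates,
                                  p_enter = 0.05, p_remove = 0.10,
                                  screen_alpha = 0.05) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(candidates %in% names(data)))
  cols <- c(outcome, candidates)
  zd <- data[stats::complete.cases(data[cols]), cols]
  n <- nrow(zd)
  if (n <= 10 * length(candidates)) {
    warning("fewer than 10 observations per candidate variable")
  }
  zd[] <- lapply(zd, function(x) {
    x <- as.numeric(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("candidate or outcome is constant after z-scoring", call. = FALSE)
    }
    (x - mean(x)) / s
  })

  full <- stats::lm(stats::reformulate(candidates, outcome), data = zd)
  aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
  if (length(aliased)) {
    stop("design is collinear to singularity in: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  uni <- purrr::map_dfr(candidates, function(tm) {
    u <- uni_fit(zd, outcome, tm)
    tibble::tibble(term = tm, uni_beta = u[["beta"]], uni_p = u[["p"]])
  })

  pool <- uni$term[!is.na(uni$uni_p) & uni$uni_p < screen_alpha]
  model <- character(0)
  repeat {
    changed <- FALSE
    # forward step: best admissible candidate
    avail <- setdiff(pool, model)
    if (length(avail)) {
      trial <- purrr::map_dbl(avail, function(tm) {
        fit <- stats::lm(stats::reformulate(c(model, tm), outcome), data = zd)
        co <- stats::coef(summary(fit))
        if (any(is.na(stats::coef(fit)))) return(NA_real_)
        co[tm, 4]
      })
      if (any(!is.na(trial)) && min(trial, na.rm = TRUE) <= p_enter) {
        model <- c(model, avail[which.min(trial)])
        changed <- TRUE
      }
    }
    # backward step: drop anything past the removal threshold
    repeat {
      if (!length(model)) break
      fit <- stats::lm(stats::reformulate(model, outcome), data = zd)
      co <- stats::coef(summary(fit))
      pv <- co[model, 4]
      if (max(pv) > p_remove) {
        model <- setdiff(model, model[which.max(pv)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  if (!length(model)) {
    final <- NULL
    retained <- tibble::tibble(term = character(0), beta = numeric(0),
                               p_value = numeric(0), vif = numeric(0),
                               tolerance = numeric(0))
    model_f <- NA_real_; model_p <- NA_real_
  } else {
    final <- stats::lm(stats::reformulate(model, outcome), data = zd)
    if (any(is.na(stats::coef(final)))) {
      bad <- names(stats::coef(final))[is.na(stats::coef(final))]
      stop("design is collinear to singularity in: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    s <- summary(final)
    co <- stats::coef(s)
    vifs <- if (length(model) >= 2) car::vif(final)[model] else stats::setNames(1, model)
    retained <- tibble::tibble(
      term = model,
      beta = co[model, 1],
      p_value = co[model, 4],
      vif = unname(vifs),
      tolerance = 1 / unname(vifs)
    )
    fstat <- s$fstatistic
    model_f <- unname(fstat[1])
    model_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }

  structure(
    list(univariate = uni, retained = retained, retained_set = retained$term,
         model_f = model_f, model_p = model_p, n = n, fit = final,
         outcome = outcome),
    class = "stepwise_report"
  )
}

#' @export
print.stepwise_report <- function(x, ...) {
  cat(sprintf("<stepwise_report> outcome = %s | retained: %s | F = %.3f, p = %.3g\n",
              x$outcome,
              if (length(x$retained_set)) paste(x$retained_set, collapse = ", ") else "(none)",
              x$model_f, x$model_p))
  invisible(x)
}

#' @export
tidy.stepwise_report <- function(x, ...) {
  dplyr::left_join(
    x$univariate,
    dplyr::rename(x$retained, multi_beta = "beta", multi_p = "p_value"),
    by = "term"
  )
}

#' @export
glance.stepwise_report <- function(x, ...) {
  tibble::tibble(n = x$n, n_retained = length(x$retained_set),
                 model_f = x$model_f, model_p = x$model_p)
}

psi_auc <- function(pos, neg) {
  # pairwise concordance kernel with 0.5 credit for ties
  outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
}

#' ROC curve with Youden-index cut-off
#'
#' Builds the empirical ROC over all observed thresholds, computes the AUC
#' by the Mann-Whitney (concordant-pair) statistic with its DeLong
#' confidence interval, and picks the cut-off maximising the Youden index
#' `J = sensitivity + specificity - 1`, breaking ties toward higher
#' sensitivity. `direction = "low"` handles predictors where a low value
#' predicts the event (a patient is called positive when the score is at or
#' below the cut-off), as with vitamin D and myocardial iron.
#'
#' @param data A data frame.
#' @param score Predictor column (tidy-eval).
#' @param label Binary outcome column, logical or 0/1 (tidy-eval).
#' @param direction `"high"` (higher score predicts the event), `"low"`, or
#'   `"auto"` (whichever yields AUC >= 0.5).
#' @param conf_level Confidence level for the DeLong interval.
#' @return An object of class `roc_report`: AUC with CI, optimal cut-off in
#'   predictor units, sensitivity and specificity in percent at that
#'   cut-off, and the full ROC curve (`$curve`).
#' @export
roc_youden <- function(data, score, label, direction = c("auto", "high", "low"),
                       conf_level = 0.95) {
  direction <- match.arg(direction)
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ label }})
  if (is.logical(y)) y <- as.integer(y)
  keep <- is.finite(s) & !is.na(y)
  s <- s[keep]; y <- y[keep]
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    stop("`label` must contain both outcome classes (0/1)", call. = FALSE)
  }
  if (direction == "auto") {
    direction <- if (mean(rank(s)[y == 1]) >= mean(rank(s)[y == 0])) "high" else "low"
  }
  sgn <- if (direction == "high") 1 else -1
  sv <- sgn * s
  pos <- sv[y == 1]; neg <- sv[y == 0]
  n1 <- length(pos); n0 <- length(neg)

  psi <- psi_auc(pos, neg)
  auc <- mean(psi)
  v10 <- rowMeans(psi)                 # DeLong placements
  v01 <- colMeans(psi)
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  thr <- sort(unique(sv))
  curve <- purrr::map_dfr(thr, function(t) {
    called <- sv >= t
    tibble::tibble(
      threshold = sgn * t,
      sensitivity = sum(called & y == 1) / n1,
      specificity = sum(!called & y == 0) / n0
    )
  })
  curve$youden_j <- curve$sensitivity + curve$specificity - 1
  best_j <- max(curve$youden_j)
  at_best <- curve[curve$youden_j >= best_j - 1e-12, ]
  best <- at_best[which.max(at_best$sensitivity), ]

  structure(
    list(
      auc = auc,
      auc_ci_low = max(0, auc - z * se),
      auc_ci_high = min(1, auc + z * se),
      auc_se = se,
      p_value = 2 * stats::pnorm(-abs((auc - 0.5) / se)),
      optimal_cutoff = best$threshold,
      sensitivity = 100 * best$sensitivity,
      specificity = 100 * best$specificity,
      direction = direction,
      curve = curve,
      n_pos = n1, n_neg = n0
    ),
    class = "roc_report"
  )
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf(
    "<roc_report> AUC = %.3f (%.0f%% CI %.3f-%.3f) | cutoff %s %.4g: sens %.1f%%, spec %.1f%%\n",
    x$auc, 95, x$auc_ci_low, x$auc_ci_high,
    if (x$direction == "low") "<=" else ">=",
    x$optimal_cutoff, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' @export
glance.roc_report <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_ci_low = x$auc_ci_low, auc_ci_high = x$auc_ci_high,
    p_value = x$p_value, optimal_cutoff = x$optimal_cutoff,
    sensitivity = x$sensitivity, specificity = x$specificity,
    direction = x$direction, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @export
autoplot.roc_report <- function(object, ...) {
  dat <- object$curve
  ggplot2::ggplot(dat, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70", linetype = 2) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::annotate("point",
                      x = 1 - dat$specificity[which.max(dat$youden_j)],
                      y = dat$sensitivity[which.max(dat$youden_j)],
                      colour = "red") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.2f (cutoff %.3g)",
                                  object$auc, object$optimal_cutoff)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
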
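test_that("ROI-mean decay equals per-pixel averaging", {
  # constant images: mean equals the constant under any mask
  stack <- array(0, dim = c(3, 4, 4))
  stack[1, , ] <- 100; stack[2, , ] <- 50; stack[3, , ] <- 25
  mask <- matrix(TRUE, 4, 4)
  es <- roi_mean_decay(stack, mask, c(1, 2, 3))
  expect_equal(es$signal, c(100, 50, 25))

  # one-pixel mask returns that pixel's trajectory
  set.seed(1)
  stack <- array(runif(5 * 8 * 8, 10, 100), dim = c(5, 8, 8))
  mask1 <- matrix(FALSE, 8, 8); mask1[3, 5] <- TRUE
  es1 <- roi_mean_decay(stack, mask1, 1:5)
  expect_equal(es1$signal, stack[, 3, 5])

  # 12-pixel mask equals an explicit per-pixel loop average
  mask12 <- matrix(FALSE, 8, 8)
  mask12[sample(64, 12)] <- TRUE
  es12 <- roi_mean_decay(stack, mask12, 1:5)
  oracle <- numeric(5)
  for (k in 1:5) {
    acc <- 0; n <- 0
    for (i in 1:8) for (j in 1:8) if (mask12[i, j]) {
      acc <- acc + stack[k, i, j]; n <- n + 1
    }
    oracle[k] <- acc / n
  }
  expect_equal(es12$signal, oracle)

  expect_error(roi_mean_decay(stack, matrix(FALSE, 8, 8), 1:5), "empty ROI")
  expect_error(roi_mean_decay(stack, matrix(TRUE, 4, 4), 1:5), "shape")
  expect_error(roi_mean_decay(stack, mask12, 1:4), "echo count")
})

test_that("offset model recovers noiseless parameters to 6+ significant digits", {
  for (t2 in c(2, 8, 20, 40)) {
    fit <- fit_offset_model(decay_series(t2, s0 = 100, offset = 5))
    expect_equal(fit$t2star, t2, tolerance = 1e-7)
    expect_equal(fit$s0, 100, tolerance = 1e-7)
    expect_equal(fit$offset, 5, tolerance = 1e-5)
    expect_equal(fit$n_echoes_used, 10L)
    expect_identical(fit$model, "offset")
  }
})

test_that("offset model agrees with a dense grid-search oracle under Rician noise", {
  es <- decay_series(8, s0 = 80, offset = 3, sigma = 1, seed = 42)
  fit <- fit_offset_model(es)
  oracle <- grid_search_offset(es$echo_times, es$signal)
  expect_equal(fit$t2star, oracle$t2star, tolerance = 0.01)
  expect_equal(fit$s0, oracle$s0, tolerance = 0.01)
  # optimizer SSE can only be at least as good as the grid's
  sse_fit <- sum((es$signal - fit$s0 * exp(-es$echo_times / fit$t2star) - fit$offset)^2)
  expect_lte(sse_fit, oracle$sse * (1 + 1e-6))
})

test_that("offset fit rejects degenerate inputs", {
  expect_error(fit_offset_model(echo_series(te10, rep(50, 10))), "no decay")
  expect_error(fit_offset_model(echo_series(te10[1:3], c(3, 2, 1))), "at least 4")
})

test_that("truncation drops exactly the echoes below the noise floor", {
  # S = 100 exp(-TE/2), noise_sd = 1 -> floor = 2; oracle by direct inequality
  sig <- 100 * exp(-te10 / 2)
  # direct-inequality oracle: strip trailing below-floor echoes
  keep <- length(sig)
  while (keep > 3 && sig[keep] < 2) keep <- keep - 1
  fit <- fit_truncated_model(echo_series(te10, sig, noise_sd = 1))
  expect_equal(fit$n_echoes_used, keep)
  expect_identical(fit$model, "truncation")
  expect_identical(fit$offset, 0)
  expect_equal(fit$t2star, 2, tolerance = 1e-6)
})

test_that("truncation is a no-op on clean data above the floor", {
  es <- decay_series(20, s0 = 100, noise_sd = 0.01)
  fit <- fit_truncated_model(es)
  expect_equal(fit$n_echoes_used, 10L)
  expect_equal(fit$t2star, 20, tolerance = 1e-7)
  expect_error(fit_truncated_model(echo_series(te10[1:2], c(2, 1))), "at least 3")
})

test_that("truncated fit beats the offset fit on severe iron (Monte-Carlo)", {
  t2_true <- 1.5
  err_trunc <- err_offset <- numeric(200)
  set.seed(7)
  for (r in 1:200) {
    es <- roi_rician_series(t2_true, s0 = 100, sigma = 2)
    err_trunc[r] <- abs(fit_truncated_model(es)$t2star - t2_true)
    err_offset[r] <- abs(fit_offset_model(es)$t2star - t2_true)
  }
  expect_lt(mean(err_trunc), mean(err_offset))
})

test_that("model arbitration switches exactly at the configured threshold", {
  expect_identical(select_fit(decay_series(30))$model, "offset")
  expect_identical(select_fit(decay_series(4))$model, "truncation")
  # noiseless T2* = 10 decay: sweep the threshold across the fitted value
  es <- decay_series(10)
  fit10 <- fit_offset_model(es)$t2star
  expect_identical(select_fit(es, heavy_iron_t2star_threshold = fit10 - 1e-6)$model,
                   "offset")
  expect_identical(select_fit(es, heavy_iron_t2star_threshold = fit10 + 1e-6)$model,
                   "truncation")
})

test_that("fit is equivariant under uniform signal rescaling", {
  es <- decay_series(12, s0 = 90, offset = 4, sigma = 0.5, seed = 5)
  base <- fit_offset_model(es)
  scaled <- fit_offset_model(echo_series(es$echo_times, es$signal * 7))
  expect_equal(scaled$t2star, base$t2star, tolerance = 1e-6)
  expect_equal(scaled$s0, base$s0 * 7, tolerance = 1e-6)
  expect_equal(scaled$offset, base$offset * 7, tolerance = 1e-5)
})

test_that("selected model keeps median relative T2* error under 5% at low noise", {
  # sigma/S0 = 0.02, the image noise level of the clinical multi-echo
  # protocol emulated by the phantoms
  set.seed(21)
  for (t2 in c(2, 10, 20, 40)) {
    rel <- replicate(125, {
      es <- roi_rician_series(t2, s0 = 100, sigma = 2)
      abs(select_fit(es)$t2star - t2) / t2
    })
    expect_lt(median(rel), 0.05)
  }
})

test_that("global pancreatic T2* is the mean of the three regional fits", {
  expect_equal(pancreas_global(12, 10, 8)$global_value, 10)
  expect_equal(pancreas_global(26, 26, 26)$global_value, 26)
  perms <- list(c(12, 10, 8), c(8, 12, 10), c(10, 8, 12))
  gv <- vapply(perms, function(p) pancreas_global(p[1], p[2], p[3])$global_value,
               numeric(1))
  expect_true(all(gv == gv[1]))
  expect_error(pancreas_global(12, Inf, 8), "finite")
  # accepts fitted objects
  f <- fit_offset_model(decay_series(20, offset = 2))
  expect_equal(pancreas_global(f, f, f)$global_value, f$t2star)
})

test_that("LIC calibration is linear in R2* and monotone decreasing in T2*", {
  expect_equal(lic_from_liver_t2star(8.466)$lic, 0.0254 * (1000 / 8.466) + 0.202)
  expect_equal(lic_from_liver_t2star(8.466)$lic, 3.202, tolerance = 1e-3)
  # limit: T2* -> Inf gives the intercept
  expect_equal(lic_from_liver_t2star(1e12)$lic, 0.202, tolerance = 1e-6)
  # halving T2* strictly increases LIC
  t2 <- c(40, 20, 10, 5, 2.5)
  lic <- lic_from_liver_t2star(t2)$lic
  expect_true(all(diff(lic) > 0))
  expect_error(lic_from_liver_t2star(0), "positive")
  expect_identical(unique(lic_from_liver_t2star(10)$calibration_id),
                   "r2star_linear_default")
})
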
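# Shared fixtures: model decays on the clinical 10-echo grid and small
# geometric phantoms, all built in code.

te10 <- default_echo_times()  # 2.26, 4.52, ..., 22.6 ms

decay_series <- function(t2star, s0 = 100, offset = 0, te = te10,
                         noise_sd = NULL, sigma = 0, seed = NULL) {
  sig <- s0 * exp(-te / t2star) + offset
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sqrt((sig + rnorm(length(sig), 0, sigma))^2 +
                  rnorm(length(sig), 0, sigma)^2)
  }
  echo_series(te, sig, noise_sd = noise_sd)
}

# ROI-mean decay over npix pixels with per-pixel Rician noise: the operating
# regime of the fits (curves are averaged over an ROI before fitting, while
# the truncation floor works off the image noise SD).
roi_rician_series <- function(t2star, s0 = 100, offset = 0, sigma = 0,
                              npix = 100, te = te10) {
  a <- s0 * exp(-te / t2star) + offset
  sig <- vapply(a, function(ak) {
    mean(sqrt((ak + rnorm(npix, 0, sigma))^2 + rnorm(npix, 0, sigma)^2))
  }, numeric(1))
  echo_series(te, sig, noise_sd = if (sigma > 0) sigma else NULL)
}

# Circular annulus contours (polygonal approximation)
circle_pts <- function(r, cx = 0, cy = 0, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

annulus_contours <- function(slice_level = "mid", cx = 32.5, cy = 32.5,
                             r_in = 10, r_out = 20, reference_angle = 90) {
  myocardial_contours(slice_level,
                      endo = circle_pts(r_in, cx, cy),
                      epi = circle_pts(r_out, cx, cy),
                      reference_angle = reference_angle)
}

# Dense grid-search oracle for the offset model, independent of the
# Levenberg-Marquardt path: coarse pass + one refinement.
grid_search_offset <- function(te, sig,
                               t2_range = c(0.5, 60), s0_range = NULL,
                               c_range = NULL) {
  if (is.null(s0_range)) s0_range <- c(0.2, 2) * max(sig)
  if (is.null(c_range)) c_range <- c(0, max(min(sig), 1e-9) * 2)
  best <- c(Inf, NA, NA, NA)
  sweep <- function(t2s, s0s, cs) {
    for (t2 in t2s) for (s0 in s0s) for (cc in cs) {
      sse <- sum((sig - s0 * exp(-te / t2) - cc)^2)
      if (sse < best[1]) best <<- c(sse, s0, t2, cc)
    }
  }
  sweep(seq(t2_range[1], t2_range[2], length.out = 120),
        seq(s0_range[1], s0_range[2], length.out = 60),
        seq(c_range[1], c_range[2], length.out = 31))
  for (w in c(0.25, 0.08, 0.025, 0.008)) {
    s <- best
    c_half <- max(s[4], 0.5) * 2 * w
    sweep(seq(s[3] * (1 - w), s[3] * (1 + w), length.out = 41),
          seq(s[2] * (1 - w / 2), s[2] * (1 + w / 2), length.out = 31),
          seq(max(0, s[4] - c_half), s[4] + c_half, length.out = 21))
  }
  list(s0 = best[2], t2star = best[3], offset = best[4], sse = best[1])
}

# calibrating the config costs ~1 s; share one instance across tests
test_cfg <- cohort_config()

make_test_cohort <- function(seed = 11, calibrated = TRUE) {
  co <- generate_cohort(test_cfg, seed = seed)
  if (calibrated) co <- calibrate_mio_prevalence(co)
  classify_cohort(co)
}
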
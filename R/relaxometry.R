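#' @keywords internal
new_relax_fit <- function(t2star, s0, offset, model, series, used) {
  te <- series$echo_times[seq_len(used)]
  sig <- series$signal[seq_len(used)]
  fitted <- s0 * exp(-te / t2star) + offset
  resid <- sig - fitted
  ss_tot <- sum((sig - mean(sig))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  structure(
    list(
      t2star = t2star, s0 = s0, offset = offset,
      model = model, n_echoes_used = used,
      rmse = sqrt(mean(resid^2)), r_squared = r2,
      series = series
    ),
    class = "relax_fit"
  )
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf(
    "<relax_fit> model = %s | T2* = %.4g ms | S0 = %.4g | C = %.4g | %d echoes | R^2 = %.5f\n",
    x$model, x$t2star, x$s0, x$offset, x$n_echoes_used, x$r_squared
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.relax_fit <- function(x, ...) {
  tibble::tibble(
    term = c("s0", "t2star", "offset"),
    estimate = c(x$s0, x$t2star, x$offset)
  )
}

#' @export
glance.relax_fit <- function(x, ...) {
  tibble::tibble(
    t2star = x$t2star, s0 = x$s0, offset = x$offset, model = x$model,
    n_echoes_used = x$n_echoes_used, rmse = x$rmse, r_squared = x$r_squared
  )
}

#' @export
autoplot.relax_fit <- function(object, ...) {
  dat <- tibble::tibble(
    echo_time = object$series$echo_times,
    signal = object$series$signal,
    used = seq_along(object$series$echo_times) <= object$n_echoes_used
  )
  grid <- tibble::tibble(echo_time = seq(0, max(dat$echo_time), length.out = 200))
  grid$signal <- object$s0 * exp(-grid$echo_time / object$t2star) + object$offset
  ggplot2::ggplot(dat, ggplot2::aes(.data$echo_time, .data$signal)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = "Echo time (ms)", y = "Signal (a.u.)",
      title = sprintf("%s model: T2* = %.3g ms", object$model, object$t2star)
    ) +
    ggplot2::theme_minimal()
}

# Log-linear starting values on the first half of echoes, with the offset
# initialised at the signal minimum.
start_values <- function(te, sig) {
  c0 <- min(sig)
  half <- seq_len(max(2L, floor(length(te) / 2)))
  y <- pmax(sig[half] - c0, max(sig) * 1e-6)
  co <- stats::coef(stats::lm(log(y) ~ te[half]))
  t2 <- -1 / co[2]
  if (!is.finite(t2) || t2 <= 0) t2 <- diff(range(te)) / 2
  s0 <- exp(co[1])
  if (!is.finite(s0) || s0 <= 0) s0 <- max(sig)
  list(s0 = unname(s0), t2star = unname(t2), offset = c0)
}

#' Fit the constant-offset mono-exponential decay model
#'
#' Least-squares fit of `S(TE) = S0 * exp(-TE / T2*) + C` to an ROI-mean
#' decay. The offset C absorbs the noise-floor plateau of magnitude images so
#' that all echoes can be used when iron burden is mild or moderate.
#' Optimisation is Levenberg-Marquardt with log-linear starting values and a
#' relative parameter tolerance of 1e-8.
#'
#' @param series An [echo_series()] with at least 4 echoes.
#' @return A `relax_fit` with `model = "offset"`.
#' @examples
#' te <- default_echo_times()
#' fit_offset_model(echo_series(te, 100 * exp(-te / 20) + 5))
#' @export
fit_offset_model <- function(series) {
  stopifnot(inherits(series, "echo_series"))
  te <- series$echo_times
  sig <- series$signal
  if (length(te) < 4) stop("offset-model fitting requires at least 4 echoes", call. = FALSE)
  if (diff(range(sig)) == 0) stop("no decay: signal is constant", call. = FALSE)
  st <- start_values(te, sig)
  # box constraints keep the flat SSE direction (T2* -> 0 with S0 -> Inf on
  # noise-floor decays) from running away; the box covers the physical range
  fit <- minpack.lm::nls.lm(
    par = c(s0 = min(st$s0, 1e4 * max(sig)),
            t2star = max(st$t2star, 0.2),
            offset = min(st$offset, 2 * max(sig))),
    lower = c(0, 0.2, 0),
    upper = c(1e4 * max(sig), 1e4, 2 * max(sig)),
    fn = function(p) sig - (p[1] * exp(-te / p[2]) + p[3]),
    control = minpack.lm::nls.lm.control(
      ftol = 1e-15, ptol = 1e-10, maxiter = 1024, maxfev = 100000
    )
  )
  if (!fit$info %in% 1:4) {
    stop("offset-model fit did not converge (last iterate: S0=",
         signif(fit$par[[1]], 6), ", T2*=", signif(fit$par[[2]], 6),
         ", C=", signif(fit$par[[3]], 6), "): ", fit$message, call. = FALSE)
  }
  p <- fit$par
  new_relax_fit(p[["t2star"]], p[["s0"]], p[["offset"]],
                model = "offset", series = series, used = length(te))
}

# Offset-free two-parameter fit on the first `n` echoes.
fit_pure_exponential <- function(series, n) {
  te <- series$echo_times[seq_len(n)]
  sig <- series$signal[seq_len(n)]
  y <- pmax(sig, max(sig) * 1e-9)
  co <- stats::coef(stats::lm(log(y) ~ te))
  t20 <- -1 / co[2]
  if (!is.finite(t20) || t20 <= 0) t20 <- diff(range(te)) / 2
  s00 <- unname(exp(co[1]))
  if (!is.finite(s00) || s00 <= 0) s00 <- max(sig)
  fit <- minpack.lm::nls.lm(
    par = c(s0 = min(s00, 1e4 * max(sig)), t2star = max(unname(t20), 0.2)),
    lower = c(0, 0.2),
    upper = c(1e4 * max(sig), 1e4),
    fn = function(p) sig - p[1] * exp(-te / p[2]),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-10,
                                         maxiter = 1024, maxfev = 100000)
  )
  if (!fit$info %in% 1:4) {
    stop("truncation-model fit did not converge: ", fit$message, call. = FALSE)
  }
  fit$par
}

#' Fit the truncation decay model
#'
#' Offset-free fit `S(TE) = S0 * exp(-TE / T2*)` used for heavily
#' iron-overloaded tissue, where late echoes sit in the noise floor and bias
#' the offset model. Late echoes are discarded iteratively: while the last
#' retained observation lies below twice the background noise SD (or, when no
#' noise estimate is available, while dropping it improves the adjusted
#' R-squared), it is removed, never going below `min_points` echoes.
#'
#' @param series An [echo_series()].
#' @param min_points Minimum number of retained echoes (default 3).
#' @return A `relax_fit` with `model = "truncation"` and `offset = 0`.
#' @export
fit_truncated_model <- function(series, min_points = 3) {
  stopifnot(inherits(series, "echo_series"))
  n_total <- length(series$echo_times)
  if (n_total < min_points) {
    stop("truncation fitting requires at least ", min_points, " echoes", call. = FALSE)
  }
  n <- n_total
  if (!is.null(series$noise_sd) && series$noise_sd > 0) {
    floor_level <- 2 * series$noise_sd
    while (n > min_points && series$signal[n] < floor_level) n <- n - 1
  } else {
    adj_r2 <- function(k) {
      p <- fit_pure_exponential(series, k)
      te <- series$echo_times[seq_len(k)]
      sig <- series$signal[seq_len(k)]
      res <- sig - p[["s0"]] * exp(-te / p[["t2star"]])
      ss_tot <- sum((sig - mean(sig))^2)
      if (ss_tot == 0 || k <= 3) return(1 - sum(res^2))
      1 - (sum(res^2) / (k - 2)) / (ss_tot / (k - 1))
    }
    current <- adj_r2(n)
    while (n > min_points) {
      cand <- adj_r2(n - 1)
      if (cand > current + 1e-12) {
        n <- n - 1
        current <- cand
      } else break
    }
  }
  p <- fit_pure_exponential(series, n)
  new_relax_fit(p[["t2star"]], p[["s0"]], 0,
                model = "truncation", series = series, used = n)
}

#' Fit a decay with automatic model arbitration
#'
#' Runs the constant-offset model first; if the fitted T2* falls below the
#' heavy-iron threshold (default 10 ms, the conventional severe-cardiac-iron
#' boundary), the decay is re-fit with the truncation model and that result
#' is returned. The returned object records which model produced it.
#'
#' @param series An [echo_series()].
#' @param heavy_iron_t2star_threshold T2* (ms) below which the truncation
#'   model is preferred.
#' @param min_points Minimum echoes retained by the truncation model.
#' @return A `relax_fit`.
#' @export
select_fit <- function(series, heavy_iron_t2star_threshold = 10, min_points = 3) {
  # an offset fit that cannot converge is itself a symptom of a noise-floor
  # decay, so it is routed to the truncation model like any heavy-iron case
  fit <- tryCatch(fit_offset_model(series), error = function(e) NULL)
  if (is.null(fit) || fit$t2star < heavy_iron_t2star_threshold) {
    fit <- fit_truncated_model(series, min_points = min_points)
  }
  fit
}

#' Global pancreatic T2*
#'
#' The global pancreas value is the arithmetic mean of the head, body and
#' tail ROI fits, mirroring the three-ROI pancreatic protocol.
#'
#' @param head,body,tail T2* values in ms, or `relax_fit` objects.
#' @return A one-row tibble with `head`, `body`, `tail` and `global_value` (ms).
#' @export
pancreas_global <- function(head, body, tail) {
  val <- function(x) if (inherits(x, "relax_fit")) x$t2star else as.numeric(x)
  v <- c(val(head), val(body), val(tail))
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("pancreatic T2* values must be finite and positive", call. = FALSE)
  }
  tibble::tibble(head = v[1], body = v[2], tail = v[3], global_value = mean(v))
}

#' Liver iron concentration from hepatic T2*
#'
#' Converts hepatic T2* to liver iron concentration (mg Fe per g dry weight)
#' with a calibration linear in R2* = 1000/T2* (Hz):
#' `LIC = slope * R2* + intercept`. The default coefficients give the widely
#' used linear R2*-LIC relationship; both are configurable and every result
#' is stamped with a `calibration_id` so downstream tables record which curve
#' produced them.
#'
#' @param t2star Hepatic T2* in ms (vectorised), must be positive.
#' @param slope,intercept Calibration coefficients (mg/g per Hz, mg/g).
#' @param calibration_id Label stored with the result.
#' @return A tibble with `t2star`, `lic` and `calibration_id`.
#' @examples
#' lic_from_liver_t2star(8.466)
#' @export
lic_from_liver_t2star <- function(t2star, slope = 0.0254, intercept = 0.202,
                                  calibration_id = "r2star_linear_default") {
  t2star <- as.numeric(t2star)
  if (any(!is.finite(t2star)) || any(t2star <= 0)) {
    stop("hepatic T2* must be finite and positive", call. = FALSE)
  }
  tibble::tibble(
    t2star = t2star,
    lic = slope * (1000 / t2star) + intercept,
    calibration_id = calibration_id
  )
}
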
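#' Myocardial contour pair for one short-axis slice
#'
#' Holds the endocardial and epicardial contours of a short-axis slice
#' together with the slice level (which fixes the AHA segment count: 6 for
#' basal and mid, 4 for apical) and the angular origin of segment 1. The
#' anterior right-ventricular insertion cannot be derived from the contours
#' alone, so the origin is an explicit input, defaulting to 90 degrees
#' (anterior) in the usual mathematical convention (counterclockwise from the
#' +x axis).
#'
#' @param slice_level One of `"basal"`, `"mid"`, `"apical"`.
#' @param endo,epi Two-column matrices of `[x, y]` contour points in pixel
#'   units; the endocardial contour must lie strictly inside the epicardial
#'   one.
#' @param reference_angle Angular origin of segment 1 in degrees.
#' @return An object of class `myocardial_contours`.
#' @export
myocardial_contours <- function(slice_level, endo, epi, reference_angle = 90) {
  slice_level <- match.arg(slice_level, c("basal", "mid", "apical"))
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  stopifnot(ncol(endo) == 2, ncol(epi) == 2, nrow(endo) >= 3, nrow(epi) >= 3)
  inside <- pracma::inpolygon(endo[, 1], endo[, 2], epi[, 1], epi[, 2],
                              boundary = FALSE)
  if (!all(inside)) {
    stop("contours cross: endocardial contour is not strictly inside the epicardial contour",
         call. = FALSE)
  }
  structure(
    list(slice_level = slice_level, endo = endo, epi = epi,
         reference_angle = as.numeric(reference_angle)),
    class = "myocardial_contours"
  )
}

#' Equiangular AHA segment masks for one slice
#'
#' Rasterises the myocardium (pixels inside the epicardial and outside the
#' endocardial contour, evaluated at pixel centres) and partitions it into
#' equiangular sectors around the myocardial centroid: 6 sectors for basal
#' and mid slices, 4 for the apical slice. Sector 1 starts at
#' `reference_angle` and numbering proceeds counterclockwise. The masks are
#' an exact partition of the myocardial mask: disjoint and exhaustive.
#'
#' @param contours A [myocardial_contours()].
#' @param grid_shape Integer vector `c(ny, nx)` giving the image dimensions.
#' @return A list of logical `ny x nx` masks (6 or 4 of them), with the full
#'   myocardial mask attached as attribute `"myocardium"`.
#' @export
segment_masks <- function(contours, grid_shape) {
  stopifnot(inherits(contours, "myocardial_contours"), length(grid_shape) == 2)
  ny <- grid_shape[1]; nx <- grid_shape[2]
  n_seg <- if (contours$slice_level == "apical") 4L else 6L

  xs <- rep(seq_len(nx), each = ny)     # pixel-centre coordinates
  ys <- rep(seq_len(ny), times = nx)
  in_epi <- pracma::inpolygon(xs, ys, contours$epi[, 1], contours$epi[, 2])
  in_endo <- pracma::inpolygon(xs, ys, contours$endo[, 1], contours$endo[, 2])
  myo <- in_epi & !in_endo
  if (!any(myo)) stop("empty myocardium on this grid", call. = FALSE)

  cx <- mean(xs[myo]); cy <- mean(ys[myo])
  ang <- atan2(ys - cy, xs - cx) * 180 / pi
  rel <- (ang - contours$reference_angle) %% 360
  width <- 360 / n_seg
  sector <- pmin(floor(rel / width) + 1L, n_seg)  # guard rel == 360 edge

  masks <- lapply(seq_len(n_seg), function(k) {
    m <- matrix(FALSE, ny, nx)
    m[cbind(ys[myo & sector == k], xs[myo & sector == k])] <- TRUE
    m
  })
  myo_mask <- matrix(FALSE, ny, nx)
  myo_mask[cbind(ys[myo], xs[myo])] <- TRUE
  attr(masks, "myocardium") <- myo_mask
  attr(masks, "centroid") <- c(x = cx, y = cy)
  masks
}

#' Sixteen-segment myocardial T2* map
#'
#' Fits each of the 16 AHA segments' decay curves with [select_fit()] (offset
#' model, truncation re-fit for heavy iron), applies optional per-segment
#' multiplicative correction factors (the susceptibility-artifact correction
#' hook; identity by default), and summarises the heart: the global value is
#' the mean of all segmental values and `n_low_segments` counts segments at
#' or below the conservative 20 ms threshold (a segment at exactly 20 ms is
#' counted as low, since normal is strictly above 20 ms).
#'
#' @param segment_series List of exactly 16 [echo_series()], ordered by AHA
#'   number: basal 1-6, mid 7-12, apical 13-16.
#' @param correction Optional numeric vector of 16 multiplicative factors
#'   applied to the fitted segmental T2* values.
#' @param low_threshold Conservative normality threshold in ms (default 20).
#' @param ... Passed to [select_fit()].
#' @return An object of class `cardiac_t2star_map`.
#' @export
build_heart_map <- function(segment_series, correction = NULL,
                            low_threshold = 20, ...) {
  if (length(segment_series) != 16L) {
    stop("exactly 16 segment series are required (got ",
         length(segment_series), ")", call. = FALSE)
  }
  corr <- if (is.null(correction)) rep(1, 16) else as.numeric(correction)
  if (length(corr) != 16L || any(!is.finite(corr)) || any(corr <= 0)) {
    stop("`correction` must be 16 positive factors", call. = FALSE)
  }
  fits <- lapply(segment_series, select_fit, ...)
  seg <- vapply(fits, function(f) f$t2star, numeric(1)) * corr
  structure(
    list(
      segment_values = seg,
      global_value = mean(seg),
      n_low_segments = sum(seg <= low_threshold),
      low_threshold = low_threshold,
      correction_applied = !is.null(correction),
      fits = fits
    ),
    class = "cardiac_t2star_map"
  )
}

aha_slice_levels <- function() {
  rep(c("basal", "mid", "apical"), times = c(6L, 6L, 4L))
}

#' @export
print.cardiac_t2star_map <- function(x, ...) {
  cat(sprintf(
    "<cardiac_t2star_map> global T2* = %.3f ms | %d/16 segments <= %.0f ms%s\n",
    x$global_value, x$n_low_segments, x$low_threshold,
    if (x$correction_applied) " | corrected" else ""
  ))
  invisible(x)
}

#' @export
tidy.cardiac_t2star_map <- function(x, ...) {
  tibble::tibble(
    segment = 1:16,
    slice_level = aha_slice_levels(),
    t2star = x$segment_values,
    model = vapply(x$fits, function(f) f$model, character(1)),
    n_echoes_used = vapply(x$fits, function(f) f$n_echoes_used, integer(1)),
    low = x$segment_values <= x$low_threshold
  )
}

#' @export
glance.cardiac_t2star_map <- function(x, ...) {
  tibble::tibble(
    global_t2star = x$global_value,
    n_low_segments = x$n_low_segments,
    low_threshold = x$low_threshold,
    correction_applied = x$correction_applied
  )
}

#' @export
autoplot.cardiac_t2star_map <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(factor(.data$segment), .data$t2star,
                                    fill = .data$slice_level)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$low_threshold, linetype = 2) +
    ggplot2::labs(x = "AHA segment", y = "T2* (ms)", fill = "Slice",
                  title = sprintf("Global heart T2* = %.1f ms", object$global_value)) +
    ggplot2::theme_minimal()
}
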
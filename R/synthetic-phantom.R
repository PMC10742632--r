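#' Specification of a multi-echo relaxometry phantom
#'
#' Describes a synthetic acquisition with known ground truth: a geometry
#' (uniform disc, 16-segment cardiac annulus over three short-axis slices,
#' three pancreatic ROIs, or a liver slab), per-region true T2*, signal
#' amplitude, constant offset, Rician noise level, echo grid and image size.
#'
#' @param geometry One of `"uniform_disc"`, `"cardiac_annulus_16seg"`,
#'   `"pancreas_3roi"`, `"liver_slice"`.
#' @param t2star True T2* in ms: length 1 (disc, liver), 3 (pancreas) or 16
#'   (cardiac annulus, AHA order).
#' @param s0 Signal amplitude (a.u.).
#' @param offset Constant signal offset (a.u.).
#' @param noise_sigma Rician noise SD (a.u.); 0 for a noiseless phantom.
#' @param echo_times Echo-time grid (ms).
#' @param grid_shape `c(ny, nx)` image size in pixels.
#' @param seed RNG seed; a fixed seed gives bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("uniform_disc", "cardiac_annulus_16seg",
                                      "pancreas_3roi", "liver_slice"),
                         t2star = 20, s0 = 100, offset = 0, noise_sigma = 0,
                         echo_times = default_echo_times(),
                         grid_shape = c(64, 64), seed = 1) {
  geometry <- match.arg(geometry)
  want <- switch(geometry, cardiac_annulus_16seg = 16L, pancreas_3roi = 3L, 1L)
  if (length(t2star) == 1L) t2star <- rep(t2star, want)
  if (length(t2star) != want) {
    stop(geometry, " needs ", want, " true T2* value(s)", call. = FALSE)
  }
  stopifnot(all(is.finite(t2star)), all(t2star > 0), s0 > 0, offset >= 0,
            noise_sigma >= 0, length(grid_shape) == 2, all(grid_shape >= 8))
  structure(
    list(geometry = geometry, t2star = t2star, s0 = s0, offset = offset,
         noise_sigma = noise_sigma, echo_times = as.numeric(echo_times),
         grid_shape = as.integer(grid_shape), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

rician <- function(a, sigma) {
  if (sigma == 0) return(a)
  n <- length(a)
  sqrt((a + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# Region maps: integer matrices, 0 = background. For the cardiac annulus one
# map per slice with global AHA region ids (basal 1-6, mid 7-12, apical 13-16).
phantom_region_maps <- function(spec) {
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  xs <- rep(seq_len(nx), each = ny); ys <- rep(seq_len(ny), times = nx)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r <- sqrt((xs - cx)^2 + (ys - cy)^2)
  rmax <- min(nx, ny) / 2
  blank <- function() matrix(0L, ny, nx)
  put <- function(m, sel, val) { m[cbind(ys[sel], xs[sel])] <- val; m }

  switch(spec$geometry,
    uniform_disc = , liver_slice = {
      m <- put(blank(), r <= 0.7 * rmax, 1L)
      list(slice = m)
    },
    pancreas_3roi = {
      m <- blank()
      centres <- cbind(x = cx + c(-0.5, 0, 0.5) * rmax, y = cy)
      for (k in 1:3) {
        sel <- sqrt((xs - centres[k, 1])^2 + (ys - centres[k, 2])^2) <= 0.2 * rmax
        m <- put(m, sel, k)
      }
      list(slice = m)
    },
    cardiac_annulus_16seg = {
      ann <- r >= 0.45 * rmax & r <= 0.75 * rmax
      ang <- (atan2(ys - cy, xs - cx) * 180 / pi - 90) %% 360
      maps <- list()
      offs <- c(basal = 0L, mid = 6L, apical = 12L)
      for (lv in names(offs)) {
        nseg <- if (lv == "apical") 4L else 6L
        sector <- pmin(floor(ang / (360 / nseg)) + 1L, nseg)
        maps[[lv]] <- put(blank(), ann, 0L)
        maps[[lv]][cbind(ys[ann], xs[ann])] <- offs[[lv]] + sector[ann]
      }
      maps
    }
  )
}

#' Generate a multi-echo phantom with Rician noise
#'
#' Renders the geometry's regions at their true T2* on the echo grid and
#' corrupts each pixel with Rician noise (the magnitude of a complex
#' Gaussian centred on the model signal), the noise distribution of
#' magnitude MRI. Background pixels have zero true signal, so under noise
#' they follow a Rayleigh distribution with mean `sigma * sqrt(pi/2)`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with `stacks` (named list of
#'   `[n_echo, ny, nx]` arrays, one per slice), `region_maps` (integer
#'   matrices of region ids), `truth` (tibble of region id and true T2*),
#'   and the `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  maps <- phantom_region_maps(spec)
  te <- spec$echo_times
  stacks <- lapply(maps, function(m) {
    stack <- array(0, dim = c(length(te), dim(m)))
    for (k in seq_along(te)) {
      a <- matrix(0, nrow(m), ncol(m))
      for (reg in sort(unique(m[m > 0]))) {
        a[m == reg] <- spec$s0 * exp(-te[k] / spec$t2star[reg]) + spec$offset
      }
      stack[k, , ] <- rician(a, spec$noise_sigma)
    }
    stack
  })
  structure(
    list(
      stacks = stacks,
      region_maps = maps,
      truth = tibble::tibble(region = seq_along(spec$t2star),
                             t2star = spec$t2star),
      spec = spec
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$spec$geometry, ", ", length(x$stacks), " slice(s), ",
      nrow(x$truth), " region(s), sigma = ", x$spec$noise_sigma, "\n", sep = "")
  invisible(x)
}

#' Extract per-region ROI-mean decay series from a phantom
#'
#' @param phantom A [make_phantom()] result.
#' @return A list of [echo_series()], one per region in region-id order (for
#'   the cardiac annulus: AHA segments 1-16).
#' @export
phantom_series <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  spec <- phantom$spec
  noise_sd <- if (spec$noise_sigma > 0) spec$noise_sigma else NULL
  out <- vector("list", nrow(phantom$truth))
  for (i in seq_along(phantom$stacks)) {
    m <- phantom$region_maps[[i]]
    for (reg in sort(unique(m[m > 0]))) {
      out[[reg]] <- roi_mean_decay(phantom$stacks[[i]], m == reg,
                                   spec$echo_times, noise_sd = noise_sd)
    }
  }
  out
}

#' Write/read a phantom as NIfTI volumes plus JSON sidecar
#'
#' Each slice is written as a NIfTI volume with echoes along the third
#' dimension, next to a JSON sidecar holding `echo_times_ms` and `noise_sd`
#' and a JSON file with the ground-truth map.
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return `write_phantom()` returns `dir` invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spec <- phantom$spec
  for (nm in names(phantom$stacks)) {
    vol <- aperm(phantom$stacks[[nm]], c(2, 3, 1))   # ny, nx, n_echo
    RNifti::writeNifti(RNifti::asNifti(vol), file.path(dir, paste0(nm, ".nii")))
    utils::write.table(phantom$region_maps[[nm]],
                       file.path(dir, paste0(nm, "_regions.tsv")),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
  }
  jsonlite::write_json(
    list(echo_times_ms = spec$echo_times,
         noise_sd = if (spec$noise_sigma > 0) spec$noise_sigma else NULL),
    file.path(dir, "sidecar.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a multi-echo stack written by [write_phantom()]
#'
#' @param nifti_path Path to a NIfTI volume with echoes on dimension 3.
#' @param sidecar_path Path to the JSON sidecar with `echo_times_ms` and
#'   optional `noise_sd`.
#' @return A list with `stack` (`[n_echo, ny, nx]` array), `echo_times` and
#'   `noise_sd`.
#' @export
read_echo_stack <- function(nifti_path, sidecar_path) {
  vol <- as.array(RNifti::readNifti(nifti_path))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  stack <- aperm(vol, c(3, 1, 2))
  if (dim(stack)[1] != length(meta$echo_times_ms)) {
    stop("echo count in volume does not match sidecar metadata", call. = FALSE)
  }
  list(stack = stack, echo_times = meta$echo_times_ms,
       noise_sd = meta$noise_sd)
}
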
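#' Simpson's-rule (disc summation) ventricular volume
#'
#' Sums per-slice cavity areas times slice spacing with no geometric model of
#' the ventricle: `V = sum(area_i) * (thickness + gap)`. Areas are in cm2 and
#' spacing in cm, so the result is in mL (1 cm3 = 1 mL). The clinical cine
#' protocol uses 0.8 cm slices with no gap.
#'
#' @param slice_areas Numeric vector of per-slice areas (cm2).
#' @param thickness Slice thickness in cm.
#' @param gap Inter-slice gap in cm.
#' @return Volume in mL.
#' @examples
#' simpson_volume(rep(10, 10), thickness = 0.8)  # 80 mL cylinder
#' @export
simpson_volume <- function(slice_areas, thickness = 0.8, gap = 0) {
  slice_areas <- as.numeric(slice_areas)
  if (length(slice_areas) == 0) stop("no slice areas supplied", call. = FALSE)
  if (any(!is.finite(slice_areas)) || any(slice_areas < 0)) {
    stop("slice areas must be finite and non-negative", call. = FALSE)
  }
  stopifnot(thickness > 0, gap >= 0)
  sum(slice_areas) * (thickness + gap)
}

#' Ejection fraction
#'
#' `EF = (EDV - ESV) * 100 / EDV`, in percent.
#'
#' @param edv End-diastolic volume (mL), positive.
#' @param esv End-systolic volume (mL), `0 <= esv <= edv`.
#' @return Ejection fraction in percent.
#' @export
ejection_fraction <- function(edv, esv) {
  stopifnot(is.finite(edv), is.finite(esv))
  if (edv <= 0) stop("EDV must be positive", call. = FALSE)
  if (esv < 0 || esv > edv) stop("ESV must lie in [0, EDV]", call. = FALSE)
  (edv - esv) * 100 / edv
}

#' Left-ventricular mass from myocardial volume
#'
#' Myocardial volume (epicardial minus endocardial) multiplied by the
#' specific weight of myocardium, 1.05 g/cm3.
#'
#' @param epi_volume,endo_volume Epicardial and endocardial volumes (mL),
#'   with `epi_volume >= endo_volume`.
#' @param density Myocardial specific weight in g/cm3.
#' @return Mass in grams.
#' @export
lv_mass <- function(epi_volume, endo_volume, density = 1.05) {
  stopifnot(is.finite(epi_volume), is.finite(endo_volume))
  if (epi_volume < endo_volume) {
    stop("negative myocardial volume: epicardial volume below endocardial",
         call. = FALSE)
  }
  (epi_volume - endo_volume) * density
}

#' Body surface area
#'
#' Du Bois (`0.007184 * height^0.725 * weight^0.425`, the default) or
#' Mosteller (`sqrt(height * weight / 3600)`).
#'
#' @param height Height in cm, positive.
#' @param weight Weight in kg, positive.
#' @param formula `"dubois"` or `"mosteller"`.
#' @return BSA in m2.
#' @export
body_surface_area <- function(height, weight, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(height <= 0) || any(weight <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  switch(formula,
    dubois = 0.007184 * height^0.725 * weight^0.425,
    mosteller = sqrt(height * weight / 3600)
  )
}

#' Index a value to body surface area
#'
#' @param value Quantity to index (e.g. EDV in mL or mass in g).
#' @param height,weight Anthropometrics (cm, kg).
#' @param formula BSA formula, see [body_surface_area()].
#' @return `value / BSA`, e.g. mL/m2 or g/m2.
#' @export
index_to_bsa <- function(value, height, weight, formula = c("dubois", "mosteller")) {
  value / body_surface_area(height, weight, formula)
}

#' Biventricular function metrics from per-slice cine areas
#'
#' Takes a tidy slice table and computes end-diastolic and end-systolic
#' volumes by disc summation, ejection fraction, left-ventricular mass (from
#' end-diastolic epicardial and endocardial volumes) and BSA-indexed values.
#' The supplied areas are expected to follow the usual convention that
#' papillary muscles are excluded from the blood pool and included in the
#' myocardium; the function operates on the areas as given.
#'
#' @param slices A data frame with columns `phase` (`"ED"` or `"ES"`),
#'   `endo_area` (cm2) and, for ED rows when mass is wanted, `epi_area`
#'   (cm2). One row per slice per phase.
#' @param height,weight Anthropometrics (cm, kg) for BSA indexing.
#' @param thickness,gap Slice geometry in cm.
#' @param bsa_formula BSA formula, see [body_surface_area()].
#' @return A one-row tibble: `edv`, `esv` (mL), `ef` (%), `mass` (g),
#'   `bsa` (m2), `edvi` (mL/m2), `mass_index` (g/m2).
#' @export
ventricular_metrics <- function(slices, height, weight,
                                thickness = 0.8, gap = 0,
                                bsa_formula = c("dubois", "mosteller")) {
  bsa_formula <- match.arg(bsa_formula)
  stopifnot(is.data.frame(slices), all(c("phase", "endo_area") %in% names(slices)))
  ed <- slices[slices$phase == "ED", , drop = FALSE]
  es <- slices[slices$phase == "ES", , drop = FALSE]
  if (nrow(ed) == 0 || nrow(es) == 0) {
    stop("both ED and ES slice sets are required", call. = FALSE)
  }
  edv <- simpson_volume(ed$endo_area, thickness, gap)
  esv <- simpson_volume(es$endo_area, thickness, gap)
  if (esv > edv) stop("end-systolic volume exceeds end-diastolic volume", call. = FALSE)
  mass <- NA_real_
  if ("epi_area" %in% names(slices) && !anyNA(ed$epi_area)) {
    mass <- lv_mass(simpson_volume(ed$epi_area, thickness, gap), edv)
  }
  bsa <- body_surface_area(height, weight, bsa_formula)
  tibble::tibble(
    edv = edv, esv = esv, ef = ejection_fraction(edv, esv),
    mass = mass, bsa = bsa,
    edvi = edv / bsa, mass_index = mass / bsa
  )
}
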
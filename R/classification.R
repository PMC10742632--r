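#' Clinical threshold configuration
#'
#' Bundles every diagnostic cut-off used by the classification stage so the
#' criteria are a single versionable artifact. Defaults follow the usual
#' clinical conventions: US Endocrine Society vitamin-D categories (ng/mL),
#' LIC >= 3 mg/g dw for significant hepatic iron, pancreatic T2* below 26 ms
#' for pancreatic iron (26.0 itself is normal), heart T2* strictly above
#' 20 ms for a normal myocardium (20.0 itself is overloaded), and a PTH
#' normal range of 4.4-58.6 pg/mL inclusive.
#'
#' @param vitd_deficient Vitamin D below this (ng/mL) is deficient.
#' @param vitd_sufficient Vitamin D at or above this (ng/mL) is sufficient.
#' @param lic_overload LIC (mg/g dw) at or above this flags hepatic overload.
#' @param pancreas_normal Pancreatic T2* (ms) below this flags overload.
#' @param heart_normal Heart T2* (ms) at or below this flags overload.
#' @param pth_low,pth_high Inclusive normal PTH range (pg/mL).
#' @return A list of class `iron_thresholds`.
#' @export
iron_thresholds <- function(vitd_deficient = 20, vitd_sufficient = 30,
                            lic_overload = 3, pancreas_normal = 26,
                            heart_normal = 20, pth_low = 4.4, pth_high = 58.6) {
  th <- list(
    vitd_deficient = vitd_deficient, vitd_sufficient = vitd_sufficient,
    lic_overload = lic_overload, pancreas_normal = pancreas_normal,
    heart_normal = heart_normal, pth_low = pth_low, pth_high = pth_high
  )
  if (any(!vapply(th, function(x) is.numeric(x) && is.finite(x) && x > 0, logical(1)))) {
    stop("all thresholds must be positive finite numbers", call. = FALSE)
  }
  if (vitd_deficient >= vitd_sufficient || pth_low >= pth_high) {
    stop("threshold ordering violated", call. = FALSE)
  }
  structure(th, class = "iron_thresholds")
}

#' Read/write a threshold configuration as YAML
#'
#' @param thresholds An [iron_thresholds()] object.
#' @param path File path.
#' @return `write_thresholds()` returns `path` invisibly;
#'   `read_thresholds()` returns an [iron_thresholds()].
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "iron_thresholds"))
  yaml::write_yaml(unclass(thresholds), path, precision = 17)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  do.call(iron_thresholds, yaml::read_yaml(path))
}

#' Vitamin-D status category
#'
#' `< 20` ng/mL deficient, `[20, 30)` insufficient, `>= 30` sufficient
#' (boundaries configurable). Serum 25(OH)D is handled in ng/mL throughout
#' the package.
#'
#' @param vitamin_d 25(OH)D in ng/mL, non-negative (vectorised).
#' @param thresholds An [iron_thresholds()].
#' @return Factor with levels `deficient`, `insufficient`, `sufficient`.
#' @export
vitd_category <- function(vitamin_d, thresholds = iron_thresholds()) {
  if (any(!is.finite(vitamin_d)) || any(vitamin_d < 0)) {
    stop("vitamin D must be finite and non-negative", call. = FALSE)
  }
  out <- ifelse(vitamin_d < thresholds$vitd_deficient, "deficient",
         ifelse(vitamin_d < thresholds$vitd_sufficient, "insufficient",
                "sufficient"))
  factor(out, levels = c("deficient", "insufficient", "sufficient"))
}

#' Parathyroid hormone status
#'
#' Normal range inclusive at both ends; below it low, above it high.
#'
#' @param pth PTH in pg/mL, non-negative (vectorised).
#' @param thresholds An [iron_thresholds()].
#' @return Factor with levels `low`, `normal`, `high`.
#' @export
pth_status <- function(pth, thresholds = iron_thresholds()) {
  if (any(!is.finite(pth)) || any(pth < 0)) {
    stop("PTH must be finite and non-negative", call. = FALSE)
  }
  out <- ifelse(pth < thresholds$pth_low, "low",
         ifelse(pth > thresholds$pth_high, "high", "normal"))
  factor(out, levels = c("low", "normal", "high"))
}

#' Organ iron-overload flags
#'
#' Hepatic overload at `LIC >= 3` mg/g dw; pancreatic overload at global
#' pancreatic `T2* < 26` ms (26.0 itself normal); myocardial overload at
#' global heart `T2* <= 20` ms (normal is strictly above 20 ms).
#'
#' @param lic LIC in mg/g dw.
#' @param pancreas_t2star Global pancreatic T2* in ms.
#' @param heart_t2star Global heart T2* in ms.
#' @param thresholds An [iron_thresholds()].
#' @return A tibble with logical columns `hepatic_overload`,
#'   `pancreatic_overload`, `myocardial_overload`.
#' @export
iron_flags <- function(lic, pancreas_t2star, heart_t2star,
                       thresholds = iron_thresholds()) {
  vals <- c(lic, pancreas_t2star, heart_t2star)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("iron metrics must be finite and non-negative", call. = FALSE)
  }
  tibble::tibble(
    hepatic_overload = lic >= thresholds$lic_overload,
    pancreatic_overload = pancreas_t2star < thresholds$pancreas_normal,
    myocardial_overload = heart_t2star <= thresholds$heart_normal
  )
}

#' Append status flags to a cohort table
#'
#' Applies [vitd_category()], [pth_status()] and [iron_flags()] to the
#' corresponding columns of a patient-level cohort table and appends the
#' results as new columns.
#'
#' @param cohort Data frame with columns `vitamin_d`, `pth`, `lic`,
#'   `pancreas_t2star`, `heart_t2star` (extra columns pass through).
#' @param thresholds An [iron_thresholds()].
#' @return The cohort as a tibble with `vitd_category`, `pth_status`,
#'   `hepatic_overload`, `pancreatic_overload`, `myocardial_overload` added.
#' @export
classify_cohort <- function(cohort, thresholds = iron_thresholds()) {
  stopifnot(is.data.frame(cohort))
  need <- c("vitamin_d", "pth", "lic", "pancreas_t2star", "heart_t2star")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(cohort)
  out$vitd_category <- vitd_category(out$vitamin_d, thresholds)
  out$pth_status <- pth_status(out$pth, thresholds)
  fl <- iron_flags(out$lic, out$pancreas_t2star, out$heart_t2star, thresholds)
  dplyr::bind_cols(out, fl)
}
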
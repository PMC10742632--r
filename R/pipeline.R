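#' Per-patient image measurement chain
#'
#' Runs the full measurement chain for a batch of patients: hepatic T2* and
#' LIC, three-ROI pancreatic T2*, the 16-segment heart map with global value
#' and low-segment count, and cine function metrics. Each patient entry is a
#' list with an `id` and any of: `liver` (an [echo_series()]),
#' `pancreas` (list of 3 series: head, body, tail), `heart` (list of 16
#' series in AHA order), and `function_study` (list with `slices`, `height`,
#' `weight`; see [ventricular_metrics()]). A failing stage is logged with
#' the patient id and the run continues; failures are summarised in the
#' `"failures"` attribute of the result.
#'
#' @param patients List of per-patient input lists.
#' @param thresholds An [iron_thresholds()] (for the low-segment count).
#' @param lic_slope,lic_intercept,calibration_id LIC calibration, see
#'   [lic_from_liver_t2star()].
#' @param correction Optional 16 per-segment correction factors.
#' @param ... Passed to [select_fit()].
#' @return A tibble with one row per patient; attribute `"failures"` holds a
#'   tibble of (id, stage, message) and attribute `"fit_log"` the per-fit
#'   diagnostics (model used, echoes retained).
#' @export
run_image_pipeline <- function(patients, thresholds = iron_thresholds(),
                               lic_slope = 0.0254, lic_intercept = 0.202,
                               calibration_id = "r2star_linear_default",
                               correction = NULL, ...) {
  stopifnot(is.list(patients))
  failures <- list()
  fit_log <- list()
  note_failure <- function(id, stage, e) {
    failures[[length(failures) + 1]] <<- tibble::tibble(
      id = id, stage = stage, message = conditionMessage(e)
    )
  }
  log_fit <- function(id, roi, fit) {
    fit_log[[length(fit_log) + 1]] <<- tibble::tibble(
      id = id, roi = roi, model = fit$model, t2star = fit$t2star,
      n_echoes_used = fit$n_echoes_used, r_squared = fit$r_squared
    )
  }

  rows <- purrr::map(patients, function(p) {
    id <- p$id %||% NA_character_
    row <- tibble::tibble(
      id = id, liver_t2star = NA_real_, lic = NA_real_,
      pancreas_t2star = NA_real_, heart_t2star = NA_real_,
      n_low_segments = NA_integer_,
      edv = NA_real_, esv = NA_real_, ef = NA_real_, mass = NA_real_,
      edvi = NA_real_, mass_index = NA_real_
    )
    if (!is.null(p$liver)) {
      tryCatch({
        fit <- select_fit(p$liver, ...)
        log_fit(id, "liver", fit)
        row$liver_t2star <- fit$t2star
        row$lic <- lic_from_liver_t2star(fit$t2star, lic_slope, lic_intercept,
                                         calibration_id)$lic
      }, error = function(e) note_failure(id, "liver", e))
    }
    if (!is.null(p$pancreas)) {
      tryCatch({
        fits <- lapply(p$pancreas, select_fit, ...)
        for (k in seq_along(fits)) log_fit(id, paste0("pancreas_", k), fits[[k]])
        row$pancreas_t2star <- pancreas_global(fits[[1]], fits[[2]], fits[[3]])$global_value
      }, error = function(e) note_failure(id, "pancreas", e))
    }
    if (!is.null(p$heart)) {
      tryCatch({
        hm <- build_heart_map(p$heart, correction = correction,
                              low_threshold = thresholds$heart_normal, ...)
        for (k in 1:16) log_fit(id, paste0("segment_", k), hm$fits[[k]])
        row$heart_t2star <- hm$global_value
        row$n_low_segments <- hm$n_low_segments
      }, error = function(e) note_failure(id, "heart", e))
    }
    if (!is.null(p$function_study)) {
      tryCatch({
        fs <- p$function_study
        vm <- ventricular_metrics(fs$slices, fs$height, fs$weight)
        row[c("edv", "esv", "ef", "mass", "edvi", "mass_index")] <-
          vm[c("edv", "esv", "ef", "mass", "edvi", "mass_index")]
      }, error = function(e) note_failure(id, "function", e))
    }
    row
  })

  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  if (length(failures)) {
    warning(length(failures), " stage failure(s); see attr(x, 'failures')")
  }
  attr(out, "failures") <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(id = character(0), stage = character(0), message = character(0))
  attr(out, "fit_log") <- if (length(fit_log)) dplyr::bind_rows(fit_log) else NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default cohort analysis plan
#'
#' Mirrors the standard analysis of a vitamin-D/cardiac-iron cohort: group
#' descriptives and three-group comparisons with Bonferroni pairs, an
#' odds-ratio panel (myocardial overload across vitamin-D groups, hepatic
#' overload as a risk factor for inadequate vitamin D), a univariate screen
#' plus stepwise model for global heart T2*, and the ROC of vitamin D
#' against myocardial overload with a Youden cut-off.
#'
#' @return A plan list for [run_cohort_analysis()].
#' @export
default_analysis_plan <- function() {
  list(
    group = "vitd_category",
    compare = c("age", "bmi", "hemoglobin", "ferritin", "alt", "ast", "ggt",
                "lic", "pancreas_t2star", "heart_t2star", "n_low_segments",
                "edvi", "mass_index", "lv_ef", "rv_edvi", "rv_ef"),
    or_panel = list(
      list(name = "mio_deficient_vs_insufficient", outcome = "myocardial_overload",
           exposed = "deficient", reference = "insufficient"),
      list(name = "mio_deficient_vs_sufficient", outcome = "myocardial_overload",
           exposed = "deficient", reference = "sufficient"),
      list(name = "hepatic_overload_for_inadequate_vitd",
           outcome = "inadequate_vitd", exposure = "hepatic_overload")
    ),
    regression = list(
      outcome = "heart_t2star",
      candidates = c("female", "age", "hemoglobin", "ferritin", "vitamin_d",
                     "pth", "lic", "pancreas_t2star")
    ),
    roc = list(score = "vitamin_d", label = "myocardial_overload",
               direction = "low")
  )
}

or_from_plan <- function(data, spec, group_col) {
  if (!is.null(spec$table)) {
    return(odds_ratio_2x2(as.matrix(spec$table)))
  }
  outcome <- data[[spec$outcome]]
  if (is.null(outcome)) stop("plan variable not found in cohort: ", spec$outcome,
                             call. = FALSE)
  if (!is.null(spec$exposure)) {
    expo <- data[[spec$exposure]]
    if (is.null(expo)) stop("plan variable not found in cohort: ", spec$exposure,
                            call. = FALSE)
  } else {
    g <- data[[group_col]]
    keep <- g %in% c(spec$exposed, spec$reference)
    data <- data[keep, , drop = FALSE]
    outcome <- outcome[keep]
    expo <- data[[group_col]] == spec$exposed
  }
  odds_ratio_2x2(sum(expo & outcome), sum(expo & !outcome),
                 sum(!expo & outcome), sum(!expo & !outcome))
}

#' Table-1-style descriptives
#'
#' Mean and SD of each requested variable, overall and (optionally) per
#' group.
#'
#' @param cohort Cohort data frame.
#' @param vars Character vector of numeric columns.
#' @param group Optional grouping column name.
#' @return A tibble in long layout.
#' @export
describe_cohort <- function(cohort, vars, group = NULL) {
  stopifnot(all(vars %in% names(cohort)))
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, dplyr::all_of(c(group, vars))),
    dplyr::all_of(vars), names_to = "variable", values_to = "value"
  )
  if (!is.null(group)) long <- dplyr::group_by(long, .data$variable,
                                               .data[[group]])
  else long <- dplyr::group_by(long, .data$variable)
  dplyr::summarise(long, n = sum(is.finite(.data$value)),
                   mean = mean(.data$value, na.rm = TRUE),
                   sd = stats::sd(.data$value, na.rm = TRUE),
                   .groups = "drop")
}

#' Run the cohort statistics stage
#'
#' Produces the full analysis report from a classified cohort table:
#' descriptives, per-variable group comparisons with Bonferroni pairwise
#' p-values, the odds-ratio panel, the univariate + stepwise regression for
#' global heart T2*, and the ROC/Youden panel. The report is a pure
#' function of its inputs.
#'
#' @param cohort A patient-level data frame; if status-flag columns are
#'   absent they are derived with [classify_cohort()].
#' @param plan Analysis plan, see [default_analysis_plan()].
#' @param thresholds An [iron_thresholds()].
#' @return A list of class `cohort_report`.
#' @export
run_cohort_analysis <- function(cohort, plan = default_analysis_plan(),
                                thresholds = iron_thresholds()) {
  stopifnot(is.data.frame(cohort))
  if (!"vitd_category" %in% names(cohort)) {
    cohort <- classify_cohort(cohort, thresholds)
  }
  if (!"inadequate_vitd" %in% names(cohort) && "vitamin_d" %in% names(cohort)) {
    cohort$inadequate_vitd <- cohort$vitamin_d < thresholds$vitd_sufficient
  }
  if (!"female" %in% names(cohort) && "sex" %in% names(cohort)) {
    cohort$female <- as.numeric(cohort$sex == "F")
  }

  group_col <- plan$group %||% "vitd_category"
  missing <- setdiff(c(group_col, plan$compare), names(cohort))
  if (length(missing)) {
    stop("plan variable(s) not found in cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  compare_vars <- intersect(plan$compare, names(cohort))
  comparisons <- purrr::map(
    stats::setNames(compare_vars, compare_vars),
    function(v) rlang::inject(
      compare_groups(cohort, !!rlang::sym(v), !!rlang::sym(group_col))
    )
  )
  comparison_tbl <- purrr::map_dfr(compare_vars, function(v) {
    dplyr::bind_cols(tibble::tibble(variable = v), glance(comparisons[[v]]))
  })

  or_panel <- purrr::map_dfr(plan$or_panel %||% list(), function(spec) {
    dplyr::bind_cols(tibble::tibble(name = spec$name),
                     or_from_plan(cohort, spec, group_col))
  })

  regression <- NULL
  if (!is.null(plan$regression)) {
    cand <- intersect(plan$regression$candidates, names(cohort))
    regression <- stepwise_t2star_model(cohort, plan$regression$outcome, cand)
  }

  roc <- NULL
  if (!is.null(plan$roc)) {
    roc <- rlang::inject(roc_youden(
      cohort, !!rlang::sym(plan$roc$score), !!rlang::sym(plan$roc$label),
      direction = plan$roc$direction %||% "auto"
    ))
  }

  structure(
    list(
      n = nrow(cohort),
      descriptives = describe_cohort(cohort, compare_vars, group_col),
      group_counts = dplyr::count(cohort, .data[[group_col]], name = "n"),
      comparisons = comparison_tbl,
      pairwise = purrr::map(comparisons, tidy),
      or_panel = or_panel,
      regression = regression,
      roc = roc
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> n =", x$n, "|", nrow(x$comparisons),
      "group comparisons |", nrow(x$or_panel), "odds ratios\n")
  if (!is.null(x$regression)) print(x$regression)
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}

report_as_list <- function(report) {
  list(
    n = report$n,
    group_counts = report$group_counts,
    descriptives = report$descriptives,
    comparisons = report$comparisons,
    pairwise = report$pairwise,
    or_panel = report$or_panel,
    regression = if (!is.null(report$regression)) list(
      univariate = report$regression$univariate,
      retained = report$regression$retained,
      model_f = report$regression$model_f,
      model_p = report$regression$model_p,
      n = report$regression$n
    ),
    roc = if (!is.null(report$roc)) glance(report$roc)
  )
}

#' Serialize a cohort report to JSON
#'
#' @param report A [run_cohort_analysis()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

fmt_tbl <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a cohort report as markdown
#'
#' Every number in the rendered text comes from a field of the JSON
#' serialization; no values are computed at render time.
#'
#' @param report A [run_cohort_analysis()] result.
#' @return A single markdown string.
#' @export
render_report_markdown <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  parts <- c(
    sprintf("# Cohort analysis report (n = %d)", report$n),
    "## Group sizes", fmt_tbl(report$group_counts),
    "## Group comparisons", fmt_tbl(report$comparisons),
    "## Odds-ratio panel",
    if (nrow(report$or_panel)) fmt_tbl(report$or_panel) else "(none)"
  )
  if (!is.null(report$regression)) {
    parts <- c(parts, "## Determinants of global heart T2*",
               fmt_tbl(tidy(report$regression)),
               sprintf("Model F = %.4g, p = %.3g",
                       report$regression$model_f, report$regression$model_p))
  }
  if (!is.null(report$roc)) {
    parts <- c(parts, "## ROC / Youden", fmt_tbl(glance(report$roc)))
  }
  paste(parts, collapse = "\n\n")
}
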
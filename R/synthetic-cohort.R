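group_levels <- c("sufficient", "insufficient", "deficient")

# Per-group marginal moments of the clinical variables, in the units used
# throughout the package. Skewed variables (ferritin, liver enzymes, LIC,
# pancreatic T2*, where the SD approaches or exceeds half the mean) are
# log-normal with exactly moment-matched parameters; the rest are (truncated)
# normal.
default_marginals <- function() {
  m <- function(family, suff, insuff, def, lo = -Inf, hi = Inf) {
    list(family = family, lo = lo, hi = hi,
         moments = list(sufficient = suff, insufficient = insuff, deficient = def))
  }
  list(
    age        = m("normal", c(41.26, 8.19), c(39.63, 9.39), c(36.96, 7.64)),
    bmi        = m("normal", c(22.89, 3.41), c(23.05, 3.47), c(22.54, 3.25)),
    hemoglobin = m("truncnorm", c(9.71, 0.40), c(9.74, 0.43), c(9.62, 0.64), lo = 6),
    ferritin   = m("lognormal", c(797.08, 765.10), c(1014.99, 788.01), c(1425.75, 1822.79)),
    alt        = m("lognormal", c(23.49, 13.26), c(28.17, 20.80), c(36.59, 30.64)),
    ast        = m("lognormal", c(24.12, 12.67), c(25.31, 15.35), c(33.45, 23.79)),
    ggt        = m("lognormal", c(22.50, 19.46), c(20.38, 14.94), c(31.06, 28.16)),
    lic        = m("lognormal", c(3.68, 4.58), c(6.10, 6.62), c(11.11, 15.51)),
    pancreas_t2star = m("lognormal", c(12.69, 7.65), c(11.03, 9.03), c(8.97, 8.01)),
    heart_t2star    = m("truncnorm", c(40.92, 5.96), c(38.25, 7.76), c(33.03, 12.66), lo = 5),
    vitamin_d  = m("truncnorm", c(35, 5), c(24.5, 3), c(14, 4.5)),  # bands applied per group
    pth        = m("truncnorm", c(17.13, 7.66), c(17.13, 7.66), c(17.13, 7.66), lo = 1, hi = 58.6),
    edvi       = m("normal", c(79.17, 14.27), c(85.54, 18.32), c(87.61, 19.19)),
    mass_index = m("normal", c(57.45, 12.90), c(59.84, 12.47), c(63.39, 13.54)),
    lv_ef      = m("normal", c(64.41, 6.74), c(63.45, 6.79), c(62.77, 7.11)),
    rv_edvi    = m("normal", c(81.99, 21.97), c(84.18, 18.55), c(87.67, 21.60)),
    rv_ef      = m("normal", c(61.38, 7.68), c(62.49, 6.77), c(60.79, 6.55))
  )
}

# Whole-cohort Spearman targets among the iron/vitamin axis; reported
# pairwise correlations where available, conservative field-plausible values
# for the unreported ferritin pairs.
default_rank_corr <- function() {
  nm <- c("vitamin_d", "ferritin", "lic", "pancreas_t2star", "heart_t2star", "pth")
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  set <- function(i, j, v) { R[i, j] <<- v; R[j, i] <<- v }
  set("vitamin_d", "ferritin", -0.25)
  set("vitamin_d", "lic", -0.334)
  set("vitamin_d", "pancreas_t2star", 0.277)
  set("vitamin_d", "heart_t2star", 0.287)
  set("vitamin_d", "pth", -0.231)
  set("ferritin", "lic", 0.75)
  set("ferritin", "pancreas_t2star", -0.35)
  set("ferritin", "heart_t2star", -0.431)
  set("ferritin", "pth", 0.065)
  set("lic", "pancreas_t2star", -0.389)
  set("lic", "heart_t2star", -0.393)
  set("lic", "pth", 0.052)
  set("pancreas_t2star", "heart_t2star", 0.396)
  set("pancreas_t2star", "pth", -0.058)
  set("heart_t2star", "pth", -0.042)
  R
}

#' Configuration of the synthetic patient cohort
#'
#' Defaults describe a 278-patient transfusion-dependent thalassemia cohort
#' split into vitamin-D groups of 75 (sufficient), 96 (insufficient) and 107
#' (deficient), with per-group marginal moments for demographics, labs and
#' MRI metrics and a rank-correlation target over the vitamin-D/iron axis
#' (vitamin D, ferritin, LIC, pancreatic and cardiac T2*, PTH). Rank (not
#' Pearson) correlation is targeted because it survives the log-normal
#' marginal transforms of the Gaussian copula.
#'
#' @param group_n Named sizes of the three vitamin-D groups.
#' @param female_prop Named per-group probability of female sex.
#' @param marginals Per-variable marginal families and per-group moments;
#'   see `ferriscope:::default_marginals()` for the structure.
#' @param rank_corr Symmetric Spearman-correlation target matrix for the
#'   copula block; repaired to the nearest positive-definite matrix if
#'   needed.
#' @param vitd_bands Per-group truncation bands (ng/mL) keeping each
#'   patient's vitamin D inside their group's category.
#' @param seg_sd Assumed SD (ms) of segmental T2* around the global value,
#'   used to derive the low-segment count.
#' @param seed Default RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_n = c(sufficient = 75, insufficient = 96, deficient = 107),
                          female_prop = c(sufficient = 0.627, insufficient = 0.615,
                                          deficient = 0.486),
                          marginals = default_marginals(),
                          rank_corr = default_rank_corr(),
                          vitd_bands = list(sufficient = c(30, 60),
                                            insufficient = c(20, 30),
                                            deficient = c(4, 20)),
                          seg_sd = 3, seed = 1) {
  stopifnot(identical(names(group_n), group_levels), all(group_n >= 2),
            isSymmetric(rank_corr), all(diag(rank_corr) == 1))
  cfg <- structure(
    list(group_n = group_n, female_prop = female_prop, marginals = marginals,
         rank_corr = rank_corr, vitd_bands = vitd_bands, seg_sd = seg_sd,
         seed = seed),
    class = "cohort_config"
  )
  cfg$latent_corr <- calibrate_latent_corr(cfg)
  cfg
}

rank_to_latent <- function(R) {
  L <- 2 * sin(pi * R / 6)
  diag(L) <- 1
  L <- as.matrix(Matrix::nearPD(L, corr = TRUE)$mat)
  dimnames(L) <- dimnames(R)
  L
}

# Draw only the copula block at an inflated sample size, for calibration.
copula_block <- function(latent, config, mult) {
  ch <- chol(latent)
  vars <- colnames(latent)
  purrr::map_dfr(group_levels, function(g) {
    n <- config$group_n[[g]] * mult
    z <- matrix(stats::rnorm(n * length(vars)), n) %*% ch
    u <- stats::pnorm(z)
    colnames(u) <- vars
    tibble::as_tibble(lapply(stats::setNames(vars, vars), function(v) {
      spec <- config$marginals[[v]]
      if (v == "vitamin_d") {
        band <- config$vitd_bands[[g]]
        spec$lo <- band[1]; spec$hi <- band[2]
      }
      marginal_quantile(u[, v], spec, g)
    }))
  })
}

# The configured rank correlations are whole-cohort targets, but generation
# is per group with group-specific marginals, so aligned group means add a
# between-group component on top of the within-group copula. A fixed-point
# iteration (deterministic: internal fixed seed, inflated n) deflates the
# within-group latent correlations until the pooled Spearman matrix matches
# the target.
calibrate_latent_corr <- function(config, iterations = 4, mult = 20) {
  target <- config$rank_corr
  within_rank <- target
  latent <- rank_to_latent(within_rank)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (i in seq_len(iterations)) {
    set.seed(104729L)
    sim <- copula_block(latent, config, mult)
    pooled <- stats::cor(as.matrix(sim), method = "spearman")
    within_rank <- within_rank + (target - pooled[colnames(target), colnames(target)])
    within_rank[] <- pmin(pmax(within_rank, -0.97), 0.97)
    diag(within_rank) <- 1
    latent <- rank_to_latent(within_rank)
  }
  latent
}

qtnorm <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

marginal_quantile <- function(u, spec, group) {
  mo <- spec$moments[[group]]
  switch(spec$family,
    normal = stats::qnorm(u, mo[1], mo[2]),
    truncnorm = qtnorm(u, mo[1], mo[2], spec$lo, spec$hi),
    lognormal = {
      p <- lnorm_params(mo[1], mo[2])
      stats::qlnorm(u, p[["mu"]], p[["sigma"]])
    },
    stop("unknown marginal family: ", spec$family)
  )
}

n_low_from_heart <- function(heart, seg_sd, threshold = 20) {
  as.integer(round(16 * stats::pnorm((threshold - heart) / seg_sd)))
}

#' Generate a synthetic patient cohort
#'
#' Gaussian-copula generation: within each vitamin-D group a latent
#' multivariate normal with the target rank-correlation structure (converted
#' to latent Pearson via `2 sin(pi * rho / 6)` and repaired to the nearest
#' positive-definite correlation matrix) is transformed through each
#' variable's configured marginal. Vitamin D is truncated inside the group's
#' category band, so category counts match the group sizes exactly by
#' construction. Remaining variables are drawn independently from their
#' group marginals. The low-segment count is derived from the global heart
#' T2* assuming segmental values spread `seg_sd` ms around it. Output is
#' deterministic for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed (defaults to the one in `config`).
#' @return A tibble with one row per patient.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)

  copula_vars <- colnames(config$rank_corr)
  latent <- config$latent_corr %||% rank_to_latent(config$rank_corr)
  ch <- tryCatch(chol(latent), error = function(e) {
    stop("correlation target is not positive definite after repair", call. = FALSE)
  })

  other_vars <- setdiff(names(config$marginals), copula_vars)
  out <- purrr::map_dfr(group_levels, function(g) {
    n <- config$group_n[[g]]
    z <- matrix(stats::rnorm(n * length(copula_vars)), n) %*% ch
    u <- stats::pnorm(z)
    colnames(u) <- copula_vars
    row <- tibble::tibble(group = g)
    df <- tibble::as_tibble(lapply(stats::setNames(copula_vars, copula_vars), function(v) {
      spec <- config$marginals[[v]]
      if (v == "vitamin_d") {
        band <- config$vitd_bands[[g]]
        spec$lo <- band[1]; spec$hi <- band[2]
      }
      marginal_quantile(u[, v], spec, g)
    }))
    for (v in other_vars) {
      df[[v]] <- marginal_quantile(stats::runif(n), config$marginals[[v]], g)
    }
    df$sex <- ifelse(stats::rbinom(n, 1, config$female_prop[[g]]) == 1, "F", "M")
    df$group <- g
    df
  })

  out$group <- factor(out$group, levels = group_levels)
  out$n_low_segments <- n_low_from_heart(out$heart_t2star, config$seg_sd)
  out$id <- seq_len(nrow(out))
  dplyr::relocate(out, "id", "group", "sex", "age", "bmi")
}

#' Calibrate the per-group prevalence of myocardial iron overload
#'
#' Applies a per-group, tail-limited location shift to the global heart T2*
#' values so that the number of patients below the 20 ms threshold in each
#' vitamin-D group equals the target exactly. The group is split between its
#' k-th and (k+1)-th order statistics; only the side of the split that sits
#' on the wrong side of the threshold is shifted onto it, so the transform
#' is monotone, preserves within-group ranks and leaves the bulk of the
#' distribution (and hence the group moments) essentially untouched. The
#' low-segment count is re-derived from the shifted values.
#'
#' @param cohort A [generate_cohort()] table.
#' @param targets Named per-group target counts of patients with heart T2*
#'   below threshold.
#' @param threshold Myocardial overload threshold in ms.
#' @param seg_sd Segmental spread (ms) used to re-derive `n_low_segments`.
#' @return The calibrated cohort tibble.
#' @export
calibrate_mio_prevalence <- function(cohort,
                                     targets = c(sufficient = 1, insufficient = 3,
                                                 deficient = 23),
                                     threshold = 20, seg_sd = 3) {
  stopifnot(is.data.frame(cohort),
            all(c("group", "heart_t2star") %in% names(cohort)))
  out <- tibble::as_tibble(cohort)
  for (g in names(targets)) {
    idx <- which(out$group == g)
    n <- length(idx)
    k <- targets[[g]]
    if (k > n) stop("infeasible target for group '", g, "': ", k, " > ", n,
                    call. = FALSE)
    s <- sort(out$heart_t2star[idx])
    lo <- if (k == 0) s[1] - 1 else s[k]
    hi <- if (k == n) s[n] + 1 else s[k + 1]
    b <- (lo + hi) / 2                   # split: exactly k values below b
    delta <- threshold - b
    x <- out$heart_t2star[idx]
    if (delta < 0) {
      # scale the low tail under the threshold (multiplicative location
      # change on the log scale, so values stay positive)
      x[x < b] <- x[x < b] * (threshold / b)
    } else if (delta > 0) {
      x[x > b] <- x[x > b] + delta       # push the rest above threshold
    }
    out$heart_t2star[idx] <- x
  }
  if (any(out$heart_t2star <= 0)) {
    stop("calibration pushed heart T2* non-positive; widen the generator's lower bound",
         call. = FALSE)
  }
  out$n_low_segments <- n_low_from_heart(out$heart_t2star, seg_sd, threshold)
  out
}

#' Write/read a cohort table as CSV
#'
#' @param cohort Cohort tibble.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   tibble with the `group` column restored as a factor.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("group" %in% names(out)) {
    out$group <- factor(out$group, levels = group_levels)
  }
  out
}
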
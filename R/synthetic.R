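# Latent variable order used throughout the generator.
LATENT_VARS <- c("height", "logbmi", "wcres", "logtg", "hdl", "logfpg",
                 "sbp", "dbp")

default_latent_corr <- function() {
  nm <- LATENT_VARS
  R <- diag(length(nm))
  dimnames(R) <- list(nm, nm)
  set <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set("logbmi", "logtg", 0.25)
  set("logbmi", "hdl", -0.20)
  set("logbmi", "logfpg", 0.20)
  set("logbmi", "sbp", 0.25)
  set("logbmi", "dbp", 0.20)
  set("wcres", "logtg", 0.15)
  set("wcres", "hdl", -0.10)
  set("wcres", "logfpg", 0.10)
  set("wcres", "sbp", 0.10)
  set("logtg", "hdl", -0.40)
  set("logtg", "logfpg", 0.25)
  set("logtg", "sbp", 0.10)
  set("logtg", "dbp", 0.10)
  set("hdl", "logfpg", -0.10)
  set("logfpg", "sbp", 0.15)
  set("logfpg", "dbp", 0.10)
  set("sbp", "dbp", 0.70)
  R
}

# Per-sex marginal parameters, anchored to the published sex-stratified
# means/SDs (waist, BMI, waist-to-height ratio, TyG index) of a middle-aged
# and elderly Chinese cohort; heights and blood pressures use standard values
# for that population since the source tables do not print them.
default_sex_params <- function(sex) {
  if (sex == "male") {
    list(
      height = list(mean = 1.65, sd = 0.06, lo = 1.40, hi = 1.95),
      logbmi = list(mean = 3.1212, sd = 0.1580),
      wc = list(slope = 2.15, intercept = 35.606, resid_sd = 5.89,
                lo = 40, hi = 180),
      logtg = list(mean = log(1.20), sd = 0.55),
      hdl = list(mean = 1.25, sd = 0.30, lo = 0.40, hi = 3.50),
      logfpg = list(mean = log(5.70), sd = 0.15),
      sbp = list(mean = 129, sd = 20, lo = 80, hi = 230),
      dbp = list(mean = 76, sd = 11, lo = 40, hi = 140),
      age_band_probs = c(`45-54` = 0.2931, `55-64` = 0.3961,
                         `65-74` = 0.2270, `>=75` = 0.0839),
      covariates = list(
        education = c(Illiterate = 0.1366, `Less than elementary school` = 0.7339,
                      `High school` = 0.0829, `Above vocational school` = 0.0465),
        marital_status = c(Single = 0.0924, Married = 0.9076),
        residence = c(Rural = 0.9212, Urban = 0.0788),
        smoking = c(No = 0.2465, `Former smoke` = 0.1684, `Current smoke` = 0.5850),
        drinking = c(No = 0.4399, `Less than once a month` = 0.1083,
                     `More than once a month` = 0.4518),
        activities = c(No = 0.4910, Yes = 0.5090),
        exercise = c(`No exercise` = 0.6221, `Less than exercises` = 0.1866,
                     `Regular exercises` = 0.1912),
        chronic_disease_band = c(`0` = 0.3265, `1-2` = 0.4968, `3-14` = 0.1767)
      )
    )
  } else {
    list(
      height = list(mean = 1.54, sd = 0.06, lo = 1.30, hi = 1.85),
      logbmi = list(mean = 3.1636, sd = 0.1676),
      wc = list(slope = 2.0069, intercept = 37.505, resid_sd = 6.10,
                lo = 40, hi = 180),
      logtg = list(mean = log(1.35), sd = 0.55),
      hdl = list(mean = 1.35, sd = 0.30, lo = 0.40, hi = 3.50),
      logfpg = list(mean = log(5.60), sd = 0.15),
      sbp = list(mean = 130, sd = 22, lo = 80, hi = 230),
      dbp = list(mean = 76, sd = 11, lo = 40, hi = 140),
      age_band_probs = c(`45-54` = 0.3750, `55-64` = 0.3760,
                         `65-74` = 0.1755, `>=75` = 0.0735),
      covariates = list(
        education = c(Illiterate = 0.4252, `Less than elementary school` = 0.5075,
                      `High school` = 0.0494, `Above vocational school` = 0.0178),
        marital_status = c(Single = 0.1503, Married = 0.8497),
        residence = c(Rural = 0.9261, Urban = 0.0739),
        smoking = c(No = 0.9216, `Former smoke` = 0.0186, `Current smoke` = 0.0598),
        drinking = c(No = 0.8796, `Less than once a month` = 0.0498,
                     `More than once a month` = 0.0705),
        activities = c(No = 0.5007, Yes = 0.4993),
        exercise = c(`No exercise` = 0.6129, `Less than exercises` = 0.1946,
                     `Regular exercises` = 0.1925),
        chronic_disease_band = c(`0` = 0.2863, `1-2` = 0.5112, `3-14` = 0.2025)
      )
    )
  }
}

#' Synthetic cohort configuration
#'
#' The frozen default emulates the sex-stratified structure of a middle-aged
#' and elderly Chinese population: sex mix 45.89% male, age drawn from the
#' published band proportions (uniform within band), a multivariate-normal
#' latent vector (height, log-BMI, waist residual, log TG, HDL, log FPG,
#' SBP, DBP) mapped to physical scales (log-normal BMI/TG/FPG, truncated
#' normal height/HDL/pressures), waist built as a sex-specific linear
#' function of BMI plus a correlated residual, categorical covariates from
#' the published proportions, and medication flags correlated with blood
#' pressure and glucose exceedance. Disease status is never drawn directly:
#' it emerges from the generated components through [mets_components()].
#'
#' @param sex_ratio Proportion male.
#' @param latent_corr Correlation matrix over the eight latent variables
#'   (must be symmetric positive-definite).
#' @param male,female Per-sex marginal parameter lists; see the frozen
#'   defaults for the expected shape.
#' @param med_probs Medication/history probabilities, conditional on
#'   exceedance of the relevant threshold.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(sex_ratio = 0.4589,
                          latent_corr = default_latent_corr(),
                          male = default_sex_params("male"),
                          female = default_sex_params("female"),
                          med_probs = list(
                            antihypertensive = c(exceed = 0.28, other = 0.04),
                            antidiabetic = c(exceed = 0.35, other = 0.005),
                            diabetes_history = c(exceed = 0.50, other = 0.02)
                          )) {
  stopifnot(sex_ratio > 0, sex_ratio < 1)
  if (!isTRUE(all.equal(latent_corr, t(latent_corr))) ||
      any(eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values <= 1e-10)) {
    abort("cohort_config: latent_corr must be symmetric positive-definite.")
  }
  if (!identical(dim(latent_corr), c(length(LATENT_VARS), length(LATENT_VARS)))) {
    abort("cohort_config: latent_corr must be 8x8 over the latent variables.")
  }
  for (p in list(male, female)) {
    probs <- p$age_band_probs
    # printed proportions carry rounding error; allow it and renormalize at draw
    if (abs(sum(probs) - 1) > 0.01) abort("age band probabilities must sum to 1.")
    for (cv in p$covariates) {
      if (abs(sum(cv) - 1) > 0.01 || any(cv < 0)) {
        abort("covariate probabilities must be non-negative and sum to 1.")
      }
    }
  }
  structure(list(sex_ratio = sex_ratio, latent_corr = latent_corr,
                 male = male, female = female, med_probs = med_probs),
            class = "cohort_config")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

draw_band_age <- function(band) {
  lo <- c(`45-54` = 45, `55-64` = 55, `65-74` = 65, `>=75` = 75)[band]
  hi <- c(`45-54` = 55, `55-64` = 65, `65-74` = 75, `>=75` = 92)[band]
  stats::runif(length(band), lo, hi)
}

generate_sex_stratum <- function(n, sex, params, latent_corr, med_probs) {
  if (n == 0) return(NULL)
  accepted <- NULL
  n_rejected <- 0
  while (is.null(accepted) || nrow(accepted) < n) {
    need <- n - if (is.null(accepted)) 0 else nrow(accepted)
    m <- max(need + 10, ceiling(need * 1.1))
    z <- MASS::mvrnorm(m, mu = rep(0, length(LATENT_VARS)), Sigma = latent_corr)
    colnames(z) <- LATENT_VARS
    height <- params$height$mean + params$height$sd * z[, "height"]
    bmi <- exp(params$logbmi$mean + params$logbmi$sd * z[, "logbmi"])
    wc <- params$wc$intercept + params$wc$slope * bmi +
      params$wc$resid_sd * z[, "wcres"]
    tg <- exp(params$logtg$mean + params$logtg$sd * z[, "logtg"])
    hdl <- params$hdl$mean + params$hdl$sd * z[, "hdl"]
    fpg <- exp(params$logfpg$mean + params$logfpg$sd * z[, "logfpg"])
    sbp <- params$sbp$mean + params$sbp$sd * z[, "sbp"]
    dbp <- params$dbp$mean + params$dbp$sd * z[, "dbp"]
    weight <- bmi * height^2

    ok <- height > params$height$lo & height < params$height$hi &
      wc > pmax(30, params$wc$lo) & wc < pmin(200, params$wc$hi) &
      weight > 20 & weight < 200 &
      hdl > params$hdl$lo & hdl < params$hdl$hi &
      tg > 0.05 & tg < 20 & fpg > 2 & fpg < 25 &
      sbp > params$sbp$lo & sbp < params$sbp$hi &
      dbp > params$dbp$lo & dbp < params$dbp$hi & dbp < sbp
    n_rejected <- n_rejected + sum(!ok)
    batch <- tibble::tibble(height = height, weight = weight, wc = wc,
                            tg = tg, hdl = hdl, fpg = fpg,
                            sbp = sbp, dbp = dbp)[ok, ]
    accepted <- dplyr::bind_rows(accepted, batch)
  }
  accepted <- accepted[seq_len(n), ]

  band <- sample(names(params$age_band_probs), n, replace = TRUE,
                 prob = params$age_band_probs)
  age <- draw_band_age(band)

  draw_cat <- function(tab) {
    factor(sample(names(tab), n, replace = TRUE, prob = tab / sum(tab)),
           levels = names(tab))
  }
  covs <- purrr::map(params$covariates, draw_cat)

  bp_exceed <- accepted$sbp >= 130 | accepted$dbp >= 85
  fpg_exceed <- accepted$fpg >= 7.0
  draw_flag <- function(p, exceed) {
    stats::runif(n) < ifelse(exceed, p[["exceed"]], p[["other"]])
  }

  dplyr::bind_cols(
    tibble::tibble(sex = sex, age = age),
    accepted,
    tibble::as_tibble(covs),
    tibble::tibble(
      antihypertensive_med = draw_flag(med_probs$antihypertensive, bp_exceed),
      antidiabetic_med = draw_flag(med_probs$antidiabetic, fpg_exceed),
      diabetes_history = draw_flag(med_probs$diabetes_history, fpg_exceed)
    )
  ) |>
    structure(n_rejected = n_rejected)
}

#' Generate a synthetic cohort
#'
#' Draws `n` participant records from the configured population model; fully
#' reproducible from `seed` (the global RNG state is left untouched).
#' Out-of-range latent draws are rejection-resampled; the count is reported
#' in the `n_rejected` attribute.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param config A [cohort_config()].
#' @return Tibble with columns `id`, `sex`, `age`, `height` (m), `weight`
#'   (kg), `wc` (cm), `tg`, `hdl`, `fpg` (mmol/L), `sbp`, `dbp` (mmHg),
#'   medication/history flags, and the categorical covariates.
#' @examples
#' cohort <- generate_cohort(n = 200, seed = 42)
#' dplyr::count(cohort, sex)
#' @export
generate_cohort <- function(n = 9457, seed = 1, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"), n >= 1)
  with_local_seed(seed, {
    n_male <- stats::rbinom(1, n, config$sex_ratio)
    males <- generate_sex_stratum(n_male, "male", config$male,
                                  config$latent_corr, config$med_probs)
    females <- generate_sex_stratum(n - n_male, "female", config$female,
                                    config$latent_corr, config$med_probs)
    n_rejected <- sum(attr(males, "n_rejected") %||% 0,
                      attr(females, "n_rejected") %||% 0)
    out <- dplyr::bind_rows(males, females) |>
      dplyr::mutate(id = sprintf("S%05d", dplyr::row_number()),
                    sex = factor(.data$sex, levels = c("male", "female"))) |>
      dplyr::relocate("id")
    attr(out, "n_rejected") <- n_rejected
    attr(out, "seed") <- seed
    out
  })
}
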
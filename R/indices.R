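#' @importFrom rlang .data abort warn `%||%`
#' @importFrom stats setNames
NULL

# Scale constant: a body shape index is reported multiplied by 100 so that
# typical values land near 8 (population mean 8.3) instead of 0.083; screening
# cut-offs are scale-covariant, so conclusions are unchanged.
ABSI_SCALE <- 100

# Conicity normalization: WC(m) / (0.109 * sqrt(weight/height)). 0.109 is the
# standard constant (= sqrt(4*pi/1050) for body density ~1050 kg/m^3 scaled);
# population means ~1.27 are only consistent with this value.
CONICITY_CONSTANT <- 0.109

check_positive <- function(..., .what = NULL) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", nms[i]))
    if (any(!is.na(x) & x <= 0)) {
      abort(sprintf("`%s` must be strictly positive%s.", nms[i],
                    if (is.null(.what)) "" else paste0(" in ", .what)))
    }
  }
  invisible(TRUE)
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female") & !is.na(sex)
  if (any(bad)) {
    abort(sprintf("`sex` must be \"male\" or \"female\"; got %s.",
                  paste(unique(sex[bad]), collapse = ", ")))
  }
  sex
}

#' Body mass index
#'
#' @param weight Body weight in kg.
#' @param height Standing height in metres.
#' @return BMI in kg/m^2.
#' @examples compute_bmi(70, 1.70)
#' @export
compute_bmi <- function(weight, height) {
  check_positive(weight = weight, height = height, .what = "compute_bmi")
  weight / height^2
}

#' Waist-to-height ratio
#'
#' @param wc Waist circumference in cm.
#' @param height Height in metres.
#' @return Dimensionless ratio (waist and height on the same length scale).
#' @export
compute_whtr <- function(wc, height) {
  check_positive(wc = wc, height = height, .what = "compute_whtr")
  wc / (height * 100)
}

#' Visceral adiposity index
#'
#' Sex-specific composite of waist circumference, BMI, triglycerides and
#' HDL-C. Male: (WC / (39.68 + 1.88 BMI)) (TG/1.03) (1.31/HDL); female:
#' (WC / (36.58 + 1.89 BMI)) (TG/0.81) (1.52/HDL).
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param wc Waist circumference, cm.
#' @param bmi Body mass index, kg/m^2.
#' @param tg Triglycerides, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @return Dimensionless index.
#' @export
compute_vai <- function(sex, wc, bmi, tg, hdl) {
  sex <- check_sex(sex)
  check_positive(wc = wc, bmi = bmi, tg = tg, hdl = hdl, .what = "compute_vai")
  male <- (wc / (39.68 + 1.88 * bmi)) * (tg / 1.03) * (1.31 / hdl)
  female <- (wc / (36.58 + 1.89 * bmi)) * (tg / 0.81) * (1.52 / hdl)
  ifelse(sex == "male", male, female)
}

#' A body shape index (x100 scale)
#'
#' WC normalized by BMI^(2/3) * height^(1/2), with waist in metres, reported
#' on a x100 scale so that population values land near 8.
#'
#' @inheritParams compute_vai
#' @param height Height in metres.
#' @export
compute_absi <- function(wc, bmi, height) {
  check_positive(wc = wc, bmi = bmi, height = height, .what = "compute_absi")
  ABSI_SCALE * (wc / 100) / (bmi^(2 / 3) * sqrt(height))
}

#' Body roundness index
#'
#' Eccentricity-based transform of waist circumference and height:
#' 364.2 - 365.5 sqrt(1 - (WC/2pi)^2 / (0.5 height)^2), lengths in metres.
#' Requires WC/(2pi) < height/2, i.e. the body ellipse eccentricity argument
#' stays in \[0, 1).
#'
#' @inheritParams compute_absi
#' @export
compute_bri <- function(wc, height) {
  check_positive(wc = wc, height = height, .what = "compute_bri")
  r <- (wc / 100) / (2 * pi)
  arg <- 1 - r^2 / (0.5 * height)^2
  if (any(!is.na(arg) & arg < 0)) {
    abort("compute_bri: waist circumference too large relative to height (radicand < 0).")
  }
  364.2 - 365.5 * sqrt(arg)
}

#' Lipid accumulation product
#'
#' (WC - 65) * TG for men, (WC - 58) * TG for women; waist in cm,
#' triglycerides in mmol/L. Values below the sex offset give a negative
#' product, which is retained (ROC ranking needs ordering, not positivity).
#'
#' @inheritParams compute_vai
#' @return cm * mmol/L.
#' @export
compute_lap <- function(sex, wc, tg) {
  sex <- check_sex(sex)
  check_positive(tg = tg, .what = "compute_lap")
  offset <- ifelse(sex == "male", 65, 58)
  (wc - offset) * tg
}

#' Conicity index
#'
#' WC(m) / (0.109 sqrt(weight / height)): the waist relative to the
#' circumference of a cylinder with the same weight and height.
#'
#' @inheritParams compute_bmi
#' @param wc Waist circumference, cm.
#' @export
compute_ci <- function(wc, weight, height) {
  check_positive(wc = wc, weight = weight, height = height, .what = "compute_ci")
  (wc / 100) / (CONICITY_CONSTANT * sqrt(weight / height))
}

#' Chinese visceral adiposity index
#'
#' Sex-specific linear score of age, BMI, WC, log10 triglycerides and HDL-C
#' calibrated for Chinese adults. Male: -267.93 + 0.68 age + 0.03 BMI +
#' 4.00 WC + 22.00 log10(TG) - 16.32 HDL; female: -187.32 + 1.71 age +
#' 4.32 BMI + 1.12 WC + 39.76 log10(TG) - 11.66 HDL.
#'
#' @inheritParams compute_vai
#' @param age Age in years.
#' @export
compute_cvai <- function(sex, age, bmi, wc, tg, hdl) {
  sex <- check_sex(sex)
  check_positive(tg = tg, .what = "compute_cvai")
  male <- -267.93 + 0.68 * age + 0.03 * bmi + 4.00 * wc +
    22.00 * log10(tg) - 16.32 * hdl
  female <- -187.32 + 1.71 * age + 4.32 * bmi + 1.12 * wc +
    39.76 * log10(tg) - 11.66 * hdl
  ifelse(sex == "male", male, female)
}

#' Triglyceride-glucose index
#'
#' ln(TG\[mg/dL\] x glucose\[mg/dL\] / 2), an insulin-resistance surrogate.
#' Inputs arrive in mmol/L (the package's canonical storage) and are
#' converted internally to mg/dL as the formula requires.
#'
#' @param tg Triglycerides, mmol/L.
#' @param fpg Fasting plasma glucose, mmol/L.
#' @export
compute_tyg <- function(tg, fpg) {
  check_positive(tg = tg, fpg = fpg, .what = "compute_tyg")
  tg_mgdl <- convert_analyte(tg, "tg", "mmol_L", "mg_dL")
  fpg_mgdl <- convert_analyte(fpg, "glucose", "mmol_L", "mg_dL")
  log(tg_mgdl * fpg_mgdl / 2)
}

#' TyG anthropometric combinations
#'
#' Elementwise products TyG x BMI, TyG x WC and TyG x WHtR.
#'
#' @param tyg Triglyceride-glucose index values.
#' @param bmi,wc,whtr The anthropometric cofactors.
#' @return A tibble with columns `tyg_bmi`, `tyg_wc`, `tyg_whtr`.
#' @export
compute_tyg_combos <- function(tyg, bmi, wc, whtr) {
  tibble::tibble(
    tyg_bmi = tyg * bmi,
    tyg_wc = tyg * wc,
    tyg_whtr = tyg * whtr
  )
}

#' Names of the thirteen screening indices
#'
#' @return Character vector in the conventional reporting order.
#' @export
index_names <- function() {
  c("wc", "bmi", "whtr", "vai", "absi", "bri", "lap", "ci", "cvai",
    "tyg", "tyg_bmi", "tyg_wc", "tyg_whtr")
}

#' Compute the full index panel for a cohort
#'
#' Adds the thirteen obesity- and lipid-related index columns to a cohort
#' tibble. Required columns: `sex` ("male"/"female"), `age` (years), `height`
#' (m), `weight` (kg), `wc` (cm), `tg`, `hdl`, `fpg` (all mmol/L). Waist
#' circumference itself is the first index and is passed through unchanged.
#'
#' Rows violating a formula's domain (e.g. waist too large for the body
#' roundness radicand) get `NA` for the offending index and are reported in
#' the `rejected_indices` attribute rather than aborting the cohort run.
#'
#' @param data A cohort data frame.
#' @return The input as a tibble with columns `bmi`, `whtr`, `vai`, `absi`,
#'   `bri`, `lap`, `ci`, `cvai`, `tyg`, `tyg_bmi`, `tyg_wc`, `tyg_whtr`
#'   appended.
#' @examples
#' cohort <- generate_cohort(n = 50, seed = 1)
#' panel <- compute_index_panel(cohort)
#' dplyr::select(panel, id, sex, bmi, lap, tyg_wc)
#' @export
compute_index_panel <- function(data) {
  required <- c("sex", "age", "height", "weight", "wc", "tg", "hdl", "fpg")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("compute_index_panel: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  sex <- check_sex(data$sex)

  # BRI's radicand can go negative for extreme waist/height pairs; compute it
  # guarded so one bad record does not abort the cohort.
  r <- (data$wc / 100) / (2 * pi)
  arg <- 1 - r^2 / (0.5 * data$height)^2
  bri <- ifelse(!is.na(arg) & arg >= 0, 364.2 - 365.5 * sqrt(pmax(arg, 0)), NA_real_)
  n_bri_rejected <- sum(!is.na(arg) & arg < 0)

  out <- data |>
    dplyr::mutate(
      bmi = compute_bmi(.data$weight, .data$height),
      whtr = compute_whtr(.data$wc, .data$height),
      vai = compute_vai(sex, .data$wc, .data$bmi, .data$tg, .data$hdl),
      absi = compute_absi(.data$wc, .data$bmi, .data$height),
      bri = bri,
      lap = compute_lap(sex, .data$wc, .data$tg),
      ci = compute_ci(.data$wc, .data$weight, .data$height),
      cvai = compute_cvai(sex, .data$age, .data$bmi, .data$wc, .data$tg, .data$hdl),
      tyg = compute_tyg(.data$tg, .data$fpg),
      tyg_bmi = .data$tyg * .data$bmi,
      tyg_wc = .data$tyg * .data$wc,
      tyg_whtr = .data$tyg * .data$whtr
    )
  if (n_bri_rejected > 0) {
    warn(sprintf("compute_index_panel: %d record(s) outside the body-roundness domain; bri set to NA.",
                 n_bri_rejected))
  }
  attr(out, "rejected_indices") <- c(bri = n_bri_rejected)
  out
}
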
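# NCEP ATP III thresholds (Chinese waist cut-offs), analyte thresholds in
# mg/dL exactly as the definition states them.
METS_THRESHOLDS <- list(
  wc_male = 90, wc_female = 80,      # cm, inclusive
  tg_mgdl = 150,                     # inclusive
  hdl_male_mgdl = 40, hdl_female_mgdl = 50, # strict <
  sbp = 130, dbp = 85,               # mmHg, inclusive
  fpg_mgdl = 100                     # inclusive
)

#' Evaluate the five NCEP ATP III components and the MetS diagnosis
#'
#' Applies the NCEP ATP III (2005) definition with Chinese waist thresholds:
#' central obesity WC >= 90 cm (men) / >= 80 cm (women); triglycerides
#' >= 150 mg/dL; HDL-C < 40 mg/dL (men) / < 50 mg/dL (women); blood pressure
#' SBP >= 130 or DBP >= 85 mmHg or antihypertensive therapy; fasting glucose
#' >= 100 mg/dL or antidiabetic medication or diabetes history. Metabolic
#' syndrome is diagnosed when at least 3 of the 5 components are present.
#' Medication/history overrides apply to blood pressure and glucose only;
#' lipid-lowering therapy is not part of the definition used here.
#'
#' Analytes are taken from the canonical mmol/L columns and converted to
#' mg/dL internally, so the diagnosis is invariant to the unit the data were
#' supplied in (conversion happens once, at ingest).
#'
#' @param data Cohort tibble with columns `sex`, `wc`, `tg`, `hdl`, `fpg`,
#'   `sbp`, `dbp`, and logical `antihypertensive_med`, `antidiabetic_med`,
#'   `diabetes_history` (missing medication/history columns are treated as
#'   all-FALSE with a warning).
#' @return The input tibble with logical columns `central_obesity`,
#'   `elevated_tg`, `low_hdl`, `elevated_bp`, `elevated_fpg`, integer
#'   `n_components` and logical `mets` appended.
#' @examples
#' cohort <- generate_cohort(n = 100, seed = 1)
#' flags <- mets_components(cohort)
#' table(flags$mets)
#' @export
mets_components <- function(data) {
  required <- c("sex", "wc", "tg", "hdl", "fpg", "sbp", "dbp")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("mets_components: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  sex <- check_sex(data$sex)
  for (flag in c("antihypertensive_med", "antidiabetic_med", "diabetes_history")) {
    if (!flag %in% names(data)) {
      warn(sprintf("mets_components: column `%s` absent; assuming FALSE.", flag))
      data[[flag]] <- FALSE
    }
  }
  th <- METS_THRESHOLDS
  tg_mgdl <- convert_analyte(data$tg, "tg", "mmol_L", "mg_dL")
  hdl_mgdl <- convert_analyte(data$hdl, "hdl", "mmol_L", "mg_dL")
  fpg_mgdl <- convert_analyte(data$fpg, "glucose", "mmol_L", "mg_dL")

  out <- data |>
    dplyr::mutate(
      central_obesity = ifelse(sex == "male",
                               .data$wc >= th$wc_male,
                               .data$wc >= th$wc_female),
      elevated_tg = tg_mgdl >= th$tg_mgdl,
      low_hdl = ifelse(sex == "male",
                       hdl_mgdl < th$hdl_male_mgdl,
                       hdl_mgdl < th$hdl_female_mgdl),
      elevated_bp = .data$sbp >= th$sbp | .data$dbp >= th$dbp |
        .data$antihypertensive_med,
      elevated_fpg = fpg_mgdl >= th$fpg_mgdl | .data$antidiabetic_med |
        .data$diabetes_history,
      n_components = as.integer(.data$central_obesity) +
        as.integer(.data$elevated_tg) + as.integer(.data$low_hdl) +
        as.integer(.data$elevated_bp) + as.integer(.data$elevated_fpg),
      mets = .data$n_components >= 3L
    )
  out
}

#' Age bands used for stratified prevalence
#'
#' \[45,54\], \[55,64\], \[65,74\], \[75, Inf).
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels `45-54`, `55-64`, `65-74`, `>=75`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 55, 65, 75, Inf), right = FALSE,
      labels = c("45-54", "55-64", "65-74", ">=75"))
}

#' Stratified metabolic-syndrome prevalence
#'
#' Prevalence (percent, 2 decimals in printed reports) overall, by sex, and
#' by sex within age band, from a cohort that already carries the `mets`
#' column (see [mets_components()]); the flags are computed on the fly if
#' absent.
#'
#' @param data Cohort tibble.
#' @return Tibble with columns `stratum`, `sex`, `age_band`, `n`, `n_mets`,
#'   `prevalence_percent`.
#' @export
mets_prevalence <- function(data) {
  if (nrow(data) == 0) abort("mets_prevalence: empty cohort.")
  if (!"mets" %in% names(data)) data <- mets_components(data)
  data <- dplyr::mutate(data, .band = age_band(.data$age))

  overall <- data |>
    dplyr::summarise(n = dplyr::n(), n_mets = sum(.data$mets)) |>
    dplyr::mutate(stratum = "overall", sex = NA_character_, age_band = NA_character_)
  by_sex <- data |>
    dplyr::group_by(sex = as.character(.data$sex)) |>
    dplyr::summarise(n = dplyr::n(), n_mets = sum(.data$mets), .groups = "drop") |>
    dplyr::mutate(stratum = "sex", age_band = NA_character_)
  by_sex_age <- data |>
    dplyr::group_by(sex = as.character(.data$sex),
                    age_band = as.character(.data$.band)) |>
    dplyr::summarise(n = dplyr::n(), n_mets = sum(.data$mets), .groups = "drop") |>
    dplyr::mutate(stratum = "sex_age")

  dplyr::bind_rows(overall, by_sex, by_sex_age) |>
    dplyr::mutate(prevalence_percent = 100 * .data$n_mets / .data$n) |>
    dplyr::select("stratum", "sex", "age_band", "n", "n_mets", "prevalence_percent")
}
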
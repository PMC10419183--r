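#' Clinical unit conversion factors
#'
#' Molar-mass conversion factors between conventional (mg/dL) and SI (mmol/L)
#' units for the three analytes the index formulas use. Values are the standard
#' clinical factors: 1 mmol/L of triglycerides = 88.57 mg/dL, of glucose =
#' 18.016 mg/dL, of HDL cholesterol = 38.67 mg/dL.
#'
#' @format Named numeric vector, mg/dL per mmol/L.
#' @export
ANALYTE_MGDL_PER_MMOL <- c(
  tg      = 88.57,
  glucose = 18.016,
  hdl     = 38.67
)

#' Convert an analyte concentration between mg/dL and mmol/L
#'
#' The index formulas disagree on units: the lipid accumulation product takes
#' triglycerides in mmol/L while the triglyceride-glucose index takes both
#' triglycerides and glucose in mg/dL. All internal storage is mmol/L; each
#' formula converts explicitly through this function.
#'
#' @param value Numeric vector of non-negative concentrations.
#' @param analyte One of `"tg"`, `"glucose"`, `"hdl"`.
#' @param from,to Unit tags, each `"mg_dL"` or `"mmol_L"`.
#' @return Numeric vector on the `to` scale.
#' @examples
#' convert_analyte(1, "tg", "mmol_L", "mg_dL") # 88.57
#' @export
convert_analyte <- function(value, analyte = c("tg", "glucose", "hdl"),
                            from = c("mmol_L", "mg_dL"),
                            to = c("mg_dL", "mmol_L")) {
  analyte <- match.arg(analyte)
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(is.numeric(value), all(is.na(value) | value >= 0))
  if (from == to) {
    return(value)
  }
  factor <- ANALYTE_MGDL_PER_MMOL[[analyte]]
  if (from == "mmol_L") value * factor else value / factor
}
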
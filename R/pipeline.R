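COHORT_REQUIRED_COLS <- c("id", "sex", "age", "height", "weight", "wc",
                          "tg", "hdl", "fpg", "sbp", "dbp")

validate_record_ranges <- function(data) {
  reasons <- rep(NA_character_, nrow(data))
  note <- function(bad, msg) {
    reasons <<- ifelse(bad & is.na(reasons), msg, reasons)
  }
  note(!data$sex %in% c("male", "female"), "sex not male/female")
  note(!is.na(data$height) & (data$height <= 0.5 | data$height >= 2.5),
       "height out of range")
  note(!is.na(data$wc) & (data$wc <= 30 | data$wc >= 200), "wc out of range")
  note(!is.na(data$weight) & (data$weight <= 20 | data$weight >= 200),
       "weight out of range")
  note(!is.na(data$tg) & data$tg <= 0, "tg non-positive")
  note(!is.na(data$hdl) & data$hdl <= 0, "hdl non-positive")
  note(!is.na(data$fpg) & data$fpg <= 0, "fpg non-positive")
  for (col in c("height", "wc", "weight", "tg", "hdl", "fpg", "sbp", "dbp", "age")) {
    note(is.na(data[[col]]), paste(col, "missing"))
  }
  reasons
}

#' Read a cohort CSV with explicit analyte unit declarations
#'
#' The analyte columns (`tg`, `hdl`, `fpg`) may arrive in either mg/dL or
#' mmol/L; the caller must declare which, and values are converted once to
#' the canonical mmol/L storage. Rows violating the record invariants
#' (implausible anthropometry, non-positive analytes, missing required
#' values) are collected into a rejects tibble with reasons rather than
#' aborting; row order is preserved.
#'
#' @param path CSV file path.
#' @param units Named list/vector declaring units for `tg`, `hdl`, `fpg`;
#'   each `"mmol_L"` or `"mg_dL"`.
#' @param age_floor Minimum age retained (default 45, the study population
#'   floor); set to `-Inf` to disable.
#' @return Tibble of accepted records (canonical units, factor covariates);
#'   the rejected rows with a `reject_reason` column are in the `rejects`
#'   attribute.
#' @export
read_cohort_csv <- function(path, units = c(tg = "mmol_L", hdl = "mmol_L",
                                            fpg = "mmol_L"),
                            age_floor = 45) {
  if (!file.exists(path)) abort(paste0("read_cohort_csv: no such file: ", path))
  units <- as.list(units)
  for (a in c("tg", "hdl", "fpg")) {
    if (is.null(units[[a]])) {
      abort(sprintf("read_cohort_csv: no unit declared for `%s`.", a))
    }
    if (!units[[a]] %in% c("mmol_L", "mg_dL")) {
      abort(sprintf("read_cohort_csv: unknown unit `%s` for `%s`.",
                    units[[a]], a))
    }
  }
  data <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(setdiff(COHORT_REQUIRED_COLS, "id"), names(data))
  if (length(missing) > 0) {
    abort(paste0("read_cohort_csv: missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"id" %in% names(data)) data$id <- sprintf("R%05d", seq_len(nrow(data)))

  analyte_of <- c(tg = "tg", hdl = "hdl", fpg = "glucose")
  for (a in c("tg", "hdl", "fpg")) {
    data[[a]] <- convert_analyte(data[[a]], analyte_of[[a]],
                                 from = units[[a]], to = "mmol_L")
  }
  for (flag in c("antihypertensive_med", "antidiabetic_med", "diabetes_history")) {
    if (flag %in% names(data)) data[[flag]] <- as.logical(data[[flag]])
  }
  for (cov in setdiff(default_covariates(), "age")) {
    if (cov %in% names(data)) data[[cov]] <- factor(data[[cov]])
  }
  data$sex <- as.character(data$sex)

  reasons <- validate_record_ranges(data)
  reasons <- ifelse(is.na(reasons) & data$age < age_floor, "age below floor",
                    reasons)
  rejects <- data[!is.na(reasons), , drop = FALSE]
  rejects$reject_reason <- reasons[!is.na(reasons)]
  accepted <- data[is.na(reasons), , drop = FALSE] |>
    dplyr::mutate(sex = factor(.data$sex, levels = c("male", "female")))
  attr(accepted, "rejects") <- tibble::as_tibble(rejects)
  tibble::as_tibble(accepted)
}

#' Sex-stratified descriptive table
#'
#' Continuous variables as mean +- SD with a pooled-variance two-sample
#' t-test across strata; categorical variables as n (%) with a Pearson
#' chi-square test (no continuity correction). Strata with fewer than two
#' records get their comparison omitted with a note.
#'
#' @param data Cohort tibble.
#' @param strata Name of the stratifying column (default `"sex"`).
#' @param continuous,categorical Column names to summarise; defaults cover
#'   the measurement and covariate sets.
#' @return Tibble: `variable`, `level` (NA for continuous), one summary
#'   column per stratum, `p_value`, `test`.
#' @export
descriptive_table <- function(data,
                              strata = "sex",
                              continuous = intersect(
                                c("age", "height", "weight", "wc", "tg", "hdl",
                                  "fpg", "sbp", "dbp", index_names()),
                                names(data)),
                              categorical = intersect(
                                setdiff(default_covariates(), "age"),
                                names(data))) {
  groups <- split(tibble::as_tibble(data), as.character(data[[strata]]))
  if (length(groups) < 2) abort("descriptive_table: need >= 2 strata.")
  small <- any(vapply(groups, nrow, integer(1)) < 2)
  gnames <- names(groups)

  cont_rows <- purrr::map(continuous, function(v) {
    cells <- purrr::map_chr(groups, function(g) {
      sprintf("%.2f ± %.2f", mean(g[[v]], na.rm = TRUE),
              stats::sd(g[[v]], na.rm = TRUE))
    })
    p <- if (small || length(groups) != 2) NA_real_ else {
      stats::t.test(groups[[1]][[v]], groups[[2]][[v]],
                    var.equal = TRUE)$p.value
    }
    tibble::tibble(variable = v, level = NA_character_,
                   !!!setNames(as.list(cells), gnames),
                   p_value = p, test = "t (pooled)")
  }) |> purrr::list_rbind()

  cat_rows <- purrr::map(categorical, function(v) {
    levels_v <- levels(factor(data[[v]]))
    tab <- vapply(groups, function(g) {
      table(factor(g[[v]], levels = levels_v))
    }, numeric(length(levels_v)))
    tab <- matrix(tab, nrow = length(levels_v),
                  dimnames = list(levels_v, gnames))
    p <- if (small || any(colSums(tab) == 0) || length(levels_v) < 2) {
      NA_real_
    } else if (sum(tab) > 0 && all(rowSums(tab) > 0)) {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    } else {
      NA_real_
    }
    purrr::map(seq_along(levels_v), function(i) {
      cells <- purrr::map_chr(gnames, function(gn) {
        sprintf("%d (%.2f)", tab[i, gn], 100 * tab[i, gn] / sum(tab[, gn]))
      })
      tibble::tibble(variable = v, level = levels_v[i],
                     !!!setNames(as.list(cells), gnames),
                     p_value = if (i == 1) p else NA_real_,
                     test = if (i == 1) "chi-square" else NA_character_)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  dplyr::bind_rows(cont_rows, cat_rows)
}

#' Run the full screening analysis
#'
#' Generates (or ingests) a cohort, computes the index panel and MetS
#' diagnosis, runs the ROC battery and the association tables, and writes
#' the report CSVs plus a JSON run manifest to `output_dir`. Identical
#' inputs, config and seed give byte-identical reports.
#'
#' @param input_path Optional cohort CSV; exactly one of `input_path` /
#'   generator settings is used.
#' @param units Analyte unit declarations for [read_cohort_csv()].
#' @param n,seed,config Generator settings used when `input_path` is NULL.
#' @param output_dir Directory for the reports (created if needed); NULL
#'   skips writing.
#' @param outcomes,covariates Passed to [association_table()].
#' @return Invisible list with `cohort`, `prevalence`, `descriptive`,
#'   `battery`, `associations`, `rejects`, `manifest`.
#' @export
run_full_analysis <- function(input_path = NULL,
                              units = c(tg = "mmol_L", hdl = "mmol_L",
                                        fpg = "mmol_L"),
                              n = 9457, seed = 1, config = cohort_config(),
                              output_dir = NULL,
                              outcomes = c("mets", "elevated_tg", "low_hdl",
                                           "elevated_bp", "elevated_fpg"),
                              covariates = default_covariates()) {
  if (!is.null(input_path)) {
    cohort <- read_cohort_csv(input_path, units = units)
    rejects <- attr(cohort, "rejects")
  } else {
    cohort <- generate_cohort(n = n, seed = seed, config = config)
    rejects <- tibble::tibble()
  }
  if (nrow(cohort) == 0) abort("run_full_analysis: no valid records.")

  cohort <- cohort |> compute_index_panel() |> mets_components()
  prevalence <- mets_prevalence(cohort)
  descriptive <- descriptive_table(cohort)
  battery <- roc_battery(cohort)
  associations <- association_table(cohort, battery, outcomes = outcomes,
                                    covariates = covariates)
  manifest <- list(
    package = "metscreen",
    version = as.character(utils::packageVersion("metscreen")),
    seed = if (is.null(input_path)) seed else NA,
    n_records = nrow(cohort),
    n_rejects = nrow(rejects),
    input = if (is.null(input_path)) "synthetic" else basename(input_path),
    input_sha = if (is.null(input_path)) NA else
      as.character(tools::md5sum(input_path))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, name) {
      readr::write_csv(x, file.path(output_dir, name))
    }
    wr(prevalence, "prevalence.csv")
    wr(descriptive, "descriptive.csv")
    wr(dplyr::mutate(battery, dplyr::across(dplyr::where(is.numeric),
                                            ~ round(.x, 6))),
       "roc_cutpoints.csv")
    wr(associations, "associations.csv")
    if (nrow(rejects) > 0) wr(rejects, "rejects.csv")
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(cohort = cohort, prevalence = prevalence,
                 descriptive = descriptive, battery = battery,
                 associations = associations, rejects = rejects,
                 manifest = manifest))
}
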
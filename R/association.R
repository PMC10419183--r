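#' Dichotomize an index at a screening cut-off
#'
#' Exposure is `value >= cutoff`, the same rule the ROC classification uses,
#' so the dichotomized variable reproduces the screening decision exactly.
#'
#' @param values Numeric vector of index values.
#' @param cutoff Finite threshold.
#' @return Logical vector (NA where the value is missing).
#' @export
dichotomize_index <- function(values, cutoff) {
  if (!is.finite(cutoff)) abort("dichotomize_index: cutoff must be finite.")
  values >= cutoff
}

#' Maximum-likelihood logistic regression with diagnostics
#'
#' Fits a binary logistic model by iteratively reweighted least squares
#' (through [stats::glm()]) and attaches the diagnostics screening pipelines
#' need: a convergence flag and a complete-separation flag (detected from
#' degenerate fitted probabilities together with exploding coefficients),
#' so a degenerate fit is flagged rather than silently reported.
#'
#' @param formula Model formula; the binary outcome on the left.
#' @param data Data frame; rows with missing values in the model variables
#'   are dropped (complete-case) with the count recorded.
#' @return Object of class `mets_logit` wrapping the `glm` fit, with
#'   [generics::tidy()] (per-term OR scale) and [generics::glance()] methods.
#' @examples
#' d <- data.frame(y = c(rep(1, 50), rep(0, 50)),
#'                 x = c(rep(c(1, 0), c(40, 10)), rep(c(1, 0), c(10, 40))))
#' fit <- fit_logistic(y ~ x, d)
#' tidy(fit) # OR 16 for x: the 2x2 cross-product ratio
#' @export
fit_logistic <- function(formula, data) {
  vars <- all.vars(formula)
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0) {
    abort(paste0("fit_logistic: variable(s) not in data: ",
                 paste(missing, collapse = ", ")))
  }
  used <- data[vars]
  complete <- stats::complete.cases(used)
  n_excluded <- sum(!complete)
  data_cc <- data[complete, , drop = FALSE]
  y <- stats::model.response(stats::model.frame(formula, data_cc))
  if (length(unique(y)) < 2) {
    abort("fit_logistic: outcome has a single class after complete-case filtering.")
  }
  fit <- suppressWarnings(
    stats::glm(formula, data = data_cc, family = stats::binomial(),
               control = stats::glm.control(maxit = 100, epsilon = 1e-10))
  )
  eps <- 1e-8
  fitted_degenerate <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  separation <- fitted_degenerate && any(abs(stats::coef(fit)) > 10, na.rm = TRUE)
  structure(
    list(fit = fit, converged = fit$converged, separation = separation,
         n = nrow(data_cc), n_excluded = n_excluded),
    class = "mets_logit"
  )
}

#' @rdname fit_logistic
#' @param x A `mets_logit` object.
#' @param ... Unused.
#' @export
#' @method tidy mets_logit
tidy.mets_logit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  tibble::tibble(
    term = rownames(sm),
    estimate = est,
    std_error = se,
    statistic = unname(sm[, "z value"]),
    p_value = unname(sm[, "Pr(>|z|)"]),
    odds_ratio = exp(est),
    or_ci_lo = exp(est - 1.96 * se),
    or_ci_hi = exp(est + 1.96 * se)
  )
}

#' @rdname fit_logistic
#' @export
#' @method glance mets_logit
glance.mets_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_excluded = x$n_excluded,
    converged = x$converged, separation = x$separation,
    deviance = x$fit$deviance, null_deviance = x$fit$null.deviance,
    aic = x$fit$aic
  )
}

#' @export
print.mets_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, %d excluded%s%s)\n", x$n, x$n_excluded,
              if (!x$converged) ", NOT CONVERGED" else "",
              if (x$separation) ", SEPARATION" else ""))
  print(tidy(x))
  invisible(x)
}

#' Default covariate adjustment set
#'
#' Age plus the categorical covariates the association analysis adjusts for.
#' Within sex strata, sex itself is dropped from the set.
#'
#' @return Character vector of column names.
#' @export
default_covariates <- function() {
  c("age", "education", "marital_status", "residence", "smoking",
    "drinking", "activities", "exercise", "chronic_disease_band")
}

#' Unadjusted and adjusted odds ratios for dichotomized indices
#'
#' Dichotomizes each index at its sex-specific Youden-optimal cut-off and
#' fits, per sex stratum and outcome, an unadjusted logistic model
#' (outcome ~ exposure) and a covariate-adjusted one. Wald 95% CIs
#' (exp(beta +- 1.96 SE)) and Wald p-values are reported. Missing covariates
#' are handled complete-case, with the exclusion count carried per row.
#'
#' @param data Cohort tibble with index columns, outcome columns (see
#'   [mets_components()]) and covariate columns.
#' @param cutpoints Tibble with columns `index`, `sex`, `optimal_cutoff` —
#'   typically the output of [roc_battery()].
#' @param outcomes Character vector of logical outcome columns (default MetS
#'   and its four non-obesity components).
#' @param covariates Adjustment set (default [default_covariates()]); sex is
#'   never included because models run within sex strata.
#' @return Tibble of class `association_table`: one row per index x sex x
#'   outcome with `or_unadj`, `ci_unadj_lo/hi`, `p_unadj`, `or_adj`,
#'   `ci_adj_lo/hi`, `p_adj`, `n`, `n_excluded`, `flag` (empty, or
#'   "separation"/"not_converged"/"undefined").
#' @examples
#' cohort <- generate_cohort(n = 600, seed = 2) |>
#'   compute_index_panel() |> mets_components()
#' battery <- roc_battery(cohort, indices = c("lap", "tyg_wc"))
#' association_table(cohort, battery, outcomes = "mets")
#' @export
association_table <- function(data, cutpoints,
                              outcomes = c("mets", "elevated_tg", "low_hdl",
                                           "elevated_bp", "elevated_fpg"),
                              covariates = default_covariates()) {
  if (!all(c("index", "sex", "optimal_cutoff") %in% names(cutpoints))) {
    abort("association_table: cutpoints needs columns index, sex, optimal_cutoff.")
  }
  if (!all(outcomes %in% names(data))) data <- mets_components(data)
  covariates <- intersect(covariates, names(data))
  data <- tibble::as_tibble(data)

  grid <- cutpoints |>
    dplyr::select("index", "sex", "optimal_cutoff") |>
    tidyr::expand_grid(outcome = outcomes)

  rows <- purrr::pmap(grid, function(index, sex, optimal_cutoff, outcome) {
    stratum <- data[as.character(data$sex) == sex, , drop = FALSE]
    stratum$.exposure <- dichotomize_index(stratum[[index]], optimal_cutoff)
    stratum$.outcome <- as.logical(stratum[[outcome]])
    base <- tibble::tibble(index = index, sex = sex, outcome = outcome,
                           cutoff = optimal_cutoff)
    cells <- with(stratum, table(factor(.exposure, c(FALSE, TRUE)),
                                 factor(.outcome, c(FALSE, TRUE))))
    if (any(cells == 0)) {
      return(dplyr::mutate(base, or_unadj = NA_real_, ci_unadj_lo = NA_real_,
                           ci_unadj_hi = NA_real_, p_unadj = NA_real_,
                           or_adj = NA_real_, ci_adj_lo = NA_real_,
                           ci_adj_hi = NA_real_, p_adj = NA_real_,
                           n = nrow(stratum), n_excluded = NA_integer_,
                           flag = "undefined"))
    }
    unadj <- fit_logistic(.outcome ~ .exposure, stratum)
    adj_formula <- stats::reformulate(c(".exposure", covariates),
                                      response = ".outcome")
    adj <- fit_logistic(adj_formula, stratum)
    row_of <- function(f) dplyr::filter(tidy(f), .data$term == ".exposureTRUE")
    u <- row_of(unadj)
    a <- row_of(adj)
    flag <- c(
      if (adj$separation || unadj$separation) "separation",
      if (!adj$converged || !unadj$converged) "not_converged"
    )
    dplyr::mutate(base,
      or_unadj = u$odds_ratio, ci_unadj_lo = u$or_ci_lo,
      ci_unadj_hi = u$or_ci_hi, p_unadj = u$p_value,
      or_adj = a$odds_ratio, ci_adj_lo = a$or_ci_lo,
      ci_adj_hi = a$or_ci_hi, p_adj = a$p_value,
      n = adj$n, n_excluded = adj$n_excluded,
      flag = paste(flag, collapse = ";")
    )
  }) |> purrr::list_rbind()

  class(rows) <- c("association_table", class(rows))
  rows
}

#' Format a p-value the way the association tables print it
#'
#' Values below 0.001 print as "<0.001" rather than as machine zeros.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}
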
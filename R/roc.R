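check_two_classes <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length.")
  }
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort("Both classes must be present to build a ROC curve.")
  }
  list(scores = scores, labels = labels, n_dropped = sum(!keep))
}

#' Empirical ROC curve
#'
#' The empirical operating points for the rule `score >= cutoff` declares
#' positive, with candidate cut-offs at midpoints between consecutive
#' distinct score values plus infinite sentinels. Cut-offs are returned in
#' descending order, so sensitivity is non-decreasing down the rows and the
#' curve runs from (0, 0) to (1, 1) in (1 - specificity, sensitivity) space.
#'
#' @param scores Numeric vector; higher values are assumed to indicate
#'   disease (no automatic direction flip).
#' @param labels Logical (or 0/1) vector of true disease status.
#' @return Tibble with columns `cutoff`, `sens`, `spec` plus attributes
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  d <- check_two_classes(scores, labels)
  o <- order(d$scores, decreasing = TRUE)
  s <- d$scores[o]
  l <- d$labels[o]
  n_pos <- sum(l)
  n_neg <- sum(!l)
  # index of the last observation in each block of tied scores
  block_end <- c(which(diff(s) != 0), length(s))
  v <- s[block_end] # distinct values, descending
  cutoffs <- c(Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, -Inf)
  tp <- c(0, cumsum(l)[block_end])
  fp <- c(0, cumsum(!l)[block_end])
  out <- tibble::tibble(
    cutoff = cutoffs,
    sens = tp / n_pos,
    spec = (n_neg - fp) / n_neg
  )
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  out
}

#' Mann-Whitney AUC with standard error and 95% CI
#'
#' The area under the empirical ROC curve computed as the Mann-Whitney
#' two-sample statistic: the proportion of case-control pairs where the case
#' outscores the control, ties counted half. The standard error uses the
#' Hanley-McNeil rank-based formula by default, with the DeLong
#' placement-variance estimator available; the 95% CI is the Wald interval
#' AUC +- 1.96 SE clipped to \[0, 1\].
#'
#' @inheritParams roc_curve
#' @param se_method `"hanley"` (default) or `"delong"`.
#' @return Tibble row with `auc`, `auc_se`, `ci_lo`, `ci_hi`, `n_pos`, `n_neg`.
#' @examples
#' auc_mann_whitney(c(1, 2, 3, 4), c(0, 1, 0, 1))
#' @export
auc_mann_whitney <- function(scores, labels, se_method = c("hanley", "delong")) {
  se_method <- match.arg(se_method)
  d <- check_two_classes(scores, labels)
  n_pos <- sum(d$labels)
  n_neg <- sum(!d$labels)
  r <- rank(d$scores) # midranks handle ties
  auc <- (sum(r[d$labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  if (se_method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                  (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  } else {
    # DeLong: variance from per-observation placements
    x <- d$scores[d$labels]
    y <- d$scores[!d$labels]
    v10 <- vapply(x, function(xi) mean(xi > y) + 0.5 * mean(xi == y), numeric(1))
    v01 <- vapply(y, function(yi) mean(x > yi) + 0.5 * mean(x == yi), numeric(1))
    se <- sqrt(stats::var(v10) / n_pos + stats::var(v01) / n_neg)
  }
  tibble::tibble(
    auc = auc,
    auc_se = se,
    ci_lo = max(0, auc - 1.96 * se),
    ci_hi = min(1, auc + 1.96 * se),
    n_pos = n_pos,
    n_neg = n_neg
  )
}

#' AUC accuracy band
#'
#' Conventional interpretation bands: above 0.9 high accuracy, 0.7-0.9
#' moderate, 0.5-0.7 low, 0.5 and below chance.
#'
#' @param auc Numeric vector of AUC values.
#' @return Character vector in `{"high","moderate","low","chance"}`.
#' @export
accuracy_band <- function(auc) {
  dplyr::case_when(
    auc > 0.9 ~ "high",
    auc > 0.7 ~ "moderate",
    auc > 0.5 ~ "low",
    TRUE ~ "chance"
  )
}

#' Diagnostic metrics at a fixed cut-off
#'
#' Standard 2x2 metrics for the rule `score >= cutoff` declares positive:
#' sensitivity, specificity, predictive values, likelihood ratios and the
#' Youden J. Metrics whose denominator is an empty cell are returned as `NA`
#' with a warning rather than silently as NaN.
#'
#' @inheritParams roc_curve
#' @param cutoff The classification threshold.
#' @return One-row tibble: `cutoff`, `tp`, `fp`, `tn`, `fn`, `sens`, `spec`,
#'   `ppv`, `npv`, `lr_pos`, `lr_neg`, `youden_j`.
#' @export
diagnostic_metrics <- function(scores, labels, cutoff) {
  d <- check_two_classes(scores, labels)
  pred <- d$scores >= cutoff
  tp <- sum(pred & d$labels)
  fp <- sum(pred & !d$labels)
  fn <- sum(!pred & d$labels)
  tn <- sum(!pred & !d$labels)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("diagnostic_metrics: %s undefined (zero denominator).", what))
      return(NA_real_)
    }
    num / den
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sens = sens, spec = spec,
    ppv = safe_div(tp, tp + fp, "PPV"),
    npv = safe_div(tn, tn + fn, "NPV"),
    lr_pos = safe_div(sens, 1 - spec, "LR+"),
    lr_neg = safe_div(1 - sens, spec, "LR-"),
    youden_j = sens + spec - 1
  )
}

#' Youden-optimal screening cut-off
#'
#' Scans the empirical ROC operating points (midpoints between consecutive
#' distinct score values, plus infinite sentinels) and returns the cut-off
#' maximizing the Youden index J = sensitivity + specificity - 1. Ties in J
#' are broken in favour of higher sensitivity (screening context), then of
#' the lower cut-off, so the result is deterministic.
#'
#' @inheritParams roc_curve
#' @param se_method Passed to [auc_mann_whitney()].
#' @return An object of class `youden_cutpoint`: a list with the ROC curve,
#'   the AUC summary, the optimal cut-off and its full diagnostic-metric row.
#'   Use [generics::tidy()] / [generics::glance()] for tibble views.
#' @examples
#' fit <- youden_cutpoint(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' tidy(fit)
#' @export
youden_cutpoint <- function(scores, labels, se_method = "hanley") {
  d <- check_two_classes(scores, labels)
  curve <- roc_curve(d$scores, d$labels)
  j <- curve$sens + curve$spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) {
    best <- best[curve$sens[best] == max(curve$sens[best])]
    if (length(best) > 1) best <- best[which.min(curve$cutoff[best])]
  }
  cutoff <- curve$cutoff[[best]]
  auc <- auc_mann_whitney(d$scores, d$labels, se_method = se_method)
  metrics <- diagnostic_metrics(d$scores, d$labels, cutoff)
  structure(
    list(curve = curve, auc = auc, optimal_cutoff = cutoff,
         metrics = metrics, n_dropped = d$n_dropped),
    class = "youden_cutpoint"
  )
}

#' @export
print.youden_cutpoint <- function(x, ...) {
  cat("Youden-optimal cut-point\n")
  cat(sprintf("  AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f) [%s accuracy]\n",
              x$auc$auc, x$auc$auc_se, x$auc$ci_lo, x$auc$ci_hi,
              accuracy_band(x$auc$auc)))
  cat(sprintf("  cut-off %.3f: J %.3f, sens %.3f, spec %.3f, LR+ %.3f, LR- %.3f\n",
              x$optimal_cutoff, x$metrics$youden_j, x$metrics$sens,
              x$metrics$spec, x$metrics$lr_pos, x$metrics$lr_neg))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname youden_cutpoint
#' @param x A `youden_cutpoint` object.
#' @param ... Unused.
#' @export
#' @method tidy youden_cutpoint
tidy.youden_cutpoint <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(optimal_cutoff = x$optimal_cutoff),
    dplyr::select(x$metrics, "youden_j", "sens", "spec", "ppv", "npv",
                  "lr_pos", "lr_neg"),
    dplyr::select(x$auc, "auc", "auc_se", "ci_lo", "ci_hi")
  ) |>
    dplyr::mutate(accuracy_band = accuracy_band(.data$auc))
}

#' @rdname youden_cutpoint
#' @export
#' @method glance youden_cutpoint
glance.youden_cutpoint <- function(x, ...) {
  tibble::tibble(
    auc = x$auc$auc, auc_se = x$auc$auc_se,
    n_pos = x$auc$n_pos, n_neg = x$auc$n_neg,
    n_dropped = x$n_dropped
  )
}

#' ROC battery over all indices, stratified by sex
#'
#' Runs [youden_cutpoint()] for every index column against the MetS outcome
#' within each sex stratum: one row per index per sex, ranked by AUC within
#' sex. Records with a missing score are excluded from that index's ROC only,
#' with the count reported in `n_dropped`.
#'
#' @param data Cohort tibble carrying the index columns and the outcome.
#' @param indices Character vector of index column names
#'   (default [index_names()]).
#' @param outcome Name of the logical outcome column (default `"mets"`;
#'   computed via [mets_components()] if absent).
#' @param se_method Passed to [auc_mann_whitney()].
#' @return Tibble of class `roc_battery` with one row per index x sex:
#'   `index`, `sex`, `auc`, `auc_se`, `ci_lo`, `ci_hi`, `accuracy_band`,
#'   `optimal_cutoff`, `youden_j`, `sens`, `spec`, `ppv`, `npv`, `lr_pos`,
#'   `lr_neg`, `auc_rank`, `n_pos`, `n_neg`, `n_dropped`.
#' @examples
#' cohort <- generate_cohort(n = 400, seed = 1)
#' battery <- cohort |> compute_index_panel() |> mets_components() |> roc_battery()
#' dplyr::filter(battery, sex == "male") |> dplyr::arrange(auc_rank)
#' @export
roc_battery <- function(data, indices = index_names(), outcome = "mets",
                        se_method = "hanley") {
  if (!outcome %in% names(data)) data <- mets_components(data)
  missing <- setdiff(indices, names(data))
  if (length(missing) > 0) {
    abort(paste0("roc_battery: index column(s) not found: ",
                 paste(missing, collapse = ", "),
                 ". Run compute_index_panel() first."))
  }
  strata <- split(tibble::as_tibble(data), as.character(data$sex))
  rows <- purrr::map(names(strata), function(sx) {
    stratum <- strata[[sx]]
    purrr::map(indices, function(ix) {
      fit <- tryCatch(
        youden_cutpoint(stratum[[ix]], stratum[[outcome]], se_method = se_method),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(tibble::tibble(index = ix, sex = sx, error = TRUE))
      }
      dplyr::bind_cols(
        tibble::tibble(index = ix, sex = sx, error = FALSE),
        tidy(fit),
        dplyr::select(glance(fit), "n_pos", "n_neg", "n_dropped")
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  out <- rows |>
    dplyr::group_by(.data$sex) |>
    dplyr::mutate(auc_rank = rank(-.data$auc, ties.method = "min")) |>
    dplyr::ungroup()
  class(out) <- c("roc_battery", class(out))
  out
}
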
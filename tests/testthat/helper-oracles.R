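# Independent oracles used to validate the ROC machinery. Deliberately naive:
# pairwise enumeration and exhaustive threshold scans, never the package path.

brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

trapezoid_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  fpr <- tpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- scores >= thresholds[i]
    tpr[i] <- sum(pred & labels) / sum(labels)
    fpr[i] <- sum(pred & !labels) / sum(!labels)
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Exhaustive scan over every threshold that yields a distinct classification:
# all midpoints, all observed values, and sentinels. Returns the maximum J.
brute_max_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  v <- sort(unique(scores))
  cands <- unique(c(-Inf, v, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf))
  best <- -Inf
  for (ct in cands) {
    pred <- scores >= ct
    j <- sum(pred & labels) / sum(labels) +
      sum(!pred & !labels) / sum(!labels) - 1
    if (j > best) best <- j
  }
  best
}

# One-row cohort record with physiologic defaults, overridable per field.
make_record <- function(...) {
  defaults <- list(
    id = "X1", sex = "male", age = 60, height = 1.70, weight = 70,
    wc = 85, tg = 1.2, hdl = 1.3, fpg = 5.0, sbp = 120, dbp = 75,
    antihypertensive_med = FALSE, antidiabetic_med = FALSE,
    diabetes_history = FALSE
  )
  over <- list(...)
  defaults[names(over)] <- over
  tibble::as_tibble(defaults)
}

mgdl <- function(value, analyte) {
  convert_analyte(value, analyte, from = "mg_dL", to = "mmol_L")
}
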
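test_that("BMI and waist-to-height ratio match hand-evaluated values", {
  expect_equal(compute_bmi(70, 1.70), 70 / 1.70^2)
  expect_equal(compute_bmi(81, 1.80), 25.0)
  expect_equal(compute_whtr(85, 1.70), 0.5)
  expect_equal(compute_whtr(90, 1.60), 0.5625)
  h <- 1.63
  expect_equal(compute_whtr(0.5 * h * 100, h), 0.5)
  expect_error(compute_bmi(-70, 1.70))
  expect_error(compute_whtr(85, 0))
})

test_that("VAI reproduces hand evaluation and its unity normalization", {
  expect_equal(compute_vai("male", 90, 24.221, 1.7, 1.2),
               (90 / (39.68 + 1.88 * 24.221)) * (1.7 / 1.03) * (1.31 / 1.2))
  expect_equal(compute_vai("male", 90, 24.221, 1.7, 1.2), 1.903,
               tolerance = 5e-4)
  bmi <- 24
  expect_equal(compute_vai("male", 39.68 + 1.88 * bmi, bmi, 1.03, 1.31), 1.0)
  expect_equal(compute_vai("female", 36.58 + 1.89 * bmi, bmi, 0.81, 1.52), 1.0)
  expect_error(compute_vai("other", 90, 24, 1.7, 1.2))
})

test_that("ABSI is on the x100 scale that gives population values near 8", {
  expect_equal(compute_absi(85, 24.221, 1.70),
               100 * 0.85 / (24.221^(2 / 3) * sqrt(1.70)))
  expect_equal(compute_absi(85, 24.221, 1.70), 7.787, tolerance = 5e-4)
  expect_equal(compute_absi(100, 25, 1.00), 100 / 25^(2 / 3), tolerance = 1e-9)
  # raw ratio 0.08 maps to 8.0 under the scale constant
  bmi <- 22; h <- 1.6
  wc_cm <- 0.08 * bmi^(2 / 3) * sqrt(h) * 100
  expect_equal(compute_absi(wc_cm, bmi, h), 8.0)
})

test_that("BRI matches hand evaluation and its geometric boundaries", {
  expect_equal(compute_bri(85, 1.70), 3.358, tolerance = 5e-4)
  # radicand 0: waist circle radius equals half the height
  h <- 1.7
  expect_equal(compute_bri(100 * pi * h, h), 364.2)
  # waist -> 0 limit: 364.2 - 365.5
  expect_equal(compute_bri(1e-9, 1.7), 364.2 - 365.5, tolerance = 1e-6)
  expect_error(compute_bri(100 * pi * 1.7 + 5, 1.7), "radicand")
})

test_that("LAP applies sex offsets and keeps negative products", {
  expect_equal(compute_lap("male", 90, 1.7), 42.5)
  expect_equal(compute_lap("female", 90, 1.7), 54.4)
  expect_equal(compute_lap("female", 58, 2.31), 0)
  expect_lt(compute_lap("male", 60, 1.0), 0) # retained, not clamped
})

test_that("conicity index uses the 0.109 normalization", {
  expect_equal(compute_ci(85, 70, 1.70), 0.85 / (0.109 * sqrt(70 / 1.70)))
  expect_equal(compute_ci(85, 70, 1.70), 1.215, tolerance = 5e-4)
  expect_equal(compute_ci(90, 80, 1.60), 0.90 / (0.109 * sqrt(50)),
               tolerance = 1e-12)
  wc_cm <- 0.109 * sqrt(65 / 1.58) * 100
  expect_equal(compute_ci(wc_cm, 65, 1.58), 1.0)
})

test_that("CVAI matches direct evaluation of the sex-specific linear scores", {
  expect_equal(compute_cvai("male", 60, 24.221, 90, 1.7, 1.2),
               -267.93 + 0.68 * 60 + 0.03 * 24.221 + 4 * 90 +
                 22 * log10(1.7) - 16.32 * 1.2)
  expect_equal(compute_cvai("male", 60, 24.221, 90, 1.7, 1.2), 119.0825,
               tolerance = 1e-4)
  expect_equal(compute_cvai("female", 60, 24.221, 90, 1.7, 1.2),
               -187.32 + 1.71 * 60 + 4.32 * 24.221 + 1.12 * 90 +
                 39.76 * log10(1.7) - 11.66 * 1.2)
  # tg = 1 zeroes the log term
  expect_equal(compute_cvai("male", 50, 22, 80, 1.0, 1.2),
               -267.93 + 0.68 * 50 + 0.03 * 22 + 4 * 80 - 16.32 * 1.2)
  expect_error(compute_cvai("male", 60, 24, 90, -1, 1.2))
})

test_that("TyG converts to mg/dL internally and the combos are products", {
  expect_equal(compute_tyg(150 / 88.57, 100 / 18.016), log(7500))
  expect_equal(compute_tyg(150 / 88.57, 100 / 18.016), 8.923, tolerance = 5e-4)
  expect_equal(compute_tyg(1, 5), log(88.57 * 5 * 18.016 / 2))
  expect_equal(compute_tyg(1, 5), 8.291, tolerance = 5e-4)
  # product = 2 mg^2/dL^2 gives exactly 0
  expect_equal(compute_tyg(1 / 88.57, 2 / 18.016), 0)
  combos <- compute_tyg_combos(8.9, 24.0, 90, 0.55)
  expect_equal(unlist(combos), c(tyg_bmi = 213.6, tyg_wc = 801.0,
                                 tyg_whtr = 4.895))
  expect_equal(unlist(compute_tyg_combos(0, 24, 90, 0.55)),
               c(tyg_bmi = 0, tyg_wc = 0, tyg_whtr = 0))
})

test_that("the index panel composes the per-index formulas", {
  rec <- make_record(sex = "male", age = 60, height = 1.70, weight = 70,
                     wc = 90, tg = 1.7, hdl = 1.2, fpg = 5.0)
  panel <- compute_index_panel(rec)
  expect_equal(panel$bmi, 70 / 1.70^2)
  expect_equal(panel$lap, 42.5)
  expect_equal(panel$cvai, 119.0825, tolerance = 1e-4)
  expect_equal(panel$tyg_bmi, panel$tyg * panel$bmi, tolerance = 1e-12)
  expect_equal(panel$tyg_wc, panel$tyg * panel$wc, tolerance = 1e-12)
  expect_equal(panel$tyg_whtr, panel$tyg * panel$whtr, tolerance = 1e-12)
})

test_that("only VAI, LAP and CVAI are sex-specific", {
  rec_m <- make_record(sex = "male")
  rec_f <- make_record(sex = "female")
  pm <- compute_index_panel(rec_m)
  pf <- compute_index_panel(rec_f)
  same <- c("wc", "bmi", "whtr", "absi", "bri", "ci", "tyg",
            "tyg_bmi", "tyg_wc", "tyg_whtr")
  for (ix in same) expect_equal(pm[[ix]], pf[[ix]])
  for (ix in c("vai", "lap", "cvai")) {
    expect_false(isTRUE(all.equal(pm[[ix]], pf[[ix]])))
  }
})

test_that("a record outside the body-roundness domain degrades gracefully", {
  bad <- make_record(id = "bad", wc = 190, height = 0.55, weight = 50)
  both <- dplyr::bind_rows(make_record(), bad)
  expect_warning(panel <- compute_index_panel(both), "body-roundness")
  expect_true(is.na(panel$bri[2]))
  expect_false(is.na(panel$bri[1]))
  expect_false(anyNA(panel$lap))
})

test_that("indices are monotone in their risk directions", {
  set.seed(21)
  for (i in 1:20) {
    sex <- sample(c("male", "female"), 1)
    wc <- runif(1, 70, 110); h <- runif(1, 1.5, 1.85)
    w <- runif(1, 50, 90); tg <- runif(1, 0.5, 4)
    hdl <- runif(1, 0.7, 2.5); fpg <- runif(1, 4, 9); age <- runif(1, 45, 85)
    bmi <- compute_bmi(w, h)
    d_wc <- wc + 1
    expect_gt(compute_lap(sex, d_wc, tg), compute_lap(sex, wc, tg))
    expect_gt(compute_vai(sex, d_wc, bmi, tg, hdl),
              compute_vai(sex, wc, bmi, tg, hdl))
    expect_gt(compute_cvai(sex, age, bmi, d_wc, tg, hdl),
              compute_cvai(sex, age, bmi, wc, tg, hdl))
    expect_gt(compute_whtr(d_wc, h), compute_whtr(wc, h))
    expect_gt(compute_bri(d_wc, h), compute_bri(wc, h))
    expect_gt(compute_tyg(tg + 0.2, fpg), compute_tyg(tg, fpg))
    # VAI and CVAI decrease in HDL
    expect_lt(compute_vai(sex, wc, bmi, tg, hdl + 0.2),
              compute_vai(sex, wc, bmi, tg, hdl))
    expect_lt(compute_cvai(sex, age, bmi, wc, tg, hdl + 0.2),
              compute_cvai(sex, age, bmi, wc, tg, hdl))
  }
})

test_that("vectorized cohort computation equals per-record computation", {
  cohort <- generate_cohort(n = 40, seed = 5)
  batch <- compute_index_panel(cohort)
  serial <- purrr::map(seq_len(nrow(cohort)),
                       function(i) compute_index_panel(cohort[i, ])) |>
    purrr::list_rbind()
  for (ix in index_names()) {
    expect_equal(batch[[ix]], serial[[ix]], tolerance = 1e-12)
  }
})
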
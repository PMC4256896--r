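test_that("urinary creatinine clearance follows the collection formula", {
  expect_equal(crcl_urine(1440, 100, 1.0, 1440), 100)
  expect_equal(crcl_urine(720, 100, 2.0, 1440), 25)
  expect_equal(crcl_urine(0, 100, 1.0, 1440), 0)
  expect_error(crcl_urine(1440, 100, 0, 1440), "positive")
  expect_error(crcl_urine(1440, 100, 1, 0), "positive")
})

test_that("CRRT intensity is effluent flow normalized to weight", {
  expect_equal(crrt_intensity(1400, 1400, 70), 40)
  expect_equal(crrt_intensity(0, 0, 70), 0)
  expect_equal(crrt_intensity(735, 735, 70), 21)
  expect_error(crrt_intensity(100, 100, 0), "positive")
})

test_that("dose bands reproduce the protocol table", {
  expect_equal(daily_dose_per_kg(100), 35)
  expect_equal(daily_dose_per_kg(160), 45)
  expect_equal(daily_dose_per_kg(crrt = TRUE), 14)
  expect_equal(daily_dose_per_kg(crcl = 10), 7)
  expect_equal(daily_dose_per_kg(oliguria = TRUE), 7)
  expect_equal(daily_dose_per_kg(30), 14)
  expect_equal(daily_dose_per_kg(60), 25)
  expect_equal(daily_dose_per_kg(130), 40)
  # documented boundary convention: lower-inclusive bands
  expect_equal(daily_dose_per_kg(25), 14)
  expect_equal(daily_dose_per_kg(50), 25)
  expect_equal(daily_dose_per_kg(80), 35)
  expect_equal(daily_dose_per_kg(120), 40)
  expect_equal(daily_dose_per_kg(150), 40)
  expect_error(daily_dose_per_kg(-5), "non-negative")
  # CRRT overrides any CrCl
  expect_equal(daily_dose_per_kg(crcl = 160, crrt = TRUE), 14)
})

test_that("every non-negative CrCl maps to exactly one dose band", {
  grid <- seq(0, 300, by = 0.5)
  doses <- vapply(grid, daily_dose_per_kg, numeric(1))
  expect_true(all(doses %in% c(7, 14, 25, 35, 40, 45)))
  # piecewise constant with the documented edges
  edges <- grid[which(diff(doses) != 0) + 1]
  expect_equal(edges, c(25, 50, 80, 120, 150.5))
})

test_that("concentration classification partitions [0, Inf)", {
  expect_equal(as.character(classify_concentration(19.9)), "insufficient")
  expect_equal(as.character(classify_concentration(25)), "appropriate")
  expect_equal(as.character(classify_concentration(31)), "excessive")
  # inclusive band edges
  expect_equal(as.character(classify_concentration(20)), "appropriate")
  expect_equal(as.character(classify_concentration(30)), "appropriate")
  grid <- seq(0, 60, by = 0.1)
  cls <- classify_concentration(grid)
  expect_false(anyNA(cls))
  expect_error(classify_concentration(-1), "non-negative")
})

test_that("dose adjustment follows the post-24-h protocol", {
  up <- adjust_dose(15, 1500)
  expect_equal(up$action, "increase")
  expect_equal(up$bolus, 750)
  expect_equal(up$new_daily, 2250)
  none <- adjust_dose(25, 1500)
  expect_equal(none$action, "none")
  expect_equal(none$new_daily, 1500)
  down <- adjust_dose(35, 1500)
  expect_equal(down$action, "decrease")
  expect_equal(down$pause, 6)
  expect_equal(down$new_daily, 750)
  expect_error(adjust_dose(15, 1500, bolus = 400), "\\[500, 1000\\]")
  expect_error(adjust_dose(35, 1500, pause = 10), "\\[4, 8\\]")
  expect_error(adjust_dose(-2, 1500), "negative")
})

test_that("the loading rule is 35 mg/kg for any renal function", {
  expect_equal(loading_dose(70), 2450)
  expect_equal(loading_dose(71), 2485)
  expect_equal(loading_dose(c(71, 70, 80, 70, 80)),
               c(2485, 2450, 2800, 2450, 2800))
})

mk_match_subject <- function(id, crcl = 60, crrt = FALSE, intensity = NA,
                             age = 50, weight = 70, sofa = 10)
  pk_subject(id, weight = weight, age = age, crrt = crrt,
             crrt_intensity = intensity, crcl = crcl, sofa = sofa)

test_that("matching pairs exact copies perfectly and respects ranges", {
  cases <- pk_cohort(list(mk_match_subject("a1", crcl = 64),
                          mk_match_subject("a2", crrt = TRUE,
                                           intensity = 40, crcl = NA)))
  pool <- pk_cohort(list(mk_match_subject("b1", crcl = 64),
                         mk_match_subject("b2", crrt = TRUE,
                                          intensity = 40, crcl = NA)))
  m <- match_controls(cases, pool)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs$control_id[m$pairs$case_id == "a1"], "b1")
  expect_equal(m$pairs$distance, c(0, 0))

  # CrCl 64: candidate at 73 eligible (delta 9), at 80 not (delta 16)
  pool2 <- pk_cohort(list(mk_match_subject("c1", crcl = 73),
                          mk_match_subject("c2", crcl = 80)))
  m2 <- match_controls(pk_cohort(list(mk_match_subject("a1", crcl = 64))),
                       pool2)
  expect_equal(m2$pairs$control_id, "c1")

  # a CRRT case never matches a non-CRRT control
  m3 <- suppressWarnings(match_controls(
    pk_cohort(list(mk_match_subject("a2", crrt = TRUE, intensity = 40,
                                    crcl = NA))),
    pk_cohort(list(mk_match_subject("c1", crcl = 73)))))
  expect_equal(m3$unmatched, "a2")
})

test_that("matching is injective and age-gated; empty pool warns", {
  cases <- pk_cohort(list(mk_match_subject("a1", crcl = 60, age = 40),
                          mk_match_subject("a2", crcl = 60, age = 41)))
  pool <- pk_cohort(list(mk_match_subject("b1", crcl = 62, age = 42),
                         mk_match_subject("b2", crcl = 58, age = 39),
                         mk_match_subject("b3", crcl = 60, age = 70)))
  m <- match_controls(cases, pool)
  expect_equal(nrow(m$pairs), 2)
  expect_false(anyDuplicated(m$pairs$control_id) > 0)
  expect_false("b3" %in% m$pairs$control_id)
  expect_warning(match_controls(cases, pk_cohort(list())), "empty pool")
})
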
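test_that("a one-subject file reads into regimen and observations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ID,TIME,AMT,RATE,DV,EVID,MDV,WT,CRCL,CRRT,ECMO",
    "1,0,2450,612.5,,1,1,70,100,0,1",
    "1,4,0,0,51,0,0,70,100,0,1",
    "1,12,0,0,23,0,0,70,100,0,1",
    "1,24,0,0,20,0,0,70,100,0,1"), path)
  coh <- read_pk_dataset(path)
  expect_length(coh, 1)
  s <- coh$subjects[[1]]
  expect_equal(nrow(s$observations), 3)
  expect_equal(s$regimen$amount, 2450)
  expect_equal(s$regimen$duration, 4)  # from AMT/RATE
  expect_true(s$ecmo)
  expect_false(s$crrt)
  expect_equal(s$weight, 70)
})

test_that("write then read is the identity on field values", {
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(2:5, 1)
    subs <- lapply(seq_len(n), function(i) {
      crrt <- runif(1) < 0.5
      pk_subject(sprintf("S%d", i), weight = runif(1, 50, 100),
                 age = runif(1, 20, 70),
                 sex = sample(c("M", "F"), 1), crrt = crrt,
                 crrt_intensity = if (crrt) runif(1, 20, 50) else NA_real_,
                 crcl = if (crrt) NA_real_ else runif(1, 20, 150),
                 ecmo = runif(1) < 0.5, sofa = sample(1:15, 1),
                 apache2 = sample(5:30, 1), shock = runif(1) < 0.5,
                 regimen = regimen(c(0, 4), c(4, 44),
                                   round(runif(2, 500, 3000), 2)),
                 observations = data.frame(time = c(4, 12, 24),
                                           conc = round(runif(3, 5, 60),
                                                        3)))
    })
    coh <- pk_cohort(subs, label = "synthetic")
    path <- withr::local_tempfile(fileext = ".csv")
    write_pk_dataset(coh, path)
    back <- read_pk_dataset(path)
    expect_length(back, length(coh))
    for (i in seq_len(n)) {
      a <- coh$subjects[[i]]; b <- back$subjects[[i]]
      for (f in c("id", "weight", "age", "sex", "crrt", "ecmo", "sofa",
                  "apache2", "shock"))
        expect_equal(b[[f]], a[[f]], info = f)
      expect_equal(b$crcl, a$crcl)
      expect_equal(b$crrt_intensity, a$crrt_intensity)
      expect_equal(as.data.frame(b$regimen), as.data.frame(a$regimen))
      expect_equal(b$observations, a$observations)
    }
  }
})

test_that("empty data section warns and returns an empty cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("ID,TIME,AMT,RATE,DV,EVID,MDV", path)
  expect_warning(coh <- read_pk_dataset(path), "empty")
  expect_length(coh, 0)
  # empty cohort writes a header-only file
  out <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(pk_cohort(list()), out)
  expect_length(readLines(out), 1)
})

test_that("malformed rows are rejected with their location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,DV,EVID,MDV", "1,0,2450,,1,1"), path)
  expect_error(read_pk_dataset(path), "RATE or DUR")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,DV,EVID,MDV",
               "1,4,0,0,51,0,0",
               "1,2,0,0,23,0,0"), path2)
  expect_error(read_pk_dataset(path2), "non-monotone TIME.*line 3")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,DV,EVID,MDV",
               "1,0,2450,,,1,1",
               "1,4,0,0,51,0,0"), path3)
  expect_error(read_pk_dataset(path3), "AMT without RATE/DUR.*line 2")

  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,DV,EVID,MDV,WT",
               "1,0,2450,612.5,,1,1,70",
               "1,4,0,0,51,0,0,75"), path4)
  expect_error(read_pk_dataset(path4), "varies within subject")
})

test_that("generated cohorts round-trip through the event-record format", {
  coh <- generate_cohort(cohort_design(n_ecmo = 3, n_control = 3,
                                       seed = 19))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(coh, path)
  back <- read_pk_dataset(path, label = "synthetic")
  expect_length(back, 6)
  for (i in 1:6) {
    expect_equal(back$subjects[[i]]$observations$conc,
                 coh$subjects[[i]]$observations$conc, tolerance = 1e-9)
    expect_equal(back$subjects[[i]]$regimen$amount,
                 coh$subjects[[i]]$regimen$amount, tolerance = 1e-9)
  }
})

test_that("configuration files define the model and demand explicit
          units", {
  cfg <- list(
    units = list(time = "hours", concentration = "mg/L"),
    model = list(
      theta = list(CL = 3, Vc = 40, Vp = 40, Q = 3),
      bsv = list(CL = 0.1, Vc = 0.2, Vp = 0.5),
      ruv = list(model = "exponential", sigma2 = 0.02),
      covariates = list(list(name = "crrt_CL", covariate = "crrt",
                             form = "multiplier", value = 0.8))),
    control = list(outer_iter = 200),
    seed = 7)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  got <- read_pk_config(yml)
  expect_equal(unname(unclass(got$model$theta)), c(3, 40, 40, 3))
  expect_equal(got$model$covariates[[1]]$value, 0.8)
  expect_equal(got$model$omega2, c(CL = 0.1, Vc = 0.2, Vp = 0.5))
  expect_equal(got$control$outer_iter, 200)
  expect_equal(got$seed, 7L)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, js, auto_unbox = TRUE)
  got2 <- read_pk_config(js)
  expect_equal(got2$model$sigma2, got$model$sigma2)
  # missing units block is rejected
  cfg$units <- NULL
  yaml::write_yaml(cfg, yml)
  expect_error(read_pk_config(yml), "units")
})
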
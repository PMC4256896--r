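test_that("typical clearance applies the dichotomous CRRT multiplier", {
  expect_equal(typical_clearance(3.7, cl_crrt = 1, cl_nocrrt = 1,
                                 on_crrt = FALSE), 3.7)
  expect_equal(typical_clearance(3.7, cl_crrt = 0.6, on_crrt = TRUE), 2.22)
  # identity multipliers leave CL unchanged under either flag
  for (cl in c(0.5, 2.4, 3.7))
    for (flag in c(TRUE, FALSE))
      expect_equal(typical_clearance(cl, 1, 1, flag), cl)
  expect_error(typical_clearance(-1, 1, 1, TRUE), "positive")
  expect_error(typical_clearance(3.7, 0, 1, TRUE), "positive")
})

test_that("individual parameters follow the exponential BSV model", {
  typ <- pk_parameters(3.7, 31.8, 57.1, 3.6)
  expect_equal(unclass(individual_parameters(typ, c(CL = 0, Vc = 0,
                                                    Vp = 0))),
               unclass(typ))
  dbl <- individual_parameters(typ, c(CL = log(2)))
  expect_equal(unname(dbl["CL"]), 7.4)
  expect_equal(unname(dbl[c("Vc", "Vp", "Q")]), c(31.8, 57.1, 3.6))
  expect_equal(unname(individual_parameters(typ,
                                            c(CL = -0.5108))["CL"]),
               3.7 * exp(-0.5108))
  expect_error(individual_parameters(typ, c(Q = 1)), "named from")
})

test_that("profile matches the one-compartment closed form as Q -> 0", {
  p <- pk_parameters(3.7, 31.8, 57.1, 1e-10)
  reg <- regimen(0, 4, 2450)
  tt <- c(1, 2, 4)
  got <- concentration_profile(p, reg, tt)
  expected <- (612.5 / 3.7) * (1 - exp(-3.7 * tt / 31.8))
  expect_equal(got, expected, tolerance = 1e-6)
  expect_equal(got[3], 61.6, tolerance = 1e-3)
})

test_that("long-run continuous infusion approaches rate/CL", {
  p <- pk_parameters(3.7, 31.8, 57.1, 3.6)
  # ~ 10 terminal half-lives
  reg <- regimen(0, 300, 102.08 * 300)
  expect_equal(concentration_profile(p, reg, 300), 102.08 / 3.7,
               tolerance = 1e-3)
  expect_equal(steady_state_concentration(102.08, 3.7), 27.59,
               tolerance = 1e-3)
  expect_equal(steady_state_concentration(0, 3.7), 0)
  expect_equal(steady_state_concentration(3.7, 3.7), 1)
  expect_error(steady_state_concentration(10, 0), "positive")
})

test_that("closed form agrees with the ODE integrator on random draws", {
  set.seed(42)
  for (rep in 1:10) {
    p <- pk_parameters(CL = runif(1, 1, 8), Vc = runif(1, 10, 60),
                       Vp = runif(1, 20, 150), Q = runif(1, 0.5, 10))
    n_ev <- sample(1:3, 1)
    reg <- regimen(start = sort(runif(n_ev, 0, 24)),
                   duration = runif(n_ev, 0.5, 30),
                   amount = runif(n_ev, 200, 3000))
    tt <- sort(runif(8, 0, 72))
    a <- concentration_profile(p, reg, tt)
    b <- concentration_profile(p, reg, tt, method = "ode")
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("profiles superpose and scale with dose (linear system)", {
  p <- pk_parameters(3.7, 31.8, 57.1, 3.6)
  r1 <- regimen(0, 4, 2450)
  r2 <- regimen(4, 44, 1925)
  r12 <- regimen(c(0, 4), c(4, 44), c(2450, 1925))
  tt <- seq(0, 48, by = 1.5)
  c1 <- concentration_profile(p, r1, tt)
  c2 <- concentration_profile(p, r2, tt)
  c12 <- concentration_profile(p, r12, tt)
  expect_equal(c12, c1 + c2, tolerance = 1e-9)
  dbl <- concentration_profile(p, regimen(c(0, 4), c(4, 44),
                                          2 * c(2450, 1925)), tt)
  expect_identical(dbl, 2 * c12)
})

test_that("profile is non-negative and strictly falls after infusions end", {
  p <- pk_parameters(2.4, 40, 60, 4)
  reg <- regimen(c(0, 4), c(4, 20), c(2450, 1500))
  tt <- seq(0, 96, by = 0.5)
  prof <- concentration_profile(p, reg, tt)
  expect_true(all(prof >= 0))
  post <- prof[tt > 24.5]
  expect_true(all(diff(post) < 0))
})

test_that("empty regimen yields a zero profile and input checks fire", {
  p <- pk_parameters(3.7, 31.8, 57.1, 3.6)
  expect_identical(concentration_profile(p, regimen(), c(0, 12, 24)),
                   c(0, 0, 0))
  expect_error(concentration_profile(p, regimen(0, 4, 100), c(4, 2)),
               "sorted")
  expect_error(concentration_profile(p, regimen(0, 4, 100), c(-1, 2)),
               "non-negative")
})

test_that("trapezoidal AUC matches hand-computed values", {
  expect_equal(auc_trapezoid(c(0, 24), c(20, 20)), 480)
  expect_equal(auc_trapezoid(c(0, 24), c(0, 24)), 288)
  # origin prepended for drug-naive subjects: 102 + 296 + 258
  expect_equal(auc_trapezoid(c(4, 12, 24), c(51, 23, 20)), 656)
  # window restriction to 24 h
  expect_equal(auc_trapezoid(c(4, 12, 24, 48), c(51, 23, 20, 10)), 656)
  expect_error(auc_trapezoid(c(0), c(5)), "two points")
  expect_error(auc_trapezoid(c(4, 2), c(1, 2)), "increasing")
})

test_that("regimen and parameter validators reject bad input", {
  expect_error(regimen(0, 0, 100), "positive")
  expect_error(regimen(0, 4, -5), "non-negative")
  expect_error(pk_parameters(0, 31.8, 57.1, 3.6), "positive")
  p <- pk_parameters(3.7, 31.8, 57.1, 3.6)
  expect_true(p["Vc"] + p["Vp"] > max(p["Vc"], p["Vp"]))
})
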
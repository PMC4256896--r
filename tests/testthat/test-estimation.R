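toy_model <- function(omega2 = c(CL = 0.3^2), sigma2 = 0.1^2)
  population_model(theta = pk_parameters(3.7, 31.8, 57.1, 3.6),
                   omega2 = omega2, sigma2 = sigma2)

test_that("joint -2 log-likelihood reduces to its penalty terms on
          noise-free data at the prior mode", {
  m <- toy_model()
  s <- make_subject()  # observations equal the typical prediction
  g <- subject_neg2loglik(m, s, 0)
  expected <- 3 * log(2 * pi * m$sigma2) + log(2 * pi * m$omega2[["CL"]])
  expect_equal(g, unname(expected), tolerance = 1e-10)
  # doubling sigma2 changes the value per the Gaussian closed form
  m2 <- toy_model(sigma2 = 2 * 0.1^2)
  expect_equal(subject_neg2loglik(m2, s, 0) - g, 3 * log(2),
               tolerance = 1e-10)
})

test_that("compiled joint likelihood agrees with an independent R oracle", {
  m <- toy_model(omega2 = c(CL = 0.2^2, Vc = 0.4^2, Vp = 0.8^2))
  set.seed(8)
  s <- make_subject(conc = c(45, 25, 18))
  for (rep in 1:5) {
    eta <- rnorm(3, 0, 0.4)
    expect_equal(subject_neg2loglik(m, s, eta),
                 joint_neg2ll_oracle(m, s, eta), tolerance = 1e-6)
  }
  expect_error(subject_neg2loglik(m, s, c(0, 0)), "declares 3")
})

test_that("with zero BSV the OFV is exactly the fixed-effect -2LL", {
  m <- population_model(theta = pk_parameters(3.7, 31.8, 57.1, 3.6),
                        omega2 = numeric(), sigma2 = 0.1^2)
  subs <- list(make_subject("a", conc = c(50, 24, 19)),
               make_subject("b", maintenance = 35, conc = c(60, 35, 30)))
  coh <- pk_cohort(subs, label = "synthetic")
  ofv <- marginal_ofv(m, coh)
  # direct evaluation, no integral to approximate
  direct <- 0
  for (s in subs) {
    f <- concentration_profile(m$theta, s$regimen, s$observations$time)
    r <- log(s$observations$conc) - log(f)
    direct <- direct + sum(log(2 * pi * m$sigma2) + r^2 / m$sigma2)
  }
  expect_equal(ofv, direct, tolerance = 1e-10)
})

test_that("Laplace OFV matches adaptive quadrature on 1-eta subjects", {
  skip_if_not_installed("pracma")
  m <- toy_model()
  s1 <- make_subject("a", maintenance = 15, conc = c(55, 22, 16))
  s2 <- make_subject("b", maintenance = 35, conc = c(70, 40, 33))
  coh <- pk_cohort(list(s1, s2), label = "synthetic")
  lap <- marginal_ofv(m, coh)
  agq <- agq_subject_ofv(m, s1) + agq_subject_ofv(m, s2)
  expect_lt(abs(lap - agq), 0.1)
})

test_that("FOCE-I and Laplace agree closely on a mild toy problem", {
  m <- toy_model(omega2 = c(CL = 0.15^2), sigma2 = 0.08^2)
  coh <- pk_cohort(list(make_subject("a", conc = c(50, 24, 18)),
                        make_subject("b", conc = c(47, 21, 15))),
                   label = "synthetic")
  expect_lt(abs(marginal_ofv(m, coh, "laplace") -
                marginal_ofv(m, coh, "foce_i")), 0.5)
})

test_that("an uninformative covariate leaves the OFV unchanged", {
  m <- toy_model()
  m1 <- m
  m1$covariates <- list(covariate_effect("ecmo_CL", "ecmo", "CL",
                                         "multiplier", value = 1))
  coh <- pk_cohort(list(make_subject("a", conc = c(50, 24, 18)),
                        make_subject("b", conc = c(47, 21, 15))),
                   label = "synthetic")
  expect_lt(abs(marginal_ofv(m, coh) - marginal_ofv(m1, coh)), 1e-9)
})

test_that("empirical-Bayes estimates sit at the prior mode when data are
          absent, exact, or uninformative", {
  m <- toy_model(omega2 = c(CL = 0.2^2, Vc = 0.4^2, Vp = 0.8^2))
  s_none <- make_subject()
  s_none$observations <- data.frame(time = numeric(), conc = numeric())
  expect_equal(unname(empirical_bayes(m, s_none)), c(0, 0, 0))
  # noise-free data generated at eta = 0
  eb <- empirical_bayes(m, make_subject())
  expect_equal(unname(eb), c(0, 0, 0), tolerance = 1e-5)
  # shrinkage: enormous residual variance pulls eta to 0 for any data
  m_huge <- toy_model(omega2 = c(CL = 0.2^2), sigma2 = 1e6)
  eb2 <- empirical_bayes(m_huge, make_subject(conc = c(80, 50, 40)))
  expect_equal(unname(eb2), 0, tolerance = 1e-3)
})

test_that("the nested-model test uses the 3.84 inclusive threshold", {
  expect_true(lrt_nested(105.774, 100))
  expect_false(lrt_nested(103.83, 100))
  expect_true(lrt_nested(103.84, 100))
  expect_warning(sig <- lrt_nested(99, 100), "negative")
  expect_false(sig)
  expect_equal(attr(lrt_nested(105, 100), "threshold"), 3.84)
  expect_error(lrt_nested(10, 5, df = 0), "df")
})

test_that("noise-free zero-BSV data identify the generating parameters", {
  gen <- population_model(theta = pk_parameters(3.7, 31.8, 57.1, 3.6),
                          omega2 = numeric(), sigma2 = 0)
  des <- cohort_design(n_ecmo = 3, n_control = 3, seed = 7, model = gen,
                       sampling_times = c(1, 4, 8, 12, 24, 48),
                       horizon = 72)
  coh <- generate_cohort(des)
  init <- population_model(theta = pk_parameters(3, 40, 40, 3),
                           omega2 = numeric(), sigma2 = 0.01)
  fit <- fit_population(coh, init)
  expect_equal(as.numeric(fit$model$theta), c(3.7, 31.8, 57.1, 3.6),
               tolerance = 1e-4)
})

test_that("refitting from the optimum does not increase the OFV and the
          fit is invariant to subject order", {
  des <- cohort_design(n_ecmo = 4, n_control = 4, seed = 3,
                       model = generating_model(NULL))
  coh <- generate_cohort(des)
  init <- population_model(theta = pk_parameters(3, 40, 40, 3),
                           omega2 = c(CL = 0.1), sigma2 = 0.02)
  fit <- fit_population(coh, init)
  refit <- fit_population(coh, fit$model)
  expect_lte(refit$ofv, fit$ofv + 1e-3)
  # permuted ids and order give the same OFV
  perm <- rev(coh$subjects)
  for (i in seq_along(perm)) perm[[i]]$id <- sprintf("P%d", i)
  ofv1 <- marginal_ofv(fit$model, coh)
  ofv2 <- marginal_ofv(fit$model, pk_cohort(perm, label = "synthetic"))
  expect_equal(ofv1, ofv2, tolerance = 1e-9)
})
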
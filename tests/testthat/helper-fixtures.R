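# shared fixtures and independent oracles for the test suite

# final-model reference values (fixed effects, BSV %CV, RUV %CV)
ref_theta <- c(CL = 3.7, Vc = 31.8, Vp = 57.1, Q = 3.6)
ref_crrt_mult <- 0.6
ref_bsv_cv <- c(CL = 16.4, Vc = 47.0, Vp = 101.0)
ref_ruv_cv <- 8.5

ref_model <- function(crrt_multiplier = ref_crrt_mult)
  generating_model(crrt_multiplier)

# a simple subject on the protocol regimen
make_subject <- function(id = "s1", weight = 70, crrt = FALSE,
                         maintenance = 15, horizon = 48,
                         times = c(4, 12, 24), conc = NULL) {
  reg <- build_regimen(weight, 35, 4, maintenance, horizon)
  if (is.null(conc)) {
    p <- pk_parameters(3.7, 31.8, 57.1, 3.6)
    conc <- concentration_profile(p, reg, times)
  }
  pk_subject(id, weight = weight, crrt = crrt,
             crrt_intensity = if (crrt) 40 else NA_real_,
             crcl = if (crrt) NA_real_ else 100,
             age = 50, sofa = 10, apache2 = 20,
             regimen = reg,
             observations = data.frame(time = times, conc = conc))
}

# independent R-level evaluation of the joint -2 log density (oracle for
# the compiled likelihood kernel); exponential error model only
joint_neg2ll_oracle <- function(model, subject, eta) {
  nm <- bsv_names(model)
  names(eta) <- nm
  tv <- vancoci::typical_values(model, subject)
  ind <- tv
  ind[nm] <- ind[nm] * exp(eta)
  f <- concentration_profile(
    structure(ind, class = "pk_parameters"), subject$regimen,
    subject$observations$time, method = "ode")
  r <- log(subject$observations$conc) - log(f)
  s2 <- model$sigma2[1]
  obs_term <- sum(log(2 * pi * s2) + r^2 / s2)
  o2 <- model$omega2[nm]
  prior_term <- sum(log(2 * pi * o2) + eta^2 / o2)
  obs_term + prior_term
}

# adaptive Gauss-Hermite quadrature of one subject's -2 log marginal
# likelihood (oracle for the Laplace approximation); single random effect
agq_subject_ofv <- function(model, subject, nq = 40) {
  gh <- pracma::gaussHermite(nq)
  g <- function(eta) subject_neg2loglik(model, subject, eta)
  mu <- stats::optimize(g, c(-6, 6), tol = 1e-10)$minimum
  h <- 1e-4
  H <- (g(mu + h) + g(mu - h) - 2 * g(mu)) / h^2
  sc <- 2 / sqrt(H)  # sqrt(2) * sigma_hat of the Gaussian approximation
  vals <- vapply(gh$x, function(x) exp(-g(mu + sc * x) / 2 + x^2),
                 numeric(1))
  -2 * log(sc * sum(gh$w * vals))
}

# access the internal helpers used by oracles above
bsv_names <- getFromNamespace("bsv_names", "vancoci")
omega2_full <- getFromNamespace("omega2_full", "vancoci")
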
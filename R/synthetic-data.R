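#' Design of a synthetic study cohort
#'
#' Describes the study design the generator emulates: 11 ECMO + 11 matched
#' control subjects dosed per protocol (35 mg/kg loading over 4 h, then the
#' CrCl-banded continuous infusion), sampled at 4, 12 and 24 h, with CRRT
#' in roughly 7 of 11 subjects per arm.  Covariates come from simple
#' parametric families anchored to the study's reported medians and ranges:
#' log-normal weight (median 70 kg), uniform age, log-normal CrCl for
#' subjects off CRRT, log-normal CRRT intensity (median 40 mL/kg/h).
#' Concentrations are generated from the two-compartment model with
#' exponential between-subject and residual variability at the generating
#' model's values.
#'
#' @param n_ecmo,n_control subjects per arm.
#' @param crrt_prevalence probability of CRRT per subject (7/11).
#' @param sampling_times observation times, h.
#' @param horizon end of the maintenance infusion, h (must cover the
#'   sampling times).
#' @param model generating [population_model()]; the default carries the
#'   final covariate model of the analysis (CL 3.7 L/h with CRRT multiplier
#'   0.6, Vc 31.8 L, Vp 57.1 L, Q 3.6 L/h, BSV %CV 16.4/47/101,
#'   exponential RUV 8.5 %CV).
#' @param weight_median,weight_sdlog log-normal weight parameters.
#' @param age_range uniform age band, years.
#' @param crcl_median,crcl_sdlog log-normal CrCl parameters (off-CRRT
#'   subjects).
#' @param intensity_median,intensity_sdlog log-normal CRRT intensity.
#' @param shock_prevalence,male_prevalence Bernoulli rates.
#' @param time_jitter_sd optional jitter (h) on sampling times (default 0).
#' @param seed mandatory integer seed.
#' @return List of class `cohort_design`.
#' @export
cohort_design <- function(n_ecmo = 11, n_control = 11,
                          crrt_prevalence = 7 / 11,
                          sampling_times = c(4, 12, 24), horizon = 48,
                          model = generating_model(),
                          weight_median = 70, weight_sdlog = 0.15,
                          age_range = c(20, 65),
                          crcl_median = 62, crcl_sdlog = 0.35,
                          intensity_median = 40, intensity_sdlog = 0.25,
                          shock_prevalence = 0.64, male_prevalence = 0.41,
                          time_jitter_sd = 0, seed) {
  if (missing(seed)) stop("cohort_design: seed is mandatory", call. = FALSE)
  if (crrt_prevalence < 0 || crrt_prevalence > 1)
    stop("cohort_design: crrt_prevalence must be in [0, 1]", call. = FALSE)
  if (max(sampling_times) > horizon)
    stop("cohort_design: sampling times must lie within the horizon",
         call. = FALSE)
  structure(list(n_ecmo = n_ecmo, n_control = n_control,
                 crrt_prevalence = crrt_prevalence,
                 sampling_times = sampling_times, horizon = horizon,
                 model = model, weight_median = weight_median,
                 weight_sdlog = weight_sdlog, age_range = age_range,
                 crcl_median = crcl_median, crcl_sdlog = crcl_sdlog,
                 intensity_median = intensity_median,
                 intensity_sdlog = intensity_sdlog,
                 shock_prevalence = shock_prevalence,
                 male_prevalence = male_prevalence,
                 time_jitter_sd = time_jitter_sd,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' The generating population model of the synthetic design
#'
#' Final covariate model values used as the default data-generating truth:
#' a dichotomous CRRT multiplier on clearance (0.6), exponential BSV on CL,
#' Vc, Vp, and exponential residual error.
#'
#' @param crrt_multiplier CRRT multiplier on CL.
#' @return A [population_model()].
#' @export
generating_model <- function(crrt_multiplier = 0.6) {
  covs <- if (is.null(crrt_multiplier) || crrt_multiplier == 1) list()
          else list(covariate_effect("crrt_CL", "crrt", "CL", "multiplier",
                                     value = crrt_multiplier))
  population_model(theta = pk_parameters(3.7, 31.8, 57.1, 3.6),
                   covariates = covs,
                   omega2 = c(CL = 0.164^2, Vc = 0.47^2, Vp = 1.01^2),
                   sigma2 = 0.085^2, error_model = "exponential")
}

draw_subject <- function(design, id, ecmo) {
  d <- design
  crrt <- stats::runif(1) < d$crrt_prevalence
  weight <- stats::rlnorm(1, log(d$weight_median), d$weight_sdlog)
  age <- stats::runif(1, d$age_range[1], d$age_range[2])
  crcl <- if (crrt) NA_real_ else stats::rlnorm(1, log(d$crcl_median),
                                                d$crcl_sdlog)
  intensity <- if (crrt) stats::rlnorm(1, log(d$intensity_median),
                                       d$intensity_sdlog) else NA_real_
  sofa <- max(0, round(stats::rnorm(1, 11, 3)))
  apache2 <- max(0, round(stats::rnorm(1, 20, 6)))
  sex <- if (stats::runif(1) < d$male_prevalence) "M" else "F"
  shock <- stats::runif(1) < d$shock_prevalence
  maint <- daily_dose_per_kg(crcl = if (crrt) NULL else crcl, crrt = crrt)
  reg <- build_regimen(weight, loading = 35, loading_duration = 4,
                       maintenance = maint, horizon = d$horizon)
  pk_subject(id, weight = weight, age = age, sex = sex, crrt = crrt,
             crrt_intensity = intensity, crcl = crcl, ecmo = ecmo,
             sofa = sofa, apache2 = apache2, shock = shock, regimen = reg)
}

simulate_observations <- function(subject, model, times, time_jitter_sd) {
  if (time_jitter_sd > 0)
    times <- sort(pmax(0.25, times +
                       stats::rnorm(length(times), 0, time_jitter_sd)))
  o2 <- omega2_full(model)
  eta <- c(CL = stats::rnorm(1, 0, sqrt(o2["CL"])),
           Vc = stats::rnorm(1, 0, sqrt(o2["Vc"])),
           Vp = stats::rnorm(1, 0, sqrt(o2["Vp"])))
  tv <- tv_named(typical_values(model, subject))
  ind <- individual_parameters(tv, eta)
  f <- concentration_profile(ind, subject$regimen, times)
  conc <- switch(model$error_model,
    exponential = f * exp(stats::rnorm(length(f), 0,
                                       sqrt(model$sigma2[1]))),
    additive = f + stats::rnorm(length(f), 0, sqrt(model$sigma2[1])),
    combined = f * exp(stats::rnorm(length(f), 0,
                                    sqrt(model$sigma2[2]))) +
      stats::rnorm(length(f), 0, sqrt(model$sigma2[1])))
  subject$observations <- data.frame(time = times, conc = conc)
  attr(subject, "eta_true") <- eta
  subject
}

#' Generate a synthetic cohort
#'
#' Draws covariates per arm, doses every subject via the clinical rules
#' (35 mg/kg loading over 4 h, then the CrCl-banded or CRRT maintenance
#' dose), draws random effects from `N(0, Omega)`, computes the true
#' concentration profile from the two-compartment model and applies
#' residual error at the sampling times.  Fully reproducible given the
#' design seed.
#'
#' @param design a [cohort_design()].
#' @return A [pk_cohort()] labelled `"synthetic"`; each subject carries its
#'   generating random effects in the attribute `eta_true`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(design$seed)
  subs <- list()
  ids <- c(sprintf("E%02d", seq_len(design$n_ecmo)),
           sprintf("C%02d", seq_len(design$n_control)))
  arms <- c(rep(TRUE, design$n_ecmo), rep(FALSE, design$n_control))
  for (i in seq_along(ids)) {
    s <- draw_subject(design, ids[i], arms[i])
    s <- simulate_observations(s, design$model, design$sampling_times,
                               design$time_jitter_sd)
    subs[[i]] <- s
  }
  pk_cohort(subs, label = "synthetic")
}

#' Generate a synthetic external-validation cohort
#'
#' Five ECMO subjects (three on CRRT, intensity near 21 mL/kg/h, weights
#' near 70-80 kg) dosed and sampled per protocol, mirroring the structure
#' of the prospective validation cohort.
#'
#' @param seed integer seed.
#' @param model generating [population_model()].
#' @param sampling_times observation times, h.
#' @return A [pk_cohort()] of 5 subjects labelled `"synthetic"`.
#' @export
generate_validation_cohort <- function(seed, model = generating_model(),
                                       sampling_times = c(4, 12, 24)) {
  design <- cohort_design(n_ecmo = 5, n_control = 0,
                          crrt_prevalence = 3 / 5,
                          sampling_times = sampling_times,
                          model = model, weight_median = 74,
                          weight_sdlog = 0.06, age_range = c(45, 71),
                          intensity_median = 21, intensity_sdlog = 0.12,
                          seed = seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(design$seed)
  # fix the CRRT mix at exactly 3 of 5
  crrt_flags <- sample(c(TRUE, TRUE, TRUE, FALSE, FALSE))
  subs <- vector("list", 5)
  for (i in 1:5) {
    d <- design
    d$crrt_prevalence <- as.numeric(crrt_flags[i])
    s <- draw_subject(d, sprintf("V%02d", i), ecmo = TRUE)
    subs[[i]] <- simulate_observations(s, model, sampling_times, 0)
  }
  pk_cohort(subs, label = "synthetic")
}
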
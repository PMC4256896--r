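#' A covariate effect on a structural parameter
#'
#' Two functional forms are supported, matching common pharmacometric
#' practice: a dichotomous multiplier for flags (`TV = theta * value^x`,
#' `x` in 0/1), and a power function for continuous covariates normalized
#' to a reference (typically the cohort median):
#' `TV = theta * (cov/ref)^value`.
#'
#' @param name label used in traces and printed model summaries.
#' @param covariate name of the subject field supplying the covariate
#'   (`"crrt"`, `"ecmo"`, `"sex"`, `"shock"`, `"age"`, `"weight"`,
#'   `"crcl"`, `"sofa"`, `"apache2"`).
#' @param parameter target structural parameter, `"CL"` or `"Vc"` (also
#'   accepts `"Vp"`, `"Q"`).
#' @param form `"multiplier"` (flags only) or `"power"` (continuous only).
#' @param value multiplier (> 0) or power exponent; the estimation starting
#'   value when the effect is being fitted.
#' @param ref reference value for the power form (filled with the cohort
#'   median by [fit_population()] when `NA`).
#' @return List of class `covariate_effect`.
#' @export
covariate_effect <- function(name, covariate, parameter = "CL",
                             form = c("multiplier", "power"),
                             value = if (match.arg(form) == "multiplier") 1
                                     else 0,
                             ref = NA_real_) {
  form <- match.arg(form)
  if (!parameter %in% c("CL", "Vc", "Vp", "Q"))
    stop("covariate_effect: parameter must be one of CL, Vc, Vp, Q",
         call. = FALSE)
  flag_covs <- c("crrt", "ecmo", "shock", "sex")
  cont_covs <- c("age", "weight", "crcl", "sofa", "apache2",
                 "crrt_intensity")
  if (form == "multiplier" && !covariate %in% flag_covs)
    stop("covariate_effect: multiplier form is for dichotomous covariates",
         call. = FALSE)
  if (form == "power" && !covariate %in% cont_covs)
    stop("covariate_effect: power form is for continuous covariates",
         call. = FALSE)
  if (form == "multiplier" && (!is.finite(value) || value <= 0))
    stop("covariate_effect: multiplier must be strictly positive",
         call. = FALSE)
  structure(list(name = name, covariate = covariate, parameter = parameter,
                 form = form, value = value, ref = ref),
            class = "covariate_effect")
}

covariate_value <- function(subject, covariate) {
  v <- subject[[covariate]]
  if (covariate == "sex") return(as.numeric(identical(v, "M")))
  if (is.logical(v)) return(as.numeric(isTRUE(v)))
  as.numeric(v)
}

#' Population PK model
#'
#' Bundles the typical two-compartment parameters, the covariate effects in
#' force, the between-subject variance components (log-scale, diagonal) and
#' the residual-error model.
#'
#' @param theta [pk_parameters()] typical values.
#' @param covariates list of [covariate_effect()]s.
#' @param omega2 named non-negative vector over a subset of
#'   `c("CL", "Vc", "Vp")`: log-scale between-subject variances.  `Q` never
#'   carries a random effect.  Parameters absent from `omega2` have none.
#' @param sigma2 residual variance: scalar for `"exponential"` (log-scale)
#'   and `"additive"` (mg/L squared), length-2 `(additive, proportional)`
#'   for `"combined"`.
#' @param error_model `"exponential"`, `"additive"` or `"combined"`.
#' @return List of class `pop_model`.
#' @export
population_model <- function(theta = pk_parameters(3.7, 31.8, 57.1, 3.6),
                             covariates = list(),
                             omega2 = c(CL = 0.164^2, Vc = 0.47^2,
                                        Vp = 1.01^2),
                             sigma2 = 0.085^2,
                             error_model = c("exponential", "additive",
                                             "combined")) {
  error_model <- match.arg(error_model)
  validate_pk_parameters(theta)
  if (length(omega2)) {
    if (is.null(names(omega2)) ||
        !all(names(omega2) %in% c("CL", "Vc", "Vp")))
      stop("population_model: omega2 must be named from CL, Vc, Vp",
           call. = FALSE)
    if (any(omega2 < 0))
      stop("population_model: omega2 must be non-negative", call. = FALSE)
  }
  need <- if (error_model == "combined") 2L else 1L
  if (length(sigma2) != need || any(sigma2 < 0))
    stop("population_model: sigma2 has the wrong length or sign",
         call. = FALSE)
  if (!is.list(covariates) ||
      !all(vapply(covariates, inherits, logical(1), "covariate_effect")))
    stop("population_model: covariates must be covariate_effect objects",
         call. = FALSE)
  structure(list(theta = theta, covariates = covariates,
                 omega2 = omega2, sigma2 = sigma2,
                 error_model = error_model),
            class = "pop_model")
}

#' Per-subject typical parameters under the covariate model
#'
#' @param model a [population_model()].
#' @param subject a [pk_subject()].
#' @return Named numeric `c(CL, Vc, Vp, Q)` after applying every covariate
#'   effect in force.
#' @export
typical_values <- function(model, subject) {
  tv <- as.numeric(model$theta[c("CL", "Vc", "Vp", "Q")])
  names(tv) <- c("CL", "Vc", "Vp", "Q")
  for (ce in model$covariates) {
    x <- covariate_value(subject, ce$covariate)
    fac <- if (ce$form == "multiplier") ce$value^x
           else (x / ce$ref)^ce$value
    tv[ce$parameter] <- tv[ce$parameter] * fac
  }
  tv
}

# full omega2 over (CL, Vc, Vp) with zeros for parameters without BSV
omega2_full <- function(model) {
  full <- c(CL = 0, Vc = 0, Vp = 0)
  full[names(model$omega2)] <- model$omega2
  full
}

bsv_names <- function(model)
  names(omega2_full(model))[omega2_full(model) > 0]

err_code <- function(model)
  match(model$error_model, c("exponential", "additive", "combined")) - 1L

#' @export
print.pop_model <- function(x, ...) {
  cat("Population two-compartment infusion model\n")
  cat(sprintf("  CL %.3g L/h, Vc %.3g L, Vp %.3g L, Q %.3g L/h (Vd %.3g L)\n",
              x$theta["CL"], x$theta["Vc"], x$theta["Vp"], x$theta["Q"],
              x$theta["Vc"] + x$theta["Vp"]))
  for (ce in x$covariates)
    cat(sprintf("  %s: %s on %s = %.3g%s\n", ce$name, ce$form,
                ce$parameter, ce$value,
                if (ce$form == "power") sprintf(" (ref %.3g)", ce$ref)
                else ""))
  if (length(x$omega2))
    cat("  BSV %CV:",
        paste(sprintf("%s %.1f", names(x$omega2),
                      100 * sqrt(x$omega2)), collapse = ", "), "\n")
  cat(sprintf("  RUV (%s): %s\n", x$error_model,
              if (x$error_model == "exponential")
                sprintf("%.1f %%CV", 100 * sqrt(x$sigma2[1]))
              else paste(signif(x$sigma2, 3), collapse = ", ")))
  invisible(x)
}
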